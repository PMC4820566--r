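#' MCMC settings for the Gibbs sampler
#'
#' Defaults: 13,000 iterations, 3,000 burn-in, thinning 10, and a weakly
#' informative scaled-inverse-chi-square prior on each variance component
#' with scale 1 and 0.002 degrees of belief (the conventional default for
#' this model family).
#'
#' @param iterations total Gibbs sweeps.
#' @param burnin sweeps discarded before storage; must be < `iterations`.
#' @param thin store every `thin`-th post-burn-in sweep.
#' @param prior_scale scale (V) of the variance-component prior.
#' @param prior_nu degrees of belief (nu) of the variance-component prior.
#' @param seed integer RNG seed; recorded in all outputs.
#' @return list of settings.
#' @export
mcmc_settings <- function(iterations = 13000, burnin = 3000, thin = 10,
                          prior_scale = 1, prior_nu = 0.002, seed = 1L) {
  if (burnin >= iterations)
    bm_stop("burnin must be smaller than iterations", "bm_domain_error")
  if (thin < 1) bm_stop("thin must be >= 1", "bm_domain_error")
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), prior_scale = prior_scale,
       prior_nu = prior_nu, seed = as.integer(seed))
}

#' Two-tailed posterior zero-crossing probability (pMCMC)
#'
#' pMCMC = 2 * max(1, min(#positive, #negative)) / N, capped at 1. Samples
#' exactly equal to zero fall in neither tail.
#'
#' @param samples numeric vector of posterior draws for one coefficient.
#' @return pMCMC in (0, 1].
#' @export
#' @examples
#' pmcmc(c(rep(1, 999), -1))   # 0.002
pmcmc <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (!n) bm_stop("no finite samples", "bm_domain_error")
  npos <- sum(samples > 0)
  nneg <- sum(samples < 0)
  min(1, 2 * max(1, min(npos, nneg)) / n)
}

# univariate slice sampler (stepping out + shrinkage), log-scale targets
slice_sample_1d <- function(x0, logf, w = 1, m = 50) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * m)
  k <- m - 1 - j
  while (j > 0 && y < logf(L)) { L <- L - w; j <- j - 1 }
  while (k > 0 && y < logf(R)) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (y < logf(x1)) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Fit the multilevel meta-analytic model by Gibbs sampling
#'
#' Conjugate Gibbs sampler for the same Gaussian model as [reml_fit()]:
#' fixed effects and each random-effect block (phylogenetic species
#' effects correlated by C, independent species effects, study effects,
#' per-effect unit effects) are drawn from their exact multivariate-normal
#' full conditionals, then each variance component from its
#' scaled-inverse-chi-square full conditional. The unit-level pair
#' (u, sigma2_unit) is drawn as one block: sigma2_unit from its conditional
#' with u integrated out (the residuals are then independent normals with
#' variance v_i + sigma2_unit; sampled by slice sampling on the log scale),
#' followed by u from its exact Gaussian conditional — a partially
#' collapsed update that removes the severe autocorrelation the one-at-a-time
#' pair exhibits when the unit variance is comparable to the sampling
#' variances. The per-effect sampling variances `v` are fixed throughout
#' and never updated. Point estimates are posterior means; intervals are
#' equal-tailed 2.5/97.5 percentiles; p-values are pMCMC.
#'
#' @param design a `bm_design`.
#' @param C a `phylo_correlation` (or `NULL` for identity).
#' @param settings list from [mcmc_settings()]; its `seed` drives all draws.
#' @return a `bm_fit` with posterior summaries and a `samples` element
#'   (matrices `beta` and `vcomp` of thinned post-burn-in draws).
#' @export
mcmc_fit <- function(design, C = NULL, settings = mcmc_settings()) {
  stopifnot(inherits(design, "bm_design"))
  set.seed(settings$seed)
  y <- design$y; X <- design$X; v <- design$v
  n <- design$n_obs; p <- ncol(X)
  is_ <- design$species; it_ <- design$study
  ns <- design$n_species; nt <- design$n_studies
  Cm <- align_correlation(design, C)
  cholC <- tryCatch(chol(Cm), error = function(e) chol(Cm + diag(1e-8, ns)))
  Cinv <- chol2inv(cholC)

  w <- 1 / v
  wsp <- as.numeric(rowsum(w, is_)[, 1])
  wst <- as.numeric(rowsum(w, it_)[, 1])
  XtW <- t(X * w)
  cholA <- chol(XtW %*% X)  # fixed-effect precision: constant, since v is known

  nu0 <- settings$prior_nu; V0 <- settings$prior_scale
  n_store <- (settings$iterations - settings$burnin) %/% settings$thin
  beta_s <- matrix(NA_real_, n_store, p,
                   dimnames = list(NULL, colnames(X)))
  vcomp_s <- matrix(NA_real_, n_store, 4,
                    dimnames = list(NULL, VCOMP_NAMES))

  # state
  beta <- drop(backsolve(cholA, backsolve(cholA, XtW %*% y, transpose = TRUE)))
  pe <- rep(0, ns); sp <- rep(0, ns); st <- rep(0, nt); u <- rep(0, n)
  s2 <- c(phylo = 0.05, species = 0.05, study = 0.05, unit = 0.05)
  Xb <- drop(X %*% beta)
  k <- 0L

  for (iter in seq_len(settings$iterations)) {
    # fixed effects
    r <- y - pe[is_] - sp[is_] - st[it_] - u
    b <- XtW %*% r
    mu <- backsolve(cholA, backsolve(cholA, b, transpose = TRUE))
    beta <- drop(mu) + drop(backsolve(cholA, stats::rnorm(p)))
    Xb <- drop(X %*% beta)

    # phylogenetic species effects (correlated by C)
    r <- y - Xb - sp[is_] - st[it_] - u
    P <- Cinv / s2[1]
    diag(P) <- diag(P) + wsp
    cholP <- chol(P)
    b <- as.numeric(rowsum(w * r, is_)[, 1])
    mu <- backsolve(cholP, backsolve(cholP, b, transpose = TRUE))
    pe <- drop(mu) + drop(backsolve(cholP, stats::rnorm(ns)))

    # independent species effects
    r <- y - Xb - pe[is_] - st[it_] - u
    prec <- wsp + 1 / s2[2]
    mu <- as.numeric(rowsum(w * r, is_)[, 1]) / prec
    sp <- mu + stats::rnorm(ns) / sqrt(prec)

    # study variance with study effects collapsed out, then the effects:
    # per study the residuals are N(0, sigma2_study * J + diag(v)); by
    # Sherman-Morrison the marginal log-likelihood reduces to group sums
    r <- y - Xb - pe[is_] - sp[is_] - u
    a_g <- as.numeric(rowsum(w * r, it_)[, 1])
    b_const <- sum(w * r^2)
    logpost_ln_s2t <- function(x) {
      s2t <- exp(x)
      -0.5 * (sum(log1p(s2t * wst)) + b_const -
                s2t * sum(a_g^2 / (1 + s2t * wst))) -
        (nu0 / 2) * x - nu0 * V0 / (2 * s2t)
    }
    s2[3] <- exp(slice_sample_1d(log(s2[3]), logpost_ln_s2t))
    prec <- wst + 1 / s2[3]
    st <- a_g / prec + stats::rnorm(nt) / sqrt(prec)

    # unit variance with u collapsed out, then u exactly: one joint block
    r <- y - Xb - pe[is_] - sp[is_] - st[it_]
    logpost_ln_s2u <- function(x) {
      tot <- v + exp(x)
      -0.5 * sum(log(tot) + r^2 / tot) - (nu0 / 2) * x -
        nu0 * V0 / (2 * exp(x))
    }
    s2[4] <- exp(slice_sample_1d(log(s2[4]), logpost_ln_s2u))
    prec <- w + 1 / s2[4]
    u <- (w * r) / prec + stats::rnorm(n) / sqrt(prec)

    # species-tied components: scaled-inverse-chi-square full conditionals
    s2[1] <- (nu0 * V0 + drop(crossprod(pe, Cinv %*% pe))) /
      stats::rchisq(1, nu0 + ns)
    s2[2] <- (nu0 * V0 + sum(sp^2)) / stats::rchisq(1, nu0 + ns)

    if (!all(is.finite(beta)) || !all(is.finite(s2)))
      bm_stop(paste0("divergent chain at iteration ", iter), "bm_divergence_error")

    if (iter > settings$burnin &&
        (iter - settings$burnin) %% settings$thin == 0) {
      k <- k + 1L
      beta_s[k, ] <- beta
      vcomp_s[k, ] <- s2
    }
  }

  summarize_mcmc(beta_s, vcomp_s, design, settings)
}

# internal: posterior summaries -> bm_fit
summarize_mcmc <- function(beta_s, vcomp_s, design, settings) {
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975),
                            names = FALSE))
  bq <- qs(beta_s)
  beta_tab <- data.frame(
    term = colnames(beta_s),
    estimate = colMeans(beta_s),
    se = apply(beta_s, 2, stats::sd),
    ci_lb = bq[, 1],
    ci_ub = bq[, 2],
    p = apply(beta_s, 2, pmcmc),
    stringsAsFactors = FALSE
  )
  vq <- qs(vcomp_s)
  vcomp_tab <- data.frame(
    component = colnames(vcomp_s),
    estimate = colMeans(vcomp_s),
    se = apply(vcomp_s, 2, stats::sd),
    ci_lb = vq[, 1],
    ci_ub = vq[, 2],
    boundary = FALSE,
    pinned = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(beta_tab) <- rownames(vcomp_tab) <- NULL
  structure(
    list(
      method = "mcmc",
      beta = beta_tab,
      vcomp = vcomp_tab,
      samples = list(beta = beta_s, vcomp = vcomp_s),
      settings = settings,
      n_obs = design$n_obs,
      n_species = design$n_species,
      n_studies = design$n_studies,
      n_by_strategy = design$n_by_strategy,
      relationship = design$relationship,
      fixed = design$fixed,
      level = 0.95
    ),
    class = "bm_fit"
  )
}
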