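#' Restricted log-likelihood of the multilevel meta-analytic model
#'
#' Evaluates the REML log-likelihood of
#' \deqn{y \sim N(X\beta,\;
#'   \sigma^2_{phylo} Z_s C Z_s' + \sigma^2_{species} Z_s Z_s' +
#'   \sigma^2_{study} Z_u Z_u' + \sigma^2_{unit} I + \mathrm{diag}(v))}
#' at a given vector of variance components, with the fixed effects
#' profiled out. Harville's form is used (the `log|X'X|` term is included),
#' so the value equals the log-density of any orthonormal set of error
#' contrasts of `y` — directly comparable against a brute-force
#' multivariate-normal oracle.
#'
#' @param design a `bm_design` from [build_design()].
#' @param C a `phylo_correlation` (or aligned matrix, or `NULL` for identity).
#' @param vcomp named numeric: `phylo`, `species`, `study`, `unit` (all >= 0).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(design, C, vcomp) {
  parts <- vcov_parts(design, C)
  ll_reml(as_theta(vcomp), parts)$ll
}

# canonical component order
VCOMP_NAMES <- c("phylo", "species", "study", "unit")

as_theta <- function(vcomp) {
  if (is.null(names(vcomp)) && length(vcomp) == 4) names(vcomp) <- VCOMP_NAMES
  if (!all(VCOMP_NAMES %in% names(vcomp)))
    bm_stop("vcomp must name phylo, species, study, unit", "bm_domain_error")
  theta <- as.numeric(vcomp[VCOMP_NAMES])
  if (any(theta < 0)) bm_stop("variance components must be >= 0", "bm_domain_error")
  theta
}

# internal: the four n x n covariance-structure matrices plus fixed parts
vcov_parts <- function(design, C) {
  Cm <- align_correlation(design, C)
  is_ <- design$species
  it_ <- design$study
  n <- design$n_obs
  list(
    y = design$y, X = design$X, v = design$v, n = n, p = ncol(design$X),
    A = list(
      phylo   = Cm[is_, is_, drop = FALSE],
      species = outer(is_, is_, "==") * 1,
      study   = outer(it_, it_, "==") * 1,
      unit    = diag(n)
    ),
    logdetXtX = determinant(crossprod(design$X), logarithm = TRUE)$modulus[1]
  )
}

# internal: REML loglik, GLS beta, and byproducts at theta
ll_reml <- function(theta, parts, want_grad = FALSE) {
  V <- diag(parts$v, parts$n)
  for (j in seq_along(theta)) if (theta[j] != 0) V <- V + theta[j] * parts$A[[j]]
  cholV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cholV)) return(list(ll = -Inf))
  X <- parts$X; y <- parts$y
  Linv_X <- backsolve(cholV, X, transpose = TRUE)
  Linv_y <- backsolve(cholV, y, transpose = TRUE)
  XtViX <- crossprod(Linv_X)
  XtViy <- crossprod(Linv_X, Linv_y)
  cholXtViX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cholXtViX)) return(list(ll = -Inf))
  beta <- drop(backsolve(cholXtViX, backsolve(cholXtViX, XtViy, transpose = TRUE)))
  resid <- y - drop(X %*% beta)
  Linv_r <- backsolve(cholV, resid, transpose = TRUE)
  quad <- sum(Linv_r^2)
  logdetV <- 2 * sum(log(diag(cholV)))
  logdetXtViX <- 2 * sum(log(diag(cholXtViX)))
  ll <- -0.5 * ((parts$n - parts$p) * log(2 * pi) - parts$logdetXtX +
                  logdetV + logdetXtViX + quad)
  out <- list(ll = ll, beta = beta, cholV = cholV,
              cov_beta = chol2inv(cholXtViX))
  if (want_grad) {
    Vinv <- chol2inv(cholV)
    VinvX <- Vinv %*% X
    P <- Vinv - VinvX %*% chol2inv(cholXtViX) %*% t(VinvX)
    Py <- drop(P %*% y)
    out$grad <- vapply(seq_along(theta), function(j) {
      Aj <- parts$A[[j]]
      -0.5 * (sum(P * Aj) - drop(crossprod(Py, Aj %*% Py)))
    }, numeric(1))
  }
  out
}

#' Fit the multilevel meta-analytic model by REML
#'
#' Maximizes the restricted likelihood over the non-negative variance
#' components (phylogeny, species, study, unit), with the per-effect
#' sampling variances `v` held fixed, then estimates the fixed effects by
#' generalized least squares at the optimum. Wald 95% intervals and
#' two-sided normal p-values are reported for the coefficients; variance
#' components get Wald intervals from the numerically differentiated REML
#' Hessian, truncated at zero, with boundary estimates flagged.
#'
#' @param design a `bm_design`.
#' @param C a `phylo_correlation` (or `NULL` for no phylogenetic structure).
#' @param pin_vcomp optional named numeric fixing some or all components
#'   (e.g. `c(phylo=0, species=0, study=0, unit=0)` for the fixed-effect
#'   meta-analysis limit); fixed components are not optimized.
#' @param level confidence level (default 0.95).
#' @return a `bm_fit` with elements `beta` (coefficient table), `vcomp`
#'   (component table with `boundary` flags), `loglik`, `convergence`,
#'   and bookkeeping counts.
#' @export
reml_fit <- function(design, C = NULL, pin_vcomp = NULL, level = 0.95) {
  stopifnot(inherits(design, "bm_design"))
  parts <- vcov_parts(design, C)
  pinned <- rep(NA_real_, 4)
  names(pinned) <- VCOMP_NAMES
  if (!is.null(pin_vcomp)) {
    bad <- setdiff(names(pin_vcomp), VCOMP_NAMES)
    if (length(bad))
      bm_stop(paste0("unknown component(s): ", paste(bad, collapse = ", ")),
              "bm_domain_error")
    pinned[names(pin_vcomp)] <- as.numeric(pin_vcomp)
  }
  free <- which(is.na(pinned))

  full_theta <- function(par) {
    th <- pinned
    th[free] <- par
    th
  }
  negll <- function(par) -ll_reml(full_theta(par), parts)$ll
  neggr <- function(par) -ll_reml(full_theta(par), parts, want_grad = TRUE)$grad[free]

  if (length(free)) {
    tau0 <- max(stats::var(parts$y) - mean(parts$v), 0.004)
    starts <- list(rep(tau0 / 4, length(free)),
                   rep(0.01, length(free)))
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(st, negll, neggr, method = "L-BFGS-B",
                     lower = rep(0, length(free)),
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best))
      bm_stop("REML optimization failed from all starts", "bm_convergence_error")
    theta <- full_theta(best$par)
    convergence <- best$convergence
  } else {
    theta <- pinned
    convergence <- 0L
  }

  at_opt <- ll_reml(theta, parts)
  if (!is.finite(at_opt$ll) || is.null(at_opt$beta))
    bm_stop("restricted likelihood is not finite at the chosen components (singular design or covariance)",
            "bm_convergence_error")
  beta <- at_opt$beta
  se <- sqrt(diag(at_opt$cov_beta))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  beta_tab <- data.frame(
    term = colnames(design$X),
    estimate = beta,
    se = se,
    ci_lb = beta - zq * se,
    ci_ub = beta + zq * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )

  boundary <- theta < 1e-6
  vc_se <- rep(NA_real_, 4)
  if (length(free)) {
    # central-difference Hessian of the negative restricted loglik
    hstep <- pmax(1e-4, 0.05 * theta[free])
    k <- length(free)
    H <- matrix(NA_real_, k, k)
    g_at <- function(par) neggr(par)
    for (j in seq_len(k)) {
      e <- rep(0, k); e[j] <- hstep[j]
      lo <- pmax(theta[free] - e, 0)
      hi <- theta[free] + e
      H[, j] <- (g_at(hi) - g_at(lo)) / (hi[j] - lo[j])
    }
    H <- (H + t(H)) / 2
    cov_theta <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cov_theta)) {
      d <- diag(cov_theta)
      d[!is.finite(d) | d <= 0] <- NA_real_
      vc_se[free] <- sqrt(d)
    }
  }
  vcomp_tab <- data.frame(
    component = VCOMP_NAMES,
    estimate = theta,
    se = vc_se,
    ci_lb = pmax(theta - zq * vc_se, 0),
    ci_ub = theta + zq * vc_se,
    boundary = boundary,
    pinned = !is.na(pinned),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      method = "reml",
      beta = beta_tab,
      vcomp = vcomp_tab,
      cov_beta = at_opt$cov_beta,
      loglik = at_opt$ll,
      convergence = convergence,
      n_obs = design$n_obs,
      n_species = design$n_species,
      n_studies = design$n_studies,
      n_by_strategy = design$n_by_strategy,
      relationship = design$relationship,
      fixed = design$fixed,
      level = level
    ),
    class = "bm_fit"
  )
}

#' @export
print.bm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Multilevel meta-analytic fit (%s): %d effect sizes, %d species, %d studies\n",
              toupper(x$method), x$n_obs, x$n_species, x$n_studies))
  tab <- x$beta
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat("Variance components (Z scale):\n")
  vt <- x$vcomp[, c("component", "estimate")]
  vt$estimate <- round(vt$estimate, digits + 1)
  print(vt, row.names = FALSE)
  invisible(x)
}
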