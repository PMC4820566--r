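#' Combine per-tree fits into one result
#'
#' Propagates phylogenetic uncertainty by pooling model fits run on each
#' tree of an ensemble. MCMC fits are pooled by concatenating their
#' posterior samples with equal weight before summarization. REML fits are
#' pooled by averaging point estimates and widening the intervals: the
#' total variance of each coefficient is the mean within-tree variance plus
#' the between-tree variance of the point estimates.
#'
#' @param fits list of `bm_fit` objects sharing method and coefficients.
#' @return a combined `bm_fit` with a `per_tree` element keeping the
#'   per-tree coefficient estimates.
#' @export
combine_over_trees <- function(fits) {
  if (!length(fits)) bm_stop("empty fit list", "bm_domain_error")
  stopifnot(all(vapply(fits, inherits, logical(1), "bm_fit")))
  terms0 <- fits[[1]]$beta$term
  same <- vapply(fits, function(f) identical(f$beta$term, terms0), logical(1))
  if (!all(same))
    bm_stop("fits have differing coefficient names", "bm_mismatch_error")
  methods <- unique(vapply(fits, `[[`, character(1), "method"))
  if (length(methods) > 1)
    bm_stop("cannot combine fits of different methods", "bm_mismatch_error")
  per_tree <- do.call(rbind, lapply(seq_along(fits), function(i) {
    cbind(tree = i, fits[[i]]$beta[, c("term", "estimate")])
  }))
  if (length(fits) == 1) {
    out <- fits[[1]]
    out$per_tree <- per_tree
    out$n_trees <- 1L
    return(out)
  }

  if (methods == "mcmc") {
    beta_s <- do.call(rbind, lapply(fits, function(f) f$samples$beta))
    vcomp_s <- do.call(rbind, lapply(fits, function(f) f$samples$vcomp))
    out <- summarize_mcmc(beta_s, vcomp_s,
                          design_stub(fits[[1]]), fits[[1]]$settings)
    out$fixed <- fits[[1]]$fixed
  } else {
    pool <- function(tabs, key) {
      est <- sapply(tabs, function(t) t$estimate)       # terms x trees
      se <- sapply(tabs, function(t) t$se)
      est_bar <- rowMeans(est)
      between <- apply(est, 1, stats::var)
      total_se <- sqrt(rowMeans(se^2, na.rm = TRUE) + between)
      zq <- stats::qnorm(0.975)
      data.frame(
        tabs[[1]][key],
        estimate = est_bar,
        se = total_se,
        ci_lb = est_bar - zq * total_se,
        ci_ub = est_bar + zq * total_se,
        stringsAsFactors = FALSE
      )
    }
    beta_tab <- pool(lapply(fits, `[[`, "beta"), "term")
    beta_tab$p <- 2 * stats::pnorm(-abs(beta_tab$estimate / beta_tab$se))
    vcomp_tab <- pool(lapply(fits, `[[`, "vcomp"), "component")
    vcomp_tab$ci_lb <- pmax(vcomp_tab$ci_lb, 0)
    vcomp_tab$boundary <- vcomp_tab$estimate < 1e-6
    vcomp_tab$pinned <- fits[[1]]$vcomp$pinned
    out <- fits[[1]]
    out$beta <- beta_tab
    out$vcomp <- vcomp_tab
    out$loglik <- mean(vapply(fits, `[[`, numeric(1), "loglik"))
  }
  out$n_obs <- fits[[1]]$n_obs
  out$n_species <- fits[[1]]$n_species
  out$n_studies <- fits[[1]]$n_studies
  out$n_by_strategy <- fits[[1]]$n_by_strategy
  out$relationship <- fits[[1]]$relationship
  out$per_tree <- per_tree
  out$n_trees <- length(fits)
  out
}

# internal: minimal design-like stub for re-summarizing pooled samples
design_stub <- function(fit) {
  list(n_obs = fit$n_obs, n_species = fit$n_species,
       n_studies = fit$n_studies, n_by_strategy = fit$n_by_strategy,
       relationship = fit$relationship, fixed = fit$fixed)
}

#' Append the derived contrast rows to a fit
#'
#' Adds the two derived quantities reported alongside the level means:
#' * `reduction_difference` = whole-brood-survival mean minus brood-reducing
#'   mean (computed per posterior sample in MCMC mode);
#' * `grand_mean` = observation-weighted average of the two fitted level
#'   means at average environment (env = 0).
#'
#' For an intercept-only fit the grand mean is the intercept itself and no
#' difference is defined.
#'
#' @param fit a `bm_fit` from the strategy/environment design.
#' @return the fit with `beta` augmented by the contrast rows.
#' @export
derived_contrasts <- function(fit) {
  stopifnot(inherits(fit, "bm_fit"))
  terms <- fit$beta$term
  if (!all(c("brood_reducing", "whole_brood_survival") %in% terms)) {
    if ("intercept" %in% terms) {
      gm <- fit$beta[terms == "intercept", ]
      gm$term <- "grand_mean"
      fit$beta <- rbind(fit$beta, gm)
      rownames(fit$beta) <- NULL
      return(fit)
    }
    bm_stop("derived contrasts need the level-means design", "bm_domain_error")
  }
  nbs <- fit$n_by_strategy
  w <- c(-1, 1)
  g <- c(nbs["brood_reducing"], nbs["whole_brood_survival"]) / sum(nbs)
  i_br <- which(terms == "brood_reducing")
  i_wbs <- which(terms == "whole_brood_survival")

  if (fit$method == "mcmc") {
    bs <- fit$samples$beta
    diff_s <- bs[, i_wbs] - bs[, i_br]
    gm_s <- g[1] * bs[, i_br] + g[2] * bs[, i_wbs]
    row <- function(name, s) data.frame(
      term = name, estimate = mean(s), se = stats::sd(s),
      ci_lb = stats::quantile(s, 0.025, names = FALSE),
      ci_ub = stats::quantile(s, 0.975, names = FALSE),
      p = pmcmc(s), stringsAsFactors = FALSE)
    extra <- rbind(row("reduction_difference", diff_s),
                   row("grand_mean", gm_s))
    fit$samples$derived <- cbind(reduction_difference = diff_s,
                                 grand_mean = gm_s)
  } else {
    lincomb <- function(name, a) {
      est <- sum(a * fit$beta$estimate[c(i_br, i_wbs)])
      if (!is.null(fit$cov_beta)) {
        cv <- fit$cov_beta[c(i_br, i_wbs), c(i_br, i_wbs)]
        se <- sqrt(drop(t(a) %*% cv %*% a))
      } else {
        # combined-over-trees REML fit: conservative independent-sum bound
        se <- sqrt(sum(a^2 * fit$beta$se[c(i_br, i_wbs)]^2))
      }
      zq <- stats::qnorm(0.975)
      data.frame(term = name, estimate = est, se = se,
                 ci_lb = est - zq * se, ci_ub = est + zq * se,
                 p = 2 * stats::pnorm(-abs(est / se)),
                 stringsAsFactors = FALSE)
    }
    extra <- rbind(lincomb("reduction_difference", w),
                   lincomb("grand_mean", g))
  }
  fit$beta <- rbind(fit$beta, extra)
  rownames(fit$beta) <- NULL
  fit
}

#' Coefficient table in the published row order
#'
#' Returns the fit's coefficients ordered as in the strategy/environment
#' tables: level means, reduction difference, environment slope,
#' interaction, grand mean.
#'
#' @param fit a `bm_fit` (after [derived_contrasts()]).
#' @return data.frame with columns term, estimate, ci_lb, ci_ub, p.
#' @export
fit_table <- function(fit) {
  order_wanted <- c("brood_reducing", "whole_brood_survival",
                    "reduction_difference", "environment",
                    "reduction_x_environment", "grand_mean")
  tab <- fit$beta[, c("term", "estimate", "ci_lb", "ci_ub", "p")]
  idx <- c(match(intersect(order_wanted, tab$term), tab$term),
           which(!tab$term %in% order_wanted))
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
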