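#' Typical within-effect sampling variance
#'
#' The "typical" sampling variance entering the I-squared denominator,
#' computed with higher-order weights so unequal variances are handled
#' properly: s2 = ((k-1) * sum(w)) / ((sum(w))^2 - sum(w^2)) with w = 1/v.
#' For equal variances this reduces to the common value.
#'
#' @param v vector of sampling variances (k >= 2).
#' @return the typical sampling variance (scalar).
#' @export
#' @examples
#' typical_sampling_variance(c(1, 1, 4))  # 1.5
typical_sampling_variance <- function(v) {
  if (length(v) < 2)
    bm_stop("typical sampling variance undefined for fewer than 2 effects",
            "bm_domain_error")
  if (any(v <= 0)) bm_stop("sampling variances must be positive", "bm_domain_error")
  w <- 1 / v
  k <- length(v)
  ((k - 1) * sum(w)) / (sum(w)^2 - sum(w^2))
}

#' I-squared heterogeneity partition across random-effect levels
#'
#' Total I-squared is the summed variance attributed to phylogeny, species,
#' study and units divided by the overall variance (those components plus
#' the typical measurement-error variance), expressed as a percentage.
#' Per-component shares use the same denominator, so they add up to the
#' total. The partition is invariant to rescaling all variances by a
#' common factor.
#'
#' @param vcomp named numeric (`phylo`, `species`, `study`, `unit`) or the
#'   `vcomp` table of a `bm_fit`.
#' @param s2_typical typical sampling variance from
#'   [typical_sampling_variance()].
#' @return a `heterogeneity_result`: list with `s2_typical`, `i2_total`
#'   (percent) and `i2_by_component` (named percents).
#' @export
i_squared <- function(vcomp, s2_typical) {
  if (is.data.frame(vcomp)) {
    v <- vcomp$estimate
    names(v) <- vcomp$component
    vcomp <- v
  }
  theta <- as_theta(vcomp)
  names(theta) <- VCOMP_NAMES
  if (s2_typical <= 0)
    bm_stop("typical sampling variance must be positive", "bm_domain_error")
  denom <- sum(theta) + s2_typical
  structure(
    list(
      s2_typical = s2_typical,
      i2_total = 100 * sum(theta) / denom,
      i2_by_component = 100 * theta / denom
    ),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Total I2: %.1f%%\n", x$i2_total))
  for (nm in names(x$i2_by_component))
    cat(sprintf("  %-8s %.1f%%\n", nm, x$i2_by_component[[nm]]))
  invisible(x)
}

#' Per-study average effects for the funnel-asymmetry test
#'
#' One row per study: the unweighted mean of the study's Fisher Z values,
#' and a pooled sampling variance from the summed brood counts,
#' v_study = 1 / (sum(n_broods) - 3).
#'
#' @param dataset an `es_dataset` (optionally restricted to one
#'   relationship beforehand).
#' @return data.frame with `study_id`, `z_mean`, `v_study`, `k_effects`.
#' @export
study_average <- function(dataset) {
  stopifnot(inherits(dataset, "es_dataset"))
  df <- dataset$data
  agg <- lapply(split(df, as.character(df$study_id)), function(g) {
    data.frame(study_id = g$study_id[1],
               z_mean = mean(g$z),
               v_study = 1 / (sum(g$n_broods) - 3),
               k_effects = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Weighted least-squares regression of the per-study mean effect on its
#' pooled sampling variance, with weights 1/variance. Under no small-study
#' bias the slope is zero; the test statistic is slope / SE(slope) against
#' a standard-normal reference. `predictor = "se"` gives the classical
#' standard-error variant for cross-checks.
#'
#' @param study_effects data.frame from [study_average()] (columns
#'   `z_mean`, `v_study`).
#' @param predictor `"variance"` (default) or `"se"`.
#' @return an `egger_result`: intercept, slope, z, p, n_studies.
#' @export
egger_test <- function(study_effects, predictor = c("variance", "se")) {
  predictor <- match.arg(predictor)
  k <- nrow(study_effects)
  if (is.null(k) || k < 3)
    bm_stop("Egger's test needs at least 3 studies", "bm_insufficient_data")
  y <- study_effects$z_mean
  v <- study_effects$v_study
  x <- if (predictor == "variance") v else sqrt(v)
  w <- 1 / v
  fit <- stats::lm.wfit(cbind(intercept = 1, predictor = x), y, w)
  cf <- fit$coefficients
  # weighted-normal-theory covariance with known weights (sigma2 fixed at 1
  # relative scale): use residual-based estimate as in standard WLS
  Xm <- cbind(1, x)
  XtWX_inv <- solve(crossprod(Xm * sqrt(w)))
  rss <- sum(w * fit$residuals^2)
  s2 <- rss / (k - 2)
  se_slope <- sqrt(s2 * XtWX_inv[2, 2])
  z <- cf[["predictor"]] / se_slope
  structure(
    list(
      intercept = cf[["intercept"]],
      slope = cf[["predictor"]],
      se_slope = se_slope,
      z = z,
      p = 2 * stats::pnorm(-abs(z)),
      n_studies = k,
      predictor = predictor
    ),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("Egger regression (%s predictor): z = %.2f, p = %.3g (%d studies)\n",
              x$predictor, x$z, x$p, x$n_studies))
  invisible(x)
}
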