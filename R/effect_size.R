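#' Correlation coefficient from a t statistic
#'
#' Converts a t statistic with its degrees of freedom to a signed
#' correlation, r = t / sqrt(t^2 + df). The sign of r is the sign of t.
#'
#' @param t t statistic.
#' @param df degrees of freedom (>= 1).
#' @return signed correlation coefficient, |r| < 1.
#' @export
#' @examples
#' r_from_t(2, 16)
r_from_t <- function(t, df) {
  if (any(!is.finite(t)) || any(!is.finite(df)) || any(df < 1))
    bm_stop("r_from_t requires finite t and df >= 1", "bm_domain_error")
  t / sqrt(t^2 + df)
}

#' Correlation magnitude from a one-way F statistic
#'
#' Only single-numerator-df F statistics can be converted: with df1 > 1 the
#' direction of the effect is undefined and the statistic is rejected.
#' Returns |r| = sqrt(F / (F + df2)); attach a direction with
#' [apply_sign()].
#'
#' @param F F statistic (>= 0).
#' @param df1 numerator degrees of freedom; must be 1.
#' @param df2 denominator degrees of freedom.
#' @return unsigned correlation magnitude.
#' @export
r_from_F <- function(F, df1, df2) {
  if (any(df1 != 1))
    bm_stop("F statistics with numerator df != 1 cannot be converted (direction undefined)",
            "bm_unsupported_statistic")
  if (any(F < 0) || any(df2 < 1))
    bm_stop("r_from_F requires F >= 0 and df2 >= 1", "bm_domain_error")
  sqrt(F / (F + df2))
}

#' Correlation magnitude from a chi-square statistic
#'
#' |r| = sqrt(chisq / N) for 1-df chi-square statistics; multi-df statistics
#' are rejected because the direction of the association is undefined.
#'
#' @param chisq chi-square statistic (>= 0).
#' @param df degrees of freedom; must be 1.
#' @param n total number of observations behind the statistic.
#' @return unsigned correlation magnitude.
#' @export
r_from_chisq <- function(chisq, df, n) {
  if (any(df != 1))
    bm_stop("chi-square statistics with df != 1 cannot be converted (direction undefined)",
            "bm_unsupported_statistic")
  if (any(chisq < 0) || any(n < 1))
    bm_stop("r_from_chisq requires chisq >= 0 and n >= 1", "bm_domain_error")
  out <- sqrt(chisq / n)
  if (any(out >= 1))
    bm_stop("chi-square conversion produced |r| >= 1; check n", "bm_domain_error")
  out
}

#' Correlation from two group means and standard deviations
#'
#' Standard handbook chain: Cohen's d from the pooled standard deviation,
#' then r = d / sqrt(d^2 + h) with the group-size correction
#' h = (n1 + n2)^2 / (n1 * n2). No small-sample (Hedges) correction is
#' applied by default; set `hedges = TRUE` to shrink d by
#' 1 - 3/(4(n1+n2) - 9) first.
#'
#' @param m1,m2 group means (signal-present or high group first).
#' @param sd1,sd2 group standard deviations (> 0).
#' @param n1,n2 group sizes (>= 2).
#' @param hedges apply the small-sample correction to d before converting.
#' @return signed correlation coefficient.
#' @export
#' @examples
#' r_from_means(1, 0, 1, 1, 10, 10)
r_from_means <- function(m1, m2, sd1, sd2, n1, n2, hedges = FALSE) {
  if (any(sd1 <= 0) || any(sd2 <= 0))
    bm_stop("group standard deviations must be positive", "bm_domain_error")
  if (any(n1 < 2) || any(n2 < 2))
    bm_stop("group sizes must be at least 2", "bm_domain_error")
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (m1 - m2) / s_pooled
  if (hedges) d <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  h <- (n1 + n2)^2 / (n1 * n2)
  d / sqrt(d^2 + h)
}

#' Fisher's Z transform of a correlation coefficient
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)).
#'
#' @param r correlation, |r| < 1.
#' @return Fisher-transformed effect size.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    bm_stop("fisher_z requires |r| < 1", "bm_domain_error")
  atanh(r)
}

#' Sampling variance of Fisher's Z from the number of broods
#'
#' v = 1 / (n_broods - 3). The number of broods is the sample size used
#' throughout: it is comparable across studies and avoids pseudoreplication
#' when chicks or observations were the reported unit.
#'
#' @param n_broods integer number of broods (>= 4).
#' @return sampling variance of z.
#' @export
z_variance <- function(n_broods) {
  if (any(n_broods < 4))
    bm_stop("z_variance requires n_broods >= 4 (v = 1/(n-3) undefined or non-positive)",
            "bm_domain_error")
  1 / (n_broods - 3)
}

#' Attach a direction to an unsigned correlation magnitude
#'
#' The sign convention is behavioural, not statistical: positive means
#' chicks signalling more (or in better condition) got more of the outcome.
#' Unsigned statistics (F, chi-square) must come with a reported direction;
#' `none_reported` is an error, never a silent positive.
#'
#' @param magnitude |r| (>= 0).
#' @param direction one of `"more_signal_more_outcome"`,
#'   `"more_signal_less_outcome"`, `"none_reported"`.
#' @return signed correlation.
#' @export
apply_sign <- function(magnitude,
                       direction = c("more_signal_more_outcome",
                                     "more_signal_less_outcome",
                                     "none_reported")) {
  direction <- match.arg(direction)
  if (any(magnitude < 0))
    bm_stop("magnitude must be non-negative", "bm_domain_error")
  switch(direction,
    more_signal_more_outcome = magnitude,
    more_signal_less_outcome = -magnitude,
    none_reported = bm_stop(
      "direction is mandatory for unsigned statistics (none_reported)",
      "bm_direction_error")
  )
}

#' Convert a table of raw test statistics to (r, z, v)
#'
#' One row per reported statistic. `statistic` selects the conversion:
#' `"r"` (pass-through), `"t"`, `"F"`, `"chisq"`, or `"means"`. Columns
#' used per kind: t: `value`, `df`; F: `value`, `df1`, `df2`, `direction`;
#' chisq: `value`, `df`, `n_total`, `direction`; means: `m1,m2,sd1,sd2,n1,n2`;
#' r: `value`. Every row needs `n_broods`. The source statistic kind is kept
#' in the output for provenance.
#'
#' @param stats_df data.frame of raw statistics.
#' @param hedges apply the small-sample correction in the means route.
#' @return data.frame with columns `r`, `z`, `v`, `n_broods`, `source_statistic`.
#' @export
convert_statistics <- function(stats_df, hedges = FALSE) {
  stopifnot(is.data.frame(stats_df))
  need <- c("statistic", "n_broods")
  missing_cols <- setdiff(need, names(stats_df))
  if (length(missing_cols))
    bm_stop(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
            "bm_schema_error")
  r <- vapply(seq_len(nrow(stats_df)), function(i) {
    row <- stats_df[i, , drop = FALSE]
    kind <- as.character(row$statistic)
    switch(kind,
      r = as.numeric(row$value),
      t = r_from_t(row$value, row$df),
      F = apply_sign(r_from_F(row$value, row$df1, row$df2),
                     as.character(row$direction)),
      chisq = apply_sign(r_from_chisq(row$value, row$df, row$n_total),
                         as.character(row$direction)),
      means = r_from_means(row$m1, row$m2, row$sd1, row$sd2, row$n1, row$n2,
                           hedges = hedges),
      bm_stop(paste0("unknown statistic kind: ", kind), "bm_unsupported_statistic")
    )
  }, numeric(1))
  data.frame(
    r = r,
    z = fisher_z(r),
    v = z_variance(stats_df$n_broods),
    n_broods = stats_df$n_broods,
    source_statistic = as.character(stats_df$statistic),
    stringsAsFactors = FALSE
  )
}
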