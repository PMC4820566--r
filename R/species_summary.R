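#' Species-level pooled effects and classification
#'
#' For each species with records on the given relationship, pools its
#' Fisher Z values into a brood-weighted mean, computes the standard error
#' from the pooled number of broods, se = 1/sqrt(n_pooled - 3), and a 95%
#' confidence interval of +/- se * t_critical with t_critical the 0.975
#' quantile of the t distribution on n_pooled - 3 degrees of freedom. A
#' species is classified `positive` or `negative` when the interval
#' excludes zero, `null` otherwise. Species pooling fewer than 4 broods are
#' skipped with a warning (their variance is undefined).
#'
#' @param dataset an `es_dataset`.
#' @param relationship one of [relationship_levels()].
#' @param level confidence level (default 0.95).
#' @return data.frame (`species_summary`) with species, z_mean, n_pooled,
#'   se, ci_low, ci_high, class, k_effects.
#' @export
summarize_species <- function(dataset, relationship, level = 0.95) {
  stopifnot(inherits(dataset, "es_dataset"))
  relationship <- match.arg(relationship, relationship_levels())
  df <- dataset$data[dataset$data$relationship == relationship, , drop = FALSE]
  if (!nrow(df))
    bm_stop(paste0("no records for relationship ", relationship),
            "bm_domain_error")
  groups <- split(df, df$species)
  skipped <- character(0)
  rows <- lapply(groups, function(g) {
    n_pooled <- sum(g$n_broods)
    if (n_pooled < 4) {
      skipped <<- c(skipped, g$species[1])
      return(NULL)
    }
    z_mean <- sum(g$z * g$n_broods) / n_pooled
    se <- 1 / sqrt(n_pooled - 3)
    tcrit <- stats::qt(1 - (1 - level) / 2, df = n_pooled - 3)
    lo <- z_mean - se * tcrit
    hi <- z_mean + se * tcrit
    data.frame(
      species = g$species[1],
      relationship = relationship,
      z_mean = z_mean,
      n_pooled = n_pooled,
      se = se,
      ci_low = lo,
      ci_high = hi,
      class = if (lo > 0) "positive" else if (hi < 0) "negative" else "null",
      k_effects = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  if (length(skipped))
    warning("species skipped (pooled broods < 4): ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_summary", "data.frame")
  out
}

#' Count species by effect classification
#'
#' Tallies the positive / negative / null species classifications from
#' [summarize_species()]. `not_preferential` counts species whose interval
#' does not support a positive effect (null or negative) — the count quoted
#' as "parents not preferentially feeding the chicks that beg the most".
#'
#' @param summaries a `species_summary` data.frame.
#' @return list with `positive`, `negative`, `null`, `total`,
#'   `not_preferential`.
#' @export
count_classes <- function(summaries) {
  stopifnot(is.data.frame(summaries), "class" %in% names(summaries))
  tab <- table(factor(summaries$class, levels = c("positive", "negative", "null")))
  out <- as.list(as.integer(tab))
  names(out) <- names(tab)
  out$total <- nrow(summaries)
  out$not_preferential <- out$negative + out$null
  out
}
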