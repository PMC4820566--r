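#' Build the model design for one relationship
#'
#' Assembles the response (Fisher Z values), the fixed-effect design matrix,
#' the grouping structure for the random effects, and the known sampling
#' variances, for a dataset restricted to one of the five relationships.
#'
#' The default fixed part is the no-intercept level-means parameterization
#' used for the strategy-by-environment tables: one mean per brood-reduction
#' strategy, a linear slope on the environment code (-1/0/+1), and a single
#' interaction column attached to the whole-brood-survival level, so that
#' the interaction coefficient is the WBS-minus-BR slope difference.
#' `fixed = "intercept"` gives the plain grand-mean design. An extra
#' moderator factor can be appended (dummy-coded against its first level)
#' for confounding-factor scans.
#'
#' @param dataset an `es_dataset`.
#' @param relationship one of [relationship_levels()].
#' @param fixed `"strategy_env"` (default) or `"intercept"`.
#' @param extra_moderator optional moderator column name to append.
#' @return a `bm_design`: list with `y`, `X`, `v`, `species`, `study`
#'   (integer group indices), level vectors, and bookkeeping counts.
#' @export
build_design <- function(dataset, relationship,
                         fixed = c("strategy_env", "intercept"),
                         extra_moderator = NULL) {
  stopifnot(inherits(dataset, "es_dataset"))
  fixed <- match.arg(fixed)
  relationship <- match.arg(relationship, relationship_levels())
  df <- dataset$data[dataset$data$relationship == relationship, , drop = FALSE]
  if (!nrow(df))
    bm_stop(paste0("no records for relationship ", relationship),
            "bm_degenerate_design")

  if (fixed == "strategy_env") {
    if (!"brood_strategy" %in% names(df))
      bm_stop("brood_strategy column required for the strategy/environment design",
              "bm_schema_error")
    br <- as.numeric(df$brood_strategy == "brood_reducing")
    wbs <- as.numeric(df$brood_strategy == "whole_brood_survival")
    if (sum(br) == 0 || sum(wbs) == 0)
      bm_stop("a brood-strategy level has zero records: level-means design is degenerate",
              "bm_degenerate_design")
    env <- df$env_code
    X <- cbind(brood_reducing = br,
               whole_brood_survival = wbs,
               environment = env,
               reduction_x_environment = env * wbs)
  } else {
    X <- cbind(intercept = rep(1, nrow(df)))
  }

  if (!is.null(extra_moderator)) {
    if (!extra_moderator %in% names(df))
      bm_stop(paste0("moderator column not found: ", extra_moderator),
              "bm_schema_error")
    f <- factor(df[[extra_moderator]])
    if (nlevels(f) < 2)
      bm_stop(paste0("moderator ", extra_moderator, " has a single level"),
              "bm_degenerate_design")
    M <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    colnames(M) <- paste0(extra_moderator, "_", levels(f)[-1])
    X <- cbind(X, M)
  }

  species_levels <- sort(unique(df$species))
  study_levels <- sort(unique(as.character(df$study_id)))
  structure(
    list(
      y = df$z,
      X = X,
      v = df$v,
      species = match(df$species, species_levels),
      study = match(as.character(df$study_id), study_levels),
      species_levels = species_levels,
      study_levels = study_levels,
      relationship = relationship,
      fixed = fixed,
      n_obs = nrow(df),
      n_species = length(species_levels),
      n_studies = length(study_levels),
      n_by_strategy = if (fixed == "strategy_env")
        c(brood_reducing = sum(X[, "brood_reducing"]),
          whole_brood_survival = sum(X[, "whole_brood_survival"]))
      else NULL
    ),
    class = "bm_design"
  )
}

# internal: align a phylo_correlation to the design's species levels
align_correlation <- function(design, C) {
  if (is.null(C)) {
    Cm <- diag(design$n_species)
    rownames(Cm) <- colnames(Cm) <- design$species_levels
    return(Cm)
  }
  if (inherits(C, "phylo_correlation")) {
    idx <- match(design$species_levels, C$species_order)
    if (anyNA(idx))
      bm_stop(paste0("species missing from correlation matrix: ",
                     paste(design$species_levels[is.na(idx)], collapse = ", ")),
              "bm_species_mismatch")
    return(C$C[idx, idx, drop = FALSE])
  }
  stopifnot(is.matrix(C), nrow(C) == design$n_species)
  C
}
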