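#' Restrict a dataset to one relationship
#'
#' @param dataset an `es_dataset`.
#' @param relationship one of [relationship_levels()].
#' @return an `es_dataset` containing only that relationship's records.
#' @export
subset_relationship <- function(dataset, relationship) {
  stopifnot(inherits(dataset, "es_dataset"))
  relationship <- match.arg(relationship, relationship_levels())
  as_es_dataset(dataset$data[dataset$data$relationship == relationship, ,
                             drop = FALSE])
}

# internal: deterministic per-(relationship, tree) MCMC seed below 2^31
derive_seed <- function(base, rel_index, tree_index) {
  as.integer((base + 1009L * rel_index + 9973L * tree_index) %%
               .Machine$integer.max)
}

#' Fit one relationship over a tree ensemble
#'
#' Runs the per-tree fits, combines them, and appends the derived
#' contrasts. This is the unit of work `run_all()` repeats per
#' relationship.
#'
#' @param dataset an `es_dataset` (all relationships; restricted internally).
#' @param ensemble a `phylo_ensemble` (pruned internally to the species
#'   with records for this relationship).
#' @param relationship one of [relationship_levels()].
#' @param method `"reml"` or `"mcmc"`.
#' @param settings MCMC settings; per-tree seeds are derived from its seed.
#' @param fixed design variant passed to [build_design()].
#' @param extra_moderator optional moderator column to append.
#' @return combined `bm_fit` with contrasts.
#' @export
fit_relationship <- function(dataset, ensemble, relationship,
                             method = c("reml", "mcmc"),
                             settings = mcmc_settings(),
                             fixed = "strategy_env",
                             extra_moderator = NULL) {
  method <- match.arg(method)
  rel_idx <- match(relationship, relationship_levels())
  sub <- subset_relationship(dataset, relationship)
  ens <- prune_ensemble(ensemble, unique(sub$data$species))
  design <- build_design(sub, relationship, fixed = fixed,
                         extra_moderator = extra_moderator)
  Cs <- ensemble_correlations(ens)
  fits <- lapply(seq_along(Cs), function(ti) {
    if (method == "reml") {
      reml_fit(design, Cs[[ti]])
    } else {
      st <- settings
      st$seed <- derive_seed(settings$seed, rel_idx, ti)
      mcmc_fit(design, Cs[[ti]], st)
    }
  })
  derived_contrasts(combine_over_trees(fits))
}

#' Run the full analysis pipeline
#'
#' For every relationship present in the dataset: eligibility filters,
#' per-tree model fits, combination over the ensemble, derived contrasts,
#' heterogeneity partition, Egger's test, and species summaries. Writes one
#' coefficient TSV per relationship (rows: level means, reduction
#' difference, environment, interaction, grand mean), a diagnostics JSON,
#' species forest and funnel-data TSVs, and a run manifest listing every
#' output file with
#' its checksum, the seeds used, the tree count and the exclusion ledger.
#' A failure in one relationship aborts that relationship only and is
#' recorded in the manifest.
#'
#' @param dataset an `es_dataset` (or CSV path).
#' @param trees a `phylo_ensemble` (or Newick path).
#' @param out_dir output directory (created if needed).
#' @param config list: `method` ("reml"/"mcmc"), `seed`, `max_trees`,
#'   `mcmc` (overrides for [mcmc_settings()]), `curation` (rules for
#'   [filter_eligible()]). May come from [load_config()].
#' @return (invisibly) list of per-relationship results plus the manifest.
#' @export
run_all <- function(dataset, trees, out_dir, config = list()) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  if (is.character(trees)) trees <- read_tree_ensemble(trees,
                                                      config$max_trees)
  else if (!is.null(config$max_trees))
    trees <- as_phylo_ensemble(trees$trees[seq_len(
      min(config$max_trees, length(trees$trees)))])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  method <- config$method %||% "reml"
  seed <- as.integer(config$seed %||% 1L)
  settings <- do.call(mcmc_settings,
                      utils::modifyList(list(seed = seed),
                                        config$mcmc %||% list()))

  filtered <- filter_eligible(dataset, config$curation %||% list())
  ds <- filtered$dataset
  rels <- intersect(relationship_levels(), unique(ds$data$relationship))
  results <- list()
  manifest <- list(seed = seed, method = method,
                   n_trees = length(trees$trees),
                   n_records = ds$n_records, n_species = ds$n_species,
                   n_studies = ds$n_studies,
                   exclusions = filtered$exclusions,
                   relationships = list(), files = list())

  for (rel in rels) {
    res <- tryCatch({
      fit <- fit_relationship(ds, trees, rel, method = method,
                              settings = settings)
      sub <- subset_relationship(ds, rel)
      s2t <- typical_sampling_variance(sub$data$v)
      het <- i_squared(fit$vcomp, s2t)
      funnel <- study_average(sub)
      egger <- tryCatch(egger_test(funnel), error = function(e) NULL)
      species <- summarize_species(sub, rel)
      list(fit = fit, heterogeneity = het, egger = egger, species = species,
           funnel = funnel)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$relationships[[rel]] <- list(status = "failed",
                                            error = conditionMessage(res))
      next
    }
    tab_file <- file.path(out_dir, paste0(rel, "_coefficients.tsv"))
    write_tsv(format_num(fit_table(res$fit)), tab_file)
    forest_file <- file.path(out_dir, paste0(rel, "_species.tsv"))
    write_tsv(format_num(res$species), forest_file)
    funnel_file <- file.path(out_dir, paste0(rel, "_funnel.tsv"))
    write_tsv(format_num(res$funnel), funnel_file)
    diag_file <- file.path(out_dir, paste0(rel, "_diagnostics.json"))
    jsonlite::write_json(list(
      heterogeneity = unclass(res$heterogeneity),
      egger = if (is.null(res$egger)) NULL else unclass(res$egger),
      class_counts = count_classes(res$species)
    ), diag_file, auto_unbox = TRUE, digits = 10, pretty = TRUE)
    manifest$relationships[[rel]] <- list(
      status = "ok",
      n_obs = res$fit$n_obs, n_species = res$fit$n_species,
      n_studies = res$fit$n_studies)
    manifest$files <- c(manifest$files,
                        as.list(tools::md5sum(c(tab_file, forest_file,
                                                funnel_file, diag_file))))
    results[[rel]] <- res
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(list(results = results, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: round numeric columns for stable text output
format_num <- function(df, digits = 8) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Sensitivity refit excluding growth and mortality feeding measures
#'
#' Growth and mortality proxies of feeding can be confounded with how the
#' brood-reduction strategy itself was classified, so the model is refit
#' without them and reported side by side with the full fit.
#'
#' @param dataset an `es_dataset`.
#' @param trees a `phylo_ensemble`.
#' @param relationship relationship to refit.
#' @param method,settings as in [fit_relationship()].
#' @param exclude_measures feeding-measure levels to drop (default growth
#'   and mortality).
#' @return list with `full`, `filtered` (both `bm_fit`) and `delta`
#'   (coefficient differences, filtered minus full).
#' @export
sensitivity_refit <- function(dataset, trees, relationship,
                              method = "reml", settings = mcmc_settings(),
                              exclude_measures = c("growth", "mortality")) {
  full <- fit_relationship(dataset, trees, relationship,
                           method = method, settings = settings)
  df <- dataset$data
  if ("feeding_measure" %in% names(df)) {
    keep <- !(df$relationship == relationship &
                df$feeding_measure %in% exclude_measures)
    df <- df[keep, , drop = FALSE]
  }
  reduced <- as_es_dataset(df)
  filtered <- fit_relationship(reduced, trees, relationship,
                               method = method, settings = settings)
  ft <- fit_table(full); gt <- fit_table(filtered)
  common <- intersect(ft$term, gt$term)
  delta <- data.frame(
    term = common,
    full = ft$estimate[match(common, ft$term)],
    filtered = gt$estimate[match(common, gt$term)],
    stringsAsFactors = FALSE
  )
  delta$delta <- delta$filtered - delta$full
  list(full = full, filtered = filtered, delta = delta)
}

#' Scan methodological moderators for one relationship
#'
#' For each candidate moderator column that passes the eligibility gate
#' (at least two levels with at least 10 effect sizes), refits the model
#' with the moderator's dummy columns appended and reports their
#' coefficients; gate-failing moderators are listed as skipped with their
#' level counts.
#'
#' @param dataset an `es_dataset`.
#' @param trees a `phylo_ensemble`.
#' @param relationship relationship to scan.
#' @param moderators candidate moderator column names (default: the
#'   standard methodological factors present in the data).
#' @param method,settings as in [fit_relationship()].
#' @return data.frame: one row per moderator level coefficient (or one
#'   `skipped` row per gate failure).
#' @export
moderator_scan <- function(dataset, trees, relationship,
                           moderators = NULL,
                           method = "reml", settings = mcmc_settings()) {
  sub <- subset_relationship(dataset, relationship)
  if (is.null(moderators))
    moderators <- intersect(names(moderator_levels()), names(sub$data))
  out <- list()
  for (mod in moderators) {
    counts <- table(sub$data[[mod]], useNA = "no")
    if (!moderator_check_gate(sub, mod)) {
      out[[mod]] <- data.frame(
        moderator = mod, term = "skipped",
        estimate = NA_real_, ci_lb = NA_real_, ci_ub = NA_real_, p = NA_real_,
        level_counts = paste(names(counts), counts, sep = "=", collapse = ";"),
        stringsAsFactors = FALSE)
      next
    }
    fit <- fit_relationship(dataset, trees, relationship, method = method,
                            settings = settings, extra_moderator = mod)
    rows <- fit$beta[startsWith(fit$beta$term, paste0(mod, "_")), , drop = FALSE]
    out[[mod]] <- data.frame(
      moderator = mod, term = rows$term,
      estimate = rows$estimate, ci_lb = rows$ci_lb, ci_ub = rows$ci_ub,
      p = rows$p,
      level_counts = paste(names(counts), counts, sep = "=", collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a YAML configuration file
#'
#' One document with sections per stage (`method`, `seed`, `max_trees`,
#' `mcmc:`, `curation:`), consumed by [run_all()].
#'
#' @param path YAML file.
#' @return named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) bm_stop(paste0("file not found: ", path), "bm_io_error")
  yaml::read_yaml(path)
}
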