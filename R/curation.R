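#' Load and validate an effect-size dataset from CSV
#'
#' Reads one row per effect size (species, study, relationship, correlation
#' or Fisher Z, number of broods, environment quality, brood-reduction
#' strategy, optional methodological moderators), validates it, and returns
#' an `es_dataset`. Column names can be remapped through `schema` (a named
#' character vector `canonical = "file_column"`), so CSVs with other header
#' dialects load without editing.
#'
#' Validation rules:
#' * rows with `n_broods <= 3` are rejected with reason `"variance undefined"`
#'   (v = 1/(n-3) does not exist);
#' * `z` is computed as `atanh(r)` when absent, and checked against `r`
#'   when present;
#' * `v` is computed as `1/(n_broods - 3)` when absent;
#' * missing environment is conservatively coded `normal` (0);
#' * unparseable rows are collected into a rejects report, never dropped
#'   silently.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return an object of class `es_dataset`: list with `data` (validated
#'   records), `rejects` (data.frame of rejected rows and reasons), and
#'   distinct counts `n_records`, `n_studies`, `n_species`.
#' @export
load_dataset <- function(path, schema = NULL) {
  if (!file.exists(path))
    bm_stop(paste0("file not found: ", path), "bm_io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw))
        bm_stop(paste0("schema maps '", canon, "' to missing column '", src, "'"),
                "bm_schema_error")
      names(raw)[names(raw) == src] <- canon
    }
  }
  as_es_dataset(raw)
}

#' Build a validated dataset from a data.frame
#'
#' The in-memory counterpart of [load_dataset()]; applies the same
#' validation and reject handling.
#'
#' @param df data.frame of effect-size records.
#' @return an `es_dataset`.
#' @export
as_es_dataset <- function(df) {
  required <- c("species", "study_id", "relationship", "n_broods")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    bm_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")), "bm_schema_error")
  if (!("r" %in% names(df)) && !("z" %in% names(df)))
    bm_stop("missing required column(s): r (or z)", "bm_schema_error")

  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"record_id" %in% names(df)) df$record_id <- seq_len(nrow(df))

  reject_reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    reject_reason[is.na(reject_reason) & cond] <<- reason
  }

  df$species <- normalize_species(df$species)
  df$n_broods <- suppressWarnings(as.numeric(df$n_broods))
  flag(!is.finite(df$n_broods), "n_broods unparseable")
  flag(df$n_broods <= 3, "variance undefined")

  bad_rel <- !(df$relationship %in% relationship_levels())
  flag(bad_rel, "unknown relationship")

  if (!"z" %in% names(df)) df$z <- NA_real_
  if (!"r" %in% names(df)) df$r <- NA_real_
  df$r <- suppressWarnings(as.numeric(df$r))
  df$z <- suppressWarnings(as.numeric(df$z))
  no_z <- is.na(df$z) & !is.na(df$r)
  df$z[no_z] <- suppressWarnings(atanh(df$r[no_z]))
  no_r <- is.na(df$r) & !is.na(df$z)
  df$r[no_r] <- tanh(df$z[no_r])
  flag(is.na(df$z), "effect size unparseable")
  flag(abs(df$r) >= 1, "|r| >= 1")
  both <- !is.na(df$r) & !is.na(df$z) & abs(df$r) < 1
  inconsistent <- both & abs(df$z - atanh(pmin(pmax(df$r, -1 + 1e-12), 1 - 1e-12))) > 1e-6
  flag(inconsistent, "z and r inconsistent")

  # environment: accept labels or codes; missing -> normal (conservative)
  env_map <- c(poor = -1, normal = 0, good = 1)
  if (!"environment" %in% names(df)) df$environment <- "normal"
  env_chr <- as.character(df$environment)
  env_chr[is.na(env_chr) | env_chr == ""] <- "normal"
  env_code <- ifelse(env_chr %in% names(env_map), env_map[env_chr],
                     suppressWarnings(as.numeric(env_chr)))
  flag(!(env_code %in% c(-1, 0, 1)), "environment code invalid")
  df$env_code <- as.numeric(env_code)

  if ("brood_strategy" %in% names(df)) {
    bad_bs <- !(df$brood_strategy %in% c("brood_reducing", "whole_brood_survival"))
    flag(bad_bs, "unknown brood strategy")
  }

  if (!"v" %in% names(df)) df$v <- NA_real_
  df$v <- suppressWarnings(as.numeric(df$v))
  ok_n <- is.finite(df$n_broods) & df$n_broods > 3
  no_v <- is.na(df$v) & ok_n
  df$v[no_v] <- 1 / (df$n_broods[no_v] - 3)

  keep <- is.na(reject_reason)
  rejects <- data.frame(record_id = df$record_id[!keep],
                        reason = reject_reason[!keep],
                        stringsAsFactors = FALSE)
  data <- df[keep, , drop = FALSE]
  rownames(data) <- NULL

  structure(
    list(
      data = data,
      rejects = rejects,
      n_records = nrow(data),
      n_species = length(unique(data$species)),
      n_studies = length(unique(data$study_id))
    ),
    class = "es_dataset"
  )
}

#' @export
print.es_dataset <- function(x, ...) {
  cat(sprintf("Effect-size dataset: %d effect sizes, %d studies, %d species\n",
              x$n_records, x$n_studies, x$n_species))
  if (nrow(x$rejects))
    cat(sprintf("  (%d rows rejected at load; see $rejects)\n", nrow(x$rejects)))
  invisible(x)
}

#' Split a dataset by species or study
#'
#' @param dataset an `es_dataset`.
#' @param by `"species"` or `"study"`.
#' @return named list of data.frames, one per group.
#' @export
dataset_index <- function(dataset, by = c("species", "study")) {
  by <- match.arg(by)
  col <- if (by == "species") "species" else "study_id"
  split(dataset$data, dataset$data[[col]])
}

#' Classify a species' brood-reduction strategy
#'
#' Primary rule: a species is brood reducing if hatching is asynchronous
#' (24 h or more between first and last chick) AND later-hatched nestlings
#' die at a greater rate. When either primary input is unknown, the fallback
#' rule applies: brood reducing if at least one chick starves in at least
#' 75% of broods. Everything else is whole-brood survival. With all three
#' inputs unknown the species cannot be classified and must be excluded.
#'
#' @param hatch_spread_hours hours between first and last hatching, or `NA`.
#' @param later_hatched_die_more `"yes"`, `"no"`, or `"unknown"`/`NA`.
#' @param starvation_brood_fraction proportion of broods losing at least one
#'   chick to starvation, in `[0, 1]`, or `NA`.
#' @return `"brood_reducing"` or `"whole_brood_survival"`.
#' @export
#' @examples
#' classify_brood_strategy(36, "yes", NA)
#' classify_brood_strategy(NA, "unknown", 0.8)
classify_brood_strategy <- function(hatch_spread_hours = NA,
                                    later_hatched_die_more = "unknown",
                                    starvation_brood_fraction = NA) {
  die <- as.character(later_hatched_die_more)
  if (is.na(die) || !die %in% c("yes", "no", "unknown"))
    die <- if (is.na(die)) "unknown" else
      bm_stop("later_hatched_die_more must be yes/no/unknown", "bm_domain_error")
  spread_known <- !is.na(hatch_spread_hours)
  die_known <- die != "unknown"
  starv_known <- !is.na(starvation_brood_fraction)
  if (!spread_known && !die_known && !starv_known)
    bm_stop("all classification inputs unknown; species must be excluded",
            "bm_classification_error")
  if (spread_known && hatch_spread_hours < 0)
    bm_stop("hatch_spread_hours must be non-negative", "bm_domain_error")
  if (starv_known &&
      (starvation_brood_fraction < 0 || starvation_brood_fraction > 1))
    bm_stop("starvation_brood_fraction must be in [0, 1]", "bm_domain_error")

  primary_known <- spread_known && die_known
  primary_met <- primary_known && hatch_spread_hours >= 24 && die == "yes"
  fallback_met <- !primary_known && starv_known && starvation_brood_fraction >= 0.75
  if (primary_met || fallback_met) "brood_reducing" else "whole_brood_survival"
}

#' Apply eligibility filters to a dataset
#'
#' Encodes the exclusion rules used before analysis:
#' * `drop_hunger_only`: records of the condition-signal relationships whose
#'   only condition measure was a proximate hunger treatment are excluded
#'   (hunger is not long-term condition). Feeding-response records are kept
#'   regardless of the measure, since analyses of parental behaviour assume
#'   nothing about what the signal transmits.
#' * `drop_confounded`: records flagged in a logical `confounded` column
#'   (begging vs size cues not separable) are excluded.
#' * `single_egg_species`: species laying one-egg clutches are excluded.
#'
#' Every removed record appears in the exclusion ledger with exactly one
#' reason; `|kept| + |excluded| = |input|`.
#'
#' @param dataset an `es_dataset`.
#' @param rules list with any of `drop_hunger_only` (logical),
#'   `drop_confounded` (logical), `single_egg_species` (character vector of
#'   species names). An empty list leaves the dataset unchanged.
#' @return list with `dataset` (filtered `es_dataset`) and `exclusions`
#'   (data.frame `record_id`, `reason`).
#' @export
filter_eligible <- function(dataset, rules = list()) {
  stopifnot(inherits(dataset, "es_dataset"))
  df <- dataset$data
  reason <- rep(NA_character_, nrow(df))
  mark <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- why
  }

  if (isTRUE(rules$drop_hunger_only) && "condition_measure" %in% names(df)) {
    mark(df$relationship %in% c("condition_begging", "condition_structural") &
           df$condition_measure == "hunger_treatment",
         "hunger-only condition measure")
  }
  if (isTRUE(rules$drop_confounded) && "confounded" %in% names(df)) {
    mark(as.logical(df$confounded), "begging/size cue not separable")
  }
  if (length(rules$single_egg_species)) {
    mark(df$species %in% normalize_species(rules$single_egg_species),
         "single-egg species")
  }

  keep <- is.na(reason)
  if (!any(keep)) warning("all records excluded by filters")
  out <- as_es_dataset(df[keep, , drop = FALSE])
  list(
    dataset = out,
    exclusions = data.frame(record_id = df$record_id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
}

#' Gate for confounding-moderator analyses
#'
#' A methodological moderator is only analysed when at least two of its
#' levels each carry at least 10 effect sizes.
#'
#' @param dataset an `es_dataset`.
#' @param factor name of a moderator column.
#' @param min_per_level minimum effect sizes per level (default 10).
#' @param min_levels minimum qualifying levels (default 2).
#' @return `TRUE` if the moderator is eligible for analysis.
#' @export
moderator_check_gate <- function(dataset, factor,
                                 min_per_level = 10, min_levels = 2) {
  stopifnot(inherits(dataset, "es_dataset"))
  if (!factor %in% names(dataset$data)) return(FALSE)
  counts <- table(dataset$data[[factor]], useNA = "no")
  sum(counts >= min_per_level) >= min_levels
}
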