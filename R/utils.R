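#' Normalize a species name for joining to tree tips
#'
#' Lowercases and converts spaces to underscores so that dataset species
#' names and Newick tip labels compare equal regardless of the convention
#' used by the source ("Parus major", "parus_major", ...).
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_species(c("Parus major", "parus_MAJOR"))
normalize_species <- function(x) {
  x <- trimws(as.character(x))
  x <- tolower(x)
  gsub("[ ]+", "_", x)
}

# internal: stop() with a class so tests can assert on error type
bm_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "broodmeta_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: draw from N(mu, Sigma) given an upper-triangular chol factor
rmvnorm_chol <- function(mu, R_upper) {
  mu + drop(crossprod(R_upper, stats::rnorm(length(mu))))
}

#' The five parent-offspring communication relationships
#'
#' Levels of the `relationship` factor: offspring long-term condition versus
#' begging or structural signals, and parental feeding versus begging,
#' structural signals or body-size cues.
#'
#' @return character vector of the five relationship codes.
#' @export
relationship_levels <- function() {
  c("condition_begging", "condition_structural",
    "feeding_begging", "feeding_structural", "feeding_size")
}

# internal: canonical moderator factor levels
moderator_levels <- function() {
  list(
    begging_measure   = c("occurrence", "intensity", "hunger_treatment"),
    feeding_measure   = c("occurrence", "continuous", "growth", "mortality"),
    condition_measure = c("health", "rank", "weight", "condition", "food_intake"),
    contrast          = c("dichotomous", "continuous"),
    responder         = c("female", "male", "both", "helper"),
    design            = c("experimental", "observational")
  )
}
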