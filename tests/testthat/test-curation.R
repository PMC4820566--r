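test_that("a clean CSV loads with consistent counts and computed z and v", {
  path <- write_toy_csv()
  ds <- load_dataset(path)
  expect_s3_class(ds, "es_dataset")
  expect_equal(ds$n_records, 10)
  expect_equal(ds$n_studies, 5)
  expect_equal(ds$n_species, 4)
  expect_equal(ds$data$z, atanh(ds$data$r))
  expect_equal(ds$data$v, 1 / (ds$data$n_broods - 3))
  expect_equal(nrow(ds$rejects), 0)
  # species names normalized for tree joining
  expect_true(all(ds$data$species %in% c("sp_a", "sp_b", "sp_c", "sp_d")))
})

test_that("rows with undefined variance are rejected with a reason, not dropped", {
  df <- make_toy_df()
  df$n_broods[3] <- 3
  ds <- as_es_dataset(df)
  expect_equal(ds$n_records, 9)
  expect_equal(ds$rejects$record_id, 3)
  expect_equal(ds$rejects$reason, "variance undefined")
})

test_that("schema mapping renames columns and missing columns are named in errors", {
  df <- make_toy_df()
  names(df)[names(df) == "species"] <- "taxon"
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(load_dataset(path), class = "bm_schema_error")
  expect_error(load_dataset(path, schema = c(species = "nope")),
               regexp = "nope", class = "bm_schema_error")
  ds <- load_dataset(path, schema = c(species = "taxon"))
  expect_equal(ds$n_records, 10)
})

test_that("missing environment is conservatively coded normal", {
  df <- make_toy_df()
  df$environment[2] <- NA
  df$environment[5] <- ""
  ds <- as_es_dataset(df)
  expect_equal(ds$data$env_code[c(2, 5)], c(0, 0))
  expect_equal(sort(unique(ds$data$env_code)), c(-1, 0, 1))
})

test_that("brood strategy decision table behaves over the full input grid", {
  spreads <- list(6, 24, 36, NA)
  dies <- c("yes", "no", "unknown")
  starvs <- list(0.10, 0.75, 0.90, NA)
  for (sp in spreads) for (d in dies) for (st in starvs) {
    if (is.na(sp) && d == "unknown" && is.na(st)) {
      expect_error(classify_brood_strategy(sp, d, st),
                   class = "bm_classification_error")
      next
    }
    got <- classify_brood_strategy(sp, d, st)
    primary_known <- !is.na(sp) && d != "unknown"
    expected <- if (primary_known && sp >= 24 && d == "yes") "brood_reducing"
      else if (!primary_known && !is.na(st) && st >= 0.75) "brood_reducing"
      else "whole_brood_survival"
    expect_equal(got, expected,
                 info = paste(sp, d, st))
  }
  # the published examples
  expect_equal(classify_brood_strategy(36, "yes", NA), "brood_reducing")
  expect_equal(classify_brood_strategy(NA, "unknown", 0.80), "brood_reducing")
  expect_equal(classify_brood_strategy(6, "no", 0.10), "whole_brood_survival")
})

test_that("eligibility filters exclude the right records with one reason each", {
  ds <- make_toy_dataset()
  rules <- list(drop_hunger_only = TRUE, drop_confounded = TRUE,
                single_egg_species = "sp d")
  out <- filter_eligible(ds, rules)
  # record 9: hunger-only condition measure on a condition relationship
  # record 10: confounded; records 7, 8: single-egg species
  expect_setequal(out$exclusions$record_id, c(7, 8, 9, 10))
  expect_equal(out$dataset$n_records + nrow(out$exclusions), ds$n_records)
  # hunger treatment on feeding relationships is retained
  expect_true(all(out$dataset$data$relationship[
    out$dataset$data$record_id <= 6] == "feeding_begging"))
})

test_that("filtering is idempotent and empty rules change nothing", {
  ds <- make_toy_dataset()
  expect_equal(filter_eligible(ds, list())$dataset$data, ds$data)
  rules <- list(drop_hunger_only = TRUE, drop_confounded = TRUE)
  once <- filter_eligible(ds, rules)$dataset
  twice <- filter_eligible(once, rules)$dataset
  expect_equal(twice$data, once$data)
})

test_that("moderator gate needs two levels with at least 10 effects", {
  mk <- function(counts) {
    df <- make_toy_df()[rep(1, sum(counts)), ]
    df$record_id <- seq_len(nrow(df))
    df$n_broods <- 10
    df$fac <- rep(paste0("L", seq_along(counts)), counts)
    as_es_dataset(df)
  }
  expect_true(moderator_check_gate(mk(c(12, 15, 3)), "fac"))
  expect_false(moderator_check_gate(mk(c(30, 9)), "fac"))
  expect_true(moderator_check_gate(mk(c(10, 10)), "fac"))
  expect_false(moderator_check_gate(make_toy_dataset(), "not_a_column"))
})
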