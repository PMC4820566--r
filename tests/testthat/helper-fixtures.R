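# Hand-built miniature dataset: 2 strategies, 4 species, 5 studies,
# both condition_* and feeding_* relationships.
make_toy_df <- function() {
  data.frame(
    record_id = 1:10,
    species = c("sp a", "sp a", "sp b", "sp b", "sp c",
                "sp c", "sp d", "sp d", "sp a", "sp b"),
    study_id = c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s4", "s5", "s5"),
    relationship = c(rep("feeding_begging", 6), rep("condition_begging", 4)),
    r = c(0.5, 0.3, 0.2, -0.1, 0.4, 0.6, -0.2, 0.1, 0.25, -0.35),
    n_broods = c(10, 12, 20, 8, 15, 30, 9, 11, 25, 14),
    environment = c("poor", "normal", "good", "normal", "normal",
                    "good", "poor", "normal", "normal", "good"),
    brood_strategy = c(rep("brood_reducing", 4), rep("whole_brood_survival", 6)),
    condition_measure = c(rep("weight", 8), "hunger_treatment", "health"),
    feeding_measure = rep(c("continuous", "growth"), 5),
    confounded = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE
  )
}

make_toy_dataset <- function() as_es_dataset(make_toy_df())

# tiny fixed newick trees
NWK_3TIP <- "((A:1,B:1):1,C:2);"
NWK_STAR <- "(A:1,B:1,C:1,D:1);"

write_toy_csv <- function(df = make_toy_df()) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  path
}

# random small model instance for oracle checks
random_instance <- function(n = 6, seed = 1) {
  set.seed(seed)
  n_sp <- sample(2:4, 1)
  n_st <- sample(2:3, 1)
  tree <- ape::rcoal(n_sp)
  tree$tip.label <- paste0("sp", seq_len(n_sp))
  df <- data.frame(
    record_id = seq_len(n),
    species = sample(tree$tip.label, n, replace = TRUE),
    study_id = sample(paste0("st", seq_len(n_st)), n, replace = TRUE),
    relationship = "feeding_begging",
    z = rnorm(n, 0.3, 0.5),
    n_broods = sample(5:40, n, replace = TRUE),
    environment = rep(c("poor", "good", "normal"), length.out = n),
    brood_strategy = rep(c("brood_reducing", "whole_brood_survival"),
                         length.out = n),
    stringsAsFactors = FALSE
  )
  list(dataset = as_es_dataset(df), tree = tree)
}
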