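test_that("Yule trees are deterministic under seed, ultrametric, right size", {
  t1 <- simulate_tree(50, 1, 4)
  t2 <- simulate_tree(50, 1, 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 50)
  depths <- diag(ape::vcv.phylo(t1))
  expect_lt(max(depths) - min(depths), 1e-9)
  expect_true(all(t1$edge.length > 0))
  cherry <- simulate_tree(2, 1, 1)
  expect_equal(length(cherry$tip.label), 2)
})

test_that("simulated datasets are reproducible and pass curation by construction", {
  cfg <- synthetic_config(seed = 31, n_species = 12)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$dataset$data, b$dataset$data)
  expect_equal(nrow(a$dataset$rejects), 0)
  expect_equal(a$dataset$data$v, 1 / (a$dataset$data$n_broods - 3))
  expect_true(all(abs(a$dataset$data$r) < 1))
  expect_true(all(a$dataset$data$n_broods >= 5))
  # ground truth reconstructs every observed record: z - true mean is the
  # measurement noise, standardized it should look standard normal
  zstd <- (a$dataset$data$z - a$truth$true_means) / sqrt(a$dataset$data$v)
  expect_lt(abs(mean(zstd)), 4 / sqrt(length(zstd)))
})

test_that("with all variances and coefficients zero, z is pure sampling noise", {
  cfg <- synthetic_config(
    seed = 77, n_species = 40, effects_per_study = 12,
    studies_per_species = 2,
    beta_true = c(brood_reducing = 0, whole_brood_survival = 0,
                  environment = 0, reduction_x_environment = 0),
    vcomp_true = c(phylo = 0, species = 0, study = 0, unit = 0))
  sim <- simulate_dataset(cfg)
  z <- sim$dataset$data$z
  v <- sim$dataset$data$v
  n <- length(z)
  expect_gt(n, 500)
  expect_lt(abs(mean(z / sqrt(v))), 4 / sqrt(n))
  expect_equal(var(z / sqrt(v)), 1, tolerance = 0.15)
})

test_that("lambda = 0 removes phylogenetic correlation from species effects", {
  # under lambda = 0 the phylo effects are iid: their empirical correlation
  # with the tree (Abouheif/Moran-type via C weights) should vanish on average
  set.seed(1)
  cors <- replicate(30, {
    cfg <- synthetic_config(seed = sample.int(1e6, 1), n_species = 30,
                            lambda = 0,
                            vcomp_true = c(phylo = 1, species = 0,
                                           study = 0, unit = 0))
    sim <- simulate_dataset(cfg)
    C <- bm_correlation(sim$tree)$C
    x <- sim$truth$phylo_effects[rownames(C)]
    W <- C - diag(diag(C))
    # Moran-like cross-product statistic, standardized
    sum(W * outer(x, x)) / (sum(W) * var(x))
  })
  expect_lt(abs(mean(cors)), 0.15)
})

test_that("strategy clustering on the tree produces both strategies", {
  cfg <- synthetic_config(seed = 9, n_species = 30,
                          phylo_clustered_strategy = TRUE)
  sim <- simulate_dataset(cfg)
  expect_setequal(unique(sim$dataset$data$brood_strategy),
                  c("brood_reducing", "whole_brood_survival"))
})

test_that("raw t statistics round-trip through the conversion layer", {
  cfg <- synthetic_config(seed = 15, n_species = 10, emit_raw_stats = TRUE)
  sim <- simulate_dataset(cfg)
  d <- sim$dataset$data
  expect_equal(r_from_t(d$t_stat, d$t_df), d$r, tolerance = 1e-10)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(lambda = 1.5), class = "bm_config_error")
  expect_error(synthetic_config(env_probs = c(0.5, 0.4, 0.2)),
               class = "bm_config_error")
  expect_error(synthetic_config(vcomp_true = c(phylo = -1, species = 0,
                                               study = 0, unit = 0)),
               class = "bm_config_error")
})

test_that("zero-variance truth piles component estimates at the boundary", {
  cfg <- synthetic_config(seed = 41, n_species = 20,
                          vcomp_true = c(phylo = 0, species = 0,
                                         study = 0, unit = 0))
  rec <- recovery_experiment(cfg, n_replicates = 3, method = "reml")
  comp <- rec$per_replicate[rec$per_replicate$parameter %in%
                              c("phylo", "species", "study", "unit"), ]
  expect_lt(mean(comp$estimate), 0.01)
})

test_that("more data reduces the RMSE of the environment slope", {
  small <- synthetic_config(seed = 55, n_species = 15)
  big <- synthetic_config(seed = 55, n_species = 60, effects_per_study = 4)
  r_small <- recovery_experiment(small, n_replicates = 8, method = "reml")
  r_big <- recovery_experiment(big, n_replicates = 8, method = "reml")
  rm_s <- r_small$summary$rmse[r_small$summary$parameter == "environment"]
  rm_b <- r_big$summary$rmse[r_big$summary$parameter == "environment"]
  expect_lt(rm_b, rm_s)
})
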