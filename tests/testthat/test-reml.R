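test_that("restricted loglik and GLS match the dense oracle on tiny instances", {
  for (seed in 1:6) {
    inst <- random_instance(n = sample(5:8, 1), seed = seed)
    design <- build_design(inst$dataset, "feeding_begging")
    pc <- bm_correlation(inst$tree)
    Cm <- pc$C[match(design$species_levels, pc$species_order),
               match(design$species_levels, pc$species_order), drop = FALSE]
    for (theta in list(c(phylo = 0.1, species = 0.05, study = 0.2, unit = 0.01),
                       c(phylo = 0, species = 0.3, study = 0, unit = 0.15))) {
      expect_equal(reml_loglik(design, pc, theta),
                   oracle_reml_loglik(design, Cm, theta),
                   tolerance = 1e-8)
      fit <- reml_fit(design, pc, pin_vcomp = theta)
      expect_equal(unname(fit$beta$estimate),
                   unname(oracle_gls_beta(design, Cm, theta)),
                   tolerance = 1e-8)
    }
  }
})

test_that("with all components pinned to zero the fit is the weighted mean", {
  ds <- make_toy_dataset()
  design <- build_design(ds, "feeding_begging", fixed = "intercept")
  fit <- reml_fit(design, NULL,
                  pin_vcomp = c(phylo = 0, species = 0, study = 0, unit = 0))
  w <- 1 / design$v
  expect_equal(fit$beta$estimate, sum(w * design$y) / sum(w),
               tolerance = 1e-12)
})

test_that("a constant response with no signal collapses to that constant", {
  df <- make_toy_df()
  df$r <- 0.3
  design <- build_design(as_es_dataset(df), "feeding_begging",
                         fixed = "intercept")
  fit <- reml_fit(design, NULL)
  expect_equal(fit$beta$estimate, atanh(0.3), tolerance = 1e-6)
  expect_true(all(fit$vcomp$estimate < 1e-4))
  expect_true(all(fit$vcomp$boundary | fit$vcomp$estimate < 1e-4))
})

test_that("estimates are invariant to rescaling all branch lengths", {
  sim <- simulate_dataset(synthetic_config(seed = 11, n_species = 15))
  design <- build_design(sim$dataset, "feeding_begging")
  tr2 <- sim$tree
  tr2$edge.length <- tr2$edge.length * 40
  f1 <- reml_fit(design, bm_correlation(sim$tree))
  f2 <- reml_fit(design, bm_correlation(tr2))
  expect_equal(f1$beta$estimate, f2$beta$estimate, tolerance = 1e-6)
  expect_equal(f1$vcomp$estimate, f2$vcomp$estimate, tolerance = 1e-5)
})

test_that("REML agrees with an independent multilevel meta-analytic fitter", {
  skip_if_not_installed("metafor")
  sim <- simulate_dataset(synthetic_config(seed = 5, n_species = 25))
  design <- build_design(sim$dataset, "feeding_begging")
  pc <- bm_correlation(sim$tree)
  fit <- reml_fit(design, pc)

  dat <- sim$dataset$data
  dat$species_phylo <- dat$species
  dat$unit <- seq_len(nrow(dat))
  dat$wbs <- as.numeric(dat$brood_strategy == "whole_brood_survival")
  Cm <- pc$C
  mf <- metafor::rma.mv(
    z ~ 0 + factor(brood_strategy) + env_code + I(env_code * wbs),
    V = dat$v, data = dat,
    random = list(~ 1 | species_phylo, ~ 1 | species, ~ 1 | study_id,
                  ~ 1 | unit),
    R = list(species_phylo = Cm), Rscale = "none",
    method = "REML", sparse = FALSE,
    control = list(optimizer = "optim", optmethod = "BFGS")
  )
  # same model, independent implementation: estimates should agree closely
  expect_equal(unname(sort(fit$beta$estimate)),
               unname(sort(as.numeric(mf$beta))), tolerance = 1e-3)
  expect_equal(sum(fit$vcomp$estimate), sum(mf$sigma2), tolerance = 1e-2)
})
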