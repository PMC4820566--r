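make_two_fits <- function(est1 = 0.2, est2 = 0.4) {
  sim <- simulate_dataset(synthetic_config(seed = 13, n_species = 8))
  design <- build_design(sim$dataset, "feeding_begging")
  C <- bm_correlation(sim$tree)
  f <- reml_fit(design, C)
  f1 <- f; f2 <- f
  f1$beta$estimate[] <- est1
  f2$beta$estimate[] <- est2
  list(f1, f2)
}

test_that("combining identical fits reproduces the single fit", {
  fits <- make_two_fits(0.3, 0.3)
  comb <- combine_over_trees(list(fits[[1]]))
  expect_equal(comb$beta$estimate, fits[[1]]$beta$estimate)
  expect_equal(comb$n_trees, 1L)
})

test_that("REML combination averages estimates and widens intervals", {
  fits <- make_two_fits(0.2, 0.4)
  comb <- combine_over_trees(fits)
  expect_equal(comb$beta$estimate, rep(0.3, 4))
  # between-tree spread inflates the pooled standard error
  expect_true(all(comb$beta$se >= fits[[1]]$beta$se - 1e-12))
  expect_equal(comb$n_trees, 2L)
})

test_that("mismatched or empty fit lists are refused", {
  fits <- make_two_fits()
  bad <- fits[[2]]
  bad$beta$term[1] <- "something_else"
  expect_error(combine_over_trees(list(fits[[1]], bad)),
               class = "bm_mismatch_error")
  expect_error(combine_over_trees(list()), class = "bm_domain_error")
})

test_that("MCMC combination pools samples with equal weight", {
  sim <- simulate_dataset(synthetic_config(seed = 17, n_species = 10))
  design <- build_design(sim$dataset, "feeding_begging")
  st <- mcmc_settings(iterations = 700, burnin = 200, thin = 5, seed = 31)
  f1 <- mcmc_fit(design, bm_correlation(sim$tree), st)
  st$seed <- 32
  f2 <- mcmc_fit(design, bm_correlation(sim$tree), st)
  comb <- combine_over_trees(list(f1, f2))
  expect_equal(nrow(comb$samples$beta),
               nrow(f1$samples$beta) + nrow(f2$samples$beta))
  expect_equal(comb$beta$estimate,
               colMeans(rbind(f1$samples$beta, f2$samples$beta)),
               ignore_attr = TRUE)
})

test_that("derived contrasts follow their definitions in both modes", {
  sim <- simulate_dataset(synthetic_config(seed = 19, n_species = 12))
  design <- build_design(sim$dataset, "feeding_begging")
  C <- bm_correlation(sim$tree)

  rf <- derived_contrasts(reml_fit(design, C))
  tab <- rf$beta
  diff <- tab$estimate[tab$term == "reduction_difference"]
  expect_equal(diff,
               tab$estimate[tab$term == "whole_brood_survival"] -
                 tab$estimate[tab$term == "brood_reducing"])
  g <- design$n_by_strategy / sum(design$n_by_strategy)
  expect_equal(tab$estimate[tab$term == "grand_mean"],
               unname(g[1] * tab$estimate[tab$term == "brood_reducing"] +
                        g[2] * tab$estimate[tab$term == "whole_brood_survival"]))

  mf <- derived_contrasts(mcmc_fit(design, C,
    mcmc_settings(iterations = 700, burnin = 200, thin = 5, seed = 8)))
  bs <- mf$samples$beta
  expect_equal(unname(mf$samples$derived[, "reduction_difference"]),
               unname(bs[, "whole_brood_survival"] - bs[, "brood_reducing"]))
  # equal group weights make the grand mean the plain average of level means
  mf2 <- mf
  mf2$n_by_strategy <- c(brood_reducing = 5, whole_brood_survival = 5)
  mf2$beta <- mf$beta[1:4, ]
  mf2 <- derived_contrasts(mf2)
  expect_equal(mf2$beta$estimate[mf2$beta$term == "grand_mean"],
               mean(c(mf2$beta$estimate[mf2$beta$term == "brood_reducing"],
                      mf2$beta$estimate[mf2$beta$term == "whole_brood_survival"])))
})

test_that("fit_table mirrors the published row order", {
  sim <- simulate_dataset(synthetic_config(seed = 23, n_species = 10))
  design <- build_design(sim$dataset, "feeding_begging")
  fit <- derived_contrasts(reml_fit(design, bm_correlation(sim$tree)))
  expect_equal(fit_table(fit)$term,
               c("brood_reducing", "whole_brood_survival",
                 "reduction_difference", "environment",
                 "reduction_x_environment", "grand_mean"))
})
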