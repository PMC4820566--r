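test_that("t and F statistics convert to the expected correlations", {
  expect_equal(r_from_t(0, 10), 0)
  expect_equal(r_from_t(2, 16), 2 / sqrt(20))
  expect_equal(r_from_t(-2, 16), -r_from_t(2, 16))
  expect_error(r_from_t(1, 0.5), class = "bm_domain_error")

  expect_equal(r_from_F(4, 1, 16), 2 / sqrt(20))
  expect_equal(r_from_F(0, 1, 9), 0)
  expect_error(r_from_F(4, 2, 16), class = "bm_unsupported_statistic")
})

test_that("F conversion agrees with the t conversion on a (t, df) grid", {
  for (t in c(-3, -1.2, 0.4, 2.5)) {
    for (df in c(4, 11, 30)) {
      expect_equal(r_from_F(t^2, 1, df), abs(r_from_t(t, df)), tolerance = 1e-12)
    }
  }
})

test_that("means conversion follows the d-to-r chain with group-size correction", {
  expect_equal(r_from_means(1, 1, 1, 2, 10, 12), 0)
  # d = 1, h = 4 -> r = 1/sqrt(5)
  expect_equal(r_from_means(1, 0, 1, 1, 10, 10), 1 / sqrt(5))
  expect_equal(r_from_means(0, 1, 1, 1, 10, 10),
               -r_from_means(1, 0, 1, 1, 10, 10))
  expect_error(r_from_means(1, 0, 0, 1, 10, 10), class = "bm_domain_error")
  # Hedges correction shrinks towards zero
  expect_lt(abs(r_from_means(1, 0, 1, 1, 5, 5, hedges = TRUE)),
            abs(r_from_means(1, 0, 1, 1, 5, 5)))
})

test_that("chi-square conversion handles df=1 only and respects N", {
  expect_equal(r_from_chisq(4, 1, 100), 0.2)
  expect_error(r_from_chisq(4, 2, 100), class = "bm_unsupported_statistic")
  expect_error(r_from_chisq(120, 1, 100), class = "bm_domain_error")
})

test_that("Fisher Z is odd, increasing, and round-trips with tanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), class = "bm_domain_error")
})

test_that("sampling variance is 1/(n-3), defined only for n >= 4, decreasing", {
  expect_equal(z_variance(4), 1)
  expect_equal(z_variance(103), 0.01)
  expect_error(z_variance(3), class = "bm_domain_error")
  n <- 4:100
  expect_true(all(diff(z_variance(n)) < 0))
})

test_that("direction attachment is mandatory for unsigned statistics", {
  expect_equal(apply_sign(0.3, "more_signal_more_outcome"), 0.3)
  expect_equal(apply_sign(0.3, "more_signal_less_outcome"), -0.3)
  expect_error(apply_sign(0.3, "none_reported"), class = "bm_direction_error")
})

test_that("convert_statistics routes each statistic kind and keeps provenance", {
  raw <- data.frame(
    statistic = c("r", "t", "F", "chisq", "means"),
    value = c(0.5, 2, 4, 4, NA),
    df = c(NA, 16, NA, 1, NA),
    df1 = c(NA, NA, 1, NA, NA),
    df2 = c(NA, NA, 16, NA, NA),
    n_total = c(NA, NA, NA, 100, NA),
    direction = c(NA, NA, "more_signal_less_outcome",
                  "more_signal_more_outcome", NA),
    m1 = c(NA, NA, NA, NA, 1), m2 = c(NA, NA, NA, NA, 0),
    sd1 = c(NA, NA, NA, NA, 1), sd2 = c(NA, NA, NA, NA, 1),
    n1 = c(NA, NA, NA, NA, 10), n2 = c(NA, NA, NA, NA, 10),
    n_broods = c(10, 19, 19, 103, 13),
    stringsAsFactors = FALSE
  )
  out <- convert_statistics(raw)
  expect_equal(out$r, c(0.5, 2 / sqrt(20), -2 / sqrt(20), 0.2, 1 / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(out$z, atanh(out$r))
  expect_equal(out$v, 1 / (raw$n_broods - 3))
  expect_equal(out$source_statistic, raw$statistic)
  expect_error(convert_statistics(raw[, -1]), class = "bm_schema_error")
})
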