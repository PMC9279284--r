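test_that("OLS temperature models recover noiseless coefficients exactly", {
  temp <- seq(-5, 27, by = 2)
  lakes <- data.frame(temp = temp, burial = 4.23 * temp + 15.15)
  forest <- data.frame(temp = temp, oc_accum = 82.93 + 4.01 * temp + 0.08 * temp^2)
  fits <- fit_temperature_models(lakes, forest)
  expect_equal(unname(fits$lake_linear$coefficients[, "estimate"]),
               c(15.15, 4.23), tolerance = 1e-10)
  expect_equal(unname(fits$forest_quadratic$coefficients[, "estimate"]),
               c(82.93, 4.01, 0.08), tolerance = 1e-10)
  expect_equal(fits$lake_linear$r_squared, 1, tolerance = 1e-10)
  # evaluation at 0 degrees returns the intercept
  expect_equal(predict(fits$lake_linear, 0), 15.15)
  # constant response: slope 0, r2 0
  flat <- fit_temperature_models(data.frame(temp = temp, burial = 50))
  expect_equal(unname(flat$lake_linear$coefficients["slope", "estimate"]), 0)
  expect_equal(flat$lake_linear$r_squared, 0)
  expect_error(fit_temperature_models(data.frame(temp = c(1, 2), burial = c(1, 2))),
               "at least 3")
})

test_that("OLS residuals are orthogonal to the design columns", {
  set.seed(14)
  for (i in 1:5) {
    x <- runif(30, 0, 30); y <- 3 + 2 * x + rnorm(30, 0, 5)
    f <- fit_temperature_models(data.frame(temp = x, burial = y))$lake_linear
    r <- stats::resid(f$fit)
    expect_lt(abs(sum(r)), 1e-8)
    expect_lt(abs(sum(r * x)), 1e-8)
  }
})

test_that("exponential fit recovers noiseless coefficients and equals log-linear", {
  g <- make_forest_gradient(seq(0, 100, by = 20), a = 56.21, b = 0.01608)
  f <- fit_forest_exponential(g$forest_pct, g$burial)
  expect_equal(f$coefficients["a", "estimate"], 56.21, tolerance = 1e-4)
  expect_equal(f$coefficients["b", "estimate"], 0.01608, tolerance = 1e-4)
  # noiseless: nonlinear and log-linear estimates coincide
  loglin <- lm(log(g$burial) ~ g$forest_pct)
  expect_equal(f$coefficients["a", "estimate"], exp(unname(coef(loglin)[1])),
               tolerance = 1e-8)
  expect_equal(predict(f, 0), 56.21, tolerance = 1e-6)
  # constant data: a equals the mean
  const <- fit_forest_exponential(seq(0, 100, 20), rep(77, 6))
  expect_equal(const$coefficients["a", "estimate"], 77, tolerance = 1e-6)
  expect_error(fit_forest_exponential(c(0, 50, 100), c(10, -5, 20)), "positive")
})

test_that("exponential coefficient bias vanishes as noise decreases", {
  x <- seq(0, 100, by = 10)
  bias <- sapply(c(0.2, 0.1, 0.05, 0.02, 0.01), function(cv) {
    ab <- rowMeans(sapply(1:40, function(s) {
      g <- make_forest_gradient(x, noise_cv = cv, seed = s)
      f <- fit_forest_exponential(g$forest_pct, g$burial)
      f$coefficients[, "estimate"]
    }))
    abs(ab - c(56.21, 0.01608)) / c(56.21, 0.01608)
  })
  # mean absolute relative bias of a and b shrinks with the noise level
  expect_lt(max(bias[, 5]), 0.005)
  expect_true(all(colMeans(bias)[5] <= colMeans(bias)[1]))
})

test_that("group comparison separates distant groups and pools identical ones", {
  # identical data in every group -> a single shared letter
  same <- list(a = c(10, 20, 30), b = c(10, 20, 30), c = c(10, 20, 30))
  g0 <- group_comparison(same)
  expect_equal(length(unique(unname(g0$letters))), 1)
  # means separated by ~10 pooled SDs -> distinct letters
  set.seed(21)
  far <- list(low = exp(rnorm(12, 3, 0.1)), high = exp(rnorm(12, 4, 0.1)))
  g1 <- group_comparison(far)
  expect_false(g1$letters[["low"]] == g1$letters[["high"]])
  expect_lt(g1$p_value, 0.001)
  # groups with n < 2 are excluded with a warning
  expect_warning(g2 <- group_comparison(list(a = c(1, 2, 3), b = 7,
                                             c = c(2, 3, 4))),
                 "excluded")
  expect_equal(g2$excluded, "b")
  # diagnostics are reported as htest objects
  expect_s3_class(g1$kruskal, "htest")
  expect_s3_class(g1$ks, "htest")
  expect_s3_class(g1$bartlett, "htest")
})

test_that("letter displays are partition-consistent with Tukey results", {
  set.seed(33)
  rates <- list(a = exp(rnorm(10, 3.0, 0.3)), b = exp(rnorm(10, 3.1, 0.3)),
                c = exp(rnorm(10, 4.5, 0.3)))
  g <- group_comparison(rates)
  p <- g$tukey$class[, "p adj"]
  share <- function(x, y) {
    lx <- strsplit(g$letters[[x]], "")[[1]]
    ly <- strsplit(g$letters[[y]], "")[[1]]
    length(intersect(lx, ly)) > 0
  }
  # non-significant pairs share at least one letter
  expect_true(!xor(p[["b-a"]] > 0.05, share("a", "b")))
  expect_true(!xor(p[["c-a"]] > 0.05, share("a", "c")))
})

test_that("buffer selection maximizes r-squared with ties to smaller buffers", {
  fits <- list("3" = list(r_squared = 0.2), "6" = list(r_squared = 0.8),
               "12" = list(r_squared = 0.5))
  expect_equal(select_buffer(fits), 6)
  expect_equal(select_buffer(list("8" = list(r_squared = 0.4))), 8)
  tied <- list("4" = list(r_squared = 0.6), "12" = list(r_squared = 0.6))
  expect_equal(select_buffer(tied), 4)
})

test_that("variance curve is seed-deterministic and exact at full sample size", {
  set.seed(2); rates <- rlnorm(40, 3, 0.8)
  curve1 <- variance_curve(rates, c(10, 20, 40), reps = 50, seed = 9)
  curve2 <- variance_curve(rates, c(10, 20, 40), reps = 50, seed = 9)
  expect_identical(curve1, curve2)
  expect_equal(curve1$mean_variance[3], var(rates))
  # E[sample variance] equals the full-sample variance at every subsample
  # size (simple random sampling), so the curve is flat within MC error
  set.seed(6); mild <- rlnorm(40, 3, 0.5)
  flat <- variance_curve(mild, c(10, 20, 40), reps = 800, seed = 4)
  expect_lt(max(abs(flat$mean_variance - var(mild))) / var(mild), 0.15)
  expect_error(variance_curve(rates, 50), "exceeds")
})
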