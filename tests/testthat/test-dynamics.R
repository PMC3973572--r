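test_that("autocovariate is the kernel-weighted leave-one-out average", {
  # constant residuals are reproduced exactly at any bandwidth
  loc <- cbind(runif(8, 0, 5), runif(8, 0, 5))
  for (s in c(0.5, 2, 10)) {
    expect_equal(build_autocovariate(loc, rep(3.7, 8), s), rep(3.7, 8))
  }
  # two units: each sees only the other
  expect_equal(build_autocovariate(cbind(c(0, 1), 0), c(1, -1), 1),
               c(-1, 1))
  # three units on a line, hand-summed kernel weights
  loc3 <- cbind(c(0, 1, 10), 0)
  r3 <- c(1, 1, 0)
  w12 <- dnorm(1, 0, 1); w13 <- dnorm(10, 0, 1); w23 <- dnorm(9, 0, 1)
  manual <- c((w12 * 1 + w13 * 0) / (w12 + w13),
              (w12 * 1 + w23 * 0) / (w12 + w23),
              (w13 * 1 + w23 * 1) / (w13 + w23))
  expect_equal(build_autocovariate(loc3, r3, 1), manual,
               tolerance = 1e-12)
  expect_error(build_autocovariate(cbind(1, 1), 0.3, 1), "2 units")
})

test_that("forcing the zero part off reproduces the plain NB likelihood", {
  d <- simulate_transect_counts(seed = 2, zi_intercept = -10)
  f1 <- fit_zinb(d, zero_inflation = FALSE)
  d2 <- dplyr::mutate(d, year = factor(.data$year))
  f2 <- MASS::glm.nb(count ~ year + offset(log(length_km)), data = d2)
  expect_equal(f1$loglik, as.numeric(logLik(f2)), tolerance = 1e-6)
})

test_that("internal ZINB engine matches glmmTMB on the same likelihood", {
  d <- simulate_transect_counts(seed = 2)
  tmb <- fit_zinb(d, year_in = "both")
  int <- fit_zinb(d, year_in = "both", engine = "internal")
  expect_equal(int$loglik, tmb$loglik, tolerance = 1e-5)
  expect_equal(unname(int$par[1:3]),
               unname(glmmTMB::fixef(tmb$model)$cond), tolerance = 1e-3)
  expect_equal(int$theta, tmb$theta, tolerance = 1e-3)
})

test_that("likelihood-ratio arithmetic and reference tail probabilities", {
  d <- simulate_transect_counts(seed = 3)
  f <- fit_zinb(d, year_in = "both")
  same <- lr_test(f, f)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  # stated year-effect test: chi2 = 9.59 on 4 df is just below 0.05
  t1 <- lr_test(fake_ll(0, 5), fake_ll(-9.59 / 2, 1))
  expect_equal(t1$df, 4)
  expect_lt(t1$p_value, 0.05)
  expect_gt(t1$p_value, 0.04)
  # chi2 = 3.71 on 2 df -> p ~ 0.16
  t2 <- lr_test(fake_ll(0, 3), fake_ll(-3.71 / 2, 1))
  expect_lt(abs(t2$p_value - 0.16), 0.005)
  expect_error(lr_test(fake_ll(0, 1), fake_ll(0, 3)), "more parameters")
})

test_that("releveling the year factor leaves the fit invariant", {
  d <- simulate_transect_counts(seed = 11)
  f1 <- fit_zinb(d, year_in = "both")
  f2 <- relevel_year(f1, 2012)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  c1 <- glmmTMB::fixef(f1$model)$cond
  c2 <- glmmTMB::fixef(f2$model)$cond
  # (2013 vs 2012) contrast equals the difference of 2011-referenced
  # effects, to optimiser tolerance
  expect_equal(unname(c2["year2013"]),
               unname(c1["year2013"] - c1["year2012"]), tolerance = 1e-4)
  # two-level factor: the slope flips sign
  d2 <- dplyr::filter(d, .data$year != 2013)
  g1 <- fit_zinb(d2, year_in = "count")
  g2 <- relevel_year(g1, 2012)
  expect_equal(unname(glmmTMB::fixef(g2$model)$cond["year2011"]),
               -unname(glmmTMB::fixef(g1$model)$cond["year2012"]),
               tolerance = 1e-4)
  expect_error(relevel_year(f1, 1999), "Unknown")
})

test_that("offsets are handled correctly for long transects", {
  d <- simulate_transect_counts(n_transects = 400,
                                length_range = c(3, 10), seed = 17)
  f <- fit_zinb(d, year_in = "both")
  td <- tidy(f)
  ic <- td[td$part == "count" & td$term == "(Intercept)", ]
  expect_lt(abs(ic$estimate - 1.172), 2 * ic$std.error)
})

test_that("jackknife influence flags a gross outlier and runs at minimal n", {
  d <- simulate_transect_counts(n_transects = 20, years = 2011:2012,
                                year_effects = c(0, 0),
                                zi_year_effects = c(0, 0), seed = 23)
  d$count[7] <- 400L
  f <- fit_zinb(d, year_in = "count")
  jk <- jackknife_influence(f)
  ic <- dplyr::filter(jk, .data$term == "(Intercept)")
  expect_equal(ic$unit[which.max(abs(ic$delta))], 7)
  expect_equal(nrow(jk) / dplyr::n_distinct(jk$term), nrow(d))
  tiny <- dplyr::slice(d, 1:3)
  f3 <- suppressWarnings(fit_zinb(tiny, year_in = "none"))
  jk3 <- suppressWarnings(jackknife_influence(f3))
  expect_equal(dplyr::n_distinct(jk3$unit), 3)
})

test_that("bandwidth profiling recovers a known correlation range", {
  grid <- exp(seq(log(0.3), log(15), length.out = 9))
  sds <- vapply(1:8, function(r) {
    optimize_bandwidth(spatial_counts(r, range_km = 2), sd_grid = grid,
                       year_in = "none", n_null = 25, seed = r)$sd_km
  }, numeric(1))
  # loose recovery: within a factor of three of the generating 2 km in
  # at least half the replicates
  expect_gte(mean(sds >= 2 / 3 & sds <= 6), 0.5)
})

test_that("single-point bandwidth grid returns trivially", {
  d <- simulate_transect_counts(seed = 5)
  bw <- optimize_bandwidth(d, sd_grid = 1.5)
  expect_equal(bw$sd_km, 1.5)
  expect_true(bw$fit$has_autocov)
  expect_equal(nrow(bw$profile), 1)
})
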