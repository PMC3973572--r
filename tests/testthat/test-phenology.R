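test_that("fruit index is the basal-area-weighted fruiting proportion", {
  obs <- tibble::tibble(
    date = as.Date("2012-01-01"),
    species = c("a", "a", "b"),
    prop_fruiting = c(0.5, 0.5, 0.25),
    forest = "F1"
  )
  ba <- tibble::tibble(species = c("a", "b"), basal_area_m2ha = c(2, 4))
  idx <- fruit_index(obs, ba, unit = "forest")
  expect_equal(idx$value, 0.5 * 2 + 0.25 * 4)
  # single species, half fruiting, basal area 2 -> 1.0
  expect_equal(fruit_index(obs[1, ], ba, unit = "forest")$value, 1)
  # nothing fruiting -> 0
  zero <- dplyr::mutate(obs, prop_fruiting = 0)
  expect_equal(fruit_index(zero, ba, unit = "forest")$value, 0)
  # additivity over disjoint species sets
  both <- fruit_index(obs, ba, species_filter = c("a", "b"),
                      unit = "forest")$value
  parts <- fruit_index(obs, ba, species_filter = "a",
                       unit = "forest")$value +
    fruit_index(obs, ba, species_filter = "b", unit = "forest")$value
  expect_equal(both, parts)
  # species without a basal area are excluded with a warning
  obs2 <- dplyr::bind_rows(obs, dplyr::mutate(obs[1, ], species = "c"))
  expect_warning(v <- fruit_index(obs2, ba,
                                  species_filter = c("a", "b", "c"),
                                  unit = "forest"),
                 "basal area")
  expect_equal(v$value, both)
})

test_that("power transform recovers identity and log scales", {
  set.seed(4)
  x <- data.frame(a = rnorm(200))
  y_norm <- 10 + 2 * x$a + rnorm(200, 0, 0.8)
  pt1 <- estimate_power_transform(y_norm, x)
  expect_true(pt1$ci[1] <= 1 && 1 <= pt1$ci[2])
  y_log <- exp(1 + 0.5 * x$a + rnorm(200, 0, 0.4))
  pt0 <- estimate_power_transform(y_log, x)
  expect_true(pt0$ci[1] <= 0 && 0 <= pt0$ci[2])
  expect_lt(abs(pt0$lambda), 0.2)
  # agrees with the profile-likelihood grid maximum
  dfb <- data.frame(yy = y_log, a = x$a)
  bc <- MASS::boxcox(lm(yy ~ a, data = dfb, y = TRUE, qr = TRUE),
                     lambda = seq(-1, 1.5, 0.01), plotit = FALSE)
  expect_lt(abs(pt0$lambda - bc$x[which.max(bc$y)]), 0.02)
  expect_error(estimate_power_transform(c(1, -1, 2)), "positive")
})

test_that("seasonal model recovers amplitude, phase and forest offset", {
  sp <- equal_basal_areas()
  sum_ba <- sum(sp$basal_area_m2ha)
  obs <- simulate_phenology(
    phenology_config(amplitude = 0.1, forest_offset = 0.1,
                     noise_sd = 0.05, phase = 0.5),
    plots = balanced_plots(), seed = 12)
  fit <- fit_seasonal_model(fruit_index(obs, sp, unit = "forest"),
                            lambda = 1)
  td <- tidy(fit)
  bf <- td[td$term == "forestNkala", ]
  expect_lt(abs(bf$estimate - 0.1 * sum_ba), 2 * bf$std.error)
  bs <- td[td$term == "sin_date", ]; bc <- td[td$term == "cos_date", ]
  expect_lt(abs(fit$amplitude - 0.1 * sum_ba),
            2 * sqrt(bs$std.error^2 + bc$std.error^2))
  expect_lt(abs(fit$phase - 0.5), 0.3)
})

test_that("null seasonality is rarely declared significant", {
  sp <- equal_basal_areas()
  rejected <- logical(20)
  for (r in 1:20) {
    obs <- simulate_phenology(
      phenology_config(amplitude = 0, forest_offset = 0.1,
                       noise_sd = 0.05),
      plots = balanced_plots(), seed = 100 + r)
    fit <- fit_seasonal_model(fruit_index(obs, sp, unit = "forest"),
                              lambda = 1)
    no_season <- lm(y ~ forest, data = fit$data)
    rejected[r] <- f_test(fit, no_season)$p_value < 0.05
  }
  expect_lte(mean(rejected), 0.15)
})

test_that("amplitude is invariant to a shift of the date origin", {
  sp <- equal_basal_areas()
  obs <- simulate_phenology(
    phenology_config(amplitude = 0.1, forest_offset = 0.1,
                     noise_sd = 0.03),
    dates = seq(as.Date("2012-02-01"), by = 14, length.out = 20),
    plots = balanced_plots(), seed = 3)
  ser <- fruit_index(obs, sp, unit = "forest")
  f1 <- fit_seasonal_model(ser, lambda = 1)
  ser2 <- dplyr::mutate(ser, date = .data$date + 50)
  f2 <- fit_seasonal_model(ser2, lambda = 1)
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-8)
})

test_that("F-test identities: null comparison and single-regressor t-square", {
  set.seed(9)
  df <- data.frame(x1 = rnorm(60), x2 = rnorm(60))
  df$y <- 1 + df$x1 + 0.5 * df$x2 + rnorm(60)
  full <- lm(y ~ x1 + x2, data = df)
  red <- lm(y ~ x1, data = df)
  same <- f_test(full, full)
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)
  ft <- f_test(full, red)
  tval <- summary(full)$coefficients["x2", "t value"]
  expect_equal(ft$F, tval^2, tolerance = 1e-8)
  expect_equal(ft$df1, 1)
  expect_error(f_test(red, full), "nested")
})

test_that("daily proportions take the nearest observation, earlier on ties", {
  obs <- tibble::tibble(date = as.Date("2012-01-01") + c(0, 14),
                        prop_fruiting = c(0.2, 0.8))
  expect_equal(daily_fruiting_proportion(obs, obs$date[1]), 0.2)
  # exact midpoint (7 days to each) -> earlier observation
  expect_equal(daily_fruiting_proportion(obs, obs$date[1] + 7), 0.2)
  # 1 day after the first, 13 before the second -> the first
  expect_equal(daily_fruiting_proportion(obs, obs$date[1] + 1), 0.2)
  expect_equal(daily_fruiting_proportion(obs, obs$date[2] - 1), 0.8)
})
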