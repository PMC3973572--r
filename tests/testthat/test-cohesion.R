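test_that("AICc closed form and large-n limit", {
  # AIC = 100 with k = 2, n = 10: correction 2*2*3/7
  expect_equal(aicc(-48, k = 2, n = 10), 100 + 12 / 7)
  expect_equal(aicc(-48, k = 2, n = 1e9), 100, tolerance = 1e-6)
  expect_error(aicc(-48, k = 5, n = 6), "n > k")
})

test_that("spatio-temporal kernel reduces and matches brute force", {
  loc <- cbind(c(0, 2, 5), c(0, 1, 4))
  dates <- as.Date("2012-01-01") + c(0, 30, 200)
  r <- c(1.5, -0.5, 2)
  # infinite temporal SD reduces to the purely spatial autocovariate
  expect_equal(spatiotemporal_autocovariate(loc, dates, r, 2, Inf),
               build_autocovariate(loc, r, 2), tolerance = 1e-10)
  expect_equal(spatiotemporal_autocovariate(loc, dates, rep(4, 3), 2, 50),
               rep(4, 3))
  # brute-force product-kernel computation
  ds <- as.matrix(dist(loc)); dt <- as.matrix(dist(as.numeric(dates)))
  w <- dnorm(ds, 0, 2) * dnorm(dt, 0, 50); diag(w) <- 0
  manual <- as.numeric((w %*% r) / rowSums(w))
  expect_equal(spatiotemporal_autocovariate(loc, dates, r, 2, 50),
               manual, tolerance = 1e-12)
  expect_error(spatiotemporal_autocovariate(loc[1, , drop = FALSE],
                                            dates[1], r[1], 2, 50),
               "2 sites")
})

test_that("scaling the community-size offset shifts only the intercept", {
  d <- simulate_nesting_sites("two_communities", seed = 5)
  f1 <- fit_cohesion(d, "two_communities")
  d2 <- dplyr::mutate(d, builders_forest = 3 * .data$builders_forest,
                      builders_total = 3 * .data$builders_total)
  f2 <- fit_cohesion(d2, "two_communities")
  c1 <- coef(f1$model); c2 <- coef(f2$model)
  expect_equal(unname(c2["(Intercept)"] - c1["(Intercept)"]), -log(3),
               tolerance = 1e-6)
  expect_equal(unname(c1[-1]), unname(c2[-1]), tolerance = 1e-6)
})

test_that("design matrix predictors are standardised", {
  d <- simulate_nesting_sites("two_communities", seed = 6)
  f <- fit_cohesion(d, "two_communities")
  X <- model.matrix(f$model)
  for (col in setdiff(colnames(X), "(Intercept)")) {
    expect_equal(mean(X[, col]), 0, tolerance = 1e-10)
    expect_equal(sd(X[, col]), 1, tolerance = 1e-10)
  }
})

test_that("hypothesis comparison reports winners and ties", {
  d <- simulate_nesting_sites("two_communities", seed = 2)
  f2 <- fit_cohesion(d, "two_communities")
  f1 <- fit_cohesion(d, "one_community")
  cmp <- compare_hypotheses(f1, f2)
  expect_equal(cmp$winner,
               if (cmp$aicc_model2 < cmp$aicc_model1) "two_communities"
               else "one_community")
  tie <- compare_hypotheses(f1, f1)
  expect_equal(tie$winner, "tie")
  expect_equal(tie$delta_aicc, 0)
  short <- fit_cohesion(d[1:60, ], "one_community")
  expect_error(compare_hypotheses(short, f2), "same sites")
})

test_that("environmental block test is a 4-df likelihood ratio", {
  d <- simulate_nesting_sites("two_communities", seed = 9)
  f <- fit_cohesion(d, "two_communities")
  null <- fit_cohesion_null(f)
  bt <- environmental_block_test(f, null)
  expect_equal(bt$df, 4)
  expect_gte(bt$chi2, 0)
  same <- environmental_block_test(f, f)
  expect_equal(same$chi2, 0)
  # stated block test: chi2 = 11.42 on 4 df is significant at 0.05
  ref <- lr_test(fake_ll(0, 5), fake_ll(-11.42 / 2, 1))
  expect_lt(abs(ref$p_value - 0.022), 0.001)
  expect_lt(ref$p_value, 0.05)
})

test_that("the environmental block test holds its size under the null", {
  rej <- logical(30)
  for (r in 1:30) {
    d <- simulate_nesting_sites("two_communities", b_fruit_site = 0,
                                b_trees = 0, seed = 400 + r)
    f <- fit_cohesion(d, "two_communities")
    rej[r] <- environmental_block_test(f, fit_cohesion_null(f))$p_value <
      0.05
  }
  # within 3 binomial SEs of the nominal 5%
  expect_lte(mean(rej), 0.17)
})

test_that("leverage screening flags constructed influential sites", {
  d <- simulate_nesting_sites("two_communities", seed = 10)
  d$fruit_site[4] <- 60 * max(d$fruit_site)
  f <- fit_cohesion(d, "two_communities")
  scr <- leverage_screen(f)
  expect_true(4 %in% scr$flagged)
  all_kept <- leverage_screen(f, threshold_mult = Inf)
  expect_length(all_kept$flagged, 0)
  expect_equal(all_kept$retained, seq_len(f$n))
})

test_that("bandwidth grid of one point returns that point", {
  d <- simulate_nesting_sites("two_communities", seed = 3)
  bw <- optimize_two_bandwidths(d, grid_s = 2, grid_t = 60, n_boot = 20,
                                seed = 1)
  expect_equal(bw$sd_s_km, 2)
  expect_equal(bw$sd_t_days, 60)
  expect_equal(nrow(bw$profile), 1)
})

test_that("a strong spatial field leads to a retained autocovariate", {
  d <- simulate_nesting_sites("two_communities", spatial_sd_km = 2,
                              spatial_amp = 1, theta = 20, seed = 201)
  bw <- suppressWarnings(
    optimize_two_bandwidths(d, grid_s = c(1, 3), grid_t = c(30, 90),
                            n_boot = 60, seed = 1))
  expect_true(bw$ac_retained)
  expect_true(is.finite(bw$sd_s_km) && is.finite(bw$sd_t_days))
  expect_true(bw$fit$has_autocov)
})
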