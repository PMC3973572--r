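test_that("half-normal ESW matches the closed form and the p_bar identity", {
  x <- halfnorm_distances(3000, sigma = 10, w = 35, seed = 42)
  fit <- fit_detection(x, 35, max_cos_order = 0)
  # quadrature ESW against the closed form at the fitted scale
  expect_equal(fit$esw_m, esw_halfnorm(fit$sigma_m, 35), tolerance = 1e-6)
  expect_equal(fit$p_bar * fit$truncation_w_m, fit$esw_m,
               tolerance = 1e-9)
  expect_equal(effective_strip_width(fit), fit$esw_m, tolerance = 1e-9)
  # the generating sigma = 10 gives ESW ~ 12.53 m
  expect_lt(abs(fit$esw_m - 12.53), 0.6)
})

test_that("degenerate concentration near zero gives a tiny scale", {
  x <- abs(rnorm(400, 0, 0.8))
  fit <- fit_detection(x, 35, max_cos_order = 0)
  expect_lt(fit$sigma_m, 2)
  expect_equal(fit$p_bar, fit$sigma_m * sqrt(pi / 2) / 35,
               tolerance = 1e-3)
})

test_that("detection-probability truncation inverts the fitted scale", {
  x <- halfnorm_distances(2500, sigma = 18, w = 60, seed = 7)
  fit <- fit_detection(x, 60, max_cos_order = 0)
  tr <- truncate_by_detection(fit, x, threshold = 0.15,
                              max_cos_order = 0)
  expect_equal(tr$truncation_w_m, fit$sigma_m * sqrt(-2 * log(0.15)),
               tolerance = 1e-6)
  expect_true(all(tr$distances_m <= tr$truncation_w_m))
  expect_lt(tr$fit$truncation_w_m, 60)
  # threshold 0 drops nothing
  tr0 <- truncate_by_detection(fit, x, threshold = 0, max_cos_order = 0)
  expect_equal(tr0$truncation_w_m, max(x))
  expect_equal(length(tr0$distances_m), length(x))
})

test_that("nest density arithmetic, equivariance and errors", {
  fake <- structure(list(esw_m = 20, truncation_w_m = 35),
                    class = "detection_fit")
  one <- nest_density(tibble::tibble(length_km = 50, n = 100), fake)
  expect_equal(one$nest_density_km2, 50)
  expect_equal(nest_density(tibble::tibble(length_km = 10, n = 0),
                            fake)$nest_density_km2, 0)
  expect_error(nest_density(tibble::tibble(length_km = 0, n = 3), fake),
               "effort")
  # doubling all efforts at fixed counts halves the estimate
  base <- nest_density(tibble::tibble(length_km = c(2, 3, 5),
                                      n = c(4, 0, 9)), fake)
  dbl <- nest_density(tibble::tibble(length_km = 2 * c(2, 3, 5),
                                     n = c(4, 0, 9)), fake)
  expect_equal(dbl$nest_density_km2, base$nest_density_km2 / 2)
})

test_that("nest-to-individual conversion identities hold", {
  cc <- conversion_constants(decay_days = 183)
  expect_equal(individuals_from_nests(1.37 * 0.75 * 183, cc), 1)
  expect_equal(individuals_from_nests(0, cc), 0)
  builders <- individuals_from_nests(100, cc, include_nonbuilders = FALSE)
  all_ind <- individuals_from_nests(100, cc)
  expect_equal(builders / all_ind, 0.75)
})

test_that("area weighting of stratified abundance", {
  areas <- tibble::tibble(stratum = c("A", "B"), area_km2 = c(25, 75))
  est <- tibble::tibble(stratum = c("A", "B"), ind_density_km2 = c(1, 0),
                        cv_pct = c(0, 0))
  g <- stratified_abundance(est, areas)
  expect_equal(g$ind_density_km2, 0.25)
  expect_equal(g$abundance_n, round(0.25 * 100))
  eq <- tibble::tibble(stratum = c("A", "B"),
                       ind_density_km2 = c(0.4, 0.4), cv_pct = c(10, 20))
  expect_equal(stratified_abundance(eq, areas)$ind_density_km2, 0.4)
})

test_that("AIC model selection breaks ties toward fewer parameters", {
  mk <- function(aic, npar) structure(
    list(aic = aic, par = numeric(npar), converged = TRUE, valid = TRUE),
    class = "detection_fit")
  expect_equal(select_key_function(list(mk(100, 1), mk(98.5, 2)))$aic, 98.5)
  tie <- select_key_function(list(mk(100, 3), mk(100, 1)))
  expect_equal(length(tie$par), 1)
  single <- mk(55, 2)
  expect_identical(select_key_function(list(single)), single)
  bad <- structure(list(converged = FALSE, valid = FALSE, aic = Inf),
                   class = "detection_fit")
  expect_error(select_key_function(list(bad)), "No converged")
})

test_that("scale recovery and key selection on simulated half-normal data", {
  cover <- hn_wins <- logical(20)
  for (r in 1:20) {
    x <- halfnorm_distances(2000, sigma = 12, w = 35, seed = r)
    f <- fit_detection(x, 35, max_cos_order = 0)
    ci <- exp(log(f$sigma_m) + c(-1.96, 1.96) * sqrt(f$vcov[1, 1]))
    cover[r] <- ci[1] <= 12 && 12 <= ci[2]
    x5 <- halfnorm_distances(500, sigma = 12, w = 35, seed = 100 + r)
    hn <- fit_detection(x5, 35, max_cos_order = 0, key = "halfnorm")
    hz <- fit_detection(x5, 35, key = "hazard")
    hn_wins[r] <- select_key_function(list(hn, hz))$key == "halfnorm"
  }
  expect_gte(mean(cover), 0.85)
  expect_gte(mean(hn_wins), 0.8)
})

test_that("density table carries coherent intervals and abundances", {
  s <- simulate_survey(seed = 21)
  d <- unlist(s$distances_m)
  fit <- fit_detection(d, 35, max_cos_order = 0)
  est <- density_by_stratum(s, fit, conversion_constants(decay_days = 183))
  expect_true(all(est$lcl <= est$ind_density_km2 + 1e-12))
  expect_true(all(est$ind_density_km2 <= est$ucl + 1e-12))
  expect_true(all(est$abundance_n >= 0))
  a <- stratum_table()
  nk <- dplyr::filter(est, .data$stratum == "Nkala", .data$year == 2011)
  expect_equal(nk$abundance_n,
               round(nk$ind_density_km2 *
                       a$area_km2[a$stratum == "Nkala"]))
})
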