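test_that("preference chi-square is zero under exact proportionality", {
  nests <- tibble::tibble(species = c("a", "b", "c"),
                          nests = c(20, 30, 50))
  ab <- tibble::tibble(species = c("a", "b", "c"),
                       n_stems = c(200, 300, 500))
  res <- preference_test(nests, ab, n_perm = 500, seed = 1)
  expect_equal(res$chi2, 0)
  expect_gt(res$p_permutation, 0.99)
  expect_length(res$preferred, 0)
  expect_error(preference_test(dplyr::mutate(nests, nests = 0), ab),
               "Zero total")
})

test_that("permutation p matches the exact binomial null tail on a 2-species toy", {
  nests <- tibble::tibble(species = c("a", "b"), nests = c(10, 0))
  ab <- tibble::tibble(species = c("a", "b"), n_stems = c(50, 50))
  res <- preference_test(nests, ab, n_perm = 20000, seed = 7)
  # exact enumeration of the multinomial (here binomial) null
  chi2_of <- function(x) (x - 5)^2 / 5 + ((10 - x) - 5)^2 / 5
  exact <- sum(dbinom(0:10, 10, 0.5)[chi2_of(0:10) >= res$chi2 - 1e-12])
  expect_equal(exact, 2 * 0.5^10, tolerance = 1e-12)
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(res$p_permutation - exact), 3 * mc_se + 1 / 20001)
})

test_that("per-species binomial tail identifies a preferred species", {
  nests <- tibble::tibble(species = c("rare", "common"), nests = c(5, 5))
  ab <- tibble::tibble(species = c("rare", "common"),
                       n_stems = c(100, 900))
  res <- preference_test(nests, ab, n_perm = 2000, seed = 3)
  p_rare <- res$by_species$p_binomial[res$by_species$species == "rare"]
  # closed-form upper tail P(X >= 5 | n = 10, p = 0.1)
  expect_equal(p_rare, sum(dbinom(5:10, 10, 0.1)), tolerance = 1e-12)
  expect_lt(abs(p_rare - 0.0016), 2e-4)
  expect_true("rare" %in% res$preferred)
  expect_false("common" %in% res$preferred)
})

test_that("suitable-tree density scales with the reference area", {
  trees <- rep(c("pref", "other"), c(20, 0))
  expect_equal(suitable_tree_density(trees, "pref",
                                     reference_area_ha = 0.1), 200)
  expect_equal(suitable_tree_density(trees, "none-here",
                                     reference_area_ha = 0.1), 0)
  expect_equal(suitable_tree_density(trees, "pref",
                                     reference_area_ha = 0.2),
               suitable_tree_density(trees, "pref",
                                     reference_area_ha = 0.1) / 2)
  expect_error(suitable_tree_density(trees, "pref",
                                     reference_area_ha = 0), "positive")
})

test_that("village influence sums population over distance", {
  v1 <- tibble::tibble(village = "A", x_km = 0, y_km = 2, pop = 100)
  expect_equal(village_influence(c(0, 0), v1), 50)
  v2 <- dplyr::bind_rows(v1, tibble::tibble(village = "B", x_km = 10,
                                            y_km = 0, pop = 300))
  expect_equal(village_influence(c(0, 0), v2), 50 + 30)
  # moving away from every village strictly decreases the index
  expect_lt(village_influence(c(-5, -5), v2),
            village_influence(c(0, 0), v2))
  expect_error(village_influence(c(0, 2), v1), "zero distance")
})

test_that("human forest use evaluates the per-activity formula", {
  q <- tibble::tibble(
    person_id = "p1", village = "V", gender = "M", activity = "hunting",
    freq_per_day = 1, n_regions = 1, region = "R1"
  )
  vil <- tibble::tibble(village = "V", n_men = 10, n_women = 999)
  # (freq / n_regions) / n_interviewed * n_men / area = 1 * 10 / 2
  expect_equal(human_forest_use("R1", q, vil, region_area_km2 = 2), 5)
  # men-only activity never draws from the women's census count
  vil2 <- dplyr::mutate(vil, n_women = 0)
  expect_equal(human_forest_use("R1", q, vil2, 2), 5)
  # nobody visits the region -> 0
  expect_equal(human_forest_use("R2", q, vil, 2), 0)
  # doubling the region area halves the index
  expect_equal(human_forest_use("R1", q, vil, 4), 2.5)
  expect_error(human_forest_use("R1", q, vil, 0), "positive")
})

test_that("rainfall window sums the 30 days strictly before building", {
  days <- seq(as.Date("2012-01-01"), as.Date("2012-04-01"), by = 1)
  rain <- tibble::tibble(date = days, rain_mm = 5)
  built <- as.Date("2012-03-01")
  expect_equal(rainfall_window(rain, built), 150)
  expect_equal(rainfall_window(dplyr::mutate(rain, rain_mm = 0), built), 0)
  # a storm exactly 31 days before is outside the window
  storm <- dplyr::mutate(rain, rain_mm = ifelse(date == built - 31,
                                                40, 0))
  expect_equal(rainfall_window(storm, built), 0)
  expect_equal(rainfall_window(dplyr::mutate(
    rain, rain_mm = ifelse(date == built - 30, 40, 0)), built), 40)
  gappy <- dplyr::filter(rain, date < built - 20)
  expect_warning(rainfall_window(gappy, built), "missing")
})

test_that("site fruit availability weights fruiting proportions by stem basal area", {
  # 10 stems of one species, half fruiting, DBH 20 cm over 0.1 ha
  st <- tibble::tibble(species = "a", dbh_cm = 20,
                       fruiting = rep(c(TRUE, FALSE), 5))
  ba <- 10 * pi * (20 / 200)^2 / 0.1
  expect_equal(site_fruit_availability(st, site_area_ha = 0.1),
               0.5 * ba)
  expect_equal(site_fruit_availability(st, species_filter = "zz"), 0)
  none <- dplyr::mutate(st, fruiting = FALSE)
  expect_equal(site_fruit_availability(none, site_area_ha = 0.1), 0)
})

test_that("windowed forest fruit availability averages daily proportions", {
  ba <- tibble::tibble(species = "a", basal_area_m2ha = 3)
  built <- as.Date("2012-06-01")
  const <- tibble::tibble(date = built - c(40, 20, 5), species = "a",
                          prop_fruiting = 0.4)
  expect_equal(forest_fruit_availability_14d(const, ba, built), 0.4 * 3)
  # proportion steps 0 -> 1 halfway through the window: obs at -11 (0)
  # and -4 (1) split the 14 days 7/7 under nearest-date assignment
  step <- tibble::tibble(date = built - c(11, 4), species = "a",
                         prop_fruiting = c(0, 1))
  expect_equal(forest_fruit_availability_14d(step, ba, built), 0.5 * 3)
  empty <- tibble::tibble(date = as.Date(character()),
                          species = character(),
                          prop_fruiting = numeric())
  expect_equal(forest_fruit_availability_14d(empty, ba, built), 0)
})

test_that("community size interpolates with inverse-gap weights", {
  sv <- tibble::tibble(date = as.Date("2012-01-01") + c(0, 100),
                       builders = c(20, 10))
  expect_equal(interpolate_community_size(sv, sv$date[1]), 20)
  expect_equal(interpolate_community_size(sv, sv$date[1] + 25), 17.5)
  expect_equal(interpolate_community_size(sv, sv$date[1] + 50), 15)
  out <- interpolate_community_size(sv, sv$date[1] - 30)
  expect_equal(as.numeric(out), 20)
  expect_true(isTRUE(attr(out, "extrapolated")))
  expect_error(interpolate_community_size(sv[0, ], sv$date[1]),
               "No surveys")
})

test_that("z-transform conventions: sample sd, idempotence, affine invariance", {
  expect_equal(z_transform(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50)
  z <- z_transform(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(z_transform(z), z, tolerance = 1e-12)
  expect_equal(z_transform(5 + 2 * x), z, tolerance = 1e-12)
  expect_error(z_transform(rep(2, 5)), "constant")
})
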