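#' Test for preferred nesting-tree species
#'
#' Chi-squared goodness-of-fit of the observed distribution of nesting
#' trees over species against expectation proportional to species
#' abundance in the forest, with the p-value taken from multinomial
#' permutation under the abundance null (not the chi-square distribution),
#' using the add-one correction `(1 + #{chi2* >= chi2}) / (n_perm + 1)`.
#' One-sided exact binomial tests per species then flag the preferred set
#' at the chosen alpha.
#'
#' @param nest_counts Tibble with `species` and `nests` (nesting-tree
#'   counts per species).
#' @param abundance Tibble with `species` and `n_stems` (stems in the
#'   tree-abundance survey); every tested species must have positive
#'   abundance.
#' @param n_perm Number of multinomial permutations (default 10000).
#' @param alpha Per-species significance threshold (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @return Object of class `preference_result`: list with `chi2`,
#'   `p_permutation`, `n_perm`, `by_species` (tibble with `species`,
#'   `nests`, `expected`, `p_binomial`, `preferred`) and `preferred`
#'   (character vector).
#' @export
preference_test <- function(nest_counts, abundance, n_perm = 10000,
                            alpha = 0.05, seed = 1) {
  check_columns(nest_counts, c("species", "nests"), "nest_counts")
  check_columns(abundance, c("species", "n_stems"), "abundance")
  df <- dplyr::inner_join(nest_counts, abundance, by = "species")
  if (any(df$n_stems <= 0)) abort("All tested species need positive abundance.")
  total <- sum(df$nests)
  if (total <= 0) abort("Zero total nests.")
  share <- df$n_stems / sum(df$n_stems)
  expected <- total * share
  chi2 <- sum((df$nests - expected)^2 / expected)
  set.seed(child_seed(seed, "preference"))
  sims <- rmultinom(n_perm, size = total, prob = share)
  chi2_sim <- colSums((sims - expected)^2 / expected)
  p_perm <- (1 + sum(chi2_sim >= chi2 - 1e-12)) / (n_perm + 1)
  p_binom <- pbinom(df$nests - 1, size = total, prob = share,
                    lower.tail = FALSE)
  by_species <- tibble::tibble(species = df$species, nests = df$nests,
                               n_stems = df$n_stems, expected = expected,
                               p_binomial = p_binom,
                               preferred = p_binom < alpha)
  structure(list(chi2 = chi2, p_permutation = p_perm, n_perm = n_perm,
                 alpha = alpha, by_species = by_species,
                 preferred = by_species$species[by_species$preferred]),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf(
    "Nesting-tree preference: chi2 = %.2f, permutation p = %.4g (n_perm = %d)\nPreferred species (binomial p < %.2g): %s\n",
    x$chi2, x$p_permutation, x$n_perm, x$alpha,
    if (length(x$preferred)) paste(x$preferred, collapse = ", ") else "none"))
  invisible(x)
}

#' Density of preferred nesting-tree species at a site
#'
#' Count of preferred-species stems among the site's nest and control
#' trees divided by the site reference area.  The reference area is a
#' fixed-radius disc around the site centroid (default radius 30 m, i.e.
#' 0.2827 ha); it is a convention, so it is exposed as an argument.
#'
#' @param site_trees Character vector of species of the site's nest and
#'   control trees (pooled).
#' @param preferred Character vector of preferred species.
#' @param reference_area_ha Site reference area in hectares
#'   (default `pi * 30^2 / 1e4`).
#' @return Stems of preferred species per hectare.
#' @export
suitable_tree_density <- function(site_trees, preferred,
                                  reference_area_ha = pi * 30^2 / 1e4) {
  if (reference_area_ha <= 0) abort("Reference area must be positive.")
  sum(site_trees %in% preferred) / reference_area_ha
}

#' Village influence on a nesting site
#'
#' Sum over villages of population size divided by distance (km) to the
#' site.
#'
#' @param site_location Numeric `c(x, y)` in km.
#' @param villages Tibble with `x_km`, `y_km` and `pop` (or `n_men` +
#'   `n_women`, which are summed).
#' @return The village-influence index (people per km).
#' @export
village_influence <- function(site_location, villages) {
  check_columns(villages, c("x_km", "y_km"), "villages")
  pop <- if ("pop" %in% names(villages)) villages$pop else
    villages$n_men + villages$n_women
  d <- sqrt((villages$x_km - site_location[1])^2 +
              (villages$y_km - site_location[2])^2)
  if (any(d == 0)) abort("Site coincides with a village (zero distance).")
  sum(pop / d)
}

#' Human forest use of a forest region
#'
#' Daily number of adults who could potentially enter the forest region to
#' hunt, fish or collect non-timber products, per km2 of the region.  For
#' each (village, activity): the per-person probability of entering the
#' region is the daily activity frequency divided by the number of regions
#' the person visits; summed over interviewed persons who visit the region
#' and divided by the number of interviewed performers, this gives the
#' proportion of questionnaire adults entering; scaled by the
#' gender-matched census adult count of the village and the region area,
#' then summed over villages and activities.  The index is log-transformed
#' before modelling (downstream, not here).
#'
#' @param region Forest region label.
#' @param questionnaire Tibble as from [simulate_questionnaire()]:
#'   `person_id`, `village`, `gender`, `activity`, `freq_per_day`,
#'   `n_regions`, `region`.
#' @param villages Census tibble with `village`, `n_men`, `n_women`.
#' @param region_area_km2 Area of the region, km2.
#' @return The human-forest-use index (adults per day per km2).
#' @export
human_forest_use <- function(region, questionnaire, villages,
                             region_area_km2) {
  if (region_area_km2 <= 0) abort("Region area must be positive.")
  check_columns(questionnaire,
                c("person_id", "village", "gender", "activity",
                  "freq_per_day", "n_regions", "region"), "questionnaire")
  check_columns(villages, c("village", "n_men", "n_women"), "villages")
  if (nrow(questionnaire) == 0) return(0)
  performers <- questionnaire |>
    dplyr::distinct(.data$village, .data$activity, .data$person_id,
                    .data$gender) |>
    dplyr::count(.data$village, .data$activity, .data$gender,
                 name = "n_interviewed")
  visits <- questionnaire |>
    dplyr::filter(.data$region == !!region) |>
    dplyr::group_by(.data$village, .data$activity, .data$gender) |>
    dplyr::summarise(enter = sum(.data$freq_per_day / .data$n_regions),
                     .groups = "drop")
  if (nrow(visits) == 0) return(0)
  terms <- visits |>
    dplyr::left_join(performers, by = c("village", "activity", "gender")) |>
    dplyr::left_join(villages[c("village", "n_men", "n_women")],
                     by = "village") |>
    dplyr::mutate(
      adults = ifelse(.data$gender == "M", .data$n_men, .data$n_women),
      prop_quest_adult = ifelse(.data$n_interviewed > 0,
                                .data$enter / .data$n_interviewed, 0)
    )
  if (any(terms$n_interviewed == 0, na.rm = TRUE)) {
    warn("Activity with zero interviewed performers contributes 0.")
  }
  sum(terms$prop_quest_adult * terms$adults, na.rm = TRUE) / region_area_km2
}

#' Rainfall total over the window before nest building
#'
#' Sum of daily rainfall over the `window_days` days strictly before the
#' build date.  If more than 20% of window days are missing from the
#' series, the result carries a `"gappy"` attribute.
#'
#' @param rain_series Tibble with `date`, `rain_mm`.
#' @param date_built Build date.
#' @param window_days Window length in days (default 30).
#' @return Rainfall total in mm.
#' @export
rainfall_window <- function(rain_series, date_built, window_days = 30) {
  check_columns(rain_series, c("date", "rain_mm"), "rain_series")
  window <- seq(date_built - window_days, date_built - 1, by = 1)
  hit <- rain_series$date %in% window
  n_missing <- window_days - sum(hit)
  total <- sum(rain_series$rain_mm[hit])
  if (n_missing > 0.2 * window_days) {
    warn(sprintf("%d of %d window days missing from the rainfall series.",
                 n_missing, window_days))
    attr(total, "gappy") <- TRUE
  }
  total
}

#' Fruit availability at a nesting site
#'
#' Per fleshy-fruit species at the site: proportion of fruiting trees
#' multiplied by the species' basal area at the site (from stem DBH over
#' the site reference area), summed over species.
#'
#' @param site_trees Tibble with `species`, `dbh_cm`, `fruiting`
#'   (logical), for the site's trees.
#' @param species_filter Fleshy-fruit species set (default: all present).
#' @param site_area_ha Site reference area, ha (default disc of radius
#'   30 m).
#' @return The site fruit-availability index.
#' @export
site_fruit_availability <- function(site_trees, species_filter = NULL,
                                    site_area_ha = pi * 30^2 / 1e4) {
  check_columns(site_trees, c("species", "dbh_cm", "fruiting"), "site_trees")
  species_filter <- species_filter %||% unique(site_trees$species)
  df <- dplyr::filter(site_trees, .data$species %in% species_filter)
  if (nrow(df) == 0) return(0)
  df |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      prop = mean(.data$fruiting),
      ba = sum(pi * (.data$dbh_cm / 200)^2) / site_area_ha,
      .groups = "drop"
    ) |>
    dplyr::summarise(value = sum(.data$prop * .data$ba)) |>
    dplyr::pull(.data$value)
}

#' Forest fruit availability over the 14 days before nest building
#'
#' Per species: the mean of daily fruiting proportions (nearest biweekly
#' observation per day) over the 14 days before the build date,
#' multiplied by the species' basal area; summed over the fleshy-fruit
#' species set.
#'
#' @param fruiting_obs Tibble with `date`, `species`, `prop_fruiting`
#'   (already restricted to the forest of interest for a two-community
#'   model, or pooled for a one-community model).
#' @param basal_areas Tibble with `species`, `basal_area_m2ha`.
#' @param date_built Build date.
#' @param window_days Averaging window (default 14).
#' @return The windowed forest fruit-availability index.
#' @export
forest_fruit_availability_14d <- function(fruiting_obs, basal_areas,
                                          date_built, window_days = 14) {
  check_columns(basal_areas, c("species", "basal_area_m2ha"), "basal_areas")
  days <- seq(date_built - window_days, date_built - 1, by = 1)
  species <- intersect(unique(fruiting_obs$species), basal_areas$species)
  if (!length(species)) return(0)
  vals <- vapply(species, function(sp) {
    obs <- fruiting_obs |>
      dplyr::filter(.data$species == sp) |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(prop_fruiting = mean(.data$prop_fruiting),
                       .groups = "drop")
    mean(daily_fruiting_proportion(obs, days))
  }, numeric(1))
  ba <- basal_areas$basal_area_m2ha[match(species, basal_areas$species)]
  sum(vals * ba)
}

#' Interpolate nest-building community size at a build date
#'
#' Weighted mean of the community-size estimates from the surveys before
#' and after the build date, with weights inverse to the time gap
#' (equivalently, linear interpolation in time).  Build dates outside the
#' survey span take the nearest survey's value, flagged with an
#' `"extrapolated"` attribute.
#'
#' @param surveys Tibble with `date` and `builders`.
#' @param date_built Build date.
#' @return Interpolated number of nest-building individuals.
#' @export
interpolate_community_size <- function(surveys, date_built) {
  check_columns(surveys, c("date", "builders"), "surveys")
  if (nrow(surveys) == 0) abort("No surveys supplied.")
  surveys <- dplyr::arrange(surveys, .data$date)
  t <- as.numeric(surveys$date); q <- as.numeric(date_built)
  if (q <= min(t) || q >= max(t)) {
    if (q %in% t) return(surveys$builders[match(q, t)])
    out <- surveys$builders[which.min(abs(t - q))]
    attr(out, "extrapolated") <- TRUE
    return(out)
  }
  stats::approx(t, surveys$builders, xout = q)$y
}
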