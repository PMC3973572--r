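#' Synthetic landscape configuration
#'
#' Defines a planar forest-savannah mosaic on a local projection in
#' kilometres (the study extent is ~17 km, so geodesy is skipped).  The
#' default lays the three strata side by side as rectangles whose areas
#' equal those of [stratum_table()], and places a handful of villages on
#' the savannah edge.
#'
#' @param forests Tibble with columns `stratum`, `x0`, `x1`, `y0`, `y1`
#'   (km) and `area_km2`.  Rectangular strata.
#' @param villages Tibble with `village`, `x_km`, `y_km`, `n_men`, `n_women`.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(forests = NULL, villages = NULL) {
  if (is.null(forests)) {
    areas <- stratum_table()
    height <- 5
    widths <- areas$area_km2 / height
    x1s <- cumsum(widths)
    forests <- tibble::tibble(
      stratum = areas$stratum,
      x0 = c(0, x1s[-length(x1s)]),
      x1 = x1s,
      y0 = 0, y1 = height,
      area_km2 = areas$area_km2
    )
  }
  if (is.null(villages)) {
    villages <- tibble::tibble(
      village = c("Nkala", "Mpelu", "Nkoo", "Malebo"),
      x_km = c(3.2, 12.0, 1.0, 16.5),
      y_km = c(6.0, 6.2, -1.0, -0.8),
      n_men = c(36, 50, 169, 9),
      n_women = c(49, 58, 202, 11)
    )
  }
  stopifnot(all(forests$area_km2 > 0), !anyDuplicated(forests$stratum))
  structure(list(forests = forests, villages = villages),
            class = "landscape_config")
}

#' Nest-building community configuration
#'
#' @param builders Tibble with `community`, `year`, `builders`: the number of
#'   nest-building individuals of each community in each survey year.  The
#'   defaults are 0.75 of the per-stratum community sizes estimated in the
#'   original surveys (Nkala 20/16/17, Mpelu 31/11/17 individuals in
#'   2011/2012/2013).
#' @param nest_rate Nests built per builder per day (default 1.37).
#' @param builder_fraction Proportion of nest-builders in the population
#'   (default 0.75).
#' @param decay_days Mean nest decay time in days (default 183); together
#'   with `nest_rate` it sets the expected standing crop of nests.
#' @param site_cluster_radius_m Maximum distance from a nest to its site
#'   centre (default 15 m, so pairwise nest distances stay below the 30 m
#'   same-site rule).
#' @param mean_site_nests Mean nests per nesting site (default 14, matching
#'   roughly 610 nests over 42 sites).
#' @return A list of class `community_config`.
#' @export
community_config <- function(builders = NULL, nest_rate = 1.37,
                             builder_fraction = 0.75, decay_days = 183,
                             site_cluster_radius_m = 15,
                             mean_site_nests = 14) {
  if (is.null(builders)) {
    builders <- tibble::tibble(
      community = rep(c("Nkala", "Mpelu"), each = 3),
      year = rep(2011:2013, 2),
      builders = c(15, 12, 13, 23, 8, 13)
    )
  }
  stopifnot(nest_rate > 0, builder_fraction > 0, builder_fraction <= 1,
            decay_days > 0, site_cluster_radius_m <= 30)
  structure(list(builders = builders, nest_rate = nest_rate,
                 builder_fraction = builder_fraction, decay_days = decay_days,
                 site_cluster_radius_m = site_cluster_radius_m,
                 mean_site_nests = mean_site_nests),
            class = "community_config")
}

#' Fruit-phenology configuration
#'
#' Parameters of the sinusoidal fruiting-proportion generator.  Proportions
#' are `baseline + amplitude * sin(2*pi*doy/period + phase) +
#' forest_offset * 1[Nkala] + noise`, clipped to `[0, 1]`.
#'
#' @param baseline Mean fruiting proportion (default 0.3).
#' @param amplitude Seasonal amplitude, proportion units (default 0.15).
#' @param phase Phase, radians (default 0).
#' @param forest_offset Additive offset of the Nkala forest over Mpelu,
#'   proportion units (default 0.1; fruit availability is higher in Nkala).
#' @param noise_sd SD of observation noise (default 0.05).
#' @param period_days Seasonal period (default 365.25).
#' @return A list of class `phenology_config`.
#' @export
phenology_config <- function(baseline = 0.3, amplitude = 0.15, phase = 0,
                             forest_offset = 0.1, noise_sd = 0.05,
                             period_days = 365.25) {
  stopifnot(amplitude >= 0, noise_sd >= 0, period_days > 0)
  structure(list(baseline = baseline, amplitude = amplitude, phase = phase,
                 forest_offset = forest_offset, noise_sd = noise_sd,
                 period_days = period_days),
            class = "phenology_config")
}

#' Default fleshy-fruit species table with per-forest basal areas
#'
#' Eight synthetic fleshy-fruit species with basal areas (m2/ha) in each
#' forest; totals are a little higher in Nkala, matching the between-forest
#' contrast the phenology model estimates.
#'
#' @return Tibble with `species`, `forest`, `basal_area_m2ha`.
#' @export
default_fruit_species <- function() {
  sp <- paste0("sp", 1:8)
  ba <- c(2.0, 1.5, 1.2, 1.0, 0.8, 0.6, 0.5, 0.4)
  dplyr::bind_rows(
    tibble::tibble(species = sp, forest = "Nkala", basal_area_m2ha = ba * 1.3),
    tibble::tibble(species = sp, forest = "Mpelu", basal_area_m2ha = ba)
  )
}

# Transects derived from the landscape: west-east lines every 500 m, split
# into segments so transect counts and lengths resemble the study design.
landscape_transects <- function(landscape) {
  segs_per_row <- c("Nkala" = 3, "Mpelu" = 7, "Lokoso&Mankere" = 1)
  rows <- purrr::pmap_dfr(landscape$forests, function(stratum, x0, x1, y0, y1, area_km2) {
    ys <- seq(y0 + 0.25, y1 - 0.25, by = 0.5)
    k <- segs_per_row[[stratum]] %||% 3
    width <- (x1 - x0) / k
    tidyr::expand_grid(y_km = ys, seg = seq_len(k)) |>
      dplyr::mutate(stratum = stratum,
                    x0 = x0 + (.data$seg - 1) * width,
                    x1 = x0 + .data$seg * width,
                    length_km = width)
  })
  rows |>
    dplyr::mutate(transect_id = sprintf("T%03d", dplyr::row_number())) |>
    dplyr::select("transect_id", "stratum", "x0", "x1", "y_km", "length_km")
}

#' Simulate a line-transect nest survey over a synthetic landscape
#'
#' Deposits nests as a Thomas-style cluster process (parents are nesting
#' sites; offspring are nests within the cluster radius) inside each
#' community's forest, with an expected standing crop of
#' `builders * nest_rate * decay_days` nests, then thins nests by
#' half-normal detection `exp(-x^2 / (2 sigma^2))` from west-east transects
#' spaced 500 m.
#'
#' @param landscape A [landscape_config()].
#' @param community A [community_config()].
#' @param detection_sigma_m Half-normal detection scale in metres
#'   (default 12; `Inf` gives perfect detection within the truncation).
#' @param truncation_m Field recording truncation in metres (default 35).
#' @param years Years to survey (default the community table's years).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble, one row per transect-year, with columns `transect_id`,
#'   `stratum`, `year`, `length_km`, `x0`, `x1`, `y_km`, `n_detected` and a
#'   list-column `distances_m` of perpendicular detection distances.  The
#'   attribute `"truth"` holds the generating builder numbers and true
#'   individual densities per stratum-year.
#' @export
simulate_survey <- function(landscape = landscape_config(),
                            community = community_config(),
                            detection_sigma_m = 12, truncation_m = 35,
                            years = NULL, seed = 1) {
  stopifnot(detection_sigma_m > 0, truncation_m > 0)
  if (nrow(landscape$forests) == 0) abort("Empty landscape.")
  transects <- landscape_transects(landscape)
  if (any(transects$length_km <= 0)) abort("Zero-length transects.")
  years <- years %||% sort(unique(community$builders$year))
  set.seed(child_seed(seed, "survey"))
  w_km <- truncation_m / 1000

  out <- purrr::map_dfr(years, function(yr) {
    tr <- transects |> dplyr::mutate(year = yr)
    det <- rep(list(numeric(0)), nrow(tr))
    byr <- dplyr::filter(community$builders, .data$year == yr)
    for (k in seq_len(nrow(byr))) {
      comm <- byr$community[k]
      rect <- dplyr::filter(landscape$forests, .data$stratum == comm)
      if (nrow(rect) == 0) next
      expected <- byr$builders[k] * community$nest_rate * community$decay_days
      n_sites <- rpois(1, expected / community$mean_site_nests)
      if (n_sites == 0) next
      site_x <- runif(n_sites, rect$x0, rect$x1)
      site_y <- runif(n_sites, rect$y0, rect$y1)
      nests_per_site <- 1 + rpois(n_sites, community$mean_site_nests - 1)
      r_km <- community$site_cluster_radius_m / 1000
      m <- sum(nests_per_site)
      ang <- runif(m, 0, 2 * pi)
      rad <- r_km * sqrt(runif(m))
      nx <- rep(site_x, nests_per_site) + rad * cos(ang)
      ny <- rep(site_y, nests_per_site) + rad * sin(ang)
      inside <- nx >= rect$x0 & nx <= rect$x1 & ny >= rect$y0 & ny <= rect$y1
      nx <- nx[inside]; ny <- ny[inside]
      if (!length(nx)) next
      # nearest west-east transect row (rows every 0.5 km from y0 + 0.25)
      rows <- sort(unique(tr$y_km[tr$stratum == comm]))
      row_idx <- pmin(pmax(round((ny - rows[1]) / 0.5) + 1, 1), length(rows))
      d_m <- abs(ny - rows[row_idx]) * 1000
      p_det <- if (is.infinite(detection_sigma_m)) rep(1, length(nx)) else
        exp(-d_m^2 / (2 * detection_sigma_m^2))
      hit <- d_m <= truncation_m & runif(length(nx)) < p_det
      if (!any(hit)) next
      # map (row, x) to the transect segment containing the nest
      seg_tab <- tr[tr$stratum == comm, ]
      key_all <- paste(round(rows[row_idx[hit]], 3),
                       findInterval(nx[hit], sort(unique(seg_tab$x0))))
      key_seg <- paste(round(seg_tab$y_km, 3),
                       findInterval(seg_tab$x0 + 1e-9,
                                    sort(unique(seg_tab$x0))))
      tr_idx <- match(key_all, key_seg)
      tr_row <- match(seg_tab$transect_id[tr_idx], tr$transect_id)
      dm_hit <- d_m[hit]
      for (g in split(seq_along(tr_row), tr_row)) {
        i <- tr_row[g[1]]
        det[[i]] <- c(det[[i]], dm_hit[g])
      }
    }
    tr$distances_m <- det
    tr$n_detected <- lengths(det)
    tr
  })

  bf <- community$builder_fraction
  truth <- community$builders |>
    dplyr::left_join(landscape$forests, by = c(community = "stratum")) |>
    dplyr::mutate(
      true_builder_density = .data$builders / .data$area_km2,
      true_ind_density = .data$true_builder_density / bf
    ) |>
    dplyr::select("community", "year", "builders", "area_km2",
                  "true_builder_density", "true_ind_density")
  out <- dplyr::relocate(out, "transect_id", "stratum", "year", "length_km")
  attr(out, "truth") <- truth
  attr(out, "detection_sigma_m") <- detection_sigma_m
  attr(out, "truncation_m") <- truncation_m
  out
}

#' Simulate nest revisit histories under logistic decay
#'
#' Nests are grouped into nesting sites and revisited on a fixed schedule
#' from construction until they disappear.  A nest's probability of still
#' being recognisable at age `t` days is `plogis(beta0 + beta1 * t)`; its
#' disappearance age is drawn by inverting that survival curve.  Visible
#' nests are coded `new`, `recent`, `old` or `very old` as they age
#' (condition never regresses); `disappeared` is absorbing and ends the
#' history.
#'
#' @param n_nests Number of nests (default 610).
#' @param beta0 Logistic intercept (default 4.6).
#' @param beta1 Logistic slope per day; must be negative (default -0.025).
#'   The defaults give a mean decay time `log(1 + exp(beta0)) / |beta1|`
#'   of about 184 days.
#' @param revisit_interval_days Days between revisits (default 7).
#' @param n_sites Number of nesting sites to spread nests over.
#' @param start_date Date of the first construction.
#' @param seed Integer seed.
#' @return Tibble with `nest_id`, `site_id`, `construction_date`,
#'   `visit_date`, `age_days`, `condition`.
#' @export
simulate_decay_histories <- function(n_nests = 610, beta0 = 4.6,
                                     beta1 = -0.025,
                                     revisit_interval_days = 7,
                                     n_sites = max(1, round(n_nests / 14)),
                                     start_date = as.Date("2011-08-01"),
                                     seed = 1) {
  if (beta1 >= 0) abort("`beta1` must be negative (nests must decay).")
  stopifnot(n_nests >= 1, revisit_interval_days >= 1)
  set.seed(child_seed(seed, "decay"))
  site_id <- sprintf("S%03d", sample.int(n_sites, n_nests, replace = TRUE))
  site_dates <- start_date + sample.int(365, n_sites, replace = TRUE) - 1
  names(site_dates) <- sprintf("S%03d", seq_len(n_sites))
  cdate <- site_dates[site_id]
  u <- runif(n_nests)
  t_disappear <- pmax((qlogis(u) - beta0) / beta1, 1e-9)
  n_visits <- pmax(ceiling(t_disappear / revisit_interval_days), 1)
  idx <- rep(seq_len(n_nests), n_visits)
  ages <- unlist(lapply(n_visits, function(k)
    revisit_interval_days * seq_len(k)), use.names = FALSE)
  frac <- ages / t_disappear[idx]
  condition <- ifelse(frac >= 1, "disappeared",
                      ifelse(frac < 0.25, "new",
                             ifelse(frac < 0.5, "recent",
                                    ifelse(frac < 0.75, "old", "very old"))))
  tibble::tibble(
    nest_id = sprintf("N%04d", idx), site_id = site_id[idx],
    construction_date = cdate[idx],
    visit_date = cdate[idx] + ages, age_days = ages, condition = condition
  )
}

#' Simulate biweekly fruiting observations
#'
#' @param p A [phenology_config()].
#' @param plots Tibble with `plot_id`, `forest`; defaults to 14 Nkala and
#'   17 Mpelu plots as in the fruiting-tree study design.
#' @param dates Observation dates at 14-day spacing; default two years of
#'   biweekly visits from 2011-05-01.
#' @param species Character vector of species observed in each plot.
#' @param seed Integer seed.
#' @return Tibble with `date`, `plot_id`, `forest`, `species`,
#'   `prop_fruiting` in `[0, 1]`.
#' @export
simulate_phenology <- function(p = phenology_config(), plots = NULL,
                               dates = NULL, species = paste0("sp", 1:8),
                               seed = 1) {
  if (is.null(plots)) {
    plots <- tibble::tibble(
      plot_id = sprintf("P%02d", 1:31),
      forest = rep(c("Nkala", "Mpelu"), c(14, 17))
    )
  }
  if (is.null(dates)) dates <- seq(as.Date("2011-05-01"), by = 14,
                                   length.out = 53)
  if (length(dates) > 1 &&
      any(diff(as.numeric(dates)) != 14)) {
    abort("`dates` must be at 14-day spacing.")
  }
  set.seed(child_seed(seed, "phenology"))
  grid <- tidyr::expand_grid(date = dates, plots, species = species)
  ang <- date_angle(grid$date, p$period_days)
  mu <- p$baseline + p$amplitude * sin(ang + p$phase) +
    p$forest_offset * (grid$forest == "Nkala")
  grid$prop_fruiting <- pmin(pmax(mu + rnorm(nrow(grid), 0, p$noise_sd), 0), 1)
  grid
}

#' Default forest-activity definitions for the questionnaire generator
#'
#' @return Tibble mapping each activity to the gender that practises it and
#'   the [village_census()] column holding its interview counts.
#' @export
default_activities <- function() {
  tibble::tibble(
    activity = c("hunting", "fishing_w", "fishing_m", "ntpc_w", "ntpc_m"),
    gender = c("M", "W", "M", "W", "M"),
    census_column = c("hunters_m", "fishermen_w", "fishermen_m",
                      "ntpc_w", "ntpc_m")
  )
}

#' Simulate questionnaire responses on forest use
#'
#' One row per (person, activity, forest region visited).  The number of
#' interviewed performers of each activity per village follows the census
#' table; gender constraints (e.g. hunting is men-only) are honoured by
#' construction.  Activity frequency is drawn from daily / twice-weekly /
#' weekly rates and each person visits one or two regions.
#'
#' @param villages A census tibble as from [village_census()].
#' @param activities An activity table as from [default_activities()].
#' @param regions Character vector of forest region labels.
#' @param seed Integer seed.
#' @return Tibble with `person_id`, `village`, `gender`, `activity`,
#'   `freq_per_day`, `n_regions`, `region`.
#' @export
simulate_questionnaire <- function(villages = village_census(),
                                   activities = default_activities(),
                                   regions = c("Nkala", "Mpelu",
                                               "Lokoso&Mankere"),
                                   seed = 1) {
  if (nrow(villages) < 1) abort("Need at least one village.")
  set.seed(child_seed(seed, "questionnaire"))
  res <- list()
  pid <- 0
  for (v in seq_len(nrow(villages))) {
    for (a in seq_len(nrow(activities))) {
      n <- villages[[activities$census_column[a]]][v]
      if (is.null(n) || n == 0) next
      for (i in seq_len(n)) {
        pid <- pid + 1
        freq <- sample(c(1, 2 / 7, 1 / 7), 1, prob = c(0.3, 0.4, 0.3))
        k <- sample(1:2, 1, prob = c(0.7, 0.3))
        vis <- sample(regions, min(k, length(regions)))
        res[[length(res) + 1]] <- tibble::tibble(
          person_id = sprintf("Q%04d", pid),
          village = villages$village[v],
          gender = activities$gender[a],
          activity = activities$activity[a],
          freq_per_day = freq,
          n_regions = length(vis),
          region = vis
        )
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(person_id = character(), village = character(),
                          gender = character(), activity = character(),
                          freq_per_day = numeric(), n_regions = integer(),
                          region = character()))
  }
  dplyr::bind_rows(res)
}
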