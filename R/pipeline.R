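# Column dictionaries for every table the pipeline exchanges between
# stages.  Each entry: required columns with a predicate on the column.
table_schemas <- function() {
  pos <- function(x) is.numeric(x) && all(x > 0, na.rm = TRUE)
  nonneg <- function(x) is.numeric(x) && all(x >= 0, na.rm = TRUE)
  chr <- function(x) is.character(x) || is.factor(x)
  list(
    survey = list(transect_id = chr, stratum = chr,
                  year = function(x) is.numeric(x) || is.factor(x),
                  length_km = pos,
                  distances_m = function(x) is.list(x) &&
                    all(vapply(x, function(d) all(d >= 0), logical(1)))),
    decay_histories = list(nest_id = chr, site_id = chr,
                           age_days = pos,
                           condition = function(x) all(x %in%
                             c("new", "recent", "old", "very old",
                               "disappeared"))),
    fruiting_obs = list(date = function(x) inherits(x, "Date"),
                        plot_id = chr, forest = chr, species = chr,
                        prop_fruiting = function(x) is.numeric(x) &&
                          all(x >= 0 & x <= 1, na.rm = TRUE)),
    questionnaire = list(person_id = chr, village = chr,
                         gender = function(x) all(x %in% c("M", "W")),
                         activity = chr, freq_per_day = pos,
                         n_regions = pos, region = chr),
    rainfall = list(date = function(x) inherits(x, "Date"),
                    rain_mm = nonneg),
    nesting_sites = list(site_id = chr, count = pos,
                         builders_forest = pos, builders_total = pos)
  )
}

#' Validate pipeline tables against their column dictionaries
#'
#' Checks that each named table has the required columns and that each
#' column satisfies its invariant (types, positivity, value sets).
#'
#' @param tables Named list of data frames (or CSV file paths); names
#'   must be among `survey`, `decay_histories`, `fruiting_obs`,
#'   `questionnaire`, `rainfall`, `nesting_sites`.
#' @return A tibble report with `table`, `column`, `check`, `ok`.  An
#'   attribute `"valid"` is TRUE when every check passed.
#' @export
validate_tables <- function(tables) {
  schemas <- table_schemas()
  unknown <- setdiff(names(tables), names(schemas))
  if (length(unknown)) {
    abort(sprintf("Unknown table(s): %s", paste(unknown, collapse = ", ")))
  }
  rows <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.character(tab)) tab <- utils::read.csv(tab)
    for (col in names(schemas[[nm]])) {
      present <- col %in% names(tab)
      ok <- present && isTRUE(schemas[[nm]][[col]](tab[[col]]))
      rows[[length(rows) + 1]] <- tibble::tibble(
        table = nm, column = col,
        check = if (!present) "missing column" else "invariant",
        ok = ok)
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "valid") <- all(report$ok)
  report
}

#' Pipeline configuration
#'
#' Bundles the fixed constants of the analysis with the synthetic-data
#' settings and a master seed from which every stage derives its own
#' stream.
#'
#' @param seed Master seed.
#' @param nest_rate Nest construction rate per builder per day (1.37).
#' @param builder_fraction Proportion of nest-builders (0.75).
#' @param truncation_prob Detection-probability truncation threshold
#'   (0.15).
#' @param alpha Significance threshold (0.05).
#' @param n_boot Decay bootstrap replicates.
#' @param n_perm Preference-test permutations.
#' @param n_decay_nests Nests in the synthetic decay study.
#' @param n_sites Nesting sites in the synthetic cohesion data.
#' @param detection_sigma_m Synthetic half-normal detection scale, m.
#' @param sd_grid_km Bandwidth grid for the dynamics autocovariate.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, nest_rate = 1.37,
                            builder_fraction = 0.75,
                            truncation_prob = 0.15, alpha = 0.05,
                            n_boot = 200, n_perm = 2000,
                            n_decay_nests = 610, n_sites = 90,
                            detection_sigma_m = 12,
                            sd_grid_km = exp(seq(log(0.25), log(8),
                                                 length.out = 7))) {
  stopifnot(nest_rate > 0, builder_fraction > 0, builder_fraction <= 1,
            truncation_prob >= 0, truncation_prob < 1, n_boot >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in dependency order: synthetic data generation,
#' nest-decay estimation, distance sampling and stratified density,
#' between-year ZINB dynamics with bandwidth profiling, fruit-phenology
#' seasonality, nesting-site covariates (tree preference), and the one-
#' versus two-community cohesion comparison.  Deterministic under the
#' config's master seed.
#'
#' @param config A [pipeline_config()].
#' @return A list (report bundle) with elements `decay`, `detection`,
#'   `density`, `global_density`, `dynamics`, `phenology`, `preference`,
#'   `cohesion`, and `validation`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  constants0 <- conversion_constants(config$nest_rate,
                                     config$builder_fraction)

  # --- synthetic inputs -------------------------------------------------
  histories <- simulate_decay_histories(n_nests = config$n_decay_nests,
                                        seed = seed)
  survey <- simulate_survey(detection_sigma_m = config$detection_sigma_m,
                            seed = seed)
  phen <- simulate_phenology(seed = seed)
  quest <- simulate_questionnaire(seed = seed)
  sites <- simulate_nesting_sites(n_sites = config$n_sites, seed = seed)
  validation <- validate_tables(list(
    survey = survey, decay_histories = histories, fruiting_obs = phen,
    questionnaire = quest, nesting_sites = sites))
  if (!isTRUE(attr(validation, "valid"))) {
    bad <- dplyr::filter(validation, !.data$ok)
    abort(sprintf("Table validation failed: %s",
                  paste(sprintf("%s$%s (%s)", bad$table, bad$column,
                                bad$check), collapse = "; ")))
  }

  # --- decay ------------------------------------------------------------
  decay <- bootstrap_decay(histories, n_boot = config$n_boot, seed = seed)
  constants <- conversion_constants(config$nest_rate,
                                    config$builder_fraction,
                                    decay$mean_days)

  # --- distance sampling ------------------------------------------------
  all_d <- unlist(survey$distances_m)
  fit0 <- fit_detection(all_d, truncation_w_m = max(all_d))
  trunc <- truncate_by_detection(fit0, all_d,
                                 threshold = config$truncation_prob)
  density <- density_by_stratum(survey, trunc$fit, constants,
                                cv_decay = decay$cv %||% 0)
  global_density <- stratified_abundance(density)

  # --- between-year dynamics (Mpelu stratum) ----------------------------
  counts <- survey |>
    dplyr::filter(.data$stratum == "Mpelu") |>
    dplyr::mutate(
      count = vapply(.data$distances_m, function(d)
        sum(d <= trunc$truncation_w_m), numeric(1)),
      x_km = (.data$x0 + .data$x1) / 2
    ) |>
    dplyr::select("transect_id", "year", "length_km", "x_km", "y_km",
                  "count")
  bw <- optimize_bandwidth(counts, sd_grid = config$sd_grid_km,
                           n_null = 20, seed = seed)
  null_fit <- fit_zinb(counts, year_in = "none",
                       autocov = bw$fit$data$.ac)
  dynamics <- list(bandwidth_km = bw$sd_km, fit = bw$fit,
                   profile = bw$profile,
                   year_test = lr_test(bw$fit, null_fit))

  # --- phenology --------------------------------------------------------
  series <- fruit_index(phen, default_fruit_species(), unit = "forest")
  seasonal <- fit_seasonal_model(series, ac_sd_days = "auto")
  no_season <- lm(y ~ forest + ac, data = seasonal$data)
  phenology <- list(series = series, fit = seasonal,
                    season_test = f_test(seasonal$model, no_season))

  # --- tree preference --------------------------------------------------
  nest_trees <- tibble::tibble(species = paste0("sp", 1:8),
                               nests = c(60, 40, 15, 10, 5, 5, 3, 2))
  abundance <- tibble::tibble(species = paste0("sp", 1:8),
                              n_stems = c(200, 300, 400, 500, 600, 700,
                                          800, 900))
  preference <- preference_test(nest_trees, abundance,
                                n_perm = config$n_perm,
                                alpha = config$alpha, seed = seed)

  # --- cohesion ---------------------------------------------------------
  fit2 <- fit_cohesion(sites, "two_communities")
  fit1 <- fit_cohesion(sites, "one_community")
  cohesion <- list(
    fit_one = fit1, fit_two = fit2,
    comparison = compare_hypotheses(fit1, fit2),
    block_test = environmental_block_test(fit2, fit_cohesion_null(fit2)))

  list(decay = decay,
       detection = trunc$fit,
       truncation_w_m = trunc$truncation_w_m,
       density = density, global_density = global_density,
       dynamics = dynamics, phenology = phenology,
       preference = preference, cohesion = cohesion,
       validation = validation, config = config)
}
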