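#' Study-site strata: areas and annual transect effort
#'
#' The three survey strata of the Malebo study site (western DRC
#' forest-savannah mosaic) with their areas and the total line-transect
#' effort walked in each survey year.  These constants parameterise the
#' synthetic landscape defaults and the post-stratified density estimator.
#'
#' @return A tibble with columns `stratum`, `area_km2`, and one
#'   `effort_<year>_km` column per survey year.
#' @export
#' @examples
#' stratum_table()
#' sum(stratum_table()$effort_2012_km)  # total 2012 effort, km
stratum_table <- function() {
  tibble::tibble(
    stratum = c("Nkala", "Mpelu", "Lokoso&Mankere"),
    area_km2 = c(32.45, 54.26, 7.13),
    effort_2011_km = c(49.9, 72.7, 7.5),
    effort_2012_km = c(61.9, 109.7, 7.5),
    effort_2013_km = c(61.9, 106.1, 7.5)
  )
}

#' Village census and questionnaire bookkeeping
#'
#' Population census of the villages and farms surrounding the study site,
#' with the number of adults interviewed in the socio-economic questionnaire,
#' overall and per forest activity (hunting is practised by men only;
#' fishing and non-timber-product collection, NTPC, by both genders and
#' interviewed separately).
#'
#' @return A tibble, one row per village, with census counts
#'   (`n_households`, `n_men`, `n_women`, `n_children`, `pop_total`),
#'   interview totals (`interviewed_total`, `interviewed_men`,
#'   `interviewed_women`) and per-activity interview counts
#'   (`hunters_m`, `fishermen_w`, `fishermen_m`, `ntpc_w`, `ntpc_m`).
#' @export
#' @examples
#' sum(village_census()$interviewed_total)
village_census <- function() {
  tibble::tribble(
    ~village, ~n_households, ~n_men, ~n_women, ~n_children, ~pop_total,
    ~interviewed_total, ~interviewed_men, ~interviewed_women,
    ~hunters_m, ~fishermen_w, ~fishermen_m, ~ntpc_w, ~ntpc_m,
    "Nkoo",               168, 169, 202, 540, 911, 50, 35, 15, 16, 13, 20,  7,  9,
    "Mpelu",               43,  50,  58, 153, 261, 50, 30, 20, 19, 20, 23, 20, 19,
    "Lebomo",              37,  37,  34, 141, 212, 26, 14, 12,  7,  9,  8,  3,  2,
    "Nkala",               34,  36,  49, 110, 195, 39, 21, 18,  7, 18, 14, 16, 10,
    "Malebo",              10,   9,  11,  38,  58,  6,  3,  3,  1,  3,  2,  3,  2,
    "Mavula",              10,  10,  12,  25,  47,  6,  3,  3,  3,  3,  2,  3,  1,
    "Bosatore",             7,   5,   7,  22,  34,  2,  1,  1,  1,  1,  1,  1,  1,
    "Mokoabuo",             6,   5,   8,  17,  30,  4,  2,  2,  1,  2,  1,  2,  1,
    "Dispensaire de Nkoo",  4,   4,   4,  19,  27,  2,  1,  1,  0,  0,  0,  0,  0,
    "Lensiana",             4,   4,   3,  18,  25,  0,  0,  0,  0,  0,  0,  0,  0,
    "Biomengele",           3,   3,   3,  13,  19,  3,  2,  1,  2,  1,  1,  1,  1,
    "Ngandjele",            3,   3,   6,   7,  16,  2,  1,  1,  0,  1,  0,  1,  0,
    "Motsuemontore",        2,   2,   4,   9,  15,  2,  1,  1,  1,  1,  0,  0,  0,
    "Ezano",                3,   2,   2,   8,  12,  1,  1,  0,  1,  0,  1,  0,  1,
    "Mayi Monene",          2,   2,   3,   5,  10,  2,  1,  1,  0,  1,  1,  0,  0,
    "Mbou-Mon-Tour",        4,   4,   4,   2,  10,  2,  1,  1,  0,  1,  0,  0,  0,
    "Moza",                 1,   1,   1,   6,   8,  2,  1,  1,  0,  1,  0,  1,  0,
    "Bosieli",              1,   1,   1,   5,   7,  2,  1,  1,  1,  1,  1,  1,  0
  )
}

#' Standard nest-to-individual conversion constants
#'
#' Literature constants used to convert standing nest density into
#' individual density: the nest construction rate (nests built per
#' nest-building individual per day), the proportion of the population that
#' builds nests (infants sleep in their mothers' nests), and the mean nest
#' decay time in days (site-specific; estimated by [bootstrap_decay()]).
#'
#' @param nest_rate Nests per builder per day. Default 1.37.
#' @param builder_fraction Proportion of nest-builders. Default 0.75.
#' @param decay_days Mean nest decay time, days. Default 183.
#' @return A list of class `conversion_constants`.
#' @export
conversion_constants <- function(nest_rate = 1.37, builder_fraction = 0.75,
                                 decay_days = 183) {
  stopifnot(nest_rate > 0, builder_fraction > 0, builder_fraction <= 1,
            decay_days > 0)
  structure(list(nest_rate = nest_rate, builder_fraction = builder_fraction,
                 decay_days = decay_days),
            class = "conversion_constants")
}
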