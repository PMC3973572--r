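#' Fleshy-fruit availability index
#'
#' For each species, the proportion of fruiting trees multiplied by that
#' species' basal area (m2/ha) in the unit; the index is the sum over the
#' fleshy-fruit species set.  Species with no basal-area entry are
#' excluded with a warning (mirroring the removal of unmatched species
#' from the abundance table).
#'
#' @param fruiting_obs Tibble with `date`, `species`, `prop_fruiting` and,
#'   for `unit = "forest"` or `"plot"`, a `forest` / `plot_id` column.
#' @param basal_areas Tibble with `species`, `basal_area_m2ha` and a
#'   `forest` column when areas are forest-specific.
#' @param species_filter Optional character vector: the fleshy-fruit
#'   species set.  Defaults to every species present in `basal_areas`.
#' @param unit `"forest"` (default), `"global"` or `"plot"`.
#' @return Tibble with the unit column(s), `date` and `value` (index,
#'   basal-area-weighted fruiting proportion, >= 0).
#' @export
fruit_index <- function(fruiting_obs, basal_areas, species_filter = NULL,
                        unit = c("forest", "global", "plot")) {
  unit <- match.arg(unit)
  check_columns(fruiting_obs, c("date", "species", "prop_fruiting"),
                "fruiting_obs")
  check_columns(basal_areas, c("species", "basal_area_m2ha"), "basal_areas")
  if (any(fruiting_obs$prop_fruiting < 0 | fruiting_obs$prop_fruiting > 1)) {
    abort("Fruiting proportions must be in [0, 1].")
  }
  species_filter <- species_filter %||% unique(basal_areas$species)
  obs <- dplyr::filter(fruiting_obs, .data$species %in% species_filter)
  missing <- setdiff(unique(obs$species), unique(basal_areas$species))
  if (length(missing)) {
    warn(sprintf("Species without basal area excluded: %s",
                 paste(missing, collapse = ", ")))
    obs <- dplyr::filter(obs, !.data$species %in% missing)
  }
  group_cols <- switch(unit, forest = "forest", plot = "plot_id",
                       global = character(0))
  if (length(group_cols)) check_columns(obs, group_cols, "fruiting_obs")
  # mean fruiting proportion per species within the unit, then weight
  props <- obs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "date",
                                                  "species")))) |>
    dplyr::summarise(prop = mean(.data$prop_fruiting), .groups = "drop")
  ba <- if (unit == "forest" && "forest" %in% names(basal_areas)) {
    dplyr::select(basal_areas, "species", "forest", "basal_area_m2ha")
  } else {
    basal_areas |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(basal_area_m2ha = mean(.data$basal_area_m2ha),
                       .groups = "drop")
  }
  joined <- dplyr::inner_join(props, ba,
                              by = intersect(names(props), names(ba)))
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "date")))) |>
    dplyr::summarise(value = sum(.data$prop * .data$basal_area_m2ha),
                     .groups = "drop")
}

#' Estimate a normalising power transform for a regression response
#'
#' Box-Cox-family lambda maximising the profile normal likelihood of the
#' residuals of a linear regression of the (transformed) response on the
#' design (via `car::powerTransform`).
#'
#' @param response Positive numeric response.
#' @param design Optional data frame of predictors; intercept-only if
#'   omitted.
#' @return List with `lambda`, `se`, `ci` (95%) and `transform`, a
#'   function applying the Box-Cox transform at the estimated lambda.
#' @export
estimate_power_transform <- function(response, design = NULL) {
  if (any(response <= 0)) {
    abort("Response must be positive; shift it before transforming.")
  }
  df <- if (is.null(design)) data.frame(.y = response)
  else cbind(data.frame(.y = response), as.data.frame(design))
  mod <- lm(.y ~ ., data = df)
  pt <- car::powerTransform(mod)
  lambda <- unname(pt$lambda)
  se <- sqrt(unname(pt$invHess[1, 1]))
  list(lambda = lambda, se = se,
       ci = lambda + c(-1, 1) * qnorm(0.975) * se,
       transform = function(y) car::bcPower(y, lambda))
}

#' Fit the seasonal fruit-availability model
#'
#' Gaussian linear model of the power-transformed fruit index on the sine
#' and cosine of the date (circular, period 365.25 days), forest, an
#' optional forest-by-season interaction, and an optional temporal
#' autocovariate (same Gaussian kernel as the spatial one, distance in
#' days, built one-pass from the no-autocovariate residuals).
#'
#' @param series Tibble with `date`, `forest`, `value` (the biweekly
#'   index per forest from [fruit_index()]).
#' @param lambda Box-Cox lambda; `NULL` (default) estimates it with
#'   [estimate_power_transform()].
#' @param interaction Include forest-by-season interaction (default
#'   FALSE).
#' @param ac_sd_days Temporal kernel SD in days; `NULL` for no
#'   autocovariate, `"auto"` to profile a log-spaced 7-200 day grid.
#' @return Object of class `seasonal_fit`: list with `model` (lm),
#'   `lambda`, `amplitude`, `phase`, `ac_sd_days`, `data`.
#' @export
fit_seasonal_model <- function(series, lambda = NULL, interaction = FALSE,
                               ac_sd_days = NULL) {
  check_columns(series, c("date", "forest", "value"), "series")
  if (dplyr::n_distinct(series$forest) < 2) {
    abort("Need at least 2 forests.")
  }
  d <- dplyr::as_tibble(series)
  ang <- date_angle(d$date)
  d$sin_date <- sin(ang); d$cos_date <- cos(ang)
  d$forest <- factor(d$forest)
  if (is.null(lambda)) {
    lambda <- estimate_power_transform(
      d$value, d[c("forest", "sin_date", "cos_date")])$lambda
  }
  d$y <- car::bcPower(d$value, lambda)
  rhs <- if (interaction) "forest * (sin_date + cos_date)" else
    "forest + sin_date + cos_date"
  base <- lm(stats::as.formula(paste("y ~", rhs)), data = d)
  if (any(is.na(coef(base)))) {
    abort(sprintf("Rank-deficient design; aliased: %s",
                  paste(names(coef(base))[is.na(coef(base))],
                        collapse = ", ")))
  }
  sd_used <- NA_real_
  if (!is.null(ac_sd_days)) {
    r <- residuals(base)
    tdays <- matrix(as.numeric(d$date - min(d$date)), ncol = 1)
    fit_at <- function(s) {
      d$ac <- build_autocovariate(tdays, r, s)
      lm(stats::as.formula(paste("y ~", rhs, "+ ac")), data = d)
    }
    if (identical(ac_sd_days, "auto")) {
      grid <- exp(seq(log(7), log(200), length.out = 15))
      lls <- vapply(grid, function(s) as.numeric(logLik(fit_at(s))),
                    numeric(1))
      sd_used <- grid[which.max(lls)]
    } else {
      sd_used <- as.numeric(ac_sd_days)
    }
    d$ac <- build_autocovariate(tdays, r, sd_used)
    base <- fit_at(sd_used)
  }
  cf <- coef(base)
  bs <- unname(cf["sin_date"]); bc <- unname(cf["cos_date"])
  structure(list(model = base, lambda = lambda,
                 amplitude = sqrt(bs^2 + bc^2),
                 phase = atan2(bc, bs),
                 ac_sd_days = sd_used, data = d),
            class = "seasonal_fit")
}

#' Extra-sum-of-squares F-test between nested Gaussian models
#'
#' @param full,reduced Nested `lm` fits (or `seasonal_fit` wrappers) on
#'   the same response.
#' @return One-row tibble with `F`, `df1`, `df2`, `p_value`.
#' @export
f_test <- function(full, reduced) {
  if (inherits(full, "seasonal_fit")) full <- full$model
  if (inherits(reduced, "seasonal_fit")) reduced <- reduced$model
  if (length(coef(reduced)) > length(coef(full))) {
    abort("`reduced` must be nested in `full`.")
  }
  if (length(coef(reduced)) == length(coef(full))) {
    return(tibble::tibble(F = 0, df1 = 0,
                          df2 = stats::df.residual(full), p_value = 1))
  }
  a <- anova(reduced, full)
  tibble::tibble(F = a$F[2], df1 = a$Df[2], df2 = a$Res.Df[2],
                 p_value = a$`Pr(>F)`[2])
}

#' Daily fruiting proportion by nearest biweekly observation
#'
#' Assigns to each query date the value of the closest recorded
#' observation; exact midpoints take the earlier observation.
#'
#' @param obs Tibble with `date` and a value column.
#' @param dates Query dates.
#' @param value_col Name of the value column (default `"prop_fruiting"`).
#' @return Numeric vector of proportions, one per query date.
#' @export
daily_fruiting_proportion <- function(obs, dates,
                                      value_col = "prop_fruiting") {
  check_columns(obs, c("date", value_col), "obs")
  if (nrow(obs) < 1) abort("Need at least one observation.")
  obs <- dplyr::arrange(obs, .data$date)
  od <- as.numeric(obs$date)
  vapply(as.numeric(dates), function(q) {
    gaps <- abs(od - q)
    # which.min returns the first (earlier) index on ties
    obs[[value_col]][which.min(gaps)]
  }, numeric(1))
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf(
    "Seasonal fruit-availability model: lambda = %.3f, amplitude = %.3f, phase = %.2f rad%s\n",
    x$lambda, x$amplitude, x$phase,
    if (is.finite(x$ac_sd_days))
      sprintf(", AC kernel SD = %.1f days", x$ac_sd_days) else ""))
  print(summary(x$model))
  invisible(x)
}
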