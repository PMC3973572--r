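#' Fit the nest-group-size model under a community hypothesis
#'
#' Negative binomial GLM (log link) of the number of nests per nesting
#' site on six predictors -- density of suitable nesting trees, fruit
#' availability in the forest, fruit availability at the nesting site,
#' village influence, human forest use (log-transformed) and rainfall over
#' the 30 days before building -- with the log of the interpolated
#' nest-building community size as offset.  Under the one-community
#' hypothesis the offset is the summed builders of both forests and the
#' forest fruit index is computed over the whole study area; under the
#' two-community hypothesis both are forest-specific.  Quantitative
#' predictors are z-transformed so coefficients are per predictor SD.
#'
#' @param data Tibble with one row per nesting site: `count`,
#'   `density_suitable_trees`, `fruit_forest_global`,
#'   `fruit_forest_local`, `fruit_site`, `village_influence`,
#'   `human_forest_use`, `rainfall_30d`, `builders_total`,
#'   `builders_forest`, and (for the autocovariate) `x_km`, `y_km`,
#'   `date`.
#' @param hypothesis `"two_communities"` (default) or `"one_community"`.
#' @param autocov Optional numeric autocovariate vector (one per row).
#' @param standardize z-transform the predictors (default TRUE).
#' @param min_date If supplied, sites built before this date are dropped
#'   (early sites whose predictors are not yet observable -- e.g. no
#'   preceding survey or phenology record -- are typically excluded).
#' @param subset_rows Optional integer vector of rows to keep (e.g. from
#'   [leverage_screen()]).
#' @param preprocessed Internal: set TRUE when `data` already carries
#'   log-transformed and z-transformed predictors (skips re-processing).
#' @return Object of class `nb_fit`: list with `model` (glm.nb), `data`
#'   (model frame used), `hypothesis`, `loglik`, `aic`, `aicc`, `n`,
#'   `theta`.
#' @export
fit_cohesion <- function(data,
                         hypothesis = c("two_communities", "one_community"),
                         autocov = NULL, standardize = TRUE,
                         min_date = NULL, subset_rows = NULL,
                         preprocessed = FALSE) {
  hypothesis <- match.arg(hypothesis)
  need <- c("count", "density_suitable_trees", "fruit_forest_global",
            "fruit_forest_local", "fruit_site", "village_influence",
            "human_forest_use", "rainfall_30d", "builders_total",
            "builders_forest")
  check_columns(data, need, "data")
  d <- dplyr::as_tibble(data)
  if (!is.null(autocov)) d$.ac <- autocov
  if (!is.null(min_date)) d <- dplyr::filter(d, .data$date >= min_date)
  if (!is.null(subset_rows)) d <- d[subset_rows, , drop = FALSE]
  d$builders <- if (hypothesis == "two_communities") d$builders_forest
  else d$builders_total
  if (any(d$builders <= 0)) abort("Community-size offsets must be positive.")
  d$fruit_forest <- if (hypothesis == "two_communities")
    d$fruit_forest_local else d$fruit_forest_global
  preds <- c("density_suitable_trees", "fruit_forest", "fruit_site",
             "village_influence", "human_forest_use", "rainfall_30d")
  if (!preprocessed) {
    d$human_forest_use <- log(d$human_forest_use +
                                ifelse(any(d$human_forest_use == 0),
                                       1e-3, 0))
    if (standardize) {
      for (p in preds) d[[p]] <- z_transform(d[[p]])
    }
  }
  if (nrow(d) < length(preds) + 2) abort("Too few sites for the model.")
  f <- stats::reformulate(c(preds, if (!is.null(autocov)) ".ac",
                            "offset(log(builders))"),
                          response = "count")
  model <- suppressWarnings(MASS::glm.nb(f, data = d))
  if (!model$converged) warn("glm.nb did not converge.")
  ll <- logLik(model)
  k <- attr(ll, "df")
  structure(list(model = model, data = d, hypothesis = hypothesis,
                 has_autocov = !is.null(autocov),
                 loglik = as.numeric(ll), df = k, aic = stats::AIC(model),
                 aicc = aicc(as.numeric(ll), k, nrow(d)),
                 n = nrow(d), theta = model$theta),
            class = "nb_fit")
}

#' Joint spatio-temporal autocovariate
#'
#' Weighted average of all other sites' residuals with product Gaussian
#' kernel weights in spatial distance (km) and temporal distance (days);
#' the site itself is excluded.  With an infinite temporal SD this reduces
#' to the purely spatial autocovariate.
#'
#' @param locations Two-column matrix/tibble of site coordinates, km.
#' @param dates Site build dates.
#' @param residuals Numeric residual vector.
#' @param sd_s_km Spatial kernel SD, km.
#' @param sd_t_days Temporal kernel SD, days (`Inf` allowed).
#' @return Numeric autocovariate vector.
#' @export
spatiotemporal_autocovariate <- function(locations, dates, residuals,
                                         sd_s_km, sd_t_days) {
  stopifnot(sd_s_km > 0, sd_t_days > 0)
  loc <- as.matrix(locations)
  n <- nrow(loc)
  if (n < 2) abort("Need at least 2 sites.")
  ds <- as.matrix(stats::dist(loc))
  dt <- as.matrix(stats::dist(as.numeric(dates)))
  w <- dnorm(ds, 0, sd_s_km) *
    (if (is.infinite(sd_t_days)) 1 else dnorm(dt, 0, sd_t_days))
  diag(w) <- 0
  as.numeric((w %*% residuals) / rowSums(w))
}

#' Jointly profile the spatial and temporal autocovariate bandwidths
#'
#' One-pass grid search: residuals come from the no-autocovariate fit;
#' for each (spatial SD, temporal SD) pair the autocovariate is rebuilt
#' and the model refitted; the pair maximising the refit likelihood wins.
#' The autocovariate is retained in the returned fit only if its
#' coefficient is significant at `drop_alpha`; a clearly non-significant
#' term is removed so final inference comes from the simpler model.
#'
#' @param data,hypothesis,min_date As for [fit_cohesion()].
#' @param grid_s Spatial SD grid, km.
#' @param grid_t Temporal SD grid, days.
#' @param drop_alpha Significance level for retaining the term
#'   (default 0.05).
#' @param n_boot Parametric-bootstrap replicates for the calibrated
#'   autocovariate test (see [ac_significance_cohesion()]); default 60.
#' @param seed Integer seed for the calibration bootstrap.
#' @return List with `sd_s_km`, `sd_t_days`, `ac_retained`, `ac_p_value`
#'   (calibrated), `fit` (with the term if retained, without it
#'   otherwise) and `profile` (tibble of the grid log-likelihoods).
#' @export
optimize_two_bandwidths <- function(data, hypothesis = "two_communities",
                                    grid_s = exp(seq(log(0.5), log(10),
                                                     length.out = 5)),
                                    grid_t = exp(seq(log(7), log(180),
                                                     length.out = 5)),
                                    drop_alpha = 0.05, min_date = NULL,
                                    n_boot = 60, seed = 1) {
  check_columns(data, c("x_km", "y_km", "date"), "data")
  base <- fit_cohesion(data, hypothesis, min_date = min_date)
  d <- base$data
  r <- d$count - predict(base$model, type = "response")
  loc <- cbind(d$x_km, d$y_km)
  grid <- tidyr::expand_grid(sd_s_km = grid_s, sd_t_days = grid_t)
  fit_at <- function(ss, st) {
    ac <- spatiotemporal_autocovariate(loc, d$date, r, ss, st)
    tryCatch(fit_cohesion(d, hypothesis, autocov = ac,
                          preprocessed = TRUE),
             error = function(e) NULL)
  }
  fits <- purrr::map2(grid$sd_s_km, grid$sd_t_days, fit_at)
  grid$loglik <- vapply(fits, function(f)
    if (is.null(f)) -Inf else f$loglik, numeric(1))
  if (all(!is.finite(grid$loglik))) abort("All autocovariate refits failed.")
  best <- which.max(grid$loglik)
  fit_ac <- fits[[best]]
  z0 <- summary(fit_ac$model)$coefficients[".ac", "z value"]
  # Calibrate the term's significance by parametric bootstrap, repeating
  # the full construction -- refit, residuals, bandwidth grid selection,
  # refit with the term -- on data simulated from the no-autocovariate
  # model.  The Wald z is not standard normal here because the covariate
  # is built from the model's own residuals and its bandwidths are
  # selected to maximise the likelihood.
  best_z <- function(dd) {
    b <- fit_cohesion(dd, hypothesis, preprocessed = TRUE)
    rr <- dd$count - predict(b$model, type = "response")
    zs <- purrr::map2_dbl(grid$sd_s_km, grid$sd_t_days, function(ss, st) {
      ac <- spatiotemporal_autocovariate(loc, dd$date, rr, ss, st)
      f <- tryCatch(fit_cohesion(dd, hypothesis, autocov = ac,
                                 preprocessed = TRUE),
                    error = function(e) NULL)
      if (is.null(f)) -Inf else f$loglik
    })
    k <- which.max(zs)
    ac <- spatiotemporal_autocovariate(loc, dd$date, rr,
                                       grid$sd_s_km[k], grid$sd_t_days[k])
    f <- fit_cohesion(dd, hypothesis, autocov = ac, preprocessed = TRUE)
    summary(f$model)$coefficients[".ac", "z value"]
  }
  set.seed(child_seed(seed, "bandwidth_calibration"))
  mu <- predict(base$model, type = "response")
  z_boot <- vapply(seq_len(n_boot), function(b) {
    dd <- d
    dd$count <- rnbinom(length(mu), mu = mu, size = base$theta)
    if (length(unique(dd$count)) < 3) return(NA_real_)
    tryCatch(best_z(dd), error = function(e) NA_real_)
  }, numeric(1))
  z_boot <- z_boot[is.finite(z_boot)]
  p_ac <- (1 + sum(abs(z_boot - median(z_boot)) >=
                     abs(z0 - median(z_boot)))) / (length(z_boot) + 1)
  retained <- is.finite(p_ac) && p_ac < drop_alpha
  list(sd_s_km = grid$sd_s_km[best], sd_t_days = grid$sd_t_days[best],
       ac_retained = retained, ac_p_value = p_ac, ac_wald_z = z0,
       fit = if (retained) fit_ac else base, profile = grid)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Log-likelihood (or a fitted `nb_fit` / model with a
#'   `logLik` method, in which case `k` and `n` are taken from it).
#' @param k Number of estimated parameters.
#' @param n Sample size; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-48, k = 2, n = 10)  # AIC 100 + 12/7
aicc <- function(loglik, k = NULL, n = NULL) {
  if (!is.numeric(loglik)) {
    if (inherits(loglik, "nb_fit")) return(loglik$aicc)
    ll <- logLik(loglik)
    k <- attr(ll, "df"); n <- attr(ll, "nobs")
    loglik <- as.numeric(ll)
  }
  if (n <= k + 1) abort("AICc needs n > k + 1.")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Compare the one- and two-community hypotheses by AICc
#'
#' @param fit1 `nb_fit` under the one-community hypothesis.
#' @param fit2 `nb_fit` under the two-community hypothesis.
#' @return One-row tibble with `aicc_model1`, `aicc_model2`, `delta_aicc`
#'   (model1 - model2), `winner` (`"one_community"`, `"two_communities"`
#'   or `"tie"`).
#' @export
compare_hypotheses <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "nb_fit"), inherits(fit2, "nb_fit"))
  if (fit1$n != fit2$n) abort("Hypotheses must be fitted to the same sites.")
  d <- fit1$aicc - fit2$aicc
  winner <- if (abs(d) < 1e-8) "tie" else
    if (d > 0) fit2$hypothesis else fit1$hypothesis
  tibble::tibble(aicc_model1 = fit1$aicc, aicc_model2 = fit2$aicc,
                 delta_aicc = d, winner = winner)
}

#' Test the environmental block of predictors
#'
#' Likelihood-ratio chi-square between the full model and a null model
#' keeping only the intercept, the two human-activity controls, any
#' autocovariate, and the offset -- i.e. dropping the four environmental
#' predictors (suitable-tree density, the two fruit indices and
#' rainfall).
#'
#' @param full A full `nb_fit`.
#' @param null The nested null `nb_fit`.
#' @return One-row tibble with `chi2`, `df`, `p_value`.
#' @export
environmental_block_test <- function(full, null) {
  if (full$df < null$df) abort("`null` must be nested in `full`.")
  lr_test(full, null)
}

#' Refit the null (human-controls-only) cohesion model
#'
#' @param fit A full `nb_fit` (its processed data are reused).
#' @return An `nb_fit` with only the human controls, autocovariate (if
#'   present) and offset.
#' @export
fit_cohesion_null <- function(fit) {
  stopifnot(inherits(fit, "nb_fit"))
  d <- fit$data
  f <- stats::reformulate(c("village_influence", "human_forest_use",
                            if (fit$has_autocov) ".ac",
                            "offset(log(builders))"),
                          response = "count")
  model <- suppressWarnings(MASS::glm.nb(f, data = d))
  ll <- logLik(model)
  structure(list(model = model, data = d, hypothesis = fit$hypothesis,
                 has_autocov = fit$has_autocov,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 aic = stats::AIC(model),
                 aicc = aicc(as.numeric(ll), attr(ll, "df"), nrow(d)),
                 n = nrow(d), theta = model$theta),
            class = "nb_fit")
}

#' Screen sites for high leverage
#'
#' Flags sites whose hat value exceeds `threshold_mult * k / n` (default
#' multiplier 3).
#'
#' @param fit An `nb_fit`.
#' @param threshold_mult Leverage threshold multiplier (default 3; `Inf`
#'   retains everything).
#' @return List with `retained` (row indices), `flagged`, and `report`
#'   (tibble with `row`, `leverage`, `flagged`).
#' @export
leverage_screen <- function(fit, threshold_mult = 3) {
  stopifnot(inherits(fit, "nb_fit"))
  h <- hatvalues(fit$model)
  k <- length(coef(fit$model))
  thr <- threshold_mult * k / fit$n
  flagged <- which(h > thr)
  list(retained = setdiff(seq_len(fit$n), flagged), flagged = flagged,
       report = tibble::tibble(row = seq_len(fit$n), leverage = as.numeric(h),
                               flagged = h > thr))
}

#' Simulate nesting-site data under a community regime
#'
#' Generates per-site nest counts and the full covariate set the cohesion
#' models need, under either a two-community regime (expected group size
#' proportional to the forest-specific nest-builder community size, with
#' forest-specific fruit regimes) or a one-community regime (proportional
#' to the pooled community size).  The fruit-at-site effect defaults to
#' 0.109 per predictor SD.
#'
#' @param regime `"two_communities"` or `"one_community"`.
#' @param n_sites Number of nesting sites (default 90).
#' @param b_fruit_site Effect of site fruit availability per SD on the
#'   log scale (default 0.109).
#' @param b_trees Effect of suitable-tree density per SD (default 0.07).
#' @param theta NB dispersion (default 10).
#' @param party_fraction Mean fraction of the community nesting together
#'   (default 0.45).
#' @param spatial_sd_km If positive, a shared Gaussian spatial field with
#'   this correlation range multiplies the expected group size
#'   (default 0 = no residual spatial autocorrelation).
#' @param spatial_amp SD of that field on the log scale (default 0.6).
#' @param seed Integer seed.
#' @return Tibble, one row per site, with all columns [fit_cohesion()]
#'   expects plus `forest`.
#' @export
simulate_nesting_sites <- function(regime = c("two_communities",
                                              "one_community"),
                                   n_sites = 90, b_fruit_site = 0.109,
                                   b_trees = 0.07, theta = 10,
                                   party_fraction = 0.45,
                                   spatial_sd_km = 0, spatial_amp = 0.6,
                                   seed = 1) {
  regime <- match.arg(regime)
  set.seed(child_seed(seed, paste0("sites_", regime)))
  survey_dates <- as.Date(c("2011-06-15", "2012-05-15", "2013-07-15"))
  builders <- list(Nkala = c(15, 12, 13), Mpelu = c(23, 8, 13))
  dates <- as.Date("2011-06-20") + sort(sample.int(730, n_sites,
                                                   replace = TRUE))
  forest <- sample(c("Nkala", "Mpelu"), n_sites, replace = TRUE)
  x <- ifelse(forest == "Nkala", runif(n_sites, 0, 6.5),
              runif(n_sites, 6.5, 17.3))
  y <- runif(n_sites, 0, 5)
  b_forest <- vapply(seq_len(n_sites), function(i) {
    interpolate_community_size(
      tibble::tibble(date = survey_dates, builders = builders[[forest[i]]]),
      dates[i])
  }, numeric(1))
  b_total <- vapply(seq_len(n_sites), function(i) {
    interpolate_community_size(
      tibble::tibble(date = survey_dates,
                     builders = builders$Nkala + builders$Mpelu),
      dates[i])
  }, numeric(1))
  ang <- date_angle(dates)
  fruit_local <- exp(rnorm(n_sites, 0.4 * sin(ang) +
                             0.5 * (forest == "Nkala"), 0.3)) * 3
  fruit_global <- exp(rnorm(n_sites, 0.4 * sin(ang), 0.2)) * 3.5
  fruit_site <- rlnorm(n_sites, 0, 0.6)
  trees <- rlnorm(n_sites, log(150), 0.4)
  vill <- rlnorm(n_sites, log(60), 0.5)
  hfu <- rlnorm(n_sites, log(5), 0.7)
  rain <- pmax(rnorm(n_sites, 120 + 60 * sin(ang), 40), 0)
  eta <- b_fruit_site * z_transform(fruit_site) +
    b_trees * z_transform(trees)
  if (spatial_sd_km > 0) {
    S <- spatial_amp^2 *
      exp(-as.matrix(stats::dist(cbind(x, y)))^2 / (2 * spatial_sd_km^2)) +
      diag(1e-8, n_sites)
    fld <- drop(chol(S) %*% rnorm(n_sites))
    eta <- eta + fld - mean(fld)
  }
  mu <- party_fraction * eta_offset(regime, b_forest, b_total) * exp(eta)
  count <- pmax(rnbinom(n_sites, mu = mu, size = theta), 1L)
  tibble::tibble(
    site_id = sprintf("NS%03d", seq_len(n_sites)), date = dates,
    forest = forest, x_km = x, y_km = y, count = count,
    density_suitable_trees = trees, fruit_forest_global = fruit_global,
    fruit_forest_local = fruit_local, fruit_site = fruit_site,
    village_influence = vill, human_forest_use = hfu,
    rainfall_30d = rain, builders_total = b_total,
    builders_forest = b_forest
  )
}

eta_offset <- function(regime, b_forest, b_total) {
  if (regime == "two_communities") b_forest else b_total
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf(
    "Negative binomial nest-group-size model (%s): logLik = %.2f, AICc = %.2f, theta = %.2f, n = %d\n",
    x$hypothesis, x$loglik, x$aicc, x$theta, x$n))
  print(summary(x$model)$coefficients)
  invisible(x)
}
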