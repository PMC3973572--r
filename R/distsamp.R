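#' Fit a detection function to perpendicular nest distances
#'
#' Maximum-likelihood fit of a half-normal key with cosine series
#' adjustments (orders 2, 3, ...), or a hazard-rate key, to perpendicular
#' distances truncated at `truncation_w_m`.  For the half-normal key the
#' number of adjustment terms (0 to `max_cos_order`) is selected by AIC;
#' any candidate whose fitted detection function goes negative on
#' `[0, w]` is rejected.  `g(0) = 1` by construction.
#'
#' @param distances_m Perpendicular distances, metres.
#' @param truncation_w_m Truncation distance, metres.
#' @param max_cos_order Maximum number of cosine adjustment terms
#'   (default 2).
#' @param key `"halfnorm"` (default) or `"hazard"`.
#' @return An object of class `detection_fit`: a list with `key`,
#'   `sigma_m`, `cos_coeffs`, `truncation_w_m`, `esw_m`, `se_esw_m`,
#'   `p_bar`, `loglik`, `aic`, `n_used`, `par`, `vcov`, `converged`,
#'   `monotone`.
#' @export
#' @examples
#' x <- abs(rnorm(300, 0, 12))
#' fit <- fit_detection(x[x <= 35], truncation_w_m = 35)
#' fit$esw_m
fit_detection <- function(distances_m, truncation_w_m, max_cos_order = 2,
                          key = c("halfnorm", "hazard")) {
  key <- match.arg(key)
  x <- distances_m[distances_m <= truncation_w_m & distances_m >= 0]
  if (length(unique(x)) < 2) {
    abort("Need at least 2 distinct distances below the truncation.")
  }
  cands <- if (key == "halfnorm") {
    lapply(0:max_cos_order, function(m)
      fit_detection_once(x, truncation_w_m, m, key))
  } else {
    list(fit_detection_once(x, truncation_w_m, 0, key))
  }
  ok <- vapply(cands, function(f) isTRUE(f$converged) && f$valid, logical(1))
  if (!any(ok)) {
    f <- cands[[1]]
    warn("No detection-function candidate converged with a valid g(x); returning the flagged key-only fit.")
    return(f)
  }
  select_key_function(cands[ok])
}

# Single fit at a fixed number of adjustment terms.
fit_detection_once <- function(x, w, n_adj, key) {
  n <- length(x)
  gmaker <- function(par) detection_g(par, w, n_adj, key)
  nll <- function(par) {
    g <- gmaker(par)
    mu <- tryCatch(integrate(g, 0, w, rel.tol = 1e-9)$value,
                   error = function(e) NA_real_)
    gi <- g(x)
    if (!is.finite(mu) || mu <= 0 || any(!is.finite(gi)) || any(gi <= 0)) {
      return(1e10)
    }
    -sum(log(gi)) + n * log(mu)
  }
  start <- if (key == "halfnorm") c(log(sd(x)), rep(0, n_adj)) else
    c(log(median(x) + 1e-6), log(2))
  opt <- tryCatch(
    optim(start, nll, method = if (length(start) == 1) "Brent" else "BFGS",
          lower = if (length(start) == 1) log(1e-4) else -Inf,
          upper = if (length(start) == 1) log(1e6) else Inf,
          hessian = TRUE),
    error = function(e) NULL)
  if (is.null(opt) || opt$value >= 1e9) {
    return(structure(list(key = key, converged = FALSE, valid = FALSE,
                          n_used = n, truncation_w_m = w,
                          aic = Inf, loglik = -Inf),
                     class = "detection_fit"))
  }
  g <- gmaker(opt$par)
  grid <- seq(0, w, length.out = 512)
  gv <- g(grid)
  valid <- all(gv >= -1e-9)
  monotone <- all(diff(gv) <= 1e-6)
  esw <- integrate(g, 0, w, rel.tol = 1e-9)$value
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se_esw <- NA_real_
  if (!is.null(vc)) {
    eps <- 1e-5
    gr <- vapply(seq_along(opt$par), function(k) {
      p1 <- opt$par; p1[k] <- p1[k] + eps
      p2 <- opt$par; p2[k] <- p2[k] - eps
      (integrate(gmaker(p1), 0, w)$value -
         integrate(gmaker(p2), 0, w)$value) / (2 * eps)
    }, numeric(1))
    v <- drop(t(gr) %*% vc %*% gr)
    if (is.finite(v) && v >= 0) se_esw <- sqrt(v)
  }
  structure(list(
    key = key,
    sigma_m = exp(opt$par[1]),
    shape = if (key == "hazard") exp(opt$par[2]) else NULL,
    cos_coeffs = if (key == "halfnorm" && n_adj > 0) opt$par[-1] else numeric(0),
    truncation_w_m = w, esw_m = esw, se_esw_m = se_esw,
    p_bar = esw / w, loglik = -opt$value,
    aic = 2 * opt$value + 2 * length(opt$par),
    n_used = n, par = opt$par, vcov = vc,
    converged = opt$convergence == 0, valid = valid, monotone = monotone
  ), class = "detection_fit")
}

# Detection function g(x) with g(0) = 1 for a parameter vector.
detection_g <- function(par, w, n_adj, key) {
  if (key == "hazard") {
    sigma <- exp(par[1]); b <- exp(par[2])
    function(x) 1 - exp(-(pmax(x, 1e-12) / sigma)^(-b))
  } else {
    sigma <- exp(par[1])
    a <- if (n_adj > 0) par[-1] else numeric(0)
    orders <- if (n_adj > 0) seq(2, 1 + n_adj) else integer(0)
    s0 <- 1 + sum(a)
    function(x) {
      k <- exp(-x^2 / (2 * sigma^2))
      s <- rep(1, length(x))
      for (i in seq_along(a)) s <- s + a[i] * cos(orders[i] * pi * x / w)
      k * s / s0
    }
  }
}

#' Evaluate a fitted detection function
#'
#' @param fit A `detection_fit`.
#' @return A function of distance (m) returning detection probability.
#' @export
detection_function <- function(fit) {
  stopifnot(inherits(fit, "detection_fit"))
  detection_g(fit$par, fit$truncation_w_m,
              length(fit$cos_coeffs %||% numeric(0)), fit$key)
}

#' Effective strip width of a fitted detection function
#'
#' `ESW = integral of g(x) over [0, w]`; the mean detection probability is
#' `ESW / w`.
#'
#' @param fit A `detection_fit`.
#' @return ESW in metres.
#' @export
effective_strip_width <- function(fit) {
  g <- detection_function(fit)
  integrate(g, 0, fit$truncation_w_m, rel.tol = 1e-9)$value
}

#' Truncate distances where detection probability falls below a threshold
#'
#' Solves `g(w) = threshold` for the fitted detection function, drops
#' distances beyond that point, and refits once on the retained data
#' (fit on provisional truncation, solve, refit).
#'
#' @param fit A `detection_fit` from a provisional truncation.
#' @param distances_m All recorded perpendicular distances (m).
#' @param threshold Detection-probability cutoff (default 0.15).
#' @param max_cos_order Passed to the refit.
#' @return A list with `truncation_w_m`, `distances_m` (retained) and
#'   `fit` (the refit on retained data).
#' @export
truncate_by_detection <- function(fit, distances_m, threshold = 0.15,
                                  max_cos_order = 2) {
  stopifnot(threshold >= 0, threshold < 1)
  g <- detection_function(fit)
  w_max <- max(fit$truncation_w_m, max(distances_m))
  if (threshold <= 0 || g(w_max) > threshold) {
    if (threshold > 0) {
      warn("g never reaches the threshold inside the data range; keeping the maximum distance.")
    }
    w_star <- max(distances_m)
  } else {
    w_star <- uniroot(function(x) g(x) - threshold, c(1e-9, w_max),
                      tol = 1e-9)$root
  }
  keep <- distances_m[distances_m <= w_star]
  refit <- fit_detection(keep, w_star, max_cos_order = max_cos_order,
                         key = fit$key)
  list(truncation_w_m = w_star, distances_m = keep, fit = refit)
}

#' Nest density for one stratum-year from transect counts
#'
#' `D_nest = n / (2 * L * ESW)` with the encounter-rate variance from
#' between-transect variability weighted by line length.
#'
#' @param records Tibble with one row per transect: `length_km` and either
#'   a `distances_m` list-column or an `n` count column (counts within the
#'   fit's truncation).
#' @param fit A `detection_fit`.
#' @return One-row tibble with `n`, `effort_km`, `nest_density_km2`,
#'   `cv_encounter`.
#' @export
nest_density <- function(records, fit) {
  check_columns(records, "length_km", "records")
  if (sum(records$length_km) <= 0) abort("Zero total effort.")
  n_i <- if ("n" %in% names(records)) records$n else
    vapply(records$distances_m, function(d)
      sum(d <= fit$truncation_w_m), numeric(1))
  l_i <- records$length_km
  L <- sum(l_i); n <- sum(n_i); K <- length(l_i)
  esw_km <- fit$esw_m / 1000
  d_nest <- n / (2 * L * esw_km)
  cv_er <- NA_real_
  if (n > 0 && K > 1) {
    er <- n / L
    var_er <- K / (L^2 * (K - 1)) * sum(l_i^2 * (n_i / l_i - er)^2)
    cv_er <- sqrt(var_er) / er
  }
  tibble::tibble(n = n, effort_km = L, nest_density_km2 = d_nest,
                 cv_encounter = cv_er)
}

#' Convert nest density to individual density
#'
#' Divides the standing nest density by the nest construction rate and the
#' mean nest decay time to obtain the density of nest-building individuals;
#' dividing additionally by the proportion of nest-builders gives the
#' density of all individuals.
#'
#' @param d_nest Nest density, nests/km2.
#' @param constants A [conversion_constants()].
#' @param include_nonbuilders If `TRUE` (default) return all-individual
#'   density; if `FALSE`, nest-builders only.
#' @return Individual density, individuals/km2.
#' @export
individuals_from_nests <- function(d_nest, constants = conversion_constants(),
                                   include_nonbuilders = TRUE) {
  d <- d_nest / (constants$nest_rate * constants$decay_days)
  if (include_nonbuilders) d <- d / constants$builder_fraction
  d
}

#' Per-stratum-year density estimates from a survey table
#'
#' Post-stratifies the survey by stratum and year, applies the global
#' detection fit, converts nest density to individual density, combines
#' the encounter-rate, detection and decay CV components by the delta
#' method and attaches log-normal 95% confidence limits and rounded
#' abundances.
#'
#' @param survey Transect tibble as from [simulate_survey()] (columns
#'   `stratum`, `year`, `length_km`, `distances_m`).
#' @param fit A `detection_fit`.
#' @param constants A [conversion_constants()].
#' @param areas Tibble with `stratum`, `area_km2` (default
#'   [stratum_table()]).
#' @param cv_decay CV of the decay-time estimate (default 0).
#' @param include_nonbuilders Passed to [individuals_from_nests()].
#' @return Tibble with one row per stratum-year: `stratum`, `year`, `n`,
#'   `effort_km`, `nest_density_km2`, `ind_density_km2`, `cv_pct`, `lcl`,
#'   `ucl`, `abundance_n`, `n_lcl`, `n_ucl`.
#' @export
density_by_stratum <- function(survey, fit,
                               constants = conversion_constants(),
                               areas = stratum_table(),
                               cv_decay = 0, include_nonbuilders = TRUE) {
  check_columns(survey, c("stratum", "year", "length_km"), "survey")
  cv_det <- if (is.finite(fit$se_esw_m %||% NA_real_))
    fit$se_esw_m / fit$esw_m else 0
  survey |>
    dplyr::group_by(.data$stratum, .data$year) |>
    dplyr::group_modify(function(df, key) {
      nd <- nest_density(df, fit)
      D <- individuals_from_nests(nd$nest_density_km2, constants,
                                  include_nonbuilders)
      cv_er <- ifelse(is.na(nd$cv_encounter), 0, nd$cv_encounter)
      cv <- sqrt(cv_er^2 + cv_det^2 + cv_decay^2)
      ci <- lognormal_ci(D, cv)
      A <- areas$area_km2[match(key$stratum, areas$stratum)]
      tibble::tibble(
        n = nd$n, effort_km = nd$effort_km,
        nest_density_km2 = nd$nest_density_km2,
        ind_density_km2 = D, cv_pct = 100 * cv,
        lcl = ci[1], ucl = ci[2],
        abundance_n = round(D * A),
        n_lcl = round(ci[1] * A), n_ucl = round(ci[2] * A)
      )
    }) |>
    dplyr::ungroup()
}

# Log-normal 95% CI for a positive estimate with coefficient of variation cv.
lognormal_ci <- function(est, cv) {
  if (!is.finite(est) || est <= 0 || !is.finite(cv) || cv <= 0) {
    return(c(est, est))
  }
  C <- exp(qnorm(0.975) * sqrt(log(1 + cv^2)))
  c(est / C, est * C)
}

#' Area-weighted global density and abundance
#'
#' `D_global = sum(D_i * A_i) / sum(A_i)`.  If several years are present
#' per stratum they are averaged first.  The global CV combines stratum
#' variances by the delta method; the 95% CI is log-normal and the
#' abundance is rounded to the nearest integer.
#'
#' @param estimates Tibble from [density_by_stratum()] (needs `stratum`,
#'   `ind_density_km2`, `cv_pct`).
#' @param areas Tibble with `stratum`, `area_km2`.
#' @return One-row tibble with `ind_density_km2`, `cv_pct`, `lcl`, `ucl`,
#'   `area_km2`, `abundance_n`, `n_lcl`, `n_ucl`.
#' @export
stratified_abundance <- function(estimates, areas = stratum_table()) {
  check_columns(estimates, c("stratum", "ind_density_km2"), "estimates")
  per <- estimates |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      D = mean(.data$ind_density_km2),
      v = if ("cv_pct" %in% names(estimates))
        mean((.data$cv_pct / 100 * .data$ind_density_km2)^2) /
        dplyr::n() else 0,
      .groups = "drop"
    ) |>
    dplyr::inner_join(areas, by = "stratum")
  A <- sum(per$area_km2)
  wts <- per$area_km2 / A
  D_g <- sum(wts * per$D)
  var_g <- sum(wts^2 * per$v)
  cv <- if (D_g > 0) sqrt(var_g) / D_g else 0
  ci <- lognormal_ci(D_g, cv)
  tibble::tibble(ind_density_km2 = D_g, cv_pct = 100 * cv,
                 lcl = ci[1], ucl = ci[2], area_km2 = A,
                 abundance_n = round(D_g * A),
                 n_lcl = round(ci[1] * A), n_ucl = round(ci[2] * A))
}

#' Select the best detection fit by AIC
#'
#' Minimum-AIC converged candidate; ties are broken in favour of fewer
#' parameters.
#'
#' @param fits List of `detection_fit` objects.
#' @return The selected `detection_fit`.
#' @export
select_key_function <- function(fits) {
  if (inherits(fits, "detection_fit")) fits <- list(fits)
  ok <- Filter(function(f) isTRUE(f$converged) && isTRUE(f$valid), fits)
  if (!length(ok)) abort("No converged detection-function candidate.")
  aics <- vapply(ok, function(f) f$aic, numeric(1))
  npar <- vapply(ok, function(f) length(f$par), numeric(1))
  ok[[order(aics, npar)[1]]]
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf(
    "Detection function (%s%s): sigma = %.2f m, w = %.1f m\n  ESW = %.2f m, mean p = %.3f, AIC = %.2f, n = %d\n",
    x$key,
    if (length(x$cos_coeffs %||% numeric(0)))
      sprintf(" + %d cosine term(s)", length(x$cos_coeffs)) else "",
    x$sigma_m %||% NA_real_, x$truncation_w_m, x$esw_m, x$p_bar,
    x$aic, x$n_used))
  invisible(x)
}
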