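#' Fit the logistic nest-decay model to revisit histories
#'
#' Binary logistic regression of "nest still recognisable" on nest age in
#' days, one observation per (nest, revisit).  Nests are marked fresh at
#' construction, so age is measured from a known origin; intermediate
#' condition codes (`recent`, `old`, `very old`) collapse to "present".
#' Because `disappeared` is absorbing, a disappeared nest's status at
#' every later scheduled visit is known without visiting; each such
#' nest's record is therefore carried forward on its own revisit schedule
#' to the common follow-up horizon.  This keeps the age-specific fraction
#' of nests still present an unbiased estimate of the survival curve
#' `plogis(beta0 + beta1 * age)` (truncating histories at the first
#' disappearance would leave late ages represented only by long-lived
#' nests and bias the decay time upward).  Censored nests (never seen to
#' disappear) contribute only their observed visits.
#'
#' @param histories Tibble with `nest_id`, `age_days` (or
#'   `construction_date` + `visit_date`) and `condition`.
#' @return An object of class `decay_fit`: list with `beta0`, `beta1`,
#'   `se`, `vcov`, `glm` (the underlying fit), `n_nests`, `n_obs`,
#'   `separation` flag.
#' @export
fit_decay <- function(histories) {
  check_columns(histories, c("nest_id", "condition"), "histories")
  if (!"age_days" %in% names(histories)) {
    check_columns(histories, c("construction_date", "visit_date"), "histories")
    histories$age_days <- as.numeric(histories$visit_date -
                                       histories$construction_date)
  }
  rows <- decay_rows(histories)
  # aggregate to binomial counts per age: identical likelihood, fast glm
  agg_p <- rowsum(as.numeric(rows$present), rows$age)
  agg_n <- rowsum(rep(1, length(rows$age)), rows$age)
  dfa <- data.frame(age_days = as.numeric(rownames(agg_p)),
                    n_present = agg_p[, 1],
                    n_absent = agg_n[, 1] - agg_p[, 1])
  fit <- suppressWarnings(glm(cbind(n_present, n_absent) ~ age_days,
                              data = dfa, family = binomial()))
  separation <- !fit$converged || any(abs(coef(fit)) > 50)
  if (separation) warn("Possible complete separation: boundary logistic fit.")
  structure(list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
                 se = sqrt(diag(vcov(fit))), vcov = vcov(fit), glm = fit,
                 n_nests = length(unique(rows$nest)),
                 n_obs = length(rows$age),
                 separation = separation),
            class = "decay_fit")
}

# Per-(nest, revisit) presence rows: collapses condition codes to binary
# presence, truncates at the first disappearance, then carries disappeared
# nests forward on their own revisit schedule to the common horizon.
decay_rows <- function(histories) {
  nest <- as.character(histories$nest_id)
  age <- as.numeric(histories$age_days)
  present <- histories$condition != "disappeared"
  ord <- order(nest, age)
  nest <- nest[ord]; age <- age[ord]; present <- present[ord]
  # keep observed visits up to and including the first disappearance
  cs <- stats::ave(as.numeric(!present), nest, FUN = cumsum)
  keep <- cs == 0 | (cs == 1 & !present)
  nest <- nest[keep]; age <- age[keep]; present <- present[keep]
  if (all(present)) {
    abort("No disappearance observed; the decay slope is not identifiable.")
  }
  horizon <- max(age)
  first_i <- !duplicated(nest)
  last_i <- !duplicated(nest, fromLast = TRUE)
  step <- age[first_i][match(nest[last_i], nest[first_i])]
  gone <- !present[last_i]
  last_age <- age[last_i]
  nest_last <- nest[last_i]
  ext <- which(gone & step > 0 & last_age + step <= horizon)
  if (length(ext)) {
    m <- floor((horizon - last_age[ext]) / step[ext])
    age <- c(age, unlist(lapply(seq_along(ext), function(k)
      last_age[ext[k]] + step[ext[k]] * seq_len(m[k])), use.names = FALSE))
    nest <- c(nest, rep(nest_last[ext], m))
    present <- c(present, rep(FALSE, sum(m)))
  }
  list(nest = nest, age = age, present = present)
}

#' Mean nest decay time from logistic survival parameters
#'
#' The survival curve is `S(t) = plogis(beta0 + beta1 t)`; its integral
#' over `[0, Inf)` is the mean decay time, with closed form
#' `log(1 + exp(beta0)) / |beta1|`.  Both the closed form and adaptive
#' quadrature are evaluated and must agree to 1e-6 relative.
#'
#' @param beta0 Logistic intercept (or a `decay_fit`).
#' @param beta1 Logistic slope per day; must be negative.
#' @return Mean decay time in days.
#' @export
#' @examples
#' mean_decay_time(4.6, -0.025)  # about 184.4 days
mean_decay_time <- function(beta0, beta1) {
  if (inherits(beta0, "decay_fit")) {
    beta1 <- beta0$beta1; beta0 <- beta0$beta0
  }
  if (beta1 >= 0) abort("`beta1` must be negative; the integral diverges.")
  # numerically stable softplus
  closed <- (if (beta0 > 30) beta0 + log1p(exp(-beta0)) else
    log1p(exp(beta0))) / abs(beta1)
  # split the domain at the survival midpoint so quadrature resolves
  # near-step survival curves
  t50 <- max(-beta0 / beta1, 0)
  quad <- integrate(function(t) plogis(beta0 + beta1 * t), 0, t50,
                    rel.tol = 1e-10)$value +
    integrate(function(t) plogis(beta0 + beta1 * t), t50, Inf,
              rel.tol = 1e-10)$value
  if (abs(quad - closed) > 1e-6 * closed) {
    abort("Quadrature and closed-form mean decay times disagree.")
  }
  closed
}

#' Bootstrap the mean nest decay time
#'
#' Resamples nests with replacement, stratified by nesting site (so
#' within-site correlation is respected), refits the logistic decay model
#' on each replicate and returns the percentile confidence interval of the
#' mean decay time at 2.5% / 97.5%.
#'
#' @param histories Revisit tibble as for [fit_decay()]; needs `site_id`.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return An object of class `decay_estimate`: list with `beta0`,
#'   `beta1`, `mean_days`, `ci_low_days`, `ci_high_days`, `cv`, `n_boot`,
#'   `n_failed`, `boot_means`.
#' @export
bootstrap_decay <- function(histories, n_boot = 1000, seed = 1) {
  fit <- fit_decay(histories)
  mean0 <- mean_decay_time(fit)
  check_columns(histories, "site_id", "histories")
  if (!"age_days" %in% names(histories)) {
    histories$age_days <- as.numeric(histories$visit_date -
                                       histories$construction_date)
  }
  nests <- histories |>
    dplyr::distinct(.data$site_id, .data$nest_id)
  if (nrow(nests) < 2) abort("Need at least 2 nests to bootstrap.")
  # Precompute each nest's per-age (present, visited) indicators on the
  # common age grid, including the carry-forward of disappeared nests to
  # the full-data horizon; a bootstrap replicate's aggregated binomial
  # table is then a multiplicity-weighted column sum, and each refit is a
  # weighted glm on ~ (number of distinct ages) rows.
  rows <- decay_rows(histories)
  grid_ages <- sort(unique(rows$age))
  nest_ids <- sort(unique(rows$nest))
  i <- match(rows$nest, nest_ids)
  j <- match(rows$age, grid_ages)
  P <- matrix(0, length(nest_ids), length(grid_ages))
  Nv <- matrix(0, length(nest_ids), length(grid_ages))
  P[cbind(i, j)] <- as.numeric(rows$present)
  Nv[cbind(i, j)] <- 1
  X <- cbind(1, grid_ages)
  site_of <- nests$site_id[match(nest_ids, nests$nest_id)]
  idx_by_site <- split(seq_along(nest_ids), site_of)
  set.seed(child_seed(seed, "bootstrap_decay"))
  means <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ids <- unlist(lapply(idx_by_site, function(v)
      v[sample.int(length(v), replace = TRUE)]), use.names = FALSE)
    m <- tabulate(ids, nbins = length(nest_ids))
    n_tot <- drop(m %*% Nv)
    n_pres <- drop(m %*% P)
    keep <- n_tot > 0
    means[b] <- tryCatch({
      f <- suppressWarnings(glm.fit(X[keep, , drop = FALSE],
                                    n_pres[keep] / n_tot[keep],
                                    weights = n_tot[keep],
                                    family = binomial()))
      cf <- coef(f)
      if (cf[2] >= 0) NA_real_ else mean_decay_time(cf[1], cf[2])
    }, error = function(e) NA_real_)
  }
  ok <- means[is.finite(means)]
  n_failed <- n_boot - length(ok)
  if (n_failed > 0.1 * n_boot) {
    warn(sprintf("%d of %d bootstrap refits failed.", n_failed, n_boot))
  }
  ci <- if (length(ok) >= 1) quantile(ok, c(0.025, 0.975), names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(beta0 = fit$beta0, beta1 = fit$beta1, mean_days = mean0,
                 ci_low_days = ci[1], ci_high_days = ci[2],
                 cv = if (length(ok) > 1) sd(ok) / mean0 else NA_real_,
                 n_boot = n_boot, n_failed = n_failed, boot_means = means,
                 fit = fit),
            class = "decay_estimate")
}

#' @export
print.decay_estimate <- function(x, ...) {
  cat(sprintf(
    "Mean nest decay time: %.1f days (bootstrap 95%% CI %.1f-%.1f, n_boot = %d)\n  logistic beta0 = %.3f, beta1 = %.5f /day\n",
    x$mean_days, x$ci_low_days, x$ci_high_days, x$n_boot,
    x$beta0, x$beta1))
  invisible(x)
}
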