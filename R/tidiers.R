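#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @describeIn fit_detection Tidy the detection-fit parameters.
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.detection_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_m",
             if (length(x$cos_coeffs))
               paste0("cos", seq(2, 1 + length(x$cos_coeffs))),
             if (!is.null(x$shape)) "shape"),
    estimate = c(x$sigma_m, x$cos_coeffs, x$shape)
  )
}

#' @describeIn fit_detection One-row fit summary (ESW, mean detection
#'   probability, AIC).
#' @export
glance.detection_fit <- function(x, ...) {
  tibble::tibble(key = x$key, esw_m = x$esw_m, p_bar = x$p_bar,
                 truncation_w_m = x$truncation_w_m,
                 logLik = x$loglik, AIC = x$aic, nobs = x$n_used)
}

#' @describeIn bootstrap_decay Tidy the decay estimate.
#' @param x A `decay_estimate`.
#' @param ... Unused.
#' @export
tidy.decay_estimate <- function(x, ...) {
  tibble::tibble(term = c("beta0", "beta1", "mean_days"),
                 estimate = c(x$beta0, x$beta1, x$mean_days),
                 conf.low = c(NA, NA, x$ci_low_days),
                 conf.high = c(NA, NA, x$ci_high_days))
}

#' @describeIn bootstrap_decay One-row summary of the decay estimate.
#' @export
glance.decay_estimate <- function(x, ...) {
  tibble::tibble(mean_days = x$mean_days, ci_low_days = x$ci_low_days,
                 ci_high_days = x$ci_high_days, cv = x$cv,
                 n_boot = x$n_boot, n_failed = x$n_failed)
}

#' @describeIn fit_zinb Coefficient table for both model parts.
#' @param x A `zinb_fit`.
#' @param ... Unused.
#' @export
tidy.zinb_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  part <- function(m, nm) {
    if (is.null(m)) return(NULL)
    tibble::tibble(part = nm, term = rownames(m), estimate = m[, 1],
                   std.error = m[, 2], statistic = m[, 3],
                   p.value = m[, 4])
  }
  dplyr::bind_rows(part(s$cond, "count"), part(s$zi, "zero"))
}

#' @describeIn fit_zinb One-row model summary.
#' @export
glance.zinb_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, df = x$df,
                 theta = x$theta, nobs = x$n, converged = x$converged)
}

#' @describeIn fit_cohesion Coefficient table of the NB fit.
#' @param x An `nb_fit`.
#' @param ... Unused.
#' @export
tidy.nb_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @describeIn fit_cohesion One-row model summary with AICc.
#' @export
glance.nb_fit <- function(x, ...) {
  tibble::tibble(hypothesis = x$hypothesis, logLik = x$loglik,
                 AIC = x$aic, AICc = x$aicc, theta = x$theta, nobs = x$n)
}

#' @describeIn fit_seasonal_model Coefficient table of the seasonal model.
#' @param x A `seasonal_fit`.
#' @param ... Unused.
#' @export
tidy.seasonal_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' @describeIn fit_seasonal_model One-row summary with amplitude and
#'   phase.
#' @export
glance.seasonal_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, amplitude = x$amplitude,
                 phase = x$phase, ac_sd_days = x$ac_sd_days,
                 r.squared = summary(x$model)$r.squared,
                 nobs = nrow(x$data))
}

#' @describeIn preference_test Per-species binomial results.
#' @param x A `preference_result`.
#' @param ... Unused.
#' @export
tidy.preference_result <- function(x, ...) x$by_species

#' @describeIn preference_test One-row test summary.
#' @export
glance.preference_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, p_permutation = x$p_permutation,
                 n_perm = x$n_perm, n_preferred = length(x$preferred))
}
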