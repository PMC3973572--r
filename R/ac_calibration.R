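#' Calibrated significance test for a residual autocovariate term
#'
#' The autocovariate is a kernel-weighted average of the *model's own*
#' residuals, so the Wald z of its coefficient does not follow the
#' standard normal under the no-autocorrelation null: the maximum-
#' likelihood score constraints tie each unit's residual (negatively) to
#' the average of the others, which biases the coefficient and its z
#' downwards even for spatially independent data.  This function
#' calibrates the test by a parametric bootstrap: data are simulated from
#' the fitted no-autocovariate model, the full construction (refit,
#' residuals, autocovariate, refit with the term) is repeated on each
#' replicate, and the observed z is referred to the bootstrap
#' distribution of z (two-sided, add-one corrected).
#'
#' @param data Transect-count tibble as for [fit_zinb()], with `x_km`,
#'   `y_km`.
#' @param sd_km Autocovariate kernel SD (km).
#' @param year_in Passed to [fit_zinb()].
#' @param n_boot Bootstrap replicates (default 60).
#' @param seed Integer seed.
#' @return List with `z` (observed Wald z of the term), `coef` (its
#'   estimate), `p_calibrated`, `coef_boot` (null coefficient
#'   replicates), `fit` (the glmmTMB model with the term).
#' @export
ac_significance <- function(data, sd_km, year_in = "both", n_boot = 60,
                            seed = 1) {
  check_columns(data, c("x_km", "y_km"), "data")
  loc <- cbind(data$x_km, data$y_km)
  base <- fit_zinb(data, year_in = year_in)
  r <- data$count - predict(base$model, type = "response")
  ac <- build_autocovariate(loc, r, sd_km)
  fit <- fit_zinb(data, year_in = year_in, autocov = ac)
  s <- summary(fit$model)$coefficients$cond
  z0 <- s[".ac", "z value"]; g0 <- s[".ac", "Estimate"]
  # bootstrap replicates run through the fast internal ZINB optimiser
  # (same likelihood as glmmTMB; cross-checked in the test suite)
  des <- zinb_design(data, year_in)
  kc <- ncol(des$Xc)
  start0 <- c(glmmTMB::fixef(base$model)$cond,
              glmmTMB::fixef(base$model)$zi, log(base$theta))
  set.seed(child_seed(seed, "ac_calibration"))
  sims <- stats::simulate(base$model, nsim = n_boot)
  g_boot <- vapply(seq_len(n_boot), function(b) {
    y <- sims[[b]]
    tryCatch({
      f0 <- zinb_ml(y, des$Xc, des$Xz, des$off_c, des$off_z,
                    start = start0)
      mu_hat <- zinb_mean(f0, des)
      acb <- build_autocovariate(loc, y - mu_hat, sd_km)
      f1 <- zinb_ml(y, cbind(des$Xc, ac = acb), des$Xz, des$off_c,
                    des$off_z,
                    start = append(f0$par, 0, after = kc))
      f1$par[kc + 1]
    }, error = function(e) NA_real_)
  }, numeric(1))
  g_boot <- g_boot[is.finite(g_boot)]
  p <- (1 + sum(abs(g_boot - stats::median(g_boot)) >=
                  abs(g0 - stats::median(g_boot)))) /
    (length(g_boot) + 1)
  list(z = z0, coef = g0, p_calibrated = p, coef_boot = g_boot, fit = fit)
}

# Design matrices and offsets for the internal ZINB likelihood.
zinb_design <- function(data, year_in) {
  yr <- factor(data$year)
  Xyr <- if (year_in == "none" || nlevels(yr) < 2)
    stats::model.matrix(~1, data) else stats::model.matrix(~yr)
  Xc <- if (year_in %in% c("both", "count")) Xyr else
    stats::model.matrix(~1, data)
  Xz <- if (year_in %in% c("both", "zero")) Xyr else
    stats::model.matrix(~1, data)
  list(Xc = Xc, Xz = Xz, off_c = log(data$length_km),
       off_z = log(1 / data$length_km))
}

zinb_mean <- function(fit, des) {
  kc <- ncol(des$Xc); kz <- ncol(des$Xz)
  mu <- exp(drop(des$Xc %*% fit$par[1:kc]) + des$off_c)
  pz <- plogis(drop(des$Xz %*% fit$par[(kc + 1):(kc + kz)]) + des$off_z)
  (1 - pz) * mu
}

# Maximum-likelihood zero-inflated negative binomial fit (log/logit links,
# fixed offsets).  Lean internal optimiser used where thousands of refits
# are needed (autocovariate calibration); agrees with glmmTMB on the same
# likelihood.
zinb_ml <- function(y, Xc, Xz, off_c, off_z, start = NULL) {
  kc <- ncol(Xc); kz <- ncol(Xz)
  nll <- function(par) {
    eta_c <- drop(Xc %*% par[1:kc]) + off_c
    eta_z <- drop(Xz %*% par[(kc + 1):(kc + kz)]) + off_z
    theta <- exp(par[kc + kz + 1])
    if (any(eta_c > 50)) return(1e10)
    mu <- exp(eta_c)
    lp <- plogis(eta_z, log.p = TRUE)
    l1mp <- plogis(-eta_z, log.p = TRUE)
    ll0 <- dnbinom(0, mu = mu, size = theta, log = TRUE)
    ll <- ifelse(y == 0,
                 pmax(lp, l1mp + ll0) +
                   log1p(exp(-abs(lp - (l1mp + ll0)))),
                 l1mp + dnbinom(y, mu = mu, size = theta, log = TRUE))
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }
  if (is.null(start)) {
    b0 <- log(mean(y / exp(off_c)) + 1e-3)
    start <- c(b0, rep(0, kc - 1),
               qlogis(max(mean(y == 0) / 2, 0.02)), rep(0, kz - 1), 0)
  }
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-10))
  list(par = opt$par, loglik = -opt$value, converged = opt$convergence == 0,
       theta = exp(opt$par[kc + kz + 1]))
}

#' Calibrated significance for the cohesion model's autocovariate
#'
#' Same parametric-bootstrap calibration as [ac_significance()], for the
#' negative binomial nest-group-size model with a joint spatio-temporal
#' autocovariate.
#'
#' @param data Nesting-site tibble as for [fit_cohesion()].
#' @param hypothesis Community hypothesis.
#' @param sd_s_km,sd_t_days Kernel SDs.
#' @param n_boot Bootstrap replicates (default 60).
#' @param seed Integer seed.
#' @param preprocessed Set TRUE when `data` already carries transformed
#'   predictors (as inside [optimize_two_bandwidths()]).
#' @return List with `z`, `p_calibrated`, `z_boot`, `fit`.
#' @export
ac_significance_cohesion <- function(data, hypothesis = "two_communities",
                                     sd_s_km, sd_t_days, n_boot = 60,
                                     seed = 1, preprocessed = FALSE) {
  base <- fit_cohesion(data, hypothesis, preprocessed = preprocessed)
  d <- base$data
  loc <- cbind(d$x_km, d$y_km)
  zstat <- function(dd) {
    b <- fit_cohesion(dd, hypothesis, preprocessed = TRUE)
    r <- dd$count - predict(b$model, type = "response")
    ac <- spatiotemporal_autocovariate(loc, dd$date, r, sd_s_km, sd_t_days)
    f <- fit_cohesion(dd, hypothesis, autocov = ac, preprocessed = TRUE)
    list(z = summary(f$model)$coefficients[".ac", "z value"], fit = f,
         base = b)
  }
  obs <- zstat(d)
  set.seed(child_seed(seed, "ac_calibration_cohesion"))
  mu <- predict(obs$base$model, type = "response")
  z_boot <- vapply(seq_len(n_boot), function(b) {
    dd <- d
    dd$count <- rnbinom(length(mu), mu = mu, size = obs$base$theta)
    if (all(dd$count == dd$count[1])) return(NA_real_)
    tryCatch(zstat(dd)$z, error = function(e) NA_real_)
  }, numeric(1))
  z_boot <- z_boot[is.finite(z_boot)]
  p <- (1 + sum(abs(z_boot - stats::median(z_boot)) >=
                  abs(obs$z - stats::median(z_boot)))) /
    (length(z_boot) + 1)
  list(z = obs$z, p_calibrated = p, z_boot = z_boot, fit = obs$fit)
}
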