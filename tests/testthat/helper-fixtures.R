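# Shared fixtures built in code.

# Half-normal perpendicular distances truncated at w.
halfnorm_distances <- function(n, sigma, w, seed) {
  set.seed(seed)
  x <- abs(rnorm(ceiling(n * 2.5), 0, sigma))
  head(x[x <= w], n)
}

# Closed-form ESW of a pure half-normal detection function.
esw_halfnorm <- function(sigma, w) {
  sigma * sqrt(pi / 2) * (2 * pnorm(w / sigma) - 1)
}

# Minimal object carrying a log-likelihood, for testing likelihood-ratio
# arithmetic against externally stated chi-square values.
fake_ll <- function(ll, df) {
  structure(list(ll = ll, df = df), class = "fake_ll_model")
}
logLik.fake_ll_model <- function(object, ...) {
  structure(object$ll, df = object$df, class = "logLik")
}
registerS3method("logLik", "fake_ll_model", logLik.fake_ll_model,
                 envir = asNamespace("stats"))

# Transect counts over a wide landscape with a smooth spatial field of
# known range, for bandwidth-recovery checks.
spatial_counts <- function(seed, range_km = 2, amp = 1, n = 120,
                           extent_km = 40) {
  set.seed(seed)
  x <- runif(n, 0, extent_km); y <- runif(n, 0, extent_km)
  len <- runif(n, 0.8, 2.5)
  D <- as.matrix(dist(cbind(x, y)))
  S <- amp^2 * exp(-D^2 / (2 * range_km^2)) + diag(1e-8, n)
  f <- drop(chol(S) %*% rnorm(n))
  mu <- exp(1.2 + f + log(len))
  pz <- plogis(-0.5 + log(1 / len))
  cnt <- ifelse(runif(n) < pz, 0L, rnbinom(n, mu = mu, size = 1.5))
  tibble::tibble(transect_id = as.character(seq_len(n)), year = 2011,
                 length_km = len, x_km = x, y_km = y, count = cnt)
}

# Balanced phenology design used in seasonality-recovery checks.
balanced_plots <- function(n_per_forest = 16) {
  tibble::tibble(
    plot_id = sprintf("P%02d", seq_len(2 * n_per_forest)),
    forest = rep(c("Nkala", "Mpelu"), each = n_per_forest)
  )
}

# Species table with forest-independent basal areas (so generator truth
# has a closed form).
equal_basal_areas <- function() {
  sp <- default_fruit_species()
  stats::aggregate(basal_area_m2ha ~ species, data = sp, FUN = mean) |>
    tibble::as_tibble()
}
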