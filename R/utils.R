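#' @importFrom rlang %||% abort warn .data
#' @importFrom stats aggregate anova binom.test coef dnorm glm integrate
#'   logLik lm median optim optimise pchisq plogis pnorm predict qlogis qnorm
#'   quantile residuals rbinom rmultinom rnbinom rnorm rpois runif rlnorm sd
#'   setNames uniroot update vcov binomial hatvalues
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed for a named pipeline stage from one master
# seed.  Keeps every derived seed inside the 32-bit integer range.
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  codes <- utf8ToInt(as.character(stage))
  h <- as.double(master) %% 2147483647
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

#' Standardise a numeric vector to mean zero and unit standard deviation
#'
#' Uses the sample (n - 1) standard deviation.  Model coefficients on
#' z-transformed predictors are in units of one predictor SD.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Numeric vector with mean 0 and sd 1.
#' @export
#' @examples
#' z_transform(c(1, 2, 3))
z_transform <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("`x` is constant; cannot z-transform.")
  (x - mean(x)) / s
}

# Day-of-year mapped onto the circle, period 365.25 days.
date_angle <- function(date, period_days = 365.25) {
  doy <- as.numeric(date - as.Date(format(date, "%Y-01-01"))) + 1
  2 * pi * doy / period_days
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
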