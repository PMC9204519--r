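#' Uncertain quantity
#'
#' A single model input with a point estimate and, optionally, a dispersion
#' (`sd`) used by the probabilistic sensitivity analysis and a range
#' (`low`/`high`) used by one-way sensitivity analysis. The `family` names the
#' sampling distribution: `"beta"` for probabilities and utilities, `"gamma"`
#' for costs and other non-negative magnitudes, `"fixed"` for quantities with
#' no sampled uncertainty. For a gamma-family quantity with a negative mean
#' (a disutility), the magnitude is gamma-distributed and the sign is carried
#' through.
#'
#' @param mean point estimate (base-case value).
#' @param sd standard deviation, or `NA` when none is published.
#' @param low,high range endpoints for one-way sensitivity, or `NA`.
#' @param family `"beta"`, `"gamma"` or `"fixed"`.
#' @param sample logical; should the probabilistic sensitivity analysis draw
#'   this quantity? Defaults to `TRUE` when an `sd` is available and the
#'   family is not `"fixed"`. Quantities whose published dispersion reflects
#'   patient-level heterogeneity or regional price policy rather than
#'   estimation uncertainty are shipped with `sample = FALSE`.
#' @return An object of class `"uq"`.
#' @export
uq <- function(mean, sd = NA_real_, low = NA_real_, high = NA_real_,
               family = c("beta", "gamma", "fixed"), sample = NULL) {
  family <- match.arg(family)
  if (is.null(sample)) sample <- is.finite(sd) && family != "fixed"
  structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd), low = as.numeric(low),
         high = as.numeric(high), family = family, sample = isTRUE(sample)),
    class = "uq")
}

is_uq <- function(x) inherits(x, "uq")

#' @export
print.uq <- function(x, ...) {
  rng <- if (is.finite(x$low) || is.finite(x$high))
    sprintf(" [%g, %g]", x$low, x$high) else ""
  sd <- if (is.finite(x$sd)) sprintf(" (sd %g)", x$sd) else ""
  cat(sprintf("<uq %s> %g%s%s%s\n", x$family, x$mean, sd, rng,
              if (x$sample) " sampled" else ""))
  invisible(x)
}

#' Method-of-moments beta fit
#'
#' Solves for the `(alpha, beta)` shape parameters of a beta distribution with
#' the given mean and standard deviation:
#' `nu = mean (1 - mean) / sd^2 - 1`, `alpha = mean nu`, `beta = (1 - mean) nu`.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return A list with `family = "beta"` and elements `alpha`, `beta`.
#' @export
beta_from_mean_sd <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly inside (0, 1), got ", mean)
  if (sd <= 0 || sd^2 >= mean * (1 - mean))
    stop(sprintf(
      "infeasible moments for beta: need 0 < sd^2 < mean(1-mean) = %g, got sd^2 = %g",
      mean * (1 - mean), sd^2))
  nu <- mean * (1 - mean) / sd^2 - 1
  list(family = "beta", alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma fit
#'
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`, so that the implied mean
#' and standard deviation recover the inputs exactly.
#'
#' @param mean positive mean.
#' @param sd positive standard deviation.
#' @return A list with `family = "gamma"` and elements `shape`, `scale`.
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (mean <= 0) stop("gamma mean must be positive, got ", mean)
  if (sd <= 0) stop("gamma sd must be positive, got ", sd)
  list(family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean)
}

# One random draw from a uq's fitted distribution; fixed and unsampled
# quantities return the mean unchanged. Used by draw_psa_sample().
draw_uq <- function(x, id = "<unnamed>") {
  if (!x$sample || x$family == "fixed" || !is.finite(x$sd)) return(x$mean)
  if (x$family == "beta") {
    fit <- tryCatch(beta_from_mean_sd(x$mean, x$sd),
                    error = function(e) stop("parameter ", id, ": ",
                                             conditionMessage(e), call. = FALSE))
    stats::rbeta(1, fit$alpha, fit$beta)
  } else {
    sgn <- if (x$mean < 0) -1 else 1
    fit <- tryCatch(gamma_from_mean_sd(abs(x$mean), x$sd),
                    error = function(e) stop("parameter ", id, ": ",
                                             conditionMessage(e), call. = FALSE))
    sgn * stats::rgamma(1, shape = fit$shape, scale = fit$scale)
  }
}

#' Convert an annual discount rate to the equivalent monthly rate
#'
#' Returns `(1 + annual_rate)^(1/12) - 1`, the monthly rate that compounds to
#' the annual rate over 12 months.
#'
#' @param annual_rate annual rate in `[0, 1)`.
#' @return The equivalent monthly rate.
#' @export
annual_to_monthly_discount <- function(annual_rate) {
  if (!is.numeric(annual_rate) || length(annual_rate) != 1 ||
      !is.finite(annual_rate) || annual_rate < 0 || annual_rate >= 1)
    stop("annual_rate must be a single number in [0, 1), got ",
         deparse(annual_rate))
  (1 + annual_rate)^(1 / 12) - 1
}

#' Reference willingness-to-pay thresholds
#'
#' One and three times the 2021 Chinese per-capita GDP, in USD per QALY.
#'
#' @return Named numeric vector `c(gdp1 = 12500, gdp3 = 37500)`.
#' @export
wtp_defaults <- function() c(gdp1 = 12500, gdp3 = 37500)
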