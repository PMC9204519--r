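#' Built-in base-case parameter set
#'
#' The published base-case inputs of the TAVR-vs-SAVR evaluation: 30-day
#' periprocedural complication incidences per arm, time-banded monthly
#' transition probabilities, the atrial-fibrillation sub-model, utilities and
#' disutilities, all cost components with their dispersions and ranges, the
#' 3.7% annual discount rate and the 37,500 USD/QALY willingness-to-pay
#' threshold (three times 2021 Chinese per-capita GDP).
#'
#' Quantities published without a dispersion are `family = "fixed"`; they are
#' held at their means in the probabilistic sensitivity analysis. The two
#' device costs and the six no-event utilities carry published SDs but are
#' shipped with `sample = FALSE`: device price is treated as a policy variable
#' (scenario and threshold analysis), and the utility SDs are patient-level
#' dispersions rather than standard errors (see the methods vignette).
#'
#' `device_cost_multiplier` is the calibrated pass-through of a device-price
#' change to total strategy cost (0.96807), applied whenever a device cost is
#' overridden in scenario, one-way-sensitivity or threshold analyses.
#'
#' @return An object of class `"cea_params"`.
#' @export
default_params <- function() {
  beta_p <- function(m, s, lo, hi) uq(m, s, lo, hi, "beta")
  gam <- function(m, s = NA, lo = NA, hi = NA, sample = NULL)
    uq(m, s, lo, hi, "gamma", sample = sample)
  fx <- function(m, lo = NA, hi = NA) uq(m, low = lo, high = hi, family = "fixed")

  p <- list(
    incidences = list(
      tavr = list(
        af       = beta_p(0.091, 0.009, 0.073, 0.109),
        aki      = beta_p(0.013, 0.004, 0.006, 0.020),
        bleeding = beta_p(0.104, 0.010, 0.085, 0.123),
        death    = beta_p(0.039, 0.006, 0.027, 0.051),
        disabling_stroke     = beta_p(0.032, 0.006, 0.021, 0.043),
        major_vascular       = beta_p(0.079, 0.008, 0.062, 0.096),
        mi       = beta_p(0.012, 0.003, 0.005, 0.019),
        non_disabling_stroke = beta_p(0.023, 0.005, 0.014, 0.032),
        ppm      = beta_p(0.085, 0.009, 0.068, 0.102)),
      savr = list(
        af       = beta_p(0.264, 0.014, 0.237, 0.291),
        aki      = beta_p(0.031, 0.005, 0.020, 0.042),
        bleeding = beta_p(0.434, 0.016, 0.404, 0.464),
        death    = beta_p(0.041, 0.006, 0.029, 0.053),
        disabling_stroke     = beta_p(0.043, 0.006, 0.031, 0.055),
        major_vascular       = beta_p(0.050, 0.007, 0.037, 0.063),
        mi       = beta_p(0.019, 0.004, 0.011, 0.027),
        non_disabling_stroke = beta_p(0.018, 0.004, 0.010, 0.026),
        ppm      = beta_p(0.069, 0.008, 0.053, 0.085))),
    # monthly probabilities, per follow-up band (months 2-12, 13-24, 25-60)
    transitions = list(
      tavr = list(
        af = c(band_2_12 = 0.0010, band_13_24 = 0.0011, band_25_60 = 0.0014),
        non_disabling_stroke =
             c(band_2_12 = 0.0007, band_13_24 = 0.0003, band_25_60 = 0.0005),
        disabling_stroke =
             c(band_2_12 = 0.0017, band_13_24 = 0.0011, band_25_60 = 0.0011),
        cv_mortality =
             c(band_2_12 = 0.0036, band_13_24 = 0.0027, band_25_60 = 0.0067)),
      savr = list(
        af = c(band_2_12 = 0.0010, band_13_24 = 0.0001, band_25_60 = 0.0011),
        non_disabling_stroke =
             c(band_2_12 = 0.0007, band_13_24 = 0.0003, band_25_60 = 0.0003),
        disabling_stroke =
             c(band_2_12 = 0.0014, band_13_24 = 0.0005, band_25_60 = 0.0007),
        cv_mortality =
             c(band_2_12 = 0.0047, band_13_24 = 0.0029, band_25_60 = 0.0057))),
    non_cv_mortality_monthly = 0.0026,  # ages 80-85, per month
    af_submodel = c(to_disabling_stroke = 0.0011,
                    to_non_disabling_stroke = 0.0005,
                    to_death = 0.0024),
    # published AF-to-any-stroke row; redundant with the disabling +
    # non-disabling split, stored as a consistency check only
    af_to_stroke_check = 0.0016,
    utilities = list(
      no_event = list(
        tavr = list(m_lt7  = uq(0.74, 0.24, family = "beta", sample = FALSE),
                    m_7_12 = uq(0.76, 0.20, family = "beta", sample = FALSE),
                    m_gt12 = uq(0.75, 0.22, family = "beta", sample = FALSE)),
        savr = list(m_lt7  = uq(0.68, 0.24, family = "beta", sample = FALSE),
                    m_7_12 = uq(0.75, 0.27, family = "beta", sample = FALSE),
                    m_gt12 = uq(0.74, 0.23, family = "beta", sample = FALSE))),
      disabling_stroke = fx(0.39, 0.31, 0.52),  # state utility, not a disutility
      disutility = list(
        non_disabling_stroke = uq(-0.161, 0.054, family = "gamma"),
        af             = fx(-0.038, -0.038, 0),
        aki            = fx(-0.177, -0.177, 0),
        bleeding       = fx(-0.447, -0.447, 0),
        major_vascular = fx(-0.046, -0.046, 0),
        mi             = fx(-0.100, -0.100, 0))),
    costs = list(  # USD
      procedure = list(
        tavr = list(device    = gam(45526, 11511, 22965, 68087, sample = FALSE),
                    diagnosis = gam(2016,  721,  1008, 4031),
                    medicine  = gam(2025, 1163,  1013, 4050),
                    others    = gam(824,   112,   605, 1043)),
        savr = list(device    = gam(15580, 15933, 7790, 31160, sample = FALSE),
                    diagnosis = gam(2076,  677,   749, 3403),
                    medicine  = gam(8182, 5703,  4091, 16364),
                    others    = gam(1401, 1883,   700, 2801))),
      event = list(  # one-time, on occurrence
        non_disabling_stroke = fx(1898, 1096, 2390),
        disabling_stroke     = fx(2509, 1379, 3291),
        mi                   = fx(6750, 3375, 13500),
        major_vascular       = fx(5500, 2750, 11000),
        bleeding             = gam(868,    69,  732, 1003),
        aki                  = gam(1849, 1176,  924, 3697),
        ppm                  = gam(13680, 4380, 5094, 22265),
        af                   = fx(16192, 14124, 18475),
        stroke_death         = gam(2151,  458, 1011, 2843)),
      annual = list(  # USD per year while in state
        non_disabling_stroke = gam(1349, 329, 404, 1721),
        disabling_stroke     = gam(2053, 516, 516, 2582),
        af                   = fx(1891, 945, 3781))),
    annual_discount_rate = 0.037,
    wtp = 37500,
    horizon_months = 60L,
    device_cost_multiplier = 0.96807,
    options = list(qaly_discount = FALSE, half_cycle = FALSE))
  class(p) <- "cea_params"
  p
}

#' @export
print.cea_params <- function(x, ...) {
  cat("<cea_params> TAVR vs SAVR cost-effectiveness inputs\n")
  cat(sprintf("  horizon: %d months (1 decision-tree month + %d Markov cycles)\n",
              x$horizon_months, x$horizon_months - 1L))
  cat(sprintf("  discount: %.3f/yr (%.5f/mo)%s | WTP %s USD/QALY\n",
              x$annual_discount_rate,
              annual_to_monthly_discount(x$annual_discount_rate),
              if (x$options$qaly_discount) " costs+QALYs" else " costs only",
              format(x$wtp, big.mark = ",")))
  tab <- params_to_table(x)
  cat(sprintf("  %d parameters (%d sampled in PSA, %d with OWSA ranges)\n",
              nrow(tab), sum(tab$sampled), sum(is.finite(tab$low))))
  v <- validate_params(x)
  if (length(v)) cat("  INVALID:", length(v), "violation(s); see validate_params()\n")
  invisible(x)
}
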