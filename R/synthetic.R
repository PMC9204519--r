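#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Replaces every sampled uncertain quantity by an independent draw from its
#' method-of-moments distribution: beta for probabilities (see
#' [beta_from_mean_sd()]), gamma for costs and the non-disabling-stroke
#' disutility magnitude (see [gamma_from_mean_sd()]). Quantities published
#' without a dispersion, and those shipped with `sample = FALSE` (device
#' costs, no-event utilities; see the methods vignette), are held at their
#' means. Draws across parameters are independent; the published analysis
#' states no correlation structure.
#'
#' @param params a valid `cea_params` object.
#' @param rng_seed integer seed; the same seed reproduces the draw exactly.
#' @return A `cea_params` object with drawn values; passes [validate_params()].
#' @export
draw_psa_sample <- function(params, rng_seed) {
  stopifnot(!length(validate_params(params)))
  set.seed(as.integer(rng_seed))
  out <- params
  for (r in uq_registry(params)) {
    q <- params[[r$path]]
    if (!q$sample || q$family == "fixed" || !is.finite(q$sd)) next
    drawn <- q
    drawn$mean <- draw_uq(q, id = r$id)
    drawn$low <- NA_real_   # published ranges describe the base value,
    drawn$high <- NA_real_  # not the realized draw
    out[[r$path]] <- drawn
  }
  out
}

#' Random valid parameter set
#'
#' Generates a structurally valid parameter set with values drawn from wide
#' but feasible ranges: periprocedural incidences that leave a positive
#' no-event remainder, monthly transition probabilities below 2% per month,
#' utilities in (0.2, 0.9), negative disutilities, log-uniform costs. Used to
#' property-test every downstream module; not a draw from any published
#' uncertainty (use [draw_psa_sample()] for that).
#'
#' @param rng_seed integer seed.
#' @return A `cea_params` object for which `validate_params()` returns no
#'   violations.
#' @export
random_valid_params <- function(rng_seed) {
  set.seed(as.integer(rng_seed))
  p <- default_params()
  ru <- function(lo, hi) stats::runif(1, lo, hi)

  for (arm in c("tavr", "savr")) {
    # state-determining incidences scaled so their sum stays well below 1
    repeat {
      vals <- stats::runif(4, 0.005, 0.30)
      if (sum(vals) < 0.8) break
    }
    st <- c("death", "disabling_stroke", "non_disabling_stroke", "af")
    for (i in seq_along(st)) {
      m <- vals[i]
      p$incidences[[arm]][[st[i]]] <-
        uq(m, sd = 0.3 * sqrt(m * (1 - m)), low = 0.5 * m,
           high = min(1, 1.5 * m), family = "beta")
    }
    for (nm in c("aki", "bleeding", "major_vascular", "mi", "ppm")) {
      m <- ru(0.005, 0.4)
      p$incidences[[arm]][[nm]] <-
        uq(m, sd = 0.3 * sqrt(m * (1 - m)), low = 0.5 * m,
           high = min(1, 1.5 * m), family = "beta")
    }
    for (nm in names(p$transitions[[arm]]))
      p$transitions[[arm]][[nm]][] <- stats::runif(3, 0, 0.02)
    for (nm in names(p$utilities$no_event[[arm]])) {
      m <- ru(0.2, 0.9)
      p$utilities$no_event[[arm]][[nm]] <-
        uq(m, sd = 0.3 * sqrt(m * (1 - m)), family = "beta", sample = FALSE)
    }
    for (nm in names(p$costs$procedure[[arm]])) {
      m <- exp(ru(log(200), log(60000)))
      p$costs$procedure[[arm]][[nm]] <-
        uq(m, sd = 0.3 * m, low = 0.5 * m, high = 2 * m, family = "gamma",
           sample = nm != "device")
    }
  }
  sub <- stats::runif(3, 1e-4, 5e-3)
  p$af_submodel[] <- sub
  p$af_to_stroke_check <- sub[1] + sub[2]
  p$non_cv_mortality_monthly <- ru(5e-4, 5e-3)
  m <- ru(0.25, 0.6)
  p$utilities$disabling_stroke <- uq(m, low = 0.8 * m, high = min(1, 1.3 * m),
                                     family = "fixed")
  for (nm in names(p$utilities$disutility)) {
    m <- -ru(0.01, 0.4)
    p$utilities$disutility[[nm]] <-
      if (nm == "non_disabling_stroke")
        uq(m, sd = 0.3 * abs(m), family = "gamma")
      else uq(m, low = m, high = 0, family = "fixed")
  }
  for (nm in names(p$costs$event)) {
    m <- exp(ru(log(200), log(20000)))
    p$costs$event[[nm]] <- uq(m, sd = 0.3 * m, low = 0.5 * m, high = 2 * m,
                              family = "gamma")
  }
  for (nm in names(p$costs$annual)) {
    m <- exp(ru(log(200), log(5000)))
    p$costs$annual[[nm]] <- uq(m, sd = 0.3 * m, low = 0.5 * m, high = 2 * m,
                               family = "gamma")
  }
  p$annual_discount_rate <- ru(0, 0.1)
  p$wtp <- ru(5000, 100000)
  p
}
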