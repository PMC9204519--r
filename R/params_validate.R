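#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and returns a
#' character vector of violations (empty when the set is valid). Violations
#' are returned, not raised, so callers can report them all at once.
#'
#' Checked invariants:
#' * beta-family quantities have means in `[0, 1]` and, when an sd is present,
#'   `sd^2 < mean (1 - mean)`;
#' * gamma-family quantities have `|mean| >= 0` and positive sd;
#' * `low <= mean <= high` whenever a range is present;
#' * utilities lie in `[0, 1]`, disutilities in `[-1, 0]`;
#' * all cost means are non-negative;
#' * every monthly transition probability lies in `[0, 1]`; the AF sub-model
#'   rows sum to less than 1; the published AF-to-stroke row equals the
#'   disabling + non-disabling split;
#' * per arm, the four state-determining periprocedural incidences (death,
#'   disabling stroke, non-disabling stroke, AF) sum to less than 1 so the
#'   no-event remainder is non-negative;
#' * the horizon is one decision-tree month plus 59 Markov cycles and the
#'   annual discount rate lies in `[0, 1)`.
#'
#' @param params a `cea_params` object.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_params <- function(params) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))

  for (r in uq_registry(params)) {
    q <- params[[r$path]]
    id <- r$id
    if (!is_uq(q)) { say("%s: not an uncertain quantity", id); next }
    if (!is.finite(q$mean)) { say("%s: non-finite mean", id); next }
    if (q$family == "beta") {
      if (q$mean < 0 || q$mean > 1)
        say("%s: beta mean %g outside [0, 1]", id, q$mean)
      else if (is.finite(q$sd) && q$sd^2 >= q$mean * (1 - q$mean))
        say("%s: sd^2 = %g not below mean(1-mean) = %g", id, q$sd^2,
            q$mean * (1 - q$mean))
    }
    if (q$family == "gamma" && is.finite(q$sd) && q$sd <= 0)
      say("%s: gamma sd must be positive, got %g", id, q$sd)
    if (is.finite(q$low) && q$low > q$mean)
      say("%s: low %g exceeds mean %g", id, q$low, q$mean)
    if (is.finite(q$high) && q$high < q$mean)
      say("%s: high %g below mean %g", id, q$high, q$mean)
    if (r$units == "usd" || r$units == "usd_per_year") {
      if (q$mean < 0) say("%s: negative cost mean %g", id, q$mean)
    }
    if (grepl("^utility", id) && (q$mean < 0 || q$mean > 1))
      say("%s: utility %g outside [0, 1]", id, q$mean)
    if (grepl("^disutility", id) && (q$mean < -1 || q$mean > 0))
      say("%s: disutility %g outside [-1, 0]", id, q$mean)
  }

  for (arm in c("tavr", "savr")) {
    inc <- params$incidences[[arm]]
    s <- sum(vapply(inc[c("death", "disabling_stroke", "non_disabling_stroke",
                          "af")], function(q) q$mean, 0))
    if (s >= 1)
      say("incidences_%s: state-determining incidences sum to %g >= 1", arm, s)
    for (nm in names(params$transitions[[arm]])) {
      tr <- params$transitions[[arm]][[nm]]
      bad <- !is.numeric(tr) | tr < 0 | tr > 1
      if (any(bad) || length(tr) != 3L)
        say("transitions_%s_%s: monthly probabilities must be 3 values in [0, 1]",
            arm, nm)
    }
  }

  af <- params$af_submodel
  if (any(af < 0 | af > 1) || sum(af) >= 1)
    say("af_submodel: entries must lie in [0, 1] and sum below 1 (sum = %g)",
        sum(af))
  if (abs(params$af_to_stroke_check -
          (af[["to_disabling_stroke"]] + af[["to_non_disabling_stroke"]])) > 1e-12)
    say("af_to_stroke_check: %g does not equal disabling + non-disabling = %g",
        params$af_to_stroke_check,
        af[["to_disabling_stroke"]] + af[["to_non_disabling_stroke"]])
  ncv <- params$non_cv_mortality_monthly
  if (!is.numeric(ncv) || ncv < 0 || ncv > 1)
    say("non_cv_mortality_monthly: must lie in [0, 1]")

  if (!identical(as.integer(params$horizon_months), 60L))
    say("horizon_months: must be 60 (1 tree month + 59 Markov cycles), got %s",
        format(params$horizon_months))
  dr <- params$annual_discount_rate
  if (!is.numeric(dr) || dr < 0 || dr >= 1)
    say("annual_discount_rate: must lie in [0, 1), got %s", format(dr))
  if (!is.numeric(params$wtp) || params$wtp <= 0)
    say("wtp: must be positive")
  if (!is.numeric(params$device_cost_multiplier) ||
      params$device_cost_multiplier <= 0)
    say("device_cost_multiplier: must be positive")

  v
}
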