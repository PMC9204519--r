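# 30-day periprocedural decision tree: expected cost and QALY of the
# procedure month, and the cohort distribution handed to the Markov model.

uqm <- function(q) if (is_uq(q)) q$mean else q

state_names <- c("no_event", "post_af", "post_disabling_stroke",
                 "post_non_disabling_stroke", "death")

#' Initial Markov state distribution after the 30-day decision tree
#'
#' The four state-determining periprocedural events (death, disabling stroke,
#' non-disabling stroke, new atrial fibrillation) are treated as a mutually
#' exclusive severity partition at their marginal incidences; the remainder
#' enters the no-event state. Patients with several complications occupy the
#' single most severe state (their additional event costs and disutilities are
#' still counted by the cost/QALY expectations).
#'
#' @param incidences one arm's periprocedural incidence list (uq objects or
#'   plain probabilities).
#' @return Named probability vector over the five states, summing to 1.
#' @export
initial_state_vector <- function(incidences) {
  g <- function(nm) uqm(incidences[[nm]])
  s <- c(NA_real_, g("af"), g("disabling_stroke"), g("non_disabling_stroke"),
         g("death"))
  s[1] <- 1 - sum(s[-1])
  if (s[1] < 0)
    stop(sprintf(
      "infeasible incidences: state-determining events sum to %.4f > 1",
      sum(s[-1])))
  stats::setNames(s, state_names)
}

#' Expected 30-day procedure-phase cost for one arm
#'
#' Sum of the four procedure components (device, diagnosis, medicine, others)
#' plus, for each of the nine periprocedural complications, incidence times
#' its one-time event cost (fatal periprocedural events carry no cost row of
#' their own). When `device_override` is given, the device contribution
#' changes by `multiplier * (override - base)`: the calibrated pass-through of
#' a device-price change to total strategy cost.
#'
#' @param arm `"tavr"` or `"savr"`.
#' @param costs the `costs` element of a `cea_params`.
#' @param incidences the arm's periprocedural incidence list.
#' @param device_override device price in USD, or `NULL` for the base price.
#' @param multiplier device-cost pass-through (see
#'   `default_params()$device_cost_multiplier`).
#' @return Expected cost in USD.
#' @export
expected_procedure_cost <- function(arm, costs, incidences,
                                    device_override = NULL,
                                    multiplier = 0.96807) {
  pc <- costs$procedure[[arm]]
  total <- sum(vapply(pc, uqm, 0))
  if (!is.null(device_override))
    total <- total + multiplier * (device_override - uqm(pc$device))
  ev <- costs$event
  for (nm in c("af", "aki", "bleeding", "disabling_stroke", "major_vascular",
               "mi", "non_disabling_stroke", "ppm"))
    total <- total + uqm(incidences[[nm]]) * uqm(ev[[nm]])
  total
}

#' Expected 30-day quality-adjusted life for one arm
#'
#' One month (1/12 year) of the arm's early (<7 months) no-event utility for
#' periprocedural survivors, with disabling-stroke survivors valued at the
#' disabling-stroke state utility instead, plus incidence-weighted one-month
#' disutilities for AF, AKI, bleeding, major vascular complication, MI and
#' non-disabling stroke. A negative expectation (possible only under extreme
#' sensitivity draws) is clamped to zero with a warning.
#'
#' @param arm `"tavr"` or `"savr"`.
#' @param utilities the `utilities` element of a `cea_params`.
#' @param incidences the arm's periprocedural incidence list.
#' @return Expected QALY accrued in the procedure month, in `[0, 1/12]`.
#' @export
expected_periprocedural_qaly <- function(arm, utilities, incidences) {
  g <- function(nm) uqm(incidences[[nm]])
  u1 <- uqm(utilities$no_event[[arm]]$m_lt7)
  q <- (1 - g("death") - g("disabling_stroke")) * u1 +
    g("disabling_stroke") * uqm(utilities$disabling_stroke)
  for (nm in c("af", "aki", "bleeding", "major_vascular", "mi",
               "non_disabling_stroke"))
    q <- q + g(nm) * uqm(utilities$disutility[[nm]])
  if (q < 0) {
    warning("expected periprocedural QALY fell below 0 (", signif(q / 12, 3),
            "); clamped to 0")
    q <- 0
  }
  q / 12
}

#' Run the 30-day decision tree for one arm
#'
#' @inheritParams expected_procedure_cost
#' @param params a `cea_params` object.
#' @return A list with `expected_cost_30d` (USD), `expected_qaly_30d` (QALY)
#'   and `initial_state` (the five-state vector entering the Markov model).
#'   The decision tree occupies month 1 of the horizon and is not discounted.
#' @export
run_decision_tree <- function(params, arm = c("tavr", "savr"),
                              device_override = NULL) {
  arm <- match.arg(arm)
  inc <- params$incidences[[arm]]
  list(
    expected_cost_30d = expected_procedure_cost(
      arm, params$costs, inc, device_override, params$device_cost_multiplier),
    expected_qaly_30d = expected_periprocedural_qaly(arm, params$utilities, inc),
    initial_state = initial_state_vector(inc))
}
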