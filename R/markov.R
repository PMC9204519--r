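# 59-cycle monthly Markov cohort model over five states with time-banded
# transition probabilities. Conventions (frozen after calibration against the
# published base case; see the methods vignette): competing risks are additive
# within a row with the residual staying put; death is absorbing; state-cost
# and utility accruals use cycle-start occupancy (transitions at cycle end);
# costs are discounted at the monthly-compounded annual rate with exponent
# (month - 1); QALYs are undiscounted by default (options$qaly_discount).

#' Follow-up band for an absolute model month
#'
#' Transition probabilities are published per follow-up band: months 2-12,
#' 13-24 and 25-60 (month 1 is the decision tree).
#'
#' @param month integer in 2..60.
#' @return `"band_2_12"`, `"band_13_24"` or `"band_25_60"`.
#' @export
band_for_month <- function(month) {
  if (!is.numeric(month) || length(month) != 1L || month != round(month) ||
      month < 2 || month > 60)
    stop("month must be an integer in 2..60, got ", deparse(month))
  if (month <= 12) "band_2_12" else if (month <= 24) "band_13_24"
  else "band_25_60"
}

#' Monthly transition matrix for one arm and month
#'
#' Row-stochastic 5x5 matrix over no-event, post-AF, post-disabling-stroke,
#' post-non-disabling-stroke and death. From no-event, the arm's banded
#' monthly probabilities feed AF and the two stroke states, and death receives
#' banded cardiovascular plus constant non-cardiovascular mortality. From
#' post-AF, the AF sub-model feeds the stroke states, and death receives the
#' AF-specific mortality plus the arm's banded cardiovascular mortality (the
#' AF cohort rate is treated as subsuming non-cardiovascular causes; a
#' calibrated convention, see the methods vignette). The stroke states face
#' banded cardiovascular plus non-cardiovascular mortality. Death is
#' absorbing; backward transitions do not exist.
#'
#' @param params a `cea_params` object.
#' @param arm `"tavr"` or `"savr"`.
#' @param month integer in 2..60.
#' @return A 5x5 row-stochastic matrix with state dimnames.
#' @export
build_transition_matrix <- function(params, arm = c("tavr", "savr"), month) {
  arm <- match.arg(arm)
  b <- band_for_month(month)
  tr <- params$transitions[[arm]]
  ncv <- params$non_cv_mortality_monthly
  afs <- params$af_submodel
  cv <- tr$cv_mortality[[b]]

  P <- matrix(0, 5, 5, dimnames = list(state_names, state_names))
  P["no_event", "post_af"] <- tr$af[[b]]
  P["no_event", "post_disabling_stroke"] <- tr$disabling_stroke[[b]]
  P["no_event", "post_non_disabling_stroke"] <- tr$non_disabling_stroke[[b]]
  P["no_event", "death"] <- cv + ncv
  P["post_af", "post_disabling_stroke"] <- afs[["to_disabling_stroke"]]
  P["post_af", "post_non_disabling_stroke"] <- afs[["to_non_disabling_stroke"]]
  P["post_af", "death"] <- afs[["to_death"]] + cv
  P["post_disabling_stroke", "death"] <- cv + ncv
  P["post_non_disabling_stroke", "death"] <- cv + ncv
  P["death", "death"] <- 1
  for (s in state_names[1:4]) {
    resid <- 1 - sum(P[s, ])
    if (resid < 0)
      stop(sprintf("infeasible probabilities in row '%s' at month %d: leave-state sum %.4f > 1",
                   s, month, sum(P[s, ])))
    P[s, s] <- resid
  }
  P
}

#' Propagate a cohort through the 59 Markov cycles
#'
#' Pure matrix algebra, no sampling: `occupancy(m) = occupancy(m-1) P(m)` for
#' months 2..60 with `occupancy(1)` equal to the decision tree's exit
#' distribution. Also records, per cycle, the probability mass flowing along
#' the event-cost-bearing edges (into AF, into each stroke state, and from the
#' stroke states into death).
#'
#' @param initial five-state probability vector (sums to 1).
#' @param params a `cea_params` object.
#' @param arm `"tavr"` or `"savr"`.
#' @return A `cohort_trace`: list with `occupancy` (60x5 matrix, month 1 = the
#'   tree month) and `flows` (59x4 matrix, months 2..60, columns `into_af`,
#'   `into_disabling`, `into_non_disabling`, `stroke_to_death`).
#' @export
run_cohort <- function(initial, params, arm = c("tavr", "savr")) {
  arm <- match.arg(arm)
  stopifnot(length(initial) == 5L, all(initial >= 0),
            abs(sum(initial) - 1) < 1e-9)
  H <- params$horizon_months
  Pb <- lapply(c(2, 13, 25), function(m) build_transition_matrix(params, arm, m))
  band_idx <- c(rep(1L, 11), rep(2L, 12), rep(3L, 36))  # months 2..60

  occ <- matrix(0, H, 5, dimnames = list(NULL, state_names))
  occ[1, ] <- as.numeric(initial)
  flows <- matrix(0, H - 1L, 4, dimnames = list(
    NULL, c("into_af", "into_disabling", "into_non_disabling",
            "stroke_to_death")))
  for (m in 2:H) {
    P <- Pb[[band_idx[m - 1L]]]
    prev <- occ[m - 1L, ]
    occ[m, ] <- prev %*% P
    flows[m - 1L, ] <- c(
      prev[1L] * P[1L, 2L],
      prev[1L] * P[1L, 3L] + prev[2L] * P[2L, 3L],
      prev[1L] * P[1L, 4L] + prev[2L] * P[2L, 4L],
      prev[3L] * P[3L, 5L] + prev[4L] * P[4L, 5L])
  }
  structure(list(occupancy = occ, flows = flows, arm = arm),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  H <- nrow(x$occupancy)
  cat(sprintf("<cohort_trace> %s, %d months; death occupancy %.3f at month %d\n",
              x$arm, H, x$occupancy[H, "death"], H))
  invisible(x)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per Markov month: state costs are cycle-start occupancy times the monthly
#' state cost (annual state costs / 12 for post-AF and the stroke states;
#' no-event carries none); event costs are the cycle's edge flows times the
#' one-time event costs (stroke events, and the stroke-death cost on
#' stroke-state deaths; incident AF is costed through its annual state cost,
#' the one-time AF cost belonging to the periprocedural tree); utilities are
#' cycle-start occupancy times the state
#' utility / 12, where no-event uses the arm's time-banded utility (months
#' <7, 7-12, >12 of the horizon), post-AF and post-non-disabling-stroke apply
#' their disutility to it, the disabling-stroke state uses its fixed utility,
#' and death scores zero. Costs are discounted by `(1+r_m)^-(m-1)`; QALYs
#' likewise when `options$qaly_discount` is on. With `options$half_cycle`,
#' occupancy-based accruals use the average of cycle-start and cycle-end
#' occupancy.
#'
#' @param trace a `cohort_trace` from [run_cohort()].
#' @param params a `cea_params` object.
#' @param arm `"tavr"` or `"savr"`; defaults to the trace's arm.
#' @return A list with totals `cost` (USD) and `qaly`, plus `cycle`, a
#'   data.frame of per-month discounted accruals and discount factors.
#' @export
accumulate_trace <- function(trace, params, arm = trace$arm) {
  H <- nrow(trace$occupancy)
  months <- 2:H
  rm_ <- annual_to_monthly_discount(params$annual_discount_rate)
  disc <- (1 + rm_)^-(months - 1)

  Obeg <- trace$occupancy[months - 1L, , drop = FALSE]
  if (isTRUE(params$options$half_cycle))
    Obeg <- (Obeg + trace$occupancy[months, , drop = FALSE]) / 2

  ann <- params$costs$annual
  state_cost <- c(0, uqm(ann$af), uqm(ann$disabling_stroke),
                  uqm(ann$non_disabling_stroke), 0) / 12
  ev <- params$costs$event
  # incident AF is costed through the AF annual state cost only; the one-time
  # AF event cost is attributed to the periprocedural complication in the
  # decision tree (calibrated convention, see the methods vignette)
  edge_cost <- c(0, uqm(ev$disabling_stroke),
                 uqm(ev$non_disabling_stroke), uqm(ev$stroke_death))
  cycle_cost <- disc * (Obeg %*% state_cost + trace$flows %*% edge_cost)

  u_ne <- params$utilities$no_event[[arm]]
  u_band <- ifelse(months <= 6, uqm(u_ne$m_lt7),
                   ifelse(months <= 12, uqm(u_ne$m_7_12), uqm(u_ne$m_gt12)))
  du <- params$utilities$disutility
  u_states <- cbind(u_band,
                    u_band + uqm(du$af),
                    uqm(params$utilities$disabling_stroke),
                    u_band + uqm(du$non_disabling_stroke),
                    0)
  raw_q <- rowSums(Obeg * u_states) / 12
  if (any(raw_q < 0)) {
    warning("negative cycle QALY accrual clamped to 0 in ",
            sum(raw_q < 0), " cycle(s)")
    raw_q <- pmax(raw_q, 0)
  }
  qdisc <- if (isTRUE(params$options$qaly_discount)) disc else rep(1, length(months))
  cycle_qaly <- qdisc * raw_q

  list(cost = sum(cycle_cost), qaly = sum(cycle_qaly),
       cycle = data.frame(month = months, cost = as.numeric(cycle_cost),
                          qaly = as.numeric(cycle_qaly), discount = disc))
}

#' Run one strategy end to end (decision tree + Markov model)
#'
#' @param params a `cea_params` object.
#' @param arm `"tavr"` or `"savr"`.
#' @param device_override device price in USD, or `NULL` for the base price.
#' @return An `arm_result`: list with `strategy`, `total_cost` (USD),
#'   `total_qaly`, and the underlying `tree`, `trace` and `accrual` pieces.
#' @export
run_strategy <- function(params, arm = c("tavr", "savr"),
                         device_override = NULL) {
  arm <- match.arg(arm)
  tree <- run_decision_tree(params, arm, device_override)
  trace <- run_cohort(tree$initial_state, params, arm)
  acc <- accumulate_trace(trace, params, arm)
  structure(list(strategy = toupper(arm),
                 total_cost = tree$expected_cost_30d + acc$cost,
                 total_qaly = tree$expected_qaly_30d + acc$qaly,
                 tree = tree, trace = trace, accrual = acc),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s: %.0f USD, %.4f QALY over %d months\n",
              x$strategy, x$total_cost, x$total_qaly, nrow(x$trace$occupancy)))
  invisible(x)
}

#' Per-month trace table for export
#'
#' @param result an `arm_result` from [run_strategy()].
#' @return A data.frame with one row per model month: the five occupancies,
#'   the discounted cycle cost and QALY, and the cost discount factor (the
#'   tree month carries its undiscounted totals).
#' @export
trace_table <- function(result) {
  occ <- result$trace$occupancy
  cyc <- result$accrual$cycle
  data.frame(arm = result$strategy, month = seq_len(nrow(occ)), occ,
             cycle_cost = c(result$tree$expected_cost_30d, cyc$cost),
             cycle_qaly = c(result$tree$expected_qaly_30d, cyc$qaly),
             discount = c(1, cyc$discount), row.names = NULL)
}
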