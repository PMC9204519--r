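# Incremental cost-effectiveness arithmetic: ICER, dominance, net monetary
# benefit, and the device-price threshold solver.

#' Compare two strategies
#'
#' Deltas are intervention minus comparator. Classification: `dominant` when
#' the intervention is no more costly and no less effective (and not
#' identical), `dominated` for the reverse, `equivalent` when both deltas are
#' zero, `trade_off` otherwise. The ICER (delta cost / delta QALY) is reported
#' whenever the effectiveness delta is non-zero — including the signed ratio
#' under dominance, matching how such results are tabulated — and is `NA` for
#' equivalent strategies. Net monetary benefit is `wtp * dQALY - dcost`;
#' `cost_effective` is true under dominance or for a trade-off with positive
#' effectiveness gain and ICER below the willingness-to-pay.
#'
#' @param intervention,comparator `arm_result` objects (or lists with
#'   `total_cost`, `total_qaly`, `strategy`).
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @return A `ce_result`: list with `delta_cost`, `delta_qaly`, `icer`,
#'   `classification`, `nmb`, `cost_effective`, `wtp`.
#' @export
compare_strategies <- function(intervention, comparator, wtp = 37500) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  eps <- 1e-12
  classification <-
    if (abs(dc) < eps && abs(dq) < eps) "equivalent"
    else if (dc <= eps && dq >= -eps) "dominant"
    else if (dc >= -eps && dq <= eps) "dominated"
    else "trade_off"
  icer <- if (classification == "equivalent" || abs(dq) < eps) NA_real_
          else dc / dq
  nmb <- wtp * dq - dc
  structure(list(
    intervention = intervention$strategy, comparator = comparator$strategy,
    delta_cost = dc, delta_qaly = dq, icer = icer,
    classification = classification, nmb = nmb, wtp = wtp,
    cost_effective = classification == "dominant" ||
      (classification == "trade_off" && dq > 0 && icer < wtp)),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s vs %s: dCost %.0f USD, dQALY %.4f (%s)\n",
              x$intervention, x$comparator, x$delta_cost, x$delta_qaly,
              x$classification))
  if (!is.na(x$icer))
    cat(sprintf("  ICER %.0f USD/QALY; NMB %.0f at WTP %s; %scost-effective\n",
                x$icer, x$nmb, format(x$wtp, big.mark = ","),
                if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Deterministic base case: both strategies plus their comparison
#'
#' Runs the decision tree and Markov model for both arms under identical
#' conventions and compares TAVR (intervention) against SAVR (comparator).
#'
#' @param params a `cea_params` object.
#' @return A list with `tavr`, `savr` (`arm_result`) and `comparison`
#'   (`ce_result`), of class `"base_case"`.
#' @export
run_base_case <- function(params) {
  v <- validate_params(params)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  tavr <- run_strategy(params, "tavr")
  savr <- run_strategy(params, "savr")
  structure(list(tavr = tavr, savr = savr,
                 comparison = compare_strategies(tavr, savr, params$wtp)),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  cat(sprintf("Base case over %d months:\n", nrow(x$tavr$trace$occupancy)))
  for (a in list(x$savr, x$tavr))
    cat(sprintf("  %s: %8.0f USD  %.3f QALY\n", a$strategy, a$total_cost,
                a$total_qaly))
  print(x$comparison)
  invisible(x)
}

#' Device price at which TAVR's ICER equals a willingness-to-pay threshold
#'
#' Total strategy cost is affine in the device price (slope equal to the
#' device-cost pass-through multiplier) while effectiveness is unaffected, so
#' the ICER is strictly increasing in price and the root is unique. The root
#' is found by [stats::uniroot()] on the full pipeline (each candidate price
#' reruns decision tree plus Markov model), to within 0.01 USD.
#'
#' @param params a `cea_params` object.
#' @param wtp positive willingness-to-pay threshold, USD/QALY.
#' @return The threshold device price in USD.
#' @export
threshold_device_price <- function(params, wtp = params$wtp) {
  if (!is.numeric(wtp) || length(wtp) != 1L || wtp <= 0)
    stop("wtp must be a single positive number, got ", deparse(wtp))
  savr <- run_strategy(params, "savr")
  icer_at <- function(p) {
    tavr <- run_strategy(params, "tavr", device_override = p)
    (tavr$total_cost - savr$total_cost) / (tavr$total_qaly - savr$total_qaly)
  }
  base_tavr <- run_strategy(params, "tavr")
  if (base_tavr$total_qaly - savr$total_qaly <= 0)
    stop("threshold price undefined: base-case effectiveness gain is not positive")
  p0 <- uqm(params$costs$procedure$tavr$device)
  stats::uniroot(function(p) icer_at(p) - wtp,
                 interval = c(1, max(4 * p0, 2e5)), extendInt = "upX",
                 tol = 0.01)$root
}
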