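# One-way (tornado) sensitivity, probabilistic sensitivity analysis,
# cost-effectiveness acceptability curves, and device-price scenarios.

#' One-way sensitivity analysis (tornado)
#'
#' Reruns the full pipeline with each parameter set to its published low and
#' high range endpoint, all others at base, and records both ICERs. Device
#' costs are swept through the device-override pathway, so a device-price
#' change propagates at the calibrated pass-through multiplier. Parameters
#' without a published range are skipped with a message. Entries are sorted
#' by descending ICER span.
#'
#' @param params a `cea_params` object.
#' @param ids parameter ids (see [params_to_table()]); default: every
#'   parameter with a range.
#' @return A data.frame of class `"tornado"`: `parameter_id`, `low`, `high`,
#'   `icer_low`, `icer_high`, `span`, plus the base-case ICER as attribute
#'   `"base_icer"`.
#' @export
one_way_sensitivity <- function(params, ids = NULL) {
  tab <- params_to_table(params)
  if (is.null(ids)) ids <- tab$parameter_id[is.finite(tab$low) &
                                            is.finite(tab$high)]
  base <- run_base_case(params)
  icer_for <- function(id, value) {
    if (id == "cost_procedure_tavr_device") {
      tavr <- run_strategy(params, "tavr", device_override = value)
      savr <- base$savr
    } else if (id == "cost_procedure_savr_device") {
      tavr <- base$tavr
      savr <- run_strategy(params, "savr", device_override = value)
    } else {
      reg <- uq_lookup(params, id)
      p2 <- params
      q <- p2[[reg$path]]
      q$mean <- value
      p2[[reg$path]] <- q
      tavr <- run_strategy(p2, "tavr")
      savr <- run_strategy(p2, "savr")
    }
    compare_strategies(tavr, savr, params$wtp)$icer
  }
  rows <- lapply(ids, function(id) {
    row <- tab[tab$parameter_id == id, ]
    if (!is.finite(row$low) || !is.finite(row$high)) {
      message("one_way_sensitivity: no range for ", id, "; skipped")
      return(NULL)
    }
    lo <- icer_for(id, row$low)
    hi <- icer_for(id, row$high)
    data.frame(parameter_id = id, low = row$low, high = row$high,
               icer_low = lo, icer_high = hi, span = abs(hi - lo))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$comparison$icer
  class(out) <- c("tornado", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' `n_draws` independent parameter draws (see [draw_psa_sample()]), each run
#' through the full decision tree + Markov pipeline for both arms. One seeded
#' stream derives a deterministic sub-seed per draw, so any single draw can
#' be reproduced in isolation; the same `seed` reproduces the whole run
#' bit-for-bit.
#'
#' @param params a valid `cea_params` object.
#' @param n_draws number of Monte-Carlo draws (the published analysis uses
#'   10,000).
#' @param seed integer seed for the run.
#' @return A `psa_result`: list with `n_draws`, `seed`, and `draws`, a
#'   data.frame with one row per draw (`draw`, per-arm costs and QALYs,
#'   `delta_cost`, `delta_qaly`).
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1) {
  stopifnot(n_draws >= 1)
  v <- validate_params(params)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  set.seed(as.integer(seed))
  draw_seeds <- sample.int(2147483646L, n_draws, replace = FALSE)
  tc <- tq <- sc <- sq <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    ps <- tryCatch(draw_psa_sample(params, draw_seeds[i]),
                   error = function(e) stop("PSA draw ", i, ": ",
                                            conditionMessage(e), call. = FALSE))
    t <- run_strategy(ps, "tavr")
    s <- run_strategy(ps, "savr")
    tc[i] <- t$total_cost; tq[i] <- t$total_qaly
    sc[i] <- s$total_cost; sq[i] <- s$total_qaly
  }
  structure(list(
    n_draws = n_draws, seed = as.integer(seed),
    draws = data.frame(draw = seq_len(n_draws), tavr_cost = tc,
                       tavr_qaly = tq, savr_cost = sc, savr_qaly = sq,
                       delta_cost = tc - sc, delta_qaly = tq - sq)),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d): mean dCost %.0f USD, mean dQALY %.4f\n",
              x$n_draws, x$seed, mean(x$draws$delta_cost),
              mean(x$draws$delta_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of PSA draws with positive
#' net monetary benefit (`wtp * dQALY - dcost > 0`).
#'
#' @param psa a `psa_result`.
#' @param wtp_grid willingness-to-pay grid, USD/QALY.
#' @return A data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 250000, by = 5000)) {
  stopifnot(length(wtp_grid) >= 1)
  dq <- psa$draws$delta_qaly
  dc <- psa$draws$delta_cost
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid,
                                  function(w) mean(w * dq - dc > 0), 0))
}

#' Device-price scenario analysis
#'
#' Reruns the TAVR arm at each device price through the calibrated
#' pass-through override, against the unchanged SAVR base case, and tabulates
#' the comparison in the published layout.
#'
#' @param params a `cea_params` object.
#' @param device_prices TAVR device prices in USD; the defaults are the
#'   published scenarios (domestic device, Canadian price, and the two
#'   threshold prices).
#' @return A data.frame with one SAVR reference row and one row per scenario:
#'   `scenario`, `arm`, `device_cost`, `summary_cost`, `summary_qaly`,
#'   `incremental_cost`, `incremental_qaly`, `icer`.
#' @export
run_scenarios <- function(params,
                          device_prices = c(33846, 17268, 26794, 29766)) {
  stopifnot(all(device_prices > 0))
  base <- run_base_case(params)
  p0 <- uqm(params$costs$procedure$tavr$device)
  row <- function(scenario, arm, device, res, cmp) {
    data.frame(scenario = scenario, arm = arm, device_cost = device,
               summary_cost = res$total_cost, summary_qaly = res$total_qaly,
               incremental_cost = if (is.null(cmp)) NA_real_ else cmp$delta_cost,
               incremental_qaly = if (is.null(cmp)) NA_real_ else cmp$delta_qaly,
               icer = if (is.null(cmp)) NA_real_ else cmp$icer)
  }
  out <- rbind(
    row("base_case", "SAVR", uqm(params$costs$procedure$savr$device),
        base$savr, NULL),
    row("base_case", "TAVR", p0, base$tavr, base$comparison))
  for (i in seq_along(device_prices)) {
    p <- device_prices[i]
    tavr <- run_strategy(params, "tavr", device_override = p)
    cmp <- compare_strategies(tavr, base$savr, params$wtp)
    out <- rbind(out, row(sprintf("scenario_%d", i), "TAVR", p, tavr, cmp))
  }
  rownames(out) <- NULL
  out
}
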