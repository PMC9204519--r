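# Flat registry of every uncertain quantity: stable ids, nested paths, units.
# Drives the CSV audit export, one-way sensitivity and the PSA draw loop.
uq_registry <- function(params) {
  rows <- list()
  add <- function(id, path, arm, units)
    rows[[length(rows) + 1L]] <<- list(id = id, path = path, arm = arm,
                                       units = units)
  for (arm in c("tavr", "savr")) {
    for (nm in names(params$incidences[[arm]]))
      add(paste("incidence", arm, nm, sep = "_"),
          c("incidences", arm, nm), arm, "probability")
    for (nm in names(params$utilities$no_event[[arm]]))
      add(paste("utility_no_event", arm, nm, sep = "_"),
          c("utilities", "no_event", arm, nm), arm, "utility")
    for (nm in names(params$costs$procedure[[arm]]))
      add(paste("cost_procedure", arm, nm, sep = "_"),
          c("costs", "procedure", arm, nm), arm, "usd")
  }
  add("utility_disabling_stroke", c("utilities", "disabling_stroke"), "both",
      "utility")
  for (nm in names(params$utilities$disutility))
    add(paste0("disutility_", nm), c("utilities", "disutility", nm), "both",
        "utility")
  for (nm in names(params$costs$event))
    add(paste0("cost_event_", nm), c("costs", "event", nm), "both", "usd")
  for (nm in names(params$costs$annual))
    add(paste0("cost_annual_", nm), c("costs", "annual", nm), "both",
        "usd_per_year")
  rows
}

#' Flat audit table of all uncertain quantities
#'
#' One row per parameter with its id, arm, mean, sd, range, family, PSA
#' sampling flag and units; the same layout `write_params()` emits as CSV.
#'
#' @param params a `cea_params` object.
#' @return A data.frame.
#' @export
params_to_table <- function(params) {
  reg <- uq_registry(params)
  do.call(rbind, lapply(reg, function(r) {
    q <- params[[r$path]]
    data.frame(parameter_id = r$id, arm = r$arm, mean = q$mean, sd = q$sd,
               low = q$low, high = q$high, family = q$family,
               sampled = q$sample, units = r$units,
               stringsAsFactors = FALSE)
  }))
}

# Look up a registry entry by id (used by one-way sensitivity).
uq_lookup <- function(params, id) {
  reg <- uq_registry(params)
  hit <- Filter(function(r) r$id == id, reg)
  if (!length(hit)) stop("unknown parameter id: ", id)
  hit[[1L]]
}
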