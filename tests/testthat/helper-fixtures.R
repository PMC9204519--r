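# Shared builders for degenerate and toy parameter sets.

# All event probabilities zero: immortal cohort stays in no_event.
immortal_params <- function(u = 0.74, discount = 0.037) {
  p <- default_params()
  for (arm in c("tavr", "savr")) {
    for (nm in names(p$incidences[[arm]])) {
      q <- p$incidences[[arm]][[nm]]
      q$mean <- 0; q$low <- 0; q$high <- 0
      p$incidences[[arm]][[nm]] <- q
    }
    for (nm in names(p$transitions[[arm]])) p$transitions[[arm]][[nm]][] <- 0
    for (nm in names(p$utilities$no_event[[arm]])) {
      q <- p$utilities$no_event[[arm]][[nm]]; q$mean <- u
      p$utilities$no_event[[arm]][[nm]] <- q
    }
  }
  p$non_cv_mortality_monthly <- 0
  p$af_submodel[] <- 0
  p$af_to_stroke_check <- 0
  p$annual_discount_rate <- discount
  p
}

set_mean <- function(params, path, value) {
  q <- params[[path]]
  if (is_uq <- inherits(q, "uq")) q$mean <- value else q <- value
  params[[path]] <- q
  params
}

# Several reproduction blocks are documented as expected-red; keep the
# progress reporter from truncating the run on their account.
options(testthat.progress.max_fails = 100L)
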