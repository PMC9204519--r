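test_that("built-in fixture carries the published cells and is valid", {
  p <- default_params()
  expect_length(validate_params(p), 0)

  expect_equal(p$incidences$tavr$af$mean, 0.091)
  expect_equal(p$incidences$tavr$death$mean, 0.039)
  expect_equal(p$incidences$savr$death$mean, 0.041)
  expect_equal(p$incidences$savr$bleeding$mean, 0.434)
  expect_equal(p$transitions$savr$cv_mortality[["band_13_24"]], 0.0029)
  expect_equal(p$transitions$tavr$cv_mortality[["band_25_60"]], 0.0067)
  expect_equal(p$transitions$tavr$af[["band_2_12"]], 0.001)
  expect_equal(p$non_cv_mortality_monthly, 0.0026)
  expect_equal(unname(p$af_submodel), c(0.0011, 0.0005, 0.0024))
  expect_equal(p$utilities$no_event$tavr$m_lt7$mean, 0.74)
  expect_equal(p$utilities$no_event$savr$m_lt7$mean, 0.68)
  expect_equal(p$utilities$disabling_stroke$mean, 0.39)
  expect_equal(p$utilities$disutility$bleeding$mean, -0.447)
  expect_equal(p$costs$procedure$tavr$device$mean, 45526)
  expect_equal(p$costs$procedure$tavr$device$sd, 11511)
  expect_equal(p$costs$procedure$savr$medicine$mean, 8182)
  expect_equal(p$costs$event$af$mean, 16192)
  expect_equal(p$costs$event$stroke_death$mean, 2151)
  expect_equal(p$costs$annual$af$mean, 1891)
  expect_equal(p$annual_discount_rate, 0.037)
  expect_equal(p$wtp, 37500)
  expect_equal(p$horizon_months, 60L)

  # published AF-to-any-stroke row is the sum of its split
  expect_equal(p$af_to_stroke_check,
               sum(p$af_submodel[c("to_disabling_stroke",
                                   "to_non_disabling_stroke")]))

  tab <- params_to_table(p)
  expect_equal(nrow(tab), 2 * (9 + 3 + 4) + 1 + 6 + 9 + 3)
  expect_false(any(duplicated(tab$parameter_id)))
})

test_that("single-field perturbations are each caught by validate_params", {
  p <- default_params()
  cases <- list(
    list(c("incidences", "tavr", "af"), 1.2, "incidence_tavr_af"),
    list(c("incidences", "savr", "death"), -0.01, "incidence_savr_death"),
    list(c("costs", "event", "ppm"), -5, "cost_event_ppm"),
    list(c("utilities", "disutility", "af"), 0.5, "disutility_af"),
    list(c("utilities", "disabling_stroke"), 1.4, "utility_disabling_stroke"))
  for (cs in cases) {
    bad <- set_mean(p, cs[[1]], cs[[2]])
    v <- validate_params(bad)
    expect_gt(length(v), 0)
    expect_true(any(grepl(cs[[3]], v, fixed = TRUE)),
                info = paste("violation should name", cs[[3]]))
  }

  bad <- p
  bad$af_submodel[] <- c(0.5, 0.4, 0.2)
  expect_match(paste(validate_params(bad), collapse = ";"), "af_submodel")

  bad <- p
  q <- bad$incidences$tavr$af
  q$sd <- 0.9  # sd^2 >= mean(1-mean)
  bad$incidences$tavr$af <- q
  expect_match(validate_params(bad), "sd\\^2")

  bad <- p
  q <- bad$costs$procedure$tavr$device
  q$low <- 5e4  # low above mean
  bad$costs$procedure$tavr$device <- q
  expect_match(validate_params(bad), "low")

  bad <- p
  bad$horizon_months <- 59L
  expect_match(validate_params(bad), "horizon")

  # incidences that leave no non-negative no-event remainder
  bad <- set_mean(p, c("incidences", "savr", "af"), 0.95)
  expect_match(paste(validate_params(bad), collapse = ";"),
               "state-determining")
})

test_that("json and yaml round-trips are lossless; csv export is flat", {
  for (seed in c(11L, 12L)) {
    p <- if (seed == 11L) default_params() else random_valid_params(seed)
    for (fmt in c("json", "yaml")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_params(p, f)
      p2 <- read_params(f)
      expect_equal(p2, p, tolerance = 1e-12)
    }
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_params(default_params(), f)
  tab <- utils::read.csv(f)
  expect_setequal(names(tab), c("parameter_id", "arm", "mean", "sd", "low",
                                "high", "family", "sampled", "units"))
  expect_equal(tab$mean[tab$parameter_id == "cost_procedure_tavr_device"],
               45526)
})

test_that("strict schema rejects missing and unknown fields", {
  p <- default_params()
  f <- withr::local_tempfile(fileext = ".json")
  write_params(p, f)
  plain <- jsonlite::read_json(f)

  broken <- plain
  broken$annual_discount_rate <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_params(f2), "missing required key.*annual_discount_rate")

  broken <- plain
  broken$typo_field <- 1
  jsonlite::write_json(broken, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_params(f2), "unknown key.*typo_field")

  broken <- plain
  broken$costs$event$af$surprise <- 3
  jsonlite::write_json(broken, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_params(f2), "unknown key.*surprise")

  expect_error(read_params(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("annual-to-monthly discount conversion matches its closed form", {
  expect_identical(annual_to_monthly_discount(0), 0)
  m <- annual_to_monthly_discount(0.037)
  expect_equal(m, 0.0030323, tolerance = 1e-7 / 0.003)
  expect_equal((1 + m)^12 - 1, 0.037, tolerance = 1e-12)
  expect_error(annual_to_monthly_discount(1), "\\[0, 1\\)")
  expect_error(annual_to_monthly_discount(-0.1), "\\[0, 1\\)")
})
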