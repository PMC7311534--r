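test_that("hematocrit correction scales blood to plasma concentration", {
  expect_equal(blood_to_plasma(c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(blood_to_plasma(0.6, 0.4), 1.0)
  # linearity: a doubled curve stays doubled
  x <- c(0.1, 0.5, 2)
  expect_equal(blood_to_plasma(2 * x, 0.5), 2 * blood_to_plasma(x, 0.5))
  expect_error(blood_to_plasma(1, 1), class = "dcedict_invalid_inputs")
  expect_error(blood_to_plasma(1, 1.2), class = "dcedict_invalid_inputs")
})

test_that("synthetic input functions have the expected vascular morphology", {
  inp <- fx_inputs()
  expect_true(all(inp$aif >= 0) && all(inp$pvif >= 0))
  # causal: zero before the bolus arrival
  expect_true(all(inp$aif[inp$time_s < 15] == 0))
  expect_true(all(inp$pvif[inp$time_s < 15] == 0))
  # portal curve peaks later and lower than the arterial first pass
  expect_gt(inp$time_s[which.max(inp$pvif)], inp$time_s[which.max(inp$aif)])
  expect_lt(max(inp$pvif), max(inp$aif))
  # smoothness: bounded frame-to-frame change relative to the peak
  expect_lt(max(abs(diff(inp$aif))) / max(inp$aif), 0.5)

  # determinism and degenerate amplitude
  again <- synthesize_inputs(default_time_grid())
  expect_identical(inp$aif, again$aif)
  expect_identical(inp$pvif, again$pvif)
  silent <- synthesize_inputs(default_time_grid(), peak_mM = 0)
  expect_true(all(silent$aif == 0) && all(silent$pvif == 0))
})

test_that("construction validates curves, grid and hematocrit", {
  g <- default_time_grid(10)
  expect_error(input_functions(g, rep(-1, 10), rep(0, 10)),
               class = "dcedict_invalid_inputs")
  expect_error(input_functions(g, rep(1, 10), rep(1, 10), hematocrit = 1),
               class = "dcedict_invalid_inputs")
  expect_error(input_functions(rev(g), rep(1, 10), rep(1, 10)),
               class = "dcedict_invalid_grid")
  # blood = TRUE applies the plasma correction on construction
  inp <- input_functions(g, rep(0.6, 10), rep(0.3, 10), hematocrit = 0.4)
  expect_equal(inp$aif, rep(1.0, 10))
})

test_that("moving-average smoothing behaves as a centred window", {
  x <- c(0, 0, 0, 9, 0, 0, 0)
  expect_identical(smooth_input(x, 1), x)
  expect_equal(smooth_input(rep(4, 10), 5), rep(4, 10))
  sm <- smooth_input(x, 3)
  expect_equal(sm[3:5], rep(3, 3))  # impulse h = 9 spreads to h/3 over 3 frames
  expect_error(smooth_input(x, 2), class = "dcedict_invalid_inputs")
  expect_error(smooth_input(x, 9), class = "dcedict_invalid_inputs")
})

test_that("curve CSV round trip preserves values and feeds input construction", {
  dir <- withr::local_tempdir()
  inp <- fx_inputs_small()
  fa <- file.path(dir, "aif.csv")
  fp <- file.path(dir, "pvif.csv")
  write_curve_csv(fa, inp$time_s, inp$aif)
  write_curve_csv(fp, inp$time_s, inp$pvif)
  back <- read_curve_csv(fa)
  expect_equal(back$value, inp$aif)
  inp2 <- input_functions_from_csv(fa, fp, blood = FALSE)
  expect_equal(inp2$aif, inp$aif)
  expect_equal(inp2$pvif, inp$pvif)
})
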