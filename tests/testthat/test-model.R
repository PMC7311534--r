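grid60 <- default_time_grid(60)

flat_inputs <- function(aif_level, pvif_level, grid = grid60) {
  input_functions(grid, rep(aif_level, length(grid)),
                  rep(pvif_level, length(grid)), blood = FALSE)
}

test_that("zero inputs give a zero tissue curve", {
  cv <- forward_model(perfusion_params(0.4, 0.5, 20), flat_inputs(0, 0))
  expect_true(all(cv$conc == 0))
})

test_that("constant arterial input matches the closed-form step response", {
  p <- perfusion_params(1, 0.5, 10)
  r <- params_to_rates(p)
  cv <- forward_model(p, flat_inputs(2, 0))
  expected <- r$k1a * 2 * (1 - exp(-r$k2 * grid60)) / r$k2
  expect_equal(cv$conc, expected, tolerance = 1e-10)
  # equilibrium limit: C -> DV * c for constant input at level c
  expect_equal(tail(cv$conc, 1), 0.5 * 2, tolerance = 1e-3)
})

test_that("tissue curve is linear in DV and superposes over the two inputs", {
  inp <- fx_inputs_small()
  base <- forward_model(perfusion_params(0.35, 1, 25), inp)$conc
  for (dv in c(0.2, 0.55, 0.9)) {
    cv <- forward_model(perfusion_params(0.35, dv, 25), inp)$conc
    expect_equal(cv, dv * base, tolerance = 1e-12)
  }
  # superposition: dual-input response = arterial-only + portal-only
  p <- perfusion_params(0.35, 0.6, 25)
  r <- params_to_rates(p)
  both <- forward_model(p, inp)$conc
  art_only <- input_functions(inp$time_s, inp$aif, rep(0, nrow(inp)), blood = FALSE)
  por_only <- input_functions(inp$time_s, rep(0, nrow(inp)), inp$pvif, blood = FALSE)
  sep <- forward_model(p, art_only)$conc + forward_model(p, por_only)$conc
  # each single-input run keeps its own k1; their sum is the dual response
  expect_equal(both, sep, tolerance = 1e-12)
})

test_that("exponential-convolution solver agrees with the forward-Euler oracle", {
  inp <- fx_inputs_small()
  set.seed(42)
  for (i in 1:5) {
    p <- fx_random_params()
    ours <- forward_model(p, inp)$conc
    euler <- euler_oracle(p, inp, dt = 0.001)
    expect_lt(max(abs(ours - euler)) / max(abs(ours)), 1e-4)
  }
})

test_that("input delays shift the response and uncovered grids error", {
  inp <- fx_inputs_small()
  delayed <- input_functions(inp$time_s, inp$aif, inp$pvif,
                             tau_a = 4.8, tau_p = 4.8,
                             hematocrit = attr(inp, "hematocrit"), blood = FALSE)
  p <- perfusion_params(0.3, 0.3, 30)
  cv0 <- forward_model(p, inp)$conc
  cvd <- forward_model(p, delayed)$conc
  # a 2-frame delay of both inputs delays the whole response by 2 frames
  expect_equal(cvd[-(1:2)], cv0[seq_len(length(cv0) - 2)], tolerance = 1e-9)
  # Euler oracle also honours the delays
  euler <- euler_oracle(p, delayed)
  expect_lt(max(abs(cvd - euler)) / max(abs(cvd)), 1e-4)

  # negative delay would need input values beyond the curve end
  future <- input_functions(inp$time_s, inp$aif, inp$pvif, tau_a = -10,
                            blood = FALSE)
  expect_error(forward_model(p, future), class = "dcedict_domain_error")
})
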