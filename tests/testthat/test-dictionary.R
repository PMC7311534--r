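test_that("default grid enumerates the production AF/MTT permutations", {
  g <- dictionary_grid()
  expect_length(g$af_values, 101)
  expect_length(g$mtt_values, 101)
  expect_equal(g$mtt_values[1], 1e-4)
  expect_equal(g$mtt_values[-1], as.numeric(1:100))
  expect_equal(g$dv_fixed, 1)
  expect_equal(length(g$af_values) * length(g$mtt_values), 10201)
})

test_that("dictionary columns are unit-norm normalised model curves in AF-major order", {
  d <- fx_dict_small()
  expect_equal(sqrt(colSums(d$entries^2)), rep(1, ncol(d$entries)),
               tolerance = 1e-10)
  inp <- fx_inputs_small()
  # spot-check entries against directly computed forward-model curves
  for (j in c(1, 57, 200, ncol(d$entries))) {
    cv <- forward_model(
      perfusion_params(d$index$af[j], 1, d$index$mtt[j]), inp)$conc
    expect_equal(d$entries[, j], cv / sqrt(sum(cv^2)), tolerance = 1e-12)
    expect_equal(d$norms[j], sqrt(sum(cv^2)), tolerance = 1e-12)
  }
  # lexicographic AF-major ordering with MTT varying fastest
  nM <- length(d$grid$mtt_values)
  expect_equal(d$index$af[1:nM], rep(d$grid$af_values[1], nM))
  expect_equal(d$index$mtt[1:nM], d$grid$mtt_values)
  # distinct grid points give distinct directions
  ip <- crossprod(d$entries[, 10], d$entries[, 11])
  expect_lt(as.numeric(ip), 1)
  expect_error(
    build_dictionary(input_functions(default_time_grid(10), rep(0, 10),
                                     rep(0, 10), blood = FALSE)),
    class = "dcedict_build_error")
})

test_that("matching recovers scaled entries exactly and flags degenerate probes", {
  d <- fx_dict_small()
  j <- 137
  probe <- 0.3 * d$entries[, j] * d$norms[j]   # DV = 0.3 model curve
  m <- match_dictionary(probe, d)
  expect_equal(m$column_index, j)
  expect_equal(m$af, d$index$af[j])
  expect_equal(m$mtt, d$index$mtt[j])
  expect_equal(m$inner_product, 1, tolerance = 1e-12)
  expect_equal(m$dv, 0.3, tolerance = 1e-12)

  # scale invariance of (AF, MTT); DV scales with the probe
  m2 <- match_dictionary(7.5 * probe, d)
  expect_equal(m2$column_index, m$column_index)
  expect_equal(m2$dv, 7.5 * m$dv, tolerance = 1e-12)

  # negated probe: inner product -1 at that column, argmax elsewhere
  mneg <- match_dictionary(-probe, d)
  expect_false(mneg$column_index == j)
  expect_equal(sum((-probe / sqrt(sum(probe^2))) * d$entries[, j]), -1,
               tolerance = 1e-12)

  # zero-norm probe: flagged, not an error
  mz <- match_dictionary(cbind(rep(0, nrow(d$entries)), probe), d)
  expect_false(mz$valid[1])
  expect_true(is.na(mz$af[1]))
  expect_true(mz$valid[2])
})

test_that("off-grid AF matches a neighbouring grid value", {
  inp <- fx_inputs()
  d <- fx_dict()
  probe <- forward_model(perfusion_params(0.305, 1, 30), inp)$conc
  m <- match_dictionary(probe, d)
  expect_true(m$af %in% c(0.30, 0.31))
  expect_equal(m$mtt, 30)
})

test_that("match results are independent of the probe batch size", {
  d <- fx_dict_small()
  inp <- fx_inputs_small()
  set.seed(5)
  probes <- sapply(1:23, function(i) forward_model(fx_random_params(), inp)$conc +
                     rnorm(nrow(inp), 0, 1e-4))
  m_all <- match_dictionary(probes, d)
  m_tiny <- match_dictionary(probes, d, batch_elements = 3 * ncol(d$entries))
  expect_identical(m_all$column_index, m_tiny$column_index)
  expect_identical(m_all$dv, m_tiny$dv)
})

test_that("matching equals the naive exhaustive double-loop search", {
  d <- fx_dict_small()
  inp <- fx_inputs_small()
  set.seed(31)
  for (i in 1:25) {
    probe <- forward_model(fx_random_params(), inp)$conc +
      rnorm(nrow(inp), 0, 5e-4)
    m <- match_dictionary(probe, d)
    o <- naive_match_oracle(probe, d)
    expect_equal(m$column_index, o$column)
    expect_equal(m$inner_product, o$inner_product, tolerance = 1e-12)
  }
})

test_that("norm-ratio DV estimation is exact under linear scaling", {
  d <- fx_dict_small()
  entry <- d$entries[, 50] * d$norms[50]
  expect_equal(estimate_dv(0.5 * entry, entry), 0.5)
  expect_equal(estimate_dv(entry, entry), 1.0)
  expect_warning(dv <- estimate_dv(entry, rep(0, length(entry))))
  expect_true(is.na(dv))
})

test_that("noiseless on-grid simulated curve recovers DV near truth end to end", {
  inp <- fx_inputs()
  d <- fx_dict()
  probe <- forward_model(perfusion_params(0.30, 0.30, 30), inp)$conc
  m <- match_dictionary(probe, d)
  expect_equal(m$af, 0.30)
  expect_equal(m$mtt, 30)
  expect_equal(m$dv, 0.30, tolerance = 0.005 / 0.30)
})

test_that("compression preserves matching at full rank and under energy truncation", {
  d <- fx_dict_small()
  inp <- fx_inputs_small()
  expect_error(compress_dictionary(d, rank = 0), class = "dcedict_invalid_rank")
  expect_error(compress_dictionary(d, rank = 1e6), class = "dcedict_invalid_rank")

  cd_full <- compress_dictionary(d, rank = min(dim(d$entries)))
  rec <- cd_full$left_basis %*% cd_full$projected_entries
  expect_lt(max(abs(rec - d$entries)), 1e-8)

  set.seed(8)
  probes <- sapply(1:60, function(i) forward_model(fx_random_params(), inp)$conc +
                     rnorm(nrow(inp), 0, 1e-3))
  m0 <- match_dictionary(probes, d)
  m_full <- match_dictionary(probes, cd_full)
  expect_identical(m_full$column_index, m0$column_index)
  expect_equal(m_full$dv, m0$dv, tolerance = 1e-10)

  # automatic rank by singular-value energy keeps >= 99% argmax agreement
  cd <- compress_dictionary(d)
  expect_lt(cd$rank, min(dim(d$entries)))
  noiseless <- sapply(1:100, function(i) forward_model(fx_random_params(), inp)$conc)
  agree <- mean(match_dictionary(noiseless, cd)$column_index ==
                  match_dictionary(noiseless, d)$column_index)
  expect_gte(agree, 0.99)

  # rank 1 reconstructs a rank-1 dictionary exactly
  d1 <- d
  d1$entries <- d$entries[, rep(3, 10)]
  d1$norms <- d$norms[rep(3, 10)]
  d1$index <- d$index[rep(3, 10), ]
  cd1 <- compress_dictionary(d1, rank = 1)
  expect_lt(max(abs(cd1$left_basis %*% cd1$projected_entries - d1$entries)), 1e-8)
})

test_that("dictionary round trips through its plain-text container", {
  d <- build_dictionary(fx_inputs_small(),
                        dictionary_grid(af_step = 0.25, mtt_step = 25))
  dir <- withr::local_tempdir()
  write_dictionary(d, dir)
  d2 <- read_dictionary(dir)
  expect_equal(d2$entries, d$entries, tolerance = 1e-12)
  expect_equal(d2$norms, d$norms, tolerance = 1e-12)
  expect_equal(d2$grid$af_values, d$grid$af_values)
  expect_equal(d2$grid$mtt_values, d$grid$mtt_values)
  expect_equal(d2$time_s, d$time_s)
  expect_identical(d2$inputs_hash, d$inputs_hash)
  probe <- d$entries[, 7] * d$norms[7] * 0.4
  expect_equal(match_dictionary(probe, d2)$column_index, 7L)
})
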