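# shared fixtures, built once per test run and memoised

.fx <- new.env(parent = emptyenv())

fx_memo <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small grid for unit tests: 60 frames at 2.4 s
fx_inputs_small <- function() {
  fx_memo("inputs_small", function() synthesize_inputs(default_time_grid(60)))
}

# production-style grid: 100 frames at 2.4 s
fx_inputs <- function() {
  fx_memo("inputs", function() synthesize_inputs(default_time_grid()))
}

fx_acq <- function() acquisition_params()

# coarse dictionary (21 AF x 21 MTT = 441 entries) for oracle-equivalence work
fx_dict_small <- function() {
  fx_memo("dict_small", function() {
    build_dictionary(fx_inputs_small(), dictionary_grid(af_step = 0.05, mtt_step = 5))
  })
}

# full production dictionary (101 x 101 = 10201 entries)
fx_dict <- function() {
  fx_memo("dict", function() build_dictionary(fx_inputs()))
}

# label-mask helper that keeps array dimensions (`%in%` drops them)
mask_in <- function(labels, keep) {
  array(labels %in% keep, dim(labels))
}

# random valid perfusion parameters
fx_random_params <- function() {
  perfusion_params(af = stats::runif(1), dv = stats::runif(1, 0.05, 1),
                   mtt = stats::runif(1, 1, 100))
}
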