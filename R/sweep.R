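#' Monte Carlo sweep design
#'
#' Describes one simulation sweep: starting from a base healthy-liver
#' parameter set (AF = 0.30, DV = 0.30, MTT = 30 s), one property is varied
#' over a range while the other two are held constant, and noisy realisations
#' are generated at each SNR level. Default sweep ranges cover AF 0.2-0.7,
#' DV 0.2-0.7 and MTT 11-71 s; the default SNR ladder is 10-100 dB in 10 dB
#' steps with 100 realisations per cell.
#'
#' @param property Which property to vary: `"af"`, `"dv"` or `"mtt"`.
#' @param values Values the varied property takes. Defaults: AF/DV
#'   `seq(0.2, 0.7, by = 0.01)`, MTT `11:71` (integers, on the dictionary
#'   grid).
#' @param base A [perfusion_params()] giving the held-constant values.
#' @param snr_db SNR levels in dB.
#' @param n_realizations Noisy realisations per (value, SNR) cell.
#' @return List of class `sweep_design`.
#' @export
sweep_design <- function(property = c("af", "dv", "mtt"), values = NULL,
                         base = perfusion_params(0.30, 0.30, 30),
                         snr_db = seq(10, 100, by = 10),
                         n_realizations = 100) {
  property <- match.arg(property)
  values <- values %||% switch(property,
    af = seq(0.2, 0.7, by = 0.01),
    dv = seq(0.2, 0.7, by = 0.01),
    mtt = 11:71)
  stopifnot(n_realizations >= 1, length(values) >= 1)
  structure(list(property = property, values = values, base = base,
                 snr_db = snr_db, n_realizations = as.integer(n_realizations)),
            class = "sweep_design")
}

set_property <- function(base, property, value) {
  p <- list(af = base$af, dv = base$dv, mtt = base$mtt)
  p[[property]] <- value
  perfusion_params(p$af, p$dv, p$mtt)
}

#' Run a Monte Carlo SNR sweep
#'
#' For every (varied value, SNR) cell: the noiseless tissue curve is computed
#' from the forward model, converted to SPGR signal intensity, white Gaussian
#' noise is added ([add_awgn()]), the noisy signal is converted back to
#' concentration with baseline-estimated M0, and the perfusion properties are
#' estimated by dictionary matching and/or curve fitting. The percent error
#' `|est - true| / true * 100` of each property is averaged over
#' realisations. Realisations whose signal-to-concentration conversion
#' produces any non-invertible frame are excluded and counted.
#'
#' The whole pipeline is driven by one seed, so identical seeds give
#' identical error tables.
#'
#' @param design A [sweep_design()].
#' @param inputs A [input_functions()] object.
#' @param acq An [acquisition_params()].
#' @param dictionary A prebuilt `dce_dictionary` (required for the
#'   dictionary method; built on the fly from `inputs` when `NULL` and the
#'   method is requested).
#' @param config A [fit_config()] for the fitting method.
#' @param methods Estimators to run: subset of `c("dictionary", "fit")`.
#' @param m0 Scanner scale used in signal synthesis.
#' @param seed Seed for the noise ensemble (default 1).
#' @return Tibble of class `dce_error_table`: one row per (value, SNR,
#'   method, property) with `mean_pct_error`, `sd_pct_error`, `n_used`,
#'   `n_excluded`.
#' @export
run_snr_sweep <- function(design, inputs, acq = acquisition_params(),
                          dictionary = NULL, config = fit_config(),
                          methods = c("dictionary", "fit"),
                          m0 = 1000, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("dictionary" %in% methods && is.null(dictionary)) {
    dictionary <- build_dictionary(inputs)
  }
  grid <- inputs$time_s
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  rows <- list()
  for (v in design$values) {
    truth <- set_property(design$base, design$property, v)
    truth_vec <- c(af = truth$af, dv = truth$dv, mtt = truth$mtt)
    clean_signal <- spgr_signal(forward_model(truth, inputs)$conc, acq, m0 = m0)
    for (snr in design$snr_db) {
      # draw the whole ensemble, convert, drop flagged realisations
      noisy <- replicate(design$n_realizations, add_awgn(clean_signal, snr))
      conc <- concentration_from_signal(noisy, acq, strict_baseline = FALSE)
      usable <- colSums(!is.finite(conc)) == 0
      n_excluded <- sum(!usable)
      conc_ok <- conc[, usable, drop = FALSE]
      est <- list()
      if ("dictionary" %in% methods && ncol(conc_ok) > 0) {
        mres <- match_dictionary(conc_ok, dictionary)
        est$dictionary <- cbind(af = mres$af, dv = mres$dv, mtt = mres$mtt)
      }
      if ("fit" %in% methods && ncol(conc_ok) > 0) {
        fres <- fit_curves(conc_ok, inputs, config, grid = grid)
        est$fit <- cbind(af = fres$af, dv = fres$dv, mtt = fres$mtt)
      }
      for (meth in names(est)) {
        pe <- abs(sweep(est[[meth]], 2, truth_vec, "-")) /
          rep(truth_vec, each = nrow(est[[meth]])) * 100
        for (prop in c("af", "dv", "mtt")) {
          x <- pe[, prop]
          x <- x[is.finite(x)]
          rows[[length(rows) + 1]] <- tibble::tibble(
            property = design$property, value = v, snr_db = snr,
            method = meth, estimated = prop,
            mean_pct_error = mean(x), sd_pct_error = stats::sd(x),
            n_used = length(x),
            n_excluded = n_excluded + (sum(usable) - length(x)))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dce_error_table", class(out))
  out
}

#' Heatmap of a Monte Carlo error table
#'
#' Reproduces the SNR-versus-property-value mean-percent-error heatmaps, one
#' panel per estimation method, for the swept property.
#'
#' @param object A `dce_error_table` from [run_snr_sweep()].
#' @param estimated Which property's error to display; defaults to the swept
#'   property.
#' @param ... Ignored.
#' @method autoplot dce_error_table
#' @export
autoplot.dce_error_table <- function(object, estimated = NULL, ...) {
  estimated <- estimated %||% object$property[1]
  df <- dplyr::filter(object, .data$estimated == !!estimated)
  ggplot2::ggplot(df, ggplot2::aes(factor(snr_db), factor(value),
                                   fill = log10(mean_pct_error + 1e-3))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_viridis_c(name = "log10 mean % error") +
    ggplot2::labs(x = "SNR (dB)", y = sprintf("true %s", toupper(estimated))) +
    ggplot2::theme_minimal()
}

#' Dictionary step-size resolution study
#'
#' Builds a sequence of dictionaries varying one property's step size while
#' holding the other at its default, matches an ideal noiseless tissue curve
#' with known properties against each, and records the estimate and its
#' deviation from truth. Default step lists are AF
#' `{0.01, 0.02, 0.04, 0.1, 0.2, 0.5}` and MTT `{1, 2, 4, 11, 25, 50}` s;
#' the default probe has AF 0.3 and MTT 15 s (DV 0.3).
#'
#' @param inputs A [input_functions()] object.
#' @param af_steps,mtt_steps Step-size lists.
#' @param truth True parameters of the probe curve.
#' @return Tibble of class `dce_stepsize`: `property`, `step`, `estimate`,
#'   `deviation` (absolute), `inner_product`.
#' @export
run_stepsize_study <- function(inputs,
                               af_steps = c(0.01, 0.02, 0.04, 0.1, 0.2, 0.5),
                               mtt_steps = c(1, 2, 4, 11, 25, 50),
                               truth = perfusion_params(0.3, 0.3, 15)) {
  stopifnot(length(af_steps) >= 1, length(mtt_steps) >= 1)
  probe <- forward_model(truth, inputs)$conc
  one <- function(prop, step) {
    g <- if (prop == "af") dictionary_grid(af_step = step)
         else dictionary_grid(mtt_step = step)
    d <- build_dictionary(inputs, g)
    m <- match_dictionary(probe, d)
    est <- if (prop == "af") m$af else m$mtt
    true_val <- if (prop == "af") truth$af else truth$mtt
    tibble::tibble(property = prop, step = step, estimate = est,
                   deviation = abs(est - true_val),
                   inner_product = m$inner_product)
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(af_steps, ~one("af", .x)),
    purrr::map_dfr(mtt_steps, ~one("mtt", .x)))
  class(out) <- c("dce_stepsize", class(out))
  out
}

#' @rdname run_stepsize_study
#' @param object A `dce_stepsize` table.
#' @param ... Ignored.
#' @method autoplot dce_stepsize
#' @export
autoplot.dce_stepsize <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(step, estimate)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dictionary step size", y = "estimate") +
    ggplot2::theme_minimal()
}
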