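#' Vascular input functions for the dual-input liver model
#'
#' Bundles the arterial (AIF) and portal-venous (PVIF) contrast concentration
#' curves on a shared time grid, together with their bolus delays and the
#' hematocrit used to convert whole-blood to plasma concentration. The stored
#' curves are **plasma** concentrations: when `blood = TRUE` (the default) the
#' supplied curves are treated as whole-blood concentrations and divided by
#' `1 - hematocrit` on construction.
#'
#' @param time_s Strictly increasing time stamps in seconds (length >= 2,
#'   first >= 0).
#' @param aif Arterial input function, mM per frame (nonnegative).
#' @param pvif Portal-venous input function, mM per frame (nonnegative).
#' @param tau_a,tau_p Delay in seconds applied to the arterial / portal curve
#'   when the forward model evaluates them (curves are defined as zero before
#'   time zero).
#' @param hematocrit Hematocrit fraction in \[0, 1); default 0.4.
#' @param blood If `TRUE`, `aif`/`pvif` are whole-blood concentrations and are
#'   scaled by `1/(1 - hematocrit)`; if `FALSE` they are stored as given.
#'
#' @return A tibble of class `dce_inputs` with columns `time_s`, `aif`, `pvif`
#'   and attributes `tau_a`, `tau_p`, `hematocrit`.
#' @export
input_functions <- function(time_s, aif, pvif, tau_a = 0, tau_p = 0,
                            hematocrit = 0.4, blood = TRUE) {
  check_time_grid(time_s)
  stopifnot(length(aif) == length(time_s), length(pvif) == length(time_s))
  if (any(!is.finite(aif)) || any(!is.finite(pvif))) {
    abort("Input curves must be finite.", class = "dcedict_invalid_inputs")
  }
  if (any(aif < 0) || any(pvif < 0)) {
    abort("Input curves must be nonnegative.", class = "dcedict_invalid_inputs")
  }
  if (isTRUE(blood)) {
    aif <- blood_to_plasma(aif, hematocrit)
    pvif <- blood_to_plasma(pvif, hematocrit)
  } else {
    check_hematocrit(hematocrit)
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        aif = as.numeric(aif), pvif = as.numeric(pvif))
  attr(out, "tau_a") <- tau_a
  attr(out, "tau_p") <- tau_p
  attr(out, "hematocrit") <- hematocrit
  class(out) <- c("dce_inputs", class(out))
  out
}

check_time_grid <- function(time_s) {
  if (length(time_s) < 2 || any(!is.finite(time_s)) ||
      any(diff(time_s) <= 0) || time_s[1] < 0) {
    abort("Time grid must be >= 2 strictly increasing nonnegative seconds.",
          class = "dcedict_invalid_grid")
  }
  invisible(time_s)
}

check_hematocrit <- function(hematocrit) {
  if (!is.numeric(hematocrit) || length(hematocrit) != 1 ||
      !is.finite(hematocrit) || hematocrit < 0 || hematocrit >= 1) {
    abort("`hematocrit` must lie in [0, 1).", class = "dcedict_invalid_inputs")
  }
  invisible(hematocrit)
}

#' Whole-blood to plasma concentration correction
#'
#' Contrast agent is confined to plasma, so a concentration measured in whole
#' blood understates the plasma concentration by the plasma volume fraction:
#' the curve is divided by `1 - hematocrit`.
#'
#' @param conc Numeric concentration curve (mM).
#' @param hematocrit Hematocrit fraction in \[0, 1).
#' @return The plasma-concentration curve.
#' @export
#' @examples
#' blood_to_plasma(0.6, hematocrit = 0.4)  # 1.0
blood_to_plasma <- function(conc, hematocrit = 0.4) {
  check_hematocrit(hematocrit)
  conc / (1 - hematocrit)
}

#' Default acquisition time grid
#'
#' Uniform sampling emulating a free-breathing 3D dynamic liver acquisition:
#' `n_frames` volumes at `dt_s` second intervals starting at zero.
#'
#' @param n_frames Number of dynamic frames (default 100).
#' @param dt_s Frame spacing in seconds (default 2.4).
#' @return Numeric vector of frame times in seconds.
#' @export
default_time_grid <- function(n_frames = 100, dt_s = 2.4) {
  stopifnot(n_frames >= 2, dt_s > 0)
  seq(0, by = dt_s, length.out = n_frames)
}

# gamma-variate bolus: peak amplitude `amp` at time t0 + tp, shape alpha
gamma_variate <- function(t, t0, amp, tp, alpha) {
  x <- (t - t0) / tp
  y <- ifelse(x > 0, amp * x^alpha * exp(alpha * (1 - x)), 0)
  y[!is.finite(y)] <- 0
  y
}

#' Synthesize arterial and portal-venous input functions
#'
#' Generates a smooth population-style AIF/PVIF pair standing in for
#' subject-measured, temporally smoothed input functions: the AIF is a
#' gamma-variate first-pass peak plus a dispersed recirculation shoulder and a
#' slow washout tail; the PVIF is the AIF passed through an exponential
#' dispersion kernel (splanchnic transit) and delayed, giving the
#' characteristic broader, later, lower portal curve. Curves are causal (zero
#' before `bolus_arrival_s`) and deterministic; a nonzero `jitter_sd` adds
#' seeded lognormal jitter to amplitude and timing for ensemble studies.
#'
#' @param grid Time grid in seconds (see [default_time_grid()]).
#' @param bolus_arrival_s Arterial bolus arrival time in seconds; must lie
#'   inside the grid. Default 15 s (after the pre-contrast baseline frames).
#' @param peak_mM Whole-blood AIF first-pass peak amplitude in mM.
#' @param peak_width_s Time-to-peak of the first pass (seconds).
#' @param sharpness Gamma-variate shape parameter (larger = sharper peak).
#' @param recirc_frac,recirc_delay_s Amplitude fraction and delay of the
#'   recirculation shoulder.
#' @param washout_frac Amplitude of the slow equilibrium tail, as a fraction
#'   of the peak.
#' @param portal_delay_s Additional delay of the portal curve (seconds).
#' @param portal_dispersion_s Mean of the exponential dispersion kernel
#'   applied to obtain the PVIF (seconds).
#' @param hematocrit,tau_a,tau_p Passed to [input_functions()].
#' @param smooth_window Odd moving-average window applied to both curves
#'   (frames); 1 disables smoothing.
#' @param jitter_sd Lognormal sd of the optional amplitude/timing jitter
#'   (default 0 = fully deterministic).
#' @param seed Optional seed used only when `jitter_sd > 0`.
#'
#' @return A `dce_inputs` tibble (plasma concentrations).
#' @export
#' @examples
#' inp <- synthesize_inputs(default_time_grid())
#' max(inp$aif) > max(inp$pvif)  # arterial first pass is the sharper peak
synthesize_inputs <- function(grid = default_time_grid(),
                              bolus_arrival_s = 15,
                              peak_mM = 5,
                              peak_width_s = 8,
                              sharpness = 3,
                              recirc_frac = 0.25,
                              recirc_delay_s = 25,
                              washout_frac = 0.12,
                              portal_delay_s = 6,
                              portal_dispersion_s = 14,
                              hematocrit = 0.4,
                              tau_a = 0, tau_p = 0,
                              smooth_window = 3,
                              jitter_sd = 0, seed = NULL) {
  check_time_grid(grid)
  if (bolus_arrival_s < grid[1] || bolus_arrival_s > grid[length(grid)]) {
    abort("`bolus_arrival_s` must lie inside the time grid.",
          class = "dcedict_invalid_inputs")
  }
  if (jitter_sd > 0) {
    if (!is.null(seed)) {
      old <- get_rng_state()
      on.exit(restore_rng_state(old), add = TRUE)
      set.seed(seed)
    }
    peak_mM <- peak_mM * exp(rnorm(1, 0, jitter_sd))
    peak_width_s <- peak_width_s * exp(rnorm(1, 0, jitter_sd))
  }

  # work on a fine internal grid so dispersion/smoothing are grid-independent
  dt <- 0.25
  tf <- seq(grid[1], grid[length(grid)], by = dt)
  first_pass <- gamma_variate(tf, bolus_arrival_s, peak_mM, peak_width_s, sharpness)
  recirc <- gamma_variate(tf, bolus_arrival_s + recirc_delay_s,
                          recirc_frac * peak_mM, 2.5 * peak_width_s, 2)
  washout <- washout_frac * peak_mM *
    ifelse(tf > bolus_arrival_s,
           1 - exp(-(tf - bolus_arrival_s) / (2 * peak_width_s)), 0) *
    exp(-(pmax(tf - bolus_arrival_s, 0)) / 600)
  aif_f <- first_pass + recirc + washout

  # portal curve: exponential transit-time dispersion + extra delay
  kern <- exp(-(tf - tf[1]) / portal_dispersion_s)
  kern <- kern / sum(kern)
  pvif_f <- stats::convolve(aif_f, rev(kern), type = "open")[seq_along(tf)]
  n_shift <- round(portal_delay_s / dt)
  pvif_f <- c(rep(0, n_shift), head(pvif_f, length(pvif_f) - n_shift))

  aif <- approx(tf, aif_f, xout = grid, rule = 2)$y
  pvif <- approx(tf, pvif_f, xout = grid, rule = 2)$y
  if (smooth_window > 1) {
    aif <- smooth_input(aif, smooth_window)
    pvif <- smooth_input(pvif, smooth_window)
  }
  # smoothing must not leak signal before the bolus arrival (causality)
  aif <- pmax(aif, 0) * (grid >= bolus_arrival_s)
  pvif <- pmax(pvif, 0) * (grid >= bolus_arrival_s)
  input_functions(grid, aif, pvif, tau_a = tau_a, tau_p = tau_p,
                  hematocrit = hematocrit, blood = TRUE)
}

#' Moving-average temporal smoothing
#'
#' Centred moving average with an odd window, the smoothing applied to
#' measured input functions before modelling. Edges use the available
#' (shrinking) window so the curve length is preserved.
#'
#' @param curve Numeric vector.
#' @param window Odd integer window length in frames; 1 is the identity.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_input <- function(curve, window = 3) {
  stopifnot(is.numeric(curve))
  if (window < 1 || window %% 2 != 1) {
    abort("`window` must be odd and >= 1.", class = "dcedict_invalid_inputs")
  }
  if (window > length(curve)) {
    abort("`window` exceeds curve length.", class = "dcedict_invalid_inputs")
  }
  if (window == 1) return(curve)
  half <- (window - 1) / 2
  n <- length(curve)
  vapply(seq_len(n), function(i) {
    j <- max(1, i - half):min(n, i + half)
    mean(curve[j])
  }, numeric(1))
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's stream
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Read / write a single concentration curve as CSV
#'
#' Plain-text interchange format: columns `time_s`, `value`, one file per
#' curve.
#'
#' @param path File path.
#' @return `read_curve_csv()` returns a tibble with columns `time_s`, `value`.
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort("Curve CSV must have columns `time_s` and `value`.",
          class = "dcedict_io_error")
  }
  tibble::as_tibble(df[c("time_s", "value")])
}

#' @param time_s,value Curve to write.
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(path, time_s, value) {
  utils::write.csv(data.frame(time_s = time_s, value = value), path,
                   row.names = FALSE)
  invisible(path)
}

#' Assemble input functions from per-curve CSV files
#'
#' @param aif_path,pvif_path Paths to `time_s,value` CSV files sharing a time
#'   grid.
#' @inheritParams input_functions
#' @return A `dce_inputs` tibble.
#' @export
input_functions_from_csv <- function(aif_path, pvif_path, tau_a = 0, tau_p = 0,
                                     hematocrit = 0.4, blood = TRUE) {
  a <- read_curve_csv(aif_path)
  p <- read_curve_csv(pvif_path)
  if (!isTRUE(all.equal(a$time_s, p$time_s))) {
    abort("AIF and PVIF files must share the same time grid.",
          class = "dcedict_io_error")
  }
  input_functions(a$time_s, a$value, p$value, tau_a = tau_a, tau_p = tau_p,
                  hematocrit = hematocrit, blood = blood)
}

#' @export
print.dce_inputs <- function(x, ...) {
  cat(sprintf(
    "<dce_inputs> %d frames, %.1f-%.1f s | tau_a = %g s, tau_p = %g s, hct = %g\n",
    nrow(x), x$time_s[1], x$time_s[nrow(x)],
    attr(x, "tau_a"), attr(x, "tau_p"), attr(x, "hematocrit")))
  NextMethod()
}

#' @rdname synthesize_inputs
#' @param object A `dce_inputs` object.
#' @param ... Ignored.
#' @method autoplot dce_inputs
#' @export
autoplot.dce_inputs <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("aif", "pvif"),
                            names_to = "vessel", values_to = "conc")
  ggplot2::ggplot(df, ggplot2::aes(time_s, conc, colour = vessel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "plasma concentration (mM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
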