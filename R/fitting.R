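#' Curve-fitting configuration
#'
#' Configuration of the bounded nonlinear least-squares baseline. Defaults
#' replicate the reference fitting setup: bounds 0-1 for AF, 0-1 for DV,
#' 0.0001-100 s for MTT, initial estimates (0.2, 0.2, 10), step tolerance
#' 1e-2, function tolerance 1e-3 and gradient (first-order optimality)
#' tolerance 1e-1. The backend is Levenberg-Marquardt with box bounds
#' ([minpack.lm::nls.lm]); the tolerances map onto its `ptol` (relative
#' parameter step), `ftol` (relative cost reduction) and `gtol` (gradient
#' orthogonality) controls, the closest semantic equivalents of the
#' trust-region step/function/optimality tolerances. The Jacobian is taken by
#' finite differences.
#'
#' @param lower,upper Bounds as `c(af, dv, mtt)` vectors.
#' @param initial Initial estimates `c(af, dv, mtt)` (must lie within bounds).
#' @param step_tol,fun_tol,grad_tol Convergence tolerances (see above).
#' @param max_iterations Iteration cap (default 400).
#' @return Named list of class `fit_config`.
#' @export
fit_config <- function(lower = c(af = 0, dv = 0, mtt = 1e-4),
                       upper = c(af = 1, dv = 1, mtt = 100),
                       initial = c(af = 0.2, dv = 0.2, mtt = 10),
                       step_tol = 1e-2, fun_tol = 1e-3, grad_tol = 1e-1,
                       max_iterations = 400) {
  stopifnot(length(lower) == 3, length(upper) == 3, length(initial) == 3)
  if (any(lower >= upper)) {
    abort("Bounds must satisfy lower < upper.", class = "dcedict_invalid_config")
  }
  if (any(initial < lower | initial > upper)) {
    abort("Initial estimates must lie within the bounds.",
          class = "dcedict_invalid_config")
  }
  structure(list(lower = setNames(as.numeric(lower), c("af", "dv", "mtt")),
                 upper = setNames(as.numeric(upper), c("af", "dv", "mtt")),
                 initial = setNames(as.numeric(initial), c("af", "dv", "mtt")),
                 step_tol = step_tol, fun_tol = fun_tol, grad_tol = grad_tol,
                 max_iterations = as.integer(max_iterations)),
            class = "fit_config")
}

#' Fit the dual-input model to a tissue curve
#'
#' Minimises the sum of squared residuals between the measured tissue
#' concentration curve and the forward model over (AF, DV, MTT) within the
#' configured bounds. Deterministic for fixed inputs and configuration.
#'
#' @param curve Tissue concentration curve: numeric vector on the inputs'
#'   grid, or a `dce_curve` tibble.
#' @param inputs A [input_functions()] object.
#' @param config A [fit_config()].
#' @param grid Time grid of the curve; defaults to the inputs' grid.
#' @return Object of class `dce_fit`: fields `params`
#'   ([perfusion_params()]), `residual_norm`, `converged`, `n_iterations`,
#'   `message`.
#' @export
#' @examples
#' inp <- synthesize_inputs(default_time_grid(60))
#' cv <- forward_model(perfusion_params(0.3, 0.3, 30), inp)
#' fit <- fit_curve(cv, inp)
#' tidy(fit)
fit_curve <- function(curve, inputs, config = fit_config(), grid = NULL) {
  if (is.data.frame(curve)) {
    grid <- grid %||% curve$time_s
    curve <- curve$conc
  }
  grid <- grid %||% inputs$time_s
  if (any(!is.finite(curve))) {
    abort("Curve contains non-finite values.", class = "dcedict_invalid_inputs")
  }
  ca <- shift_input(inputs$time_s, inputs$aif, grid, attr(inputs, "tau_a") %||% 0)
  cp <- shift_input(inputs$time_s, inputs$pvif, grid, attr(inputs, "tau_p") %||% 0)
  model_at <- function(par) {
    k2 <- 1 / par[3]
    ktot <- par[2] * k2
    expconv(grid, par[1] * ktot * ca + (1 - par[1]) * ktot * cp, k2)
  }
  resid_fn <- function(par) curve - model_at(par)
  res <- minpack.lm::nls.lm(
    par = config$initial, lower = config$lower, upper = config$upper,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ptol = config$step_tol, ftol = config$fun_tol, gtol = config$grad_tol,
      maxiter = config$max_iterations))
  par <- unname(as.numeric(res$par))
  structure(list(
    params = perfusion_params(par[1], par[2], par[3]),
    residual_norm = sqrt(res$deviance),
    converged = res$info %in% 1:4,
    n_iterations = res$niter,
    message = res$message
  ), class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf(
    "<dce_fit> AF = %.4g, DV = %.4g, MTT = %.4g s | ||r|| = %.4g, %s in %d iter\n",
    x$params$af, x$params$dv, x$params$mtt, x$residual_norm,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' @rdname fit_curve
#' @param x A `dce_fit` object.
#' @param ... Ignored.
#' @method tidy dce_fit
#' @export
tidy.dce_fit <- function(x, ...) {
  tibble::tibble(term = c("af", "dv", "mtt"),
                 estimate = c(x$params$af, x$params$dv, x$params$mtt))
}

#' @rdname fit_curve
#' @method glance dce_fit
#' @export
glance.dce_fit <- function(x, ...) {
  tibble::tibble(residual_norm = x$residual_norm, converged = x$converged,
                 n_iterations = x$n_iterations)
}

#' Fit a batch of tissue curves
#'
#' @param curves As in [match_dictionary()]: matrix (one curve per column),
#'   vector, or long tibble with `id`, `time_s`, `conc`.
#' @inheritParams fit_curve
#' @return Tibble with one row per curve: `id`, `af`, `dv`, `mtt`,
#'   `residual_norm`, `converged`, `n_iterations`.
#' @export
fit_curves <- function(curves, inputs, config = fit_config(), grid = NULL) {
  grid <- grid %||% inputs$time_s
  X <- as_curve_matrix(curves, length(grid))
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  purrr::map2_dfr(seq_len(ncol(X)), ids, function(j, id) {
    f <- fit_curve(X[, j], inputs, config, grid = grid)
    tibble::tibble(id = id, af = f$params$af, dv = f$params$dv,
                   mtt = f$params$mtt, residual_norm = f$residual_norm,
                   converged = f$converged, n_iterations = f$n_iterations)
  })
}
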