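#' Perfusion parameter triplet
#'
#' Constructs the parameter set of the dual-input single-compartment liver
#' model in its physiological reparameterisation: arterial fraction (`af`),
#' distribution volume (`dv`) and mean transit time (`mtt`).
#'
#' @param af Arterial fraction, dimensionless in \[0, 1\]: the fraction of the
#'   hepatic blood supply delivered by the hepatic artery (the remainder
#'   arrives through the portal vein).
#' @param dv Distribution volume, dimensionless in \[0, 1\]: the fraction of
#'   tissue volume accessible to the extracellular contrast agent.
#' @param mtt Mean transit time in seconds (> 0): mean time for contrast
#'   particles to traverse the tissue compartment.
#'
#' @return An object of class `perfusion_params` (named list).
#' @seealso [params_to_rates()], [rates_to_params()]
#' @export
#' @examples
#' perfusion_params(af = 0.30, dv = 0.30, mtt = 30)
perfusion_params <- function(af, dv, mtt) {
  stopifnot(is.numeric(af), is.numeric(dv), is.numeric(mtt),
            length(af) == 1, length(dv) == 1, length(mtt) == 1)
  if (!is.finite(af) || af < 0 || af > 1) {
    abort("`af` must lie in [0, 1].", class = "dcedict_invalid_params")
  }
  if (!is.finite(dv) || dv < 0) {
    abort("`dv` must be a nonnegative finite fraction.",
          class = "dcedict_invalid_params")
  }
  if (!is.finite(mtt) || mtt <= 0) {
    abort("`mtt` must be > 0 seconds.", class = "dcedict_invalid_params")
  }
  structure(list(af = af, dv = dv, mtt = mtt), class = "perfusion_params")
}

#' @export
print.perfusion_params <- function(x, ...) {
  cat(sprintf("<perfusion_params> AF = %.4g, DV = %.4g, MTT = %.4g s\n",
              x$af, x$dv, x$mtt))
  invisible(x)
}

#' Convert perfusion properties to compartmental rate constants
#'
#' The model's native rate constants are the arterial and portal influx rates
#' `k1a`, `k1p` (1/s) and the efflux rate `k2` (1/s). They relate to the
#' physiological triplet by
#' `AF = k1a / (k1a + k1p)`, `DV = (k1a + k1p) / k2`, `MTT = 1 / k2`.
#'
#' @param p A [perfusion_params()] object.
#' @return A named list with fields `k1a`, `k1p`, `k2` (class `rate_constants`).
#' @export
#' @examples
#' params_to_rates(perfusion_params(0.30, 0.30, 30))
params_to_rates <- function(p) {
  if (!inherits(p, "perfusion_params")) p <- do.call(perfusion_params, as.list(p)[c("af", "dv", "mtt")])
  k2 <- 1 / p$mtt
  ktot <- p$dv * k2
  structure(list(k1a = p$af * ktot, k1p = (1 - p$af) * ktot, k2 = k2),
            class = "rate_constants")
}

#' Convert rate constants back to perfusion properties
#'
#' Inverse of [params_to_rates()]. Requires `k2 > 0` and `k1a + k1p > 0`
#' (otherwise the arterial fraction is undefined).
#'
#' @param r A `rate_constants` object or named list with `k1a`, `k1p`, `k2`.
#' @return A [perfusion_params()] object.
#' @export
rates_to_params <- function(r) {
  k1a <- r$k1a; k1p <- r$k1p; k2 <- r$k2
  stopifnot(is.numeric(k1a), is.numeric(k1p), is.numeric(k2))
  if (k1a < 0 || k1p < 0) {
    abort("Influx rates must be nonnegative.", class = "dcedict_invalid_params")
  }
  if (!is.finite(k2) || k2 <= 0) {
    abort("`k2` must be > 0.", class = "dcedict_invalid_params")
  }
  ktot <- k1a + k1p
  if (ktot <= 0) {
    abort("k1a + k1p = 0: arterial fraction is undefined.",
          class = "dcedict_undefined_af")
  }
  perfusion_params(af = k1a / ktot, dv = ktot / k2, mtt = 1 / k2)
}
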