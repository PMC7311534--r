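#' Voxel-wise perfusion parameter mapping
#'
#' Applies an estimator voxel-by-voxel to a 4D dynamic signal volume: each
#' masked voxel's signal curve is converted to contrast concentration
#' ([concentration_from_signal()]) and its perfusion properties estimated by
#' dictionary matching or curve fitting. Voxels whose conversion produces a
#' non-invertible frame, or whose concentration curve has zero norm (no
#' enhancement), are flagged invalid and carry `NA` in the maps.
#'
#' @param vol 4D numeric array `(x, y, z, t)` of signal intensities (an
#'   `RNifti` image is accepted; its geometry attributes are carried onto the
#'   output maps).
#' @param mask 3D logical or integer array; voxels with `TRUE`/nonzero labels
#'   are analysed.
#' @param inputs A [input_functions()] on the volume's frame times.
#' @param acq An [acquisition_params()]; choose `t10_ms` for the tissue class
#'   being mapped (healthy liver 800 ms, cirrhotic 950 ms, blood 1800 ms).
#' @param method `"dictionary"` or `"fit"`.
#' @param dictionary Optional prebuilt `dce_dictionary` (built from `inputs`
#'   when needed).
#' @param config A [fit_config()] for `method = "fit"`.
#' @param frame_times Frame times in seconds; default the inputs' grid.
#' @param min_enhancement Minimum L2 norm (mM) of a voxel's concentration
#'   curve; voxels below it (flat, non-enhancing signal, where the model is
#'   not identifiable) are flagged invalid. Default 1e-6.
#' @param ... Passed to [match_dictionary()] (e.g. `min_inner_product`,
#'   `batch_elements`).
#' @return List of class `dce_maps`: 3D arrays `af`, `dv`, `mtt`,
#'   `inner_product` (NA for fitting), `valid` (logical), plus `method` and
#'   `geometry` (carried attributes).
#' @export
map_volume <- function(vol, mask, inputs, acq = acquisition_params(),
                       method = c("dictionary", "fit"), dictionary = NULL,
                       config = fit_config(), frame_times = NULL,
                       min_enhancement = 1e-6, ...) {
  method <- match.arg(method)
  dims <- dim(vol)
  if (length(dims) != 4) {
    abort("`vol` must be a 4D (x, y, z, t) array.", class = "dcedict_invalid_inputs")
  }
  if (!identical(dim(mask), dims[1:3])) {
    abort("`mask` geometry does not match the volume.",
          class = "dcedict_geometry_error")
  }
  sel <- which(as.logical(mask != 0))
  if (length(sel) == 0) {
    abort("Empty mask.", class = "dcedict_invalid_inputs")
  }
  frame_times <- frame_times %||% inputs$time_s
  if (length(frame_times) != dims[4]) {
    abort("Frame times do not match the number of volumes.",
          class = "dcedict_geometry_error")
  }

  nvox <- prod(dims[1:3])
  sig <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = dims[4])[, sel, drop = FALSE]

  blank <- array(NA_real_, dims[1:3])
  maps <- list(af = blank, dv = blank, mtt = blank, inner_product = blank,
               valid = array(FALSE, dims[1:3]))

  # flag voxels with non-positive baseline rather than aborting the whole map
  s0 <- colMeans(sig[seq_len(acq$n_baseline), , drop = FALSE])
  ok0 <- s0 > 0
  conc <- matrix(NA_real_, dims[4], length(sel))
  if (any(ok0)) {
    conc[, ok0] <- concentration_from_signal(sig[, ok0, drop = FALSE], acq)
  }
  usable <- ok0 & colSums(!is.finite(conc)) == 0
  usable[usable] <- sqrt(colSums(conc[, usable, drop = FALSE]^2)) > min_enhancement

  if (any(usable)) {
    cu <- conc[, usable, drop = FALSE]
    if (method == "dictionary") {
      if (is.null(dictionary)) dictionary <- build_dictionary(inputs)
      res <- match_dictionary(cu, dictionary, ...)
      est <- tibble::tibble(af = res$af, dv = res$dv, mtt = res$mtt,
                            inner_product = res$inner_product,
                            valid = res$valid)
    } else {
      fres <- fit_curves(cu, inputs, config, grid = frame_times)
      est <- tibble::tibble(af = fres$af, dv = fres$dv, mtt = fres$mtt,
                            inner_product = NA_real_,
                            valid = is.finite(fres$af))
    }
    vox <- sel[usable]
    maps$af[vox] <- ifelse(est$valid, est$af, NA_real_)
    maps$dv[vox] <- ifelse(est$valid, est$dv, NA_real_)
    maps$mtt[vox] <- ifelse(est$valid, est$mtt, NA_real_)
    maps$inner_product[vox] <- est$inner_product
    maps$valid[vox] <- est$valid
  }

  structure(c(maps, list(method = method,
                         geometry = volume_geometry(vol))),
            class = "dce_maps")
}

volume_geometry <- function(vol) {
  list(dim = dim(vol)[1:3],
       pixdim = attr(vol, "pixdim"),
       pixunits = attr(vol, "pixunits"))
}

#' @export
print.dce_maps <- function(x, ...) {
  cat(sprintf("<dce_maps> %s method, %s voxels valid of %s masked\n",
              x$method, sum(x$valid), sum(!is.na(x$af) | !x$valid)))
  invisible(x)
}

#' Voxel-wise difference between two sets of perfusion maps
#'
#' Computes `a - b` per property; voxels invalid in either input are `NA`.
#'
#' @param maps_a,maps_b `dce_maps` objects on the same geometry.
#' @return List of class `dce_diff_maps` with 3D arrays `af`, `dv`, `mtt`.
#' @export
difference_map <- function(maps_a, maps_b) {
  if (!identical(dim(maps_a$af), dim(maps_b$af))) {
    abort("Map geometries differ.", class = "dcedict_geometry_error")
  }
  both <- maps_a$valid & maps_b$valid
  d <- lapply(c(af = "af", dv = "dv", mtt = "mtt"), function(p) {
    out <- maps_a[[p]] - maps_b[[p]]
    out[!both] <- NA_real_
    out
  })
  structure(c(d, list(valid = both, geometry = maps_a$geometry)),
            class = "dce_diff_maps")
}

#' ROI summary statistics and method comparison
#'
#' For each ROI label and property, reports mean and SD of the two methods'
#' estimates over valid voxels and a two-tailed two-sample t-test between
#' the methods' voxel value sets (Student's equal-variance by default, as is
#' conventional for this comparison; set `var_equal = FALSE` for Welch).
#' ROIs with fewer than 2 valid voxels in either map are excluded with a
#' warning. Degenerate zero-variance comparisons are handled by convention:
#' identical means give `t = 0, p = 1`, different means with zero variance
#' give `p = 0`.
#'
#' @param maps_a,maps_b `dce_maps` from the two estimators (conventionally
#'   curve fitting and dictionary matching).
#' @param labels 3D integer array of ROI labels (0 = background).
#' @param var_equal Use the pooled-variance Student t-test (default `TRUE`).
#' @return Tibble: `roi`, `property`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `t_statistic`, `p_value`, `n_a`, `n_b`.
#' @export
roi_compare <- function(maps_a, maps_b, labels, var_equal = TRUE) {
  if (!identical(dim(labels), dim(maps_a$af)) ||
      !identical(dim(labels), dim(maps_b$af))) {
    abort("Label geometry does not match the maps.",
          class = "dcedict_geometry_error")
  }
  rois <- sort(setdiff(unique(as.integer(labels)), 0L))
  rows <- list()
  for (r in rois) {
    sel <- labels == r
    if (sum(sel & maps_a$valid) < 2 || sum(sel & maps_b$valid) < 2) {
      warn(sprintf("ROI %d has < 2 valid voxels: excluded.", r))
      next
    }
    for (prop in c("af", "dv", "mtt")) {
      xa <- maps_a[[prop]][sel & maps_a$valid]
      xb <- maps_b[[prop]][sel & maps_b$valid]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (length(xa) < 2 || length(xb) < 2) next
      tt <- safe_t_test(xa, xb, var_equal)
      rows[[length(rows) + 1]] <- tibble::tibble(
        roi = r, property = prop,
        mean_a = mean(xa), sd_a = sd(xa),
        mean_b = mean(xb), sd_b = sd(xb),
        t_statistic = tt$statistic, p_value = tt$p.value,
        n_a = length(xa), n_b = length(xb))
    }
  }
  dplyr::bind_rows(rows)
}

safe_t_test <- function(x, y, var_equal = TRUE) {
  if (sd(x) == 0 && sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else Inf,
                p.value = if (same) 1 else 0))
  }
  tt <- t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Plot slices of a perfusion map set
#'
#' @param object A `dce_maps` object.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Ignored.
#' @method autoplot dce_maps
#' @export
autoplot.dce_maps <- function(object, slice = NULL, ...) {
  dims <- dim(object$af)
  slice <- slice %||% ceiling(dims[3] / 2)
  df <- purrr::map_dfr(c("af", "dv", "mtt"), function(p) {
    m <- object[[p]][, , slice]
    tibble::tibble(x = rep(seq_len(dims[1]), dims[2]),
                   y = rep(seq_len(dims[2]), each = dims[1]),
                   value = as.vector(m), property = toupper(p))
  })
  ggplot2::ggplot(df, ggplot2::aes(x, y, fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' NIfTI input/output helpers
#'
#' Thin wrappers over RNifti for reading dynamic volumes/masks and writing
#' each perfusion map as its own NIfTI file.
#'
#' @param path NIfTI file path.
#' @return `read_volume()` returns the image array with RNifti attributes.
#' @export
read_volume <- function(path) {
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @param maps A `dce_maps` object.
#' @param prefix Output path prefix; files `<prefix>_af.nii.gz` etc. are
#'   written.
#' @param template Optional image whose geometry is stamped on the outputs.
#' @export
write_maps <- function(maps, prefix, template = NULL) {
  paths <- character()
  for (p in c("af", "dv", "mtt", "inner_product")) {
    img <- maps[[p]]
    if (!is.null(template)) {
      img <- RNifti::asNifti(img, reference = RNifti::asNifti(template))
    }
    f <- paste0(prefix, "_", p, ".nii.gz")
    RNifti::writeNifti(img, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
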