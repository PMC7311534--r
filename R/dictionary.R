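#' Dictionary parameter grid
#'
#' The grid of (AF, MTT) pairs enumerated by the dictionary. The default is
#' the production grid: AF from 0 to 1 in steps of 0.01 (101 values) and MTT
#' taking the near-zero lower bound 0.0001 s (MTT = 0 is excluded by the
#' model) plus the integers 1..100 s (101 values), for 10,201 entries. DV is
#' always fixed to 1 in the dictionary — it is a pure scaling property and is
#' recovered after matching from an L2-norm ratio.
#'
#' @param af_step AF step size (default 0.01).
#' @param mtt_step MTT step size in seconds (default 1).
#' @param af_range AF range (default 0 to 1).
#' @param mtt_range MTT range in seconds; the lower bound is kept verbatim as
#'   the first grid value (default 0.0001 to 100).
#' @return List of class `dict_grid` with `af_values`, `mtt_values`,
#'   `dv_fixed = 1`.
#' @export
#' @examples
#' g <- dictionary_grid()
#' length(g$af_values) * length(g$mtt_values)  # 10201
dictionary_grid <- function(af_step = 0.01, mtt_step = 1,
                            af_range = c(0, 1), mtt_range = c(1e-4, 100)) {
  stopifnot(af_step > 0, mtt_step > 0)
  af_values <- seq(af_range[1], af_range[2], by = af_step)
  if (af_values[length(af_values)] < af_range[2] - 1e-12) {
    af_values <- c(af_values, af_range[2])
  }
  mtt_values <- seq(mtt_step, mtt_range[2], by = mtt_step)
  if (mtt_range[1] < mtt_values[1]) {
    mtt_values <- c(mtt_range[1], mtt_values)
  }
  if (any(af_values < 0 | af_values > 1)) {
    abort("AF grid must lie in [0, 1].", class = "dcedict_invalid_grid")
  }
  structure(list(af_values = af_values, mtt_values = mtt_values,
                 dv_fixed = 1), class = "dict_grid")
}

#' Build the dictionary of normalised model curves
#'
#' Every (AF, MTT) permutation of the grid is run through the forward model
#' at DV = 1 on the acquisition time grid; each resulting tissue curve is
#' divided by its own L2 norm and stored as one column of the `t x n`
#' dictionary matrix. The pre-normalisation norms are stored so that the
#' distribution volume can later be recovered as
#' `DV = ||C_L||_2 / ||C_LD||_2` against the un-normalised best-match curve.
#' Columns are ordered AF-major (MTT varies fastest).
#'
#' @param inputs A [input_functions()] object.
#' @param grid A [dictionary_grid()].
#' @param time_grid Acquisition time grid; defaults to the inputs' grid.
#' @return List of class `dce_dictionary`: `entries` (t x n, unit-norm
#'   columns), `norms`, `index` (tibble column/af/mtt), `grid`, `time_s`,
#'   `inputs_hash`.
#' @export
build_dictionary <- function(inputs, grid = dictionary_grid(),
                             time_grid = NULL) {
  time_grid <- time_grid %||% inputs$time_s
  check_time_grid(time_grid)
  ca <- shift_input(inputs$time_s, inputs$aif, time_grid,
                    attr(inputs, "tau_a") %||% 0)
  cp <- shift_input(inputs$time_s, inputs$pvif, time_grid,
                    attr(inputs, "tau_p") %||% 0)
  t_len <- length(time_grid)
  nA <- length(grid$af_values)
  nM <- length(grid$mtt_values)
  # at DV = 1: curve(AF, MTT) = AF * base_a(MTT) + (1 - AF) * base_p(MTT),
  # where base_x is the pure single-input response — build the two bases once
  base_a <- matrix(0, t_len, nM)
  base_p <- matrix(0, t_len, nM)
  for (j in seq_len(nM)) {
    k2 <- 1 / grid$mtt_values[j]
    base_a[, j] <- expconv(time_grid, k2 * ca, k2)
    base_p[, j] <- expconv(time_grid, k2 * cp, k2)
  }
  entries <- matrix(0, t_len, nA * nM)
  for (i in seq_len(nA)) {
    af <- grid$af_values[i]
    entries[, (i - 1) * nM + seq_len(nM)] <- af * base_a + (1 - af) * base_p
  }
  norms <- sqrt(colSums(entries^2))
  if (any(norms == 0)) {
    abort("Dictionary contains zero-norm model curves (are the inputs all zero?).",
          class = "dcedict_build_error")
  }
  entries <- sweep(entries, 2, norms, "/")
  index <- tibble::tibble(
    column = seq_len(nA * nM),
    af = rep(grid$af_values, each = nM),
    mtt = rep(grid$mtt_values, times = nA)
  )
  structure(list(entries = entries, norms = norms, index = index,
                 grid = grid, time_s = time_grid,
                 inputs_hash = inputs_hash(inputs)),
            class = "dce_dictionary")
}

inputs_hash <- function(inputs) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(tibble::as_tibble(inputs), attr(inputs, "tau_a"),
               attr(inputs, "tau_p"), attr(inputs, "hematocrit")),
          f, version = 2)
  unname(tools::md5sum(f))
}

#' @export
print.dce_dictionary <- function(x, ...) {
  cat(sprintf(
    "<dce_dictionary> %d frames x %d entries (%d AF x %d MTT), DV fixed at 1\n",
    nrow(x$entries), ncol(x$entries),
    length(x$grid$af_values), length(x$grid$mtt_values)))
  invisible(x)
}

#' Low-rank dictionary compression via randomized SVD
#'
#' Approximates the dictionary matrix with a rank-`r` randomized singular
#' value decomposition (Gaussian sketch, orthonormal range basis, small exact
#' SVD), storing the left basis and the projected entries. Matching through
#' the compressed dictionary scores probes in the rank-`r` subspace; at full
#' rank it reproduces uncompressed matching exactly.
#'
#' @param d A `dce_dictionary`.
#' @param rank Target rank; `NULL` (default) selects the smallest rank
#'   retaining `energy` of the singular-value energy (sum of squared singular
#'   values).
#' @param energy Energy fraction for automatic rank selection
#'   (default 0.99999).
#' @param oversample Sketch oversampling columns (default 10).
#' @param seed Seed for the Gaussian sketch (default 1), for reproducibility.
#' @return List of class `dce_compressed_dictionary` with `left_basis`
#'   (t x rank), `projected_entries` (rank x n), `singular_values`, plus the
#'   source `norms`, `index`, `grid`, `time_s`.
#' @export
compress_dictionary <- function(d, rank = NULL, energy = 0.99999,
                                oversample = 10, seed = 1) {
  stopifnot(inherits(d, "dce_dictionary"))
  A <- d$entries
  t_len <- nrow(A); n <- ncol(A)
  max_rank <- min(t_len, n)
  if (!is.null(rank) && (rank < 1 || rank > max_rank)) {
    abort("`rank` must lie in [1, min(t, n)].", class = "dcedict_invalid_rank")
  }
  sketch <- min(max_rank, (rank %||% max_rank) + oversample)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  Omega <- matrix(rnorm(n * sketch), n, sketch)
  Q <- qr.Q(qr(A %*% Omega))
  B <- crossprod(Q, A)
  sv <- svd(B)
  if (is.null(rank)) {
    e <- cumsum(sv$d^2) / sum(sv$d^2)
    rank <- which(e >= energy)[1]
  }
  U <- Q %*% sv$u[, seq_len(rank), drop = FALSE]
  structure(list(left_basis = U,
                 projected_entries = crossprod(U, A),
                 singular_values = sv$d,
                 rank = rank, norms = d$norms, index = d$index,
                 grid = d$grid, time_s = d$time_s,
                 inputs_hash = d$inputs_hash),
            class = "dce_compressed_dictionary")
}

#' @export
print.dce_compressed_dictionary <- function(x, ...) {
  cat(sprintf("<dce_compressed_dictionary> rank %d of %d frames x %d entries\n",
              x$rank, nrow(x$left_basis), ncol(x$projected_entries)))
  invisible(x)
}

# coerce supported curve containers to a t x m matrix
as_curve_matrix <- function(curves, t_len) {
  if (is.data.frame(curves)) {
    if (all(c("id", "time_s", "conc") %in% names(curves))) {
      wide <- tidyr::pivot_wider(curves, id_cols = "time_s",
                                 names_from = "id", values_from = "conc")
      curves <- as.matrix(wide[, -1, drop = FALSE])
    } else if ("conc" %in% names(curves)) {
      curves <- matrix(curves$conc, ncol = 1)
    } else {
      abort("Data-frame curves need columns `conc` (+ optional `id`, `time_s`).",
            class = "dcedict_invalid_inputs")
    }
  } else if (is.numeric(curves) && is.null(dim(curves))) {
    curves <- matrix(curves, ncol = 1)
  }
  curves <- as.matrix(curves)
  if (nrow(curves) != t_len) {
    abort(sprintf("Curves have %d frames; dictionary expects %d.",
                  nrow(curves), t_len),
          class = "dcedict_invalid_inputs")
  }
  curves
}

#' Match tissue curves against the dictionary
#'
#' Exhaustive inner-product template search. Each curve is divided by its own
#' L2 norm and scored against every dictionary column by inner product; the
#' arg-max column supplies the (AF, MTT) estimate (ties broken by lowest
#' column index), and DV is recovered as the ratio of the curve's L2 norm to
#' the un-normalised best-match model curve's norm. Zero-norm curves (no
#' enhancement) are flagged invalid rather than raising an error, for
#' voxel-wise robustness. Probes are processed in batches so the score matrix
#' never exceeds `batch_elements`; results are independent of the batch size.
#'
#' @param curves A numeric vector (one curve), a `t x m` matrix (one curve
#'   per column), a `dce_curve` tibble, or a long tibble with columns `id`,
#'   `time_s`, `conc`. Frames with `NA` invalidate the curve.
#' @param dict A `dce_dictionary` or `dce_compressed_dictionary`.
#' @param batch_elements Memory budget: maximum number of elements of the
#'   `m x n` inner-product matrix held at once (default 5e7).
#' @param clip_dv_to_unit Clip recovered DV values into \[0, 1\]
#'   (default `FALSE`; norm-ratio DV can transiently exceed 1).
#' @param min_inner_product Validity threshold on the best inner product
#'   (default `-Inf` keeps every match; for nonnegative enhancement curves
#'   the inner product lives on a 0-1 goodness scale, so e.g. 0.95 filters
#'   poor matches); failed matches stay in the output with `valid = FALSE`.
#' @return A tibble of class `dce_match` with one row per curve: `id`, `af`,
#'   `mtt`, `dv`, `inner_product`, `column_index`, `valid`.
#' @export
match_dictionary <- function(curves, dict, batch_elements = 5e7,
                             clip_dv_to_unit = FALSE,
                             min_inner_product = -Inf) {
  compressed <- inherits(dict, "dce_compressed_dictionary")
  if (!compressed && !inherits(dict, "dce_dictionary")) {
    abort("`dict` must be a (compressed) dictionary.",
          class = "dcedict_invalid_inputs")
  }
  t_len <- length(dict$time_s)
  X <- as_curve_matrix(curves, t_len)
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  m <- ncol(X)
  n <- ncol(if (compressed) dict$projected_entries else dict$entries)

  cnorm <- sqrt(colSums(X^2))
  ok <- is.finite(cnorm) & cnorm > 0 & colSums(!is.finite(X)) == 0

  best_col <- rep(NA_integer_, m)
  best_ip <- rep(NA_real_, m)
  idx_ok <- which(ok)
  if (length(idx_ok)) {
    Xn <- sweep(X[, idx_ok, drop = FALSE], 2, cnorm[idx_ok], "/")
    if (compressed) Xn <- crossprod(dict$left_basis, Xn)
    batch <- max(1L, min(length(idx_ok), floor(batch_elements / n)))
    for (s in seq(1, length(idx_ok), by = batch)) {
      e <- min(s + batch - 1, length(idx_ok))
      scores <- crossprod(Xn[, s:e, drop = FALSE],
                          if (compressed) dict$projected_entries else dict$entries)
      j <- max.col(scores, ties.method = "first")
      best_col[idx_ok[s:e]] <- j
      best_ip[idx_ok[s:e]] <- scores[cbind(seq_len(nrow(scores)), j)]
    }
  }

  dv <- cnorm / dict$norms[best_col]
  if (clip_dv_to_unit) dv <- pmin(pmax(dv, 0), 1)
  valid <- ok & !is.na(best_ip) & best_ip >= min_inner_product
  out <- tibble::tibble(
    id = ids,
    af = ifelse(valid, dict$index$af[best_col], NA_real_),
    mtt = ifelse(valid, dict$index$mtt[best_col], NA_real_),
    dv = ifelse(valid, dv, NA_real_),
    inner_product = best_ip,
    column_index = ifelse(valid, best_col, NA_integer_),
    valid = valid
  )
  class(out) <- c("dce_match", class(out))
  out
}

#' Distribution volume from the L2-norm ratio
#'
#' `DV = ||C_L||_2 / ||C_LD||_2`, where `C_LD` is the un-normalised model
#' curve of the best dictionary match (built at DV = 1). Exact when the curve
#' is a noiseless DV-scaled model curve, by linearity of the model in DV.
#'
#' @param curve Numeric tissue concentration curve (or `dce_curve` tibble).
#' @param best_entry Un-normalised best-match model curve.
#' @return The DV estimate; `NA` with a warning if the entry has zero norm.
#' @export
estimate_dv <- function(curve, best_entry) {
  if (is.data.frame(curve)) curve <- curve$conc
  if (is.data.frame(best_entry)) best_entry <- best_entry$conc
  den <- sqrt(sum(best_entry^2))
  if (den == 0) {
    warn("Zero-norm dictionary entry: DV flagged as NA.")
    return(NA_real_)
  }
  sqrt(sum(curve^2)) / den
}

#' Write / read a dictionary as a plain-text directory
#'
#' On-disk container: `entries.txt` (whitespace matrix, one row per entry),
#' `norms.csv`, and `meta.json` (grid, time stamps, input-function hash).
#' `index.csv` is also written for interoperability.
#'
#' @param d A `dce_dictionary`.
#' @param dir Directory path (created if missing).
#' @return `write_dictionary()` returns `dir` invisibly; `read_dictionary()`
#'   returns the reconstructed `dce_dictionary`.
#' @export
write_dictionary <- function(d, dir) {
  stopifnot(inherits(d, "dce_dictionary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(d$entries), file.path(dir, "entries.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(cbind(d$index, norm = d$norms), file.path(dir, "norms.csv"),
                   row.names = FALSE)
  utils::write.csv(d$index, file.path(dir, "index.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(af_values = d$grid$af_values, mtt_values = d$grid$mtt_values,
         dv_fixed = d$grid$dv_fixed, time_s = d$time_s,
         inputs_hash = d$inputs_hash),
    file.path(dir, "meta.json"), digits = NA)
  invisible(dir)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  entries <- t(as.matrix(utils::read.table(file.path(dir, "entries.txt"))))
  dimnames(entries) <- NULL
  norms_df <- utils::read.csv(file.path(dir, "norms.csv"))
  grid <- structure(list(af_values = meta$af_values,
                         mtt_values = meta$mtt_values,
                         dv_fixed = meta$dv_fixed), class = "dict_grid")
  structure(list(entries = entries, norms = norms_df$norm,
                 index = tibble::as_tibble(norms_df[c("column", "af", "mtt")]),
                 grid = grid, time_s = meta$time_s,
                 inputs_hash = meta$inputs_hash),
            class = "dce_dictionary")
}
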