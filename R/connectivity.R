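#' Specification of a spherical region of interest
#'
#' @param center Sphere centre, 3-vector, mm (MNI).
#' @param radius Sphere radius, mm (default 10).
#' @param voxel_size Isotropic voxel edge of the mask grid, mm (default 2).
#' @param dim Grid dimensions, 3 integers.
#' @param origin Position of the first voxel centre, 3-vector, mm.
#' @return A list of class `roi_mask_spec`.
#' @export
roi_mask_spec <- function(center, radius = 10, voxel_size = 2,
                          dim = c(91, 109, 91),
                          origin = c(-90, -126, -72)) {
  stopifnot(length(center) == 3, radius > 0, voxel_size > 0,
            length(dim) == 3, all(dim >= 1), length(origin) == 3)
  structure(list(center = center, radius = radius, voxel_size = voxel_size,
                 dim = as.integer(dim), origin = origin),
            class = "roi_mask_spec")
}

#' Build a binary sphere mask on a voxel grid
#'
#' A voxel is included iff its centre lies within `radius` of the sphere
#' centre.  Warns when the sphere is clipped by the grid boundary; errors
#' when no voxel is included.
#'
#' @param spec A [roi_mask_spec()].
#' @return A list of class `roi_mask`: logical 3-D `mask` array plus the
#'   `spec` and the included-voxel count `n_voxels`.
#' @export
sphere_mask <- function(spec) {
  stopifnot(inherits(spec, "roi_mask_spec"))
  ax <- lapply(1:3, function(k) spec$origin[k] + (seq_len(spec$dim[k]) - 1) * spec$voxel_size)
  lo <- vapply(ax, min, numeric(1)); hi <- vapply(ax, max, numeric(1))
  if (any(spec$center - spec$radius < lo) || any(spec$center + spec$radius > hi))
    warning("sphere extends beyond the mask grid; mask may be clipped")
  dx2 <- (ax[[1]] - spec$center[1])^2
  dy2 <- (ax[[2]] - spec$center[2])^2
  dz2 <- (ax[[3]] - spec$center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  mask <- d2 <= spec$radius^2
  if (!any(mask)) stop("empty mask: sphere does not cover any voxel centre")
  structure(list(mask = mask, spec = spec, n_voxels = sum(mask)),
            class = "roi_mask")
}

#' Write a binary ROI mask as a NIfTI-1 volume
#'
#' @param mask A `roi_mask`.
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim = dim(mask$mask)))
  RNifti::pixdim(img) <- rep(mask$spec$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract mean ROI time series from a 4-D NIfTI volume
#'
#' The plug-in path for real data: averages, at each volume, the voxels
#' under a binary mask.
#'
#' @param path 4-D NIfTI file.
#' @param mask A `roi_mask` whose grid matches the volume.
#' @return Numeric vector, one mean per volume.
#' @export
extract_roi_series <- function(path, mask) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  stopifnot(length(d) == 4, all(d[1:3] == dim(mask$mask)))
  apply(matrix(img, prod(d[1:3]), d[4])[as.vector(mask$mask), , drop = FALSE],
        2, mean)
}

legendre_basis <- function(n, order) {
  x <- if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0
  out <- matrix(1, n, order + 1)
  if (order >= 1) out[, 2] <- x
  for (k in 2:max(2, order)) {
    if (k > order) break
    # P_k from pracma's associated-Legendre table (row m = 0)
    out[, k + 1] <- pracma::legendre(k, x)[1, ]
  }
  colnames(out) <- paste0("poly", 0:order)
  out
}

#' Build the online nuisance design matrix
#'
#' Column families, in fixed order: Legendre polynomials of orders
#' `0..poly_order` on time rescaled to [-1, 1] (high-pass / drift), the
#' six motion channels, mean white-matter and CSF signals, and RETROICOR
#' Fourier pairs \{cos(k phi), sin(k phi)\} for `k = 1..retroicor_order`,
#' cardiac phase first, then respiratory.
#'
#' @param ts A `roi_timeseries` (only its nuisance channels are used).
#' @param poly_order Legendre order (default 3).
#' @param retroicor_order Fourier order per physiological trace (default 2).
#' @param n_samples Use only the first `n_samples` rows (default all):
#'   this is how the expanding online design is built causally.
#' @return Numeric design matrix, `n_samples` x k, with descriptive
#'   column names.
#' @export
build_nuisance_regressors <- function(ts, poly_order = 3, retroicor_order = 2,
                                      n_samples = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"), poly_order >= 0, retroicor_order >= 0)
  n_all <- nrow(ts$data)
  n <- if (is.null(n_samples)) n_all else as.integer(n_samples)
  stopifnot(n >= 1, n <= n_all)
  lens <- c(nrow(ts$motion), length(ts$wm), length(ts$csf),
            length(ts$cardiac_phase), length(ts$resp_phase))
  if (any(lens != n_all)) stop("nuisance channel lengths do not match the data")
  idx <- seq_len(n)
  X <- legendre_basis(n, poly_order)
  mot <- ts$motion[idx, , drop = FALSE]
  colnames(mot) <- paste0("motion", 1:6)
  X <- cbind(X, mot, wm = ts$wm[idx], csf = ts$csf[idx])
  if (retroicor_order > 0) {
    for (trace in c("cardiac", "resp")) {
      phi <- ts[[paste0(trace, "_phase")]][idx]
      for (k in seq_len(retroicor_order)) {
        X <- cbind(X, cos(k * phi), sin(k * phi))
        colnames(X)[ncol(X) - 1:0] <- paste0(trace, c("_cos", "_sin"), k)
      }
    }
  }
  X
}

#' Least-squares residualization of signals against a design
#'
#' Projects each column of `series` onto the orthogonal complement of the
#' column space of `design`.  Rank-deficient designs have their dependent
#' columns dropped with a warning.  Residuals are orthogonal to every
#' design column; the operation is idempotent.
#'
#' @param series Numeric matrix, samples x m (a vector is treated as one
#'   column).
#' @param design Numeric design matrix, samples x k.
#' @return Residual matrix with the dimensions of `series`.
#' @export
residualize <- function(series, design) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  design <- as.matrix(design)
  n <- nrow(series)
  if (nrow(design) != n) stop("series and design have different sample counts")
  if (n <= ncol(design))
    stop("need more samples (", n, ") than design columns (", ncol(design), ")")
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    warning("design is rank deficient; dropping ", ncol(design) - qd$rank,
            " dependent column(s)")
    design <- design[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    qd <- qr(design)
  }
  qr.resid(qd, series)
}

#' Windowed connectivity outcome of one block
#'
#' Pearson correlation between the two cleaned ROI channels over the
#' block's sample window, with Fisher's r-to-z transform
#' (`z = atanh(r)`, `|r|` clipped at `1 - 1e-7` so degenerate windows
#' yield a finite z of about 8.1).  Windows where either channel has
#' (numerically) zero variance are returned as invalid outcomes, which
#' the closed loop treats as failed blocks.
#'
#' @param cleaned Residualized signals, samples x 2.
#' @param window Integer `c(start, end)`, 0-based half-open sample range
#'   (as from [block_window_samples()]).
#' @param block_index Block number carried into the outcome.
#' @return A list of class `connectivity_outcome`: `block_index`, `r`,
#'   `z`, `n_samples`, `valid`.
#' @export
windowed_connectivity <- function(cleaned, window, block_index = NA_integer_) {
  stopifnot(is.matrix(cleaned), ncol(cleaned) == 2,
            length(window) == 2, window[2] > window[1])
  n <- window[2] - window[1]
  if (n < 4) stop("window must contain at least 4 samples")
  if (window[2] > nrow(cleaned)) stop("window extends past the available samples")
  w <- cleaned[(window[1] + 1):window[2], , drop = FALSE]
  s <- apply(w, 2, stats::sd)
  if (any(!is.finite(s)) || any(s < 1e-12 * max(1, max(abs(w))))) {
    out <- list(block_index = block_index, r = NA_real_, z = NA_real_,
                n_samples = n, valid = FALSE)
  } else {
    r <- stats::cor(w[, 1], w[, 2])
    rc <- max(min(r, 1 - 1e-7), -1 + 1e-7)
    out <- list(block_index = block_index, r = r, z = atanh(rc),
                n_samples = n, valid = TRUE)
  }
  structure(out, class = "connectivity_outcome")
}

#' @export
print.connectivity_outcome <- function(x, ...) {
  if (x$valid)
    cat(sprintf("block %s: r = %.3f, z = %.3f (n = %d)\n",
                x$block_index, x$r, x$z, x$n_samples))
  else cat(sprintf("block %s: invalid window (n = %d)\n",
                   x$block_index, x$n_samples))
  invisible(x)
}

#' Score one block online (causal, expanding design)
#'
#' Mimics the real-time pipeline: uses only the samples acquired up to the
#' block's window end, builds the nuisance design over those samples,
#' residualizes the two ROI channels, and computes the windowed
#' connectivity.  No lookahead: samples at or beyond the window end are
#' never touched.  Early in a run, when fewer samples than design columns
#' have been acquired, the design is truncated to its leading columns
#' (polynomials first, then motion, WM/CSF, RETROICOR) so that at least
#' `min_resid_df` residual degrees of freedom remain -- regressors are
#' phased in as data accumulate, as online GLM pipelines do.
#'
#' @param ts A `roi_timeseries` (may contain the whole run; only the
#'   causal prefix is used).
#' @param run The `run_schedule` the series was acquired under.
#' @param block_index Block to score.
#' @param poly_order,retroicor_order Passed to
#'   [build_nuisance_regressors()].
#' @param shift_s,window_s Passed to [block_window_samples()].
#' @param min_resid_df Minimum residual degrees of freedom preserved when
#'   truncating the early-run design (default 5).
#' @return A `connectivity_outcome`.
#' @export
evaluate_block_online <- function(ts, run, block_index, poly_order = 3,
                                  retroicor_order = 2, shift_s = 6,
                                  window_s = NULL, min_resid_df = 5) {
  win <- block_window_samples(run, block_index, shift_s, window_s)
  n_avail <- win[2]
  X <- build_nuisance_regressors(ts, poly_order, retroicor_order,
                                 n_samples = n_avail)
  k_max <- n_avail - min_resid_df
  if (k_max < 1)
    return(structure(list(block_index = block_index, r = NA_real_,
                          z = NA_real_, n_samples = win[2] - win[1],
                          valid = FALSE), class = "connectivity_outcome"))
  if (ncol(X) > k_max) X <- X[, seq_len(k_max), drop = FALSE]
  out <- tryCatch({
    cleaned <- residualize(ts$data[seq_len(n_avail), , drop = FALSE], X)
    windowed_connectivity(cleaned, win, block_index)
  }, error = function(e) {
    structure(list(block_index = block_index, r = NA_real_, z = NA_real_,
                   n_samples = win[2] - win[1], valid = FALSE),
              class = "connectivity_outcome")
  })
  out
}

#' Append connectivity outcomes to a tab-separated log
#'
#' @param outcomes List of `connectivity_outcome`s.
#' @param params_per_block List of [stim_params()], one per outcome.
#' @param path Log path; created with a header when missing.
#' @return `path`, invisibly.
#' @export
write_connectivity_log <- function(outcomes, params_per_block, path) {
  stopifnot(length(outcomes) == length(params_per_block))
  tab <- data.frame(
    block_index = vapply(outcomes, function(o) as.integer(o$block_index), integer(1)),
    frequency = vapply(params_per_block, function(p) p$frequency, numeric(1)),
    phase = vapply(params_per_block, device_phase, numeric(1)),
    r = vapply(outcomes, function(o) o$r, numeric(1)),
    z = vapply(outcomes, function(o) o$z, numeric(1)),
    valid = vapply(outcomes, function(o) o$valid, logical(1)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}
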