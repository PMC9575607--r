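#' Electric field of a point current source on a conductive half-space
#'
#' Quasistatic field of a point electrode injecting current `current_mA`
#' into a homogeneous half-space of conductivity `sigma`:
#' \deqn{E(p) = \frac{I}{2\pi\sigma r^2}\,\hat{r},}
#' radial from the source, with \eqn{I} in amperes and \eqn{r} the
#' source-to-point distance in metres (the factor \eqn{2\pi} rather than
#' \eqn{4\pi} accounts for the insulating scalp boundary).  Positions are
#' given in millimetres; the returned vector is in V/m.
#'
#' @param current_mA Source current, mA (signed; negative for a sink).
#' @param sigma Conductivity, S/m.
#' @param source Source position, 3-vector, mm.
#' @param point Evaluation position, 3-vector, mm.
#' @return Field vector, length-3 numeric, V/m.
#' @export
point_source_field <- function(current_mA, sigma, source, point) {
  stopifnot(sigma > 0, length(source) == 3, length(point) == 3)
  d <- (point - source) * 1e-3
  r <- sqrt(sum(d^2))
  if (r == 0) stop("evaluation point coincides with the source (r = 0)")
  (current_mA * 1e-3) / (2 * pi * sigma) * d / r^3
}

#' Field magnitude of a full montage by point-source superposition
#'
#' Vector-sums the half-space point-source contribution of every electrode
#' in the montage at each evaluation point and returns the magnitudes.
#' Linear in all electrode currents.
#'
#' @param m A `tacs_montage`.
#' @param points Evaluation points: a 3-vector or an n x 3 matrix, mm.
#' @param sigma Conductivity, S/m (default 0.275, gray matter).
#' @param vector If `TRUE`, return the n x 3 matrix of field vectors
#'   instead of magnitudes.
#' @return Numeric vector of field magnitudes (V/m), or an n x 3 matrix of
#'   field vectors if `vector = TRUE`.
#' @export
montage_field <- function(m, points, sigma = 0.275, vector = FALSE) {
  stopifnot(inherits(m, "tacs_montage"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  e <- m$electrodes
  src <- as.matrix(e[, c("x", "y", "z")])
  E <- matrix(0, nrow(points), 3)
  for (i in seq_len(nrow(src))) {
    d <- sweep(points, 2, src[i, ]) * 1e-3
    r <- sqrt(rowSums(d^2))
    if (any(r == 0))
      stop("evaluation point coincides with electrode '", e$label[i], "'")
    E <- E + (e$current[i] * 1e-3) / (2 * pi * sigma) * d / r^3
  }
  if (vector) E else sqrt(rowSums(E^2))
}

#' Idealized flat dual-site 4x1 montage
#'
#' The plane-scalp abstraction used by the analytic shunt derivation: both
#' sites are laid out on the z = 0 plane along the x axis, centres at
#' \eqn{\pm} half the site separation, with in-line returns toward and away
#' from the midpoint and a lateral return pair at \eqn{\pm} the
#' centre-return distance in y.  Mirror-symmetric about the midplane
#' x = 0, so in-phase tangential fields cancel there exactly.
#'
#' @param site_separation Centre-to-centre distance, mm (default 130).
#' @param center_return Centre-to-return distance, mm (default 30).
#' @param center_current Centre current, mA (default 1).
#' @param phase_condition `"in_phase"` or `"anti_phase"`.
#' @return A `tacs_montage` with planar coordinates.
#' @export
flat_dual_site_montage <- function(site_separation = 130,
                                   center_return = 30,
                                   center_current = 1,
                                   phase_condition = c("in_phase", "anti_phase")) {
  phase_condition <- match.arg(phase_condition)
  stopifnot(site_separation > 0, center_return > 0,
            center_return < site_separation / 2)
  h <- site_separation / 2
  cr <- center_return
  pos <- data.frame(
    label = c("Fc", "Fr_near", "Fr_far", "Fr_lat1", "Fr_lat2",
              "Pc", "Pr_near", "Pr_far", "Pr_lat1", "Pr_lat2"),
    x = c(-h, -h + cr, -h - cr, -h, -h,
          h, h - cr, h + cr, h, h),
    y = c(0, 0, 0, cr, -cr,
          0, 0, 0, cr, -cr),
    z = 0,
    role = rep(c("center", rep("return", 4)), 2),
    site = rep(c("frontal", "parietal"), each = 5),
    stringsAsFactors = FALSE
  )
  build_dual_site_montage(montage_config(
    positions = pos, center_current = center_current,
    phase_condition = phase_condition,
    center_return_distance = center_return))
}

#' Geometry of the inter-site shunt estimate
#'
#' Distances (cm) from the scalp point midway between the two sites to the
#' in-line electrodes of one site: `d1` to the near return, `d2` to the
#' centre, `d3` to the far return, so that `2*d2` is the site separation
#' and `d1 + d3 = 2*d2` when the returns straddle the centre symmetrically.
#' The lateral return pair sits at the centre-return distance `d2 - d1`
#' off-axis.  `depth` is the evaluation depth of the gray-matter point
#' below the scalp midpoint.
#'
#' @param d1,d2,d3 Distances, cm (defaults 3.5, 6.5, 9.5: a 13-cm site
#'   separation with 3-cm centre-return spacing).
#' @param sigma Gray-matter conductivity, S/m (default 0.275).
#' @param depth Evaluation depth below the scalp, cm (default 2, a typical
#'   adult scalp-to-cortex distance).
#' @return A list of class `shunt_geometry`.
#' @export
shunt_geometry <- function(d1 = 3.5, d2 = 6.5, d3 = 9.5,
                           sigma = 0.275, depth = 2) {
  stopifnot(d1 > 0, d2 > 0, d3 > 0, sigma > 0, depth >= 0, d1 < d2, d2 < d3)
  if (abs((d1 + d3) - 2 * d2) > 1e-9)
    warning("asymmetric return placement: d1 + d3 != 2*d2")
  structure(list(d1 = d1, d2 = d2, d3 = d3, sigma = sigma, depth = depth),
            class = "shunt_geometry")
}

#' Analytic shunt field at the gray-matter point midway between sites
#'
#' Point-source superposition over the idealized flat dual 4x1 montage,
#' evaluated at depth `g$depth` below the scalp midpoint, keeping the
#' component along the frontal-parietal axis -- the tangential field that
#' drives shunt current between the sites.  On the midplane this component
#' cancels exactly under in-phase stimulation (mirror symmetry) and equals
#' the full midplane field magnitude under anti-phase (the normal
#' component vanishes by antisymmetry).  Linear in the centre current and
#' inversely proportional to the conductivity.
#'
#' @param g A [shunt_geometry()].
#' @param center_current Centre-electrode current, mA (default 1; returns
#'   carry a quarter each).
#' @param condition `"anti_phase"` (default) or `"in_phase"`.
#' @return Shunt field magnitude at the midpoint, V/m.
#' @export
midpoint_shunt_field <- function(g, center_current = 1,
                                 condition = c("anti_phase", "in_phase")) {
  condition <- match.arg(condition)
  stopifnot(inherits(g, "shunt_geometry"))
  m <- flat_dual_site_montage(site_separation = 20 * g$d2,  # cm -> mm
                              center_return = 10 * (g$d2 - g$d1),
                              center_current = center_current,
                              phase_condition = condition)
  E <- montage_field(m, c(0, 0, -10 * g$depth), sigma = g$sigma, vector = TRUE)
  abs(E[1, 1])
}

#' A regular grid of electric-field magnitudes
#'
#' @param values 3-D numeric array of field magnitudes, V/m (all finite,
#'   non-negative).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param origin Position of the first voxel centre, 3-vector, mm.
#' @return A list of class `field_grid`.
#' @export
field_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            voxel_size > 0, length(origin) == 3)
  if (!all(is.finite(values)) || any(values < 0))
    stop("field magnitudes must be finite and non-negative")
  structure(list(values = values, voxel_size = voxel_size, origin = origin),
            class = "field_grid")
}

#' Focality volume of a field grid
#'
#' The focality of the stimulated region: the volume of voxels whose field
#' magnitude is at least 75% of the peak value, where the peak is the
#' 99.9th percentile of all magnitudes (nearest-rank convention) so single
#' outlier voxels do not define it.  Smaller volume = more focal field.
#' For an all-zero grid the threshold degenerates to zero and the whole
#' grid volume is returned with a warning.
#'
#' @param grid A [field_grid()].
#' @param peak_quantile Percentile defining the peak (default 0.999).
#' @param threshold_frac Fraction of the peak defining the stimulated
#'   region (default 0.75).
#' @return List with `volume_mm3`, `peak` (V/m), `threshold` (V/m) and
#'   `n_voxels` (count at or above threshold).
#' @export
focality_volume <- function(grid, peak_quantile = 0.999, threshold_frac = 0.75) {
  stopifnot(inherits(grid, "field_grid"))
  v <- as.numeric(grid$values)
  n <- length(v)
  if (n == 0) stop("empty field grid")
  k <- min(n, max(1L, as.integer(ceiling(peak_quantile * n))))
  peak <- sort(v, partial = k)[k]     # nearest-rank percentile
  if (peak == 0) warning("all-zero field grid: focality volume is the whole grid")
  thr <- threshold_frac * peak
  n_above <- sum(v >= thr)
  list(volume_mm3 = n_above * grid$voxel_size^3,
       peak = peak, threshold = thr, n_voxels = n_above)
}

#' Percent change of the stimulated volume between phase conditions
#'
#' @param v_in In-phase focality volume, mm^3 (must be positive).
#' @param v_anti Anti-phase focality volume, mm^3.
#' @return Percent change `100 * (v_anti - v_in) / v_in` (unrounded; round
#'   to two decimals for display).
#' @export
compare_conditions <- function(v_in, v_anti) {
  if (!is.finite(v_in) || v_in <= 0) stop("v_in must be positive")
  100 * (v_anti - v_in) / v_in
}

#' Read / write a field grid as a NIfTI-1 volume
#'
#' @param grid A [field_grid()].
#' @param path NIfTI file path (`.nii`).
#' @return `write_field_grid()` returns `path` invisibly;
#'   `read_field_grid()` returns a `field_grid` (origin taken from the
#'   sform offset when present).
#' @export
write_field_grid <- function(grid, path) {
  stopifnot(inherits(grid, "field_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- rep(grid$voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_field_grid
#' @export
read_field_grid <- function(path) {
  img <- RNifti::readNifti(path)
  field_grid(array(as.numeric(img), dim = dim(img)),
             voxel_size = RNifti::pixdim(img)[1])
}
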