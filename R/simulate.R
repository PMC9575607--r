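#' A stimulation parameter setting
#'
#' One device setting: integer stimulation frequency (1-150 Hz) and
#' integer inter-site phase difference (degrees).  The phase is stored as
#' given -- the optimizer works on an unwrapped axis where negative values
#' are meaningful -- and is wrapped into [0, 359] only when reported to
#' the device (see [device_phase()]).
#'
#' @param frequency Stimulation frequency, Hz (integer, 1-150).
#' @param phase_diff Inter-site phase difference, degrees (integer, any
#'   sign).
#' @return A list of class `stim_params`.
#' @export
stim_params <- function(frequency, phase_diff) {
  stopifnot(is.finite(frequency), is.finite(phase_diff))
  if (abs(frequency - round(frequency)) > 1e-9 ||
      abs(phase_diff - round(phase_diff)) > 1e-9)
    stop("device parameters must be integers; use round_to_device()")
  frequency <- as.integer(round(frequency))
  phase_diff <- as.integer(round(phase_diff))
  if (frequency < 1L || frequency > 150L)
    stop("frequency must be within 1-150 Hz")
  structure(list(frequency = frequency, phase_diff = phase_diff),
            class = "stim_params")
}

#' @rdname stim_params
#' @param p A `stim_params`.
#' @return `device_phase()` returns the phase wrapped into [0, 359].
#' @export
device_phase <- function(p) {
  stopifnot(inherits(p, "stim_params"))
  ((p$phase_diff %% 360) + 360) %% 360
}

#' @export
print.stim_params <- function(x, ...) {
  cat(sprintf("stim: %d Hz, phase %d deg (device %d deg)\n",
              x$frequency, x$phase_diff, device_phase(x)))
  invisible(x)
}

#' Hidden stimulation-response surface of the simulated brain
#'
#' Stands in for the unknown individual relationship between stimulation
#' parameters and frontoparietal coupling: the inter-ROI population
#' correlation is a Gaussian bump over (frequency, phase) space,
#' \deqn{r(f,\phi) = r_{base} + (r_{max}-r_{base})
#'   \exp\{-(\Delta f/w_f)^2 - (\Delta\phi_{circ}/w_\phi)^2\},}
#' with the phase distance measured on the circle (wrap at 360 deg).  The
#' default optimum sits at 6 Hz / 0 deg, mirroring the theta-band prior
#' used to centre the optimizer's initial triangle.
#'
#' @param f_opt Optimal frequency, Hz (default 6).
#' @param phi_opt Optimal phase difference, degrees (default 0).
#' @param r_max Peak coupling (default 0.8).
#' @param r_base Off-target coupling (default 0).
#' @param width_f Frequency width of the bump, Hz (default 20).
#' @param width_phi Phase width, degrees (default 60).
#' @param noise_sd SD of additive white measurement noise, in units of the
#'   unit-variance coupled BOLD component (default 1).
#' @param seed Optional default seed for [simulate_run()].
#' @return A list of class `surface_model`.
#' @export
surface_model <- function(f_opt = 6, phi_opt = 0, r_max = 0.8, r_base = 0,
                          width_f = 20, width_phi = 60, noise_sd = 1,
                          seed = NULL) {
  stopifnot(r_base > -1, r_base <= r_max, r_max < 1,
            width_f > 0, width_phi > 0, noise_sd >= 0)
  structure(list(f_opt = f_opt, phi_opt = phi_opt, r_max = r_max,
                 r_base = r_base, width_f = width_f, width_phi = width_phi,
                 noise_sd = noise_sd, seed = seed),
            class = "surface_model")
}

wrap_phase_dist <- function(dphi) {
  d <- abs(dphi) %% 360
  pmin(d, 360 - d)
}

#' Target coupling for a parameter setting
#'
#' @param m A [surface_model()].
#' @param p A [stim_params()].
#' @return The population inter-ROI correlation targeted when stimulating
#'   at `p` (deterministic).
#' @export
surface_coupling <- function(m, p) {
  stopifnot(inherits(m, "surface_model"), inherits(p, "stim_params"))
  df <- (p$frequency - m$f_opt) / m$width_f
  dp <- wrap_phase_dist(p$phase_diff - m$phi_opt) / m$width_phi
  m$r_base + (m$r_max - m$r_base) * exp(-df^2 - dp^2)
}

#' Cardiac and respiratory phase traces
#'
#' Idealized periodic physiological phases sampled at the scan TR:
#' \eqn{\phi_t = 2\pi\,\mathrm{rate}\,t \bmod 2\pi}.  These are the phase
#' inputs that RETROICOR-style Fourier regressors expand.
#'
#' @param n_samples Number of TR samples.
#' @param tr Repetition time, s.
#' @param cardiac_hz Cardiac rate, Hz (default 1.1, i.e. 66 bpm).
#' @param resp_hz Respiratory rate, Hz (default 0.25).
#' @return List with numeric vectors `cardiac` and `resp`, radians in
#'   [0, 2*pi).
#' @export
make_physio_traces <- function(n_samples, tr, cardiac_hz = 1.1, resp_hz = 0.25) {
  stopifnot(n_samples >= 0, tr > 0, cardiac_hz > 0, resp_hz > 0)
  t <- (seq_len(n_samples) - 1) * tr
  list(cardiac = (2 * pi * cardiac_hz * t) %% (2 * pi),
       resp = (2 * pi * resp_hz * t) %% (2 * pi))
}

#' Nuisance structure of the simulated acquisition
#'
#' Amplitudes (in units of the unit-variance coupled BOLD component) of
#' the additive nuisance processes painted onto the ROI signals: slow
#' polynomial drift, linear leakage of six rigid-body motion channels
#' (random-walk traces), white-matter/CSF compartment signals, and
#' sinusoids of the cardiac/respiratory phases.  Setting all amplitudes to
#' zero leaves pure coupled signal plus white measurement noise.
#'
#' @param drift_amp Drift amplitude (default 0.5).
#' @param drift_order Polynomial order of the drift (default 3).
#' @param motion_amp Motion leakage amplitude (default 0.3).
#' @param motion_spike_prob Per-sample probability of a motion spike, an
#'   abrupt jump in the motion traces (default 0: off).
#' @param wmcsf_amp WM/CSF leakage amplitude (default 0.3).
#' @param physio_amp Physiological amplitude (default 0.2).
#' @param cardiac_hz,resp_hz Physiological rates, Hz (defaults 1.13 and
#'   0.31, i.e. about 68 bpm and 19 breaths/min, chosen incommensurate with
#'   the 0.5 Hz sampling rate so the aliased RETROICOR harmonics of the two
#'   traces stay linearly independent at TR 2 s).
#' @return A list of class `nuisance_spec`.
#' @export
nuisance_spec <- function(drift_amp = 0.5, drift_order = 3,
                          motion_amp = 0.3, motion_spike_prob = 0,
                          wmcsf_amp = 0.3, physio_amp = 0.2,
                          cardiac_hz = 1.13, resp_hz = 0.31) {
  stopifnot(drift_amp >= 0, drift_order >= 0, motion_amp >= 0,
            motion_spike_prob >= 0, motion_spike_prob <= 1,
            wmcsf_amp >= 0, physio_amp >= 0, cardiac_hz > 0, resp_hz > 0)
  structure(list(drift_amp = drift_amp, drift_order = drift_order,
                 motion_amp = motion_amp, motion_spike_prob = motion_spike_prob,
                 wmcsf_amp = wmcsf_amp, physio_amp = physio_amp,
                 cardiac_hz = cardiac_hz, resp_hz = resp_hz),
            class = "nuisance_spec")
}

# Draw a pair of series with exact population correlation r via
# shared-latent mixing: x = sqrt(|r|) s + sqrt(1-|r|) e1,
# y = sign(r) sqrt(|r|) s + sqrt(1-|r|) e2, s/e1/e2 iid unit normal.
coupled_pair <- function(r, n) {
  s <- stats::rnorm(n); e1 <- stats::rnorm(n); e2 <- stats::rnorm(n)
  a <- sqrt(abs(r)); b <- sqrt(1 - abs(r))
  cbind(a * s + b * e1, sign(r + (r == 0)) * a * s + b * e2)
}

# Simulation context: pre-draws all run-level nuisance structure from the
# master seed and one RNG substream seed per block, so blocks can be
# generated incrementally (closed loop) or in one pass (simulate_run) with
# identical results.
sim_context <- function(run, model, seed, nuisance = nuisance_spec()) {
  stopifnot(inherits(run, "run_schedule"), inherits(model, "surface_model"))
  n <- run$n_samples
  nb <- nrow(run$blocks)
  tr <- run$tr
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  block_seeds <- sample.int(.Machine$integer.max - 1L, nb)

  tsc <- if (n > 1) 2 * (seq_len(n) - 1) / (n - 1) - 1 else 0
  drift_coef <- matrix(stats::rnorm(2 * nuisance$drift_order, sd = 1), ncol = 2)
  drift <- if (nuisance$drift_order > 0)
    nuisance$drift_amp * stats::poly(tsc, nuisance$drift_order, raw = FALSE,
                                     simple = TRUE) %*% drift_coef * sqrt(n)
  else matrix(0, n, 2)

  steps <- matrix(stats::rnorm(n * 6, sd = 0.05), n, 6)
  if (nuisance$motion_spike_prob > 0) {
    spikes <- matrix(stats::runif(n * 6) < nuisance$motion_spike_prob, n, 6)
    steps <- steps + spikes * matrix(stats::rnorm(n * 6, sd = 1), n, 6)
  }
  motion <- apply(steps, 2, cumsum)
  motion_load <- matrix(stats::rnorm(12, sd = 1), 6, 2)

  ar_smooth <- function(x) as.numeric(stats::filter(x, 0.8, method = "recursive"))
  wm <- ar_smooth(stats::rnorm(n, sd = sqrt(1 - 0.8^2)))
  csf <- ar_smooth(stats::rnorm(n, sd = sqrt(1 - 0.8^2)))
  wm_load <- stats::rnorm(2, sd = 1)
  csf_load <- stats::rnorm(2, sd = 1)

  physio <- make_physio_traces(n, tr, nuisance$cardiac_hz, nuisance$resp_hz)
  physio_shift <- stats::runif(4, 0, 2 * pi)

  nuis <- drift +
    nuisance$motion_amp * scale(motion, scale = FALSE) %*% motion_load +
    nuisance$wmcsf_amp * cbind(wm * wm_load[1] + csf * csf_load[1],
                               wm * wm_load[2] + csf * csf_load[2]) +
    nuisance$physio_amp *
      cbind(sin(physio$cardiac + physio_shift[1]) + sin(physio$resp + physio_shift[2]),
            sin(physio$cardiac + physio_shift[3]) + sin(physio$resp + physio_shift[4]))

  block_samples <- function(b) {
    blk <- run$blocks[b, ]
    i0 <- as.integer(round(blk$onset / tr))
    i1 <- if (b < nb) as.integer(round(run$blocks$onset[b + 1] / tr)) else n
    (i0 + 1):i1                      # 1-based rows of this block's segment
  }

  gen_block <- function(b, params, hemodynamic_delay = 6, window_s = NULL) {
    stopifnot(inherits(params, "stim_params"))
    rows <- block_samples(b)
    blk <- run$blocks[b, ]
    if (is.null(window_s)) window_s <- blk$stim_duration
    tt <- (rows - 1) * tr
    r_target <- surface_coupling(model, params)
    in_win <- tt >= blk$onset + hemodynamic_delay &
      tt < blk$onset + hemodynamic_delay + window_s
    set.seed(block_seeds[b])
    sig <- matrix(0, length(rows), 2)
    sig[in_win, ] <- coupled_pair(r_target, sum(in_win))
    sig[!in_win, ] <- coupled_pair(model$r_base, sum(!in_win))
    noise <- matrix(stats::rnorm(2 * length(rows), sd = model$noise_sd),
                    ncol = 2)
    list(rows = rows, data = sig + noise + nuis[rows, , drop = FALSE])
  }

  list(n = n, tr = tr, run = run, model = model, nuisance = nuisance,
       seed = seed, motion = motion, wm = wm, csf = csf,
       cardiac_phase = physio$cardiac, resp_phase = physio$resp,
       block_samples = block_samples, gen_block = gen_block)
}

assemble_roi_timeseries <- function(ctx, data, block_params) {
  structure(list(tr = ctx$tr, data = data, motion = ctx$motion,
                 wm = ctx$wm, csf = ctx$csf,
                 cardiac_phase = ctx$cardiac_phase,
                 resp_phase = ctx$resp_phase,
                 block_params = block_params, seed = ctx$seed),
            class = "roi_timeseries")
}

#' Simulate a two-ROI BOLD run under a schedule of stimulation settings
#'
#' Generates TR-sampled frontal/parietal ROI mean signals whose inter-ROI
#' correlation inside each block's (hemodynamically lagged) evaluation
#' window equals the hidden response surface's value for that block's
#' stimulation parameters, and `r_base` elsewhere.  The coupling onset
#' lags the block onset by `hemodynamic_delay` seconds, matching the shift
#' of the scoring window.  Nuisance structure (drift, motion leakage,
#' WM/CSF, physiological sinusoids) and white measurement noise are added
#' on top.  Fully reproducible from `seed`: block signal substreams are
#' derived by counter, so the same block gets the same draw regardless of
#' how the run is generated.
#'
#' @param run A `run_schedule`.
#' @param model A [surface_model()].
#' @param params_per_block List of [stim_params()], one per block.
#' @param seed Integer seed (defaults to `model$seed`).
#' @param nuisance A [nuisance_spec()].
#' @param hemodynamic_delay Coupling onset lag, s (default 6).
#' @param window_s Coupled-window length, s (default `NULL`: each
#'   block's stimulation duration, 20 s in the standard schedule, so the
#'   lagged coupled period always matches the scoring window).
#' @return An object of class `roi_timeseries`: list with `tr`, `data`
#'   (samples x 2, columns frontal/parietal), `motion` (samples x 6),
#'   `wm`, `csf`, `cardiac_phase`, `resp_phase`, `block_params`, `seed`.
#' @export
simulate_run <- function(run, model, params_per_block, seed = model$seed,
                         nuisance = nuisance_spec(),
                         hemodynamic_delay = 6, window_s = NULL) {
  if (is.null(seed)) stop("a seed is required (argument or model$seed)")
  if (length(params_per_block) != nrow(run$blocks))
    stop("need exactly one stim_params per block (",
         nrow(run$blocks), " blocks, ", length(params_per_block), " given)")
  ctx <- sim_context(run, model, seed, nuisance)
  data <- matrix(NA_real_, ctx$n, 2, dimnames = list(NULL, c("frontal", "parietal")))
  for (b in seq_len(nrow(run$blocks))) {
    seg <- ctx$gen_block(b, params_per_block[[b]], hemodynamic_delay, window_s)
    data[seg$rows, ] <- seg$data
  }
  bp <- data.frame(
    block = seq_along(params_per_block),
    frequency = vapply(params_per_block, function(p) p$frequency, numeric(1)),
    phase_diff = vapply(params_per_block, function(p) p$phase_diff, numeric(1)))
  assemble_roi_timeseries(ctx, data, bp)
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("Two-ROI BOLD time series: %d samples at TR %g s, %d blocks (seed %d)\n",
              nrow(x$data), x$tr, nrow(x$block_params), x$seed))
  invisible(x)
}

#' Paint a simulated run into a toy 4-D NIfTI volume
#'
#' Writes a small 4-D volume in which the frontal and parietal ROI signals
#' are painted into two sphere masks (all other voxels zero), so the
#' NIfTI-reading path of a real-time pipeline can be exercised end to end
#' against [extract_roi_series()].
#'
#' @param ts A `roi_timeseries`.
#' @param frontal_mask,parietal_mask `roi_mask` objects on a common grid.
#' @param path Output path (`.nii`).
#' @return `path`, invisibly.
#' @export
paint_roi_volume <- function(ts, frontal_mask, parietal_mask, path) {
  stopifnot(inherits(ts, "roi_timeseries"),
            inherits(frontal_mask, "roi_mask"),
            inherits(parietal_mask, "roi_mask"),
            all(dim(frontal_mask$mask) == dim(parietal_mask$mask)))
  d <- dim(frontal_mask$mask)
  n <- nrow(ts$data)
  vol <- array(0, c(d, n))
  for (t in seq_len(n)) {
    v <- array(0, d)
    v[frontal_mask$mask] <- ts$data[t, 1]
    v[parietal_mask$mask] <- ts$data[t, 2]
    vol[, , , t] <- v
  }
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(rep(frontal_mask$spec$voxel_size, 3), ts$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a simulated run as a TSV table plus JSON sidecar
#'
#' One row per sample (frontal, parietal, six motion channels, wm, csf,
#' cardiac/respiratory phase); the sidecar records tr, seed and the
#' per-block stimulation parameters.
#'
#' @param ts A `roi_timeseries`.
#' @param path Output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  tab <- data.frame(frontal = ts$data[, 1], parietal = ts$data[, 2],
                    ts$motion, wm = ts$wm, csf = ts$csf,
                    cardiac_phase = ts$cardiac_phase,
                    resp_phase = ts$resp_phase)
  names(tab)[3:8] <- paste0("motion", 1:6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(list(tr = ts$tr, seed = ts$seed,
                            block_params = ts$block_params),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
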