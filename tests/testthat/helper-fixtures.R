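# Shared fixtures for the test suite.

# The sharply peaked, noise-free response surface used by the recovery
# benchmarks: chosen so that, at the benchmark window length (100 samples,
# per-window Fisher-z SE ~0.10), parameter points outside the acceptance
# neighbourhood of the optimum are deficient by >= 5 SE and each integer
# step near the optimum moves z by >= 2 SE.
benchmark_surface <- function() {
  surface_model(f_opt = 6, phi_opt = 0, r_max = 0.9, r_base = 0,
                width_f = 2, width_phi = 5, noise_sd = 0)
}

# Long-block schedule for the recovery benchmarks: 100-sample windows.
benchmark_schedule <- function() {
  build_run_schedule(n_blocks = 15, stim_s = 200, rest_s = 20)
}

# Two vectors with exactly the requested sample correlation, built by
# orthonormalization (independent of the connectivity code under test).
vectors_with_correlation <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- scale(stats::rnorm(n))[, 1]
  w <- stats::rnorm(n)
  w <- stats::residuals(stats::lm(w ~ x))
  w <- w / sqrt(sum(w^2) / (n - 1))
  y <- r * x + sqrt(1 - r^2) * w
  cbind(x, y)
}

# A roi_timeseries wrapper around raw signal matrices, with flat nuisance
# channels, for unit tests that bypass the simulator.
manual_roi_timeseries <- function(data, tr = 2) {
  n <- nrow(data)
  structure(list(tr = tr, data = data,
                 motion = matrix(stats::rnorm(n * 6, sd = 1e-4), n, 6),
                 wm = stats::rnorm(n, sd = 1e-4),
                 csf = stats::rnorm(n, sd = 1e-4),
                 cardiac_phase = (2 * pi * 1.13 * 2 * (seq_len(n) - 1)) %% (2 * pi),
                 resp_phase = (2 * pi * 0.31 * 2 * (seq_len(n) - 1)) %% (2 * pi),
                 block_params = NULL, seed = 0L),
            class = "roi_timeseries")
}
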