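test_that("sphere mask matches a brute-force voxel count", {
  spec <- roi_mask_spec(center = c(-45, 49, 27), radius = 10, voxel_size = 2,
                        dim = c(30, 30, 30), origin = c(-75, 19, -3))
  msk <- sphere_mask(spec)
  # independent brute force over every voxel centre
  cnt <- 0L
  for (i in 0:29) for (j in 0:29) for (k in 0:29) {
    p <- spec$origin + 2 * c(i, j, k)
    if (sum((p - spec$center)^2) <= 100) cnt <- cnt + 1L
  }
  expect_equal(msk$n_voxels, cnt)
  # volume within 5% of (4/3) pi r^3 at 2-mm voxels
  expect_equal(msk$n_voxels * 8, 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("sphere mask handles degenerate radii and off-grid centres", {
  base <- roi_mask_spec(center = c(10, 10, 10), radius = 0.9, voxel_size = 2,
                        dim = c(11, 11, 11), origin = c(0, 0, 0))
  expect_equal(sphere_mask(base)$n_voxels, 1)   # centre on a voxel centre
  off <- roi_mask_spec(center = c(500, 500, 500), radius = 5, voxel_size = 2,
                       dim = c(11, 11, 11), origin = c(0, 0, 0))
  expect_error(suppressWarnings(sphere_mask(off)), "empty mask")
  clip <- roi_mask_spec(center = c(1, 10, 10), radius = 6, voxel_size = 2,
                        dim = c(11, 11, 11), origin = c(0, 0, 0))
  expect_warning(sphere_mask(clip), "clipped")
})

test_that("roi masks round-trip through NIfTI and extract mean series", {
  spec <- roi_mask_spec(center = c(10, 10, 10), radius = 5, voxel_size = 2,
                        dim = c(11, 11, 11), origin = c(0, 0, 0))
  msk <- sphere_mask(spec)
  mpath <- withr::local_tempfile(fileext = ".nii")
  write_roi_mask(msk, mpath)
  img <- RNifti::readNifti(mpath)
  expect_equal(sum(img), msk$n_voxels)

  # paint a known signal into the mask of a toy 4-D volume
  vol <- array(0, c(11, 11, 11, 5))
  sig <- c(1, 2, 3, 4, 5)
  for (t in 1:5) vol[, , , t][msk$mask] <- sig[t]
  vpath <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(vol), vpath)
  expect_equal(extract_roi_series(vpath, msk), sig)
})

test_that("painted toy volumes round-trip the simulated ROI signals", {
  run <- build_run_schedule(n_blocks = 2)
  ts <- simulate_run(run, surface_model(), rep(list(stim_params(6, 0)), 2),
                     seed = 17)
  grid <- list(voxel_size = 2, dim = c(20, 20, 20), origin = c(0, 0, 0))
  fm <- sphere_mask(roi_mask_spec(c(10, 10, 10), radius = 5,
                                  voxel_size = 2, dim = grid$dim,
                                  origin = grid$origin))
  pm <- sphere_mask(roi_mask_spec(c(28, 28, 28), radius = 5,
                                  voxel_size = 2, dim = grid$dim,
                                  origin = grid$origin))
  path <- withr::local_tempfile(fileext = ".nii")
  paint_roi_volume(ts, fm, pm, path)
  expect_equal(extract_roi_series(path, fm), unname(ts$data[, 1]),
               tolerance = 1e-6)
  expect_equal(extract_roi_series(path, pm), unname(ts$data[, 2]),
               tolerance = 1e-6)
})

test_that("nuisance design has the documented column families in order", {
  ts <- manual_roi_timeseries(matrix(stats::rnorm(200), 100, 2))
  X <- build_nuisance_regressors(ts, poly_order = 3, retroicor_order = 2)
  expect_equal(colnames(X),
               c("poly0", "poly1", "poly2", "poly3",
                 paste0("motion", 1:6), "wm", "csf",
                 "cardiac_cos1", "cardiac_sin1", "cardiac_cos2", "cardiac_sin2",
                 "resp_cos1", "resp_sin1", "resp_cos2", "resp_sin2"))
  # P0 = 1; P1 linear from -1 to 1 with zero mean at even counts
  expect_equal(X[, "poly0"], rep(1, 100))
  expect_equal(X[, "poly1"], seq(-1, 1, length.out = 100))
  expect_equal(mean(X[, "poly1"]), 0)
  # P2, P3 satisfy the Legendre recurrence values at the ends
  expect_equal(unname(X[c(1, 100), "poly2"]), c(1, 1))
  expect_equal(unname(X[c(1, 100), "poly3"]), c(-1, 1))
  # intercept-only design
  X0 <- build_nuisance_regressors(ts, poly_order = 0, retroicor_order = 0)
  expect_equal(colnames(X0), c("poly0", paste0("motion", 1:6), "wm", "csf"))
})

test_that("constant phases give the degenerate RETROICOR columns", {
  ts <- manual_roi_timeseries(matrix(stats::rnorm(40), 20, 2))
  ts$cardiac_phase <- rep(0, 20)
  X <- build_nuisance_regressors(ts, poly_order = 0, retroicor_order = 2)
  expect_equal(unname(X[, "cardiac_cos1"]), rep(1, 20))
  expect_equal(unname(X[, "cardiac_sin1"]), rep(0, 20))
  expect_equal(unname(X[, "cardiac_cos2"]), rep(1, 20))
  expect_equal(unname(X[, "cardiac_sin2"]), rep(0, 20))
})

test_that("residualization matches the normal equations and is idempotent", {
  set.seed(21)
  Y <- matrix(stats::rnorm(100), 50, 2)
  X <- cbind(1, matrix(stats::rnorm(200), 50, 4))
  R <- residualize(Y, X)
  # independent normal-equations solution
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  expect_equal(R, Y - X %*% beta, tolerance = 1e-10, ignore_attr = TRUE)
  # orthogonality to every design column
  expect_lt(max(abs(t(X) %*% R)) / max(abs(Y)), 1e-8)
  # idempotence
  expect_equal(residualize(R, X), R, tolerance = 1e-10)
  # trivial cases
  expect_equal(residualize(rep(3, 10), matrix(1, 10, 1)),
               matrix(0, 10, 1), ignore_attr = TRUE)
  expect_equal(residualize(X[, 2], X), matrix(0, 50, 1),
               tolerance = 1e-10, ignore_attr = TRUE)
  # errors and rank handling
  expect_error(residualize(Y[1:3, ], X[1:3, ]), "more samples")
  expect_warning(residualize(Y, cbind(X, X[, 2])), "rank deficient")
})

test_that("windowed connectivity computes Pearson r with Fisher z", {
  W <- vectors_with_correlation(0.9, 20)
  out <- windowed_connectivity(W, c(0, 20), 7)
  expect_true(out$valid)
  expect_equal(out$r, 0.9)
  expect_equal(out$z, atanh(0.9))
  expect_equal(round(out$z, 4), 1.4722)
  expect_equal(out$block_index, 7)
  expect_equal(out$n_samples, 20)

  # orthogonal channels: z = 0
  W0 <- vectors_with_correlation(0, 16)
  expect_equal(windowed_connectivity(W0, c(0, 16))$z, 0)

  # identical channels: clipped r, finite z with the documented clip
  x <- stats::rnorm(12)
  outc <- windowed_connectivity(cbind(x, x), c(0, 12))
  expect_equal(outc$r, 1)
  expect_equal(outc$z, atanh(1 - 1e-7))
  expect_gt(outc$z, 8)
  # zero variance marks the window invalid instead of erroring
  flat <- windowed_connectivity(cbind(rep(1, 10), stats::rnorm(10)), c(0, 10))
  expect_false(flat$valid)
  expect_true(is.na(flat$z))
  expect_error(windowed_connectivity(W, c(0, 3)), "at least 4")
})

test_that("Fisher transform is odd and strictly increasing", {
  rs <- seq(-0.95, 0.95, by = 0.05)
  zs <- vapply(rs, function(r)
    windowed_connectivity(vectors_with_correlation(r, 30), c(0, 30))$z,
    numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_equal(zs, -rev(zs), tolerance = 1e-10)
})

test_that("online scoring is causal: truncated feed reproduces the outcome", {
  run <- build_run_schedule()
  m <- surface_model(noise_sd = 0.3)
  ts <- simulate_run(run, m, rep(list(stim_params(6, 0)), 15), seed = 31)
  for (b in c(3, 9, 15)) {
    full <- evaluate_block_online(ts, run, b)
    n_end <- block_window_samples(run, b)[2]
    trunc <- ts
    trunc$data <- ts$data[seq_len(n_end), , drop = FALSE]
    trunc$motion <- ts$motion[seq_len(n_end), , drop = FALSE]
    trunc$wm <- ts$wm[seq_len(n_end)]
    trunc$csf <- ts$csf[seq_len(n_end)]
    trunc$cardiac_phase <- ts$cardiac_phase[seq_len(n_end)]
    trunc$resp_phase <- ts$resp_phase[seq_len(n_end)]
    got <- evaluate_block_online(trunc, run, b)
    expect_equal(got$z, full$z)
    expect_equal(got$r, full$r)
  }
})

test_that("nuisance regression recovers the coupling buried in structure", {
  # per-setting mean z within 2 SE of atanh(r), SE = 1/sqrt((n-3)*blocks)
  run <- build_run_schedule(n_blocks = 10, stim_s = 100, rest_s = 20)
  m <- surface_model(r_max = 0.6, r_base = 0, noise_sd = 0)
  nb <- 5; n_win <- 50
  zs <- unlist(lapply(1:nb, function(s) {
    ts <- simulate_run(run, m, rep(list(stim_params(6, 0)), 10), seed = 60 + s)
    vapply(1:10, function(b) evaluate_block_online(ts, run, b)$z, numeric(1))
  }))
  se <- 1 / sqrt((n_win - 3) * length(zs))
  expect_lt(abs(mean(zs) - atanh(0.6)), 2 * se + 0.6 / (2 * (n_win - 1)))
})

test_that("connectivity log appends tab-separated outcomes", {
  W <- vectors_with_correlation(0.5, 10)
  outs <- list(windowed_connectivity(W, c(0, 10), 1),
               windowed_connectivity(W, c(0, 10), 2))
  params <- list(stim_params(6, 0), stim_params(7, -2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_log(outs, params, path)
  write_connectivity_log(outs[1], params[1], path)
  log <- utils::read.delim(path)
  expect_equal(nrow(log), 3)
  expect_equal(log$block_index, c(1, 2, 1))
  expect_equal(log$phase, c(0, 358, 0))
})
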