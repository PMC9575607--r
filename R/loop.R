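#' Run the training phase of the closed loop
#'
#' Plays the full online protocol over the training schedules (by default
#' two 15-block runs, a 30-evaluation budget): for each block the
#' optimizer proposes a parameter point, the point is rounded to device
#' integers, the simulator generates the block's samples, the
#' connectivity engine scores the hemodynamically shifted window causally
#' (expanding nuisance design), and the outcome is fed back into the
#' optimizer.  Invalid windows count as failed blocks and the loop
#' continues.  The simplex state is carried across the run boundary,
#' which is recorded as a marker in the history.
#'
#' @param model A [surface_model()] (the simulated brain).
#' @param arm `"experimental"` (maximize connectivity) or `"control"`
#'   (minimize).
#' @param seed Integer seed; each training run uses `seed + run index`.
#' @param schedules List of `run_schedule`s (default two standard runs).
#' @param state Optional pre-built [simplex_state()]; its mode must match
#'   the arm.
#' @param nuisance A [nuisance_spec()].
#' @param poly_order,retroicor_order Online nuisance-regression orders.
#' @return An object of class `training_result`: list with `arm`, `mode`,
#'   `state`, `history` (with a `run` column), `outcomes`,
#'   `params_per_block`, `selected_params` (best under the arm's mode)
#'   and `best_z`.
#' @export
run_training <- function(model, arm = c("experimental", "control"), seed,
                         schedules = list(build_run_schedule(),
                                          build_run_schedule()),
                         state = NULL, nuisance = nuisance_spec(),
                         poly_order = 3, retroicor_order = 2) {
  arm <- match.arg(arm)
  mode <- if (arm == "experimental") "maximize" else "minimize"
  if (is.null(state)) state <- simplex_state(mode = mode)
  if (state$mode != mode)
    stop("optimizer mode '", state$mode, "' does not match arm '", arm, "'")

  outcomes <- list(); params_all <- list(); run_of_eval <- integer(0)
  for (rr in seq_along(schedules)) {
    run <- schedules[[rr]]
    ctx <- sim_context(run, model, seed + rr, nuisance)
    data <- matrix(NA_real_, ctx$n, 2,
                   dimnames = list(NULL, c("frontal", "parietal")))
    params_run <- vector("list", nrow(run$blocks))
    for (b in seq_len(nrow(run$blocks))) {
      prop <- tryCatch(propose_next(state),
                       tacsloop_degenerate_simplex = function(e) NULL)
      if (is.null(prop)) {
        state <- restart_simplex(state)
        prop <- propose_next(state)
      }
      params <- round_to_device(prop$point, state$freq_bounds)
      seg <- ctx$gen_block(b, params)
      data[seg$rows, ] <- seg$data
      ts <- assemble_roi_timeseries(ctx, data, NULL)
      out <- evaluate_block_online(ts, run, b, poly_order, retroicor_order)
      state <- update(state, params, if (out$valid) out$z else NA_real_)
      outcomes[[length(outcomes) + 1L]] <- out
      params_run[[b]] <- params
      run_of_eval <- c(run_of_eval, rr)
    }
    params_all <- c(params_all, params_run)
  }
  history <- state$history
  history$run <- run_of_eval
  structure(list(arm = arm, mode = mode, state = state, history = history,
                 outcomes = outcomes, params_per_block = params_all,
                 selected_params = state$best$params,
                 best_z = state$best$outcome, seed = seed),
            class = "training_result")
}

#' Run the test phase at fixed stimulation parameters
#'
#' One 15-block run with every block stimulated at `params`, scored with
#' the same causal connectivity engine as training.
#'
#' @param params The selected [stim_params()].
#' @param model A [surface_model()].
#' @param seed Integer seed.
#' @param schedule A `run_schedule` (default the standard 15-block run).
#' @param nuisance A [nuisance_spec()].
#' @param poly_order,retroicor_order Online nuisance-regression orders.
#' @return An object of class `test_result`: list with `params`,
#'   `outcomes`, `z` (vector of valid z values, one per block),
#'   `mean_z`, `sd_z`, `seed`.
#' @export
run_test <- function(params, model, seed,
                     schedule = build_run_schedule(),
                     nuisance = nuisance_spec(),
                     poly_order = 3, retroicor_order = 2) {
  stopifnot(inherits(params, "stim_params"))
  nb <- nrow(schedule$blocks)
  ts <- simulate_run(schedule, model, rep(list(params), nb), seed = seed,
                     nuisance = nuisance)
  outcomes <- lapply(seq_len(nb), function(b)
    evaluate_block_online(ts, schedule, b, poly_order, retroicor_order))
  z <- vapply(outcomes, function(o) o$z, numeric(1))
  structure(list(params = params, outcomes = outcomes, z = z,
                 mean_z = mean(z, na.rm = TRUE),
                 sd_z = stats::sd(z, na.rm = TRUE), seed = seed),
            class = "test_result")
}

#' Run the complete closed-loop protocol for one simulated participant
#'
#' Training (two runs, online optimization under the arm's mode), a
#' washout rest interval recorded in the session log (the simulated brain
#' carries no aftereffect state, so the washout is a protocol marker
#' only), then the test run at the selected parameters.
#'
#' @param model A [surface_model()].
#' @param arm `"experimental"` or `"control"`.
#' @param seed Integer seed (training runs use `seed + 1`, `seed + 2`;
#'   the test run `seed + 100`).
#' @param washout_s Washout rest duration, s (default 410, a 6-min-50-s
#'   resting scan).
#' @param ... Passed on to [run_training()] and [run_test()]
#'   (`schedules`/`nuisance`/regression orders).
#' @param nuisance A [nuisance_spec()].
#' @return An object of class `loop_result`: `arm`, `selected_params`,
#'   `training` (a `training_result`), `test` (a `test_result`),
#'   `summary` (mean/SD of test z), `session_log`, `seed`.
#' @export
run_protocol <- function(model, arm = c("experimental", "control"), seed,
                         washout_s = 410, nuisance = nuisance_spec(), ...) {
  arm <- match.arg(arm)
  training <- run_training(model, arm, seed, nuisance = nuisance, ...)
  if (is.null(training$selected_params))
    stop("training produced no valid outcome; cannot select parameters")
  test <- run_test(training$selected_params, model, seed + 100,
                   nuisance = nuisance)
  log <- data.frame(
    event = c("rsfMRI_pre", "training1", "training2", "washout_rest", "test",
              "rsfMRI_post"),
    duration_s = c(410, 450, 450, washout_s, 450, 410))
  structure(list(arm = arm, selected_params = training$selected_params,
                 training = training, test = test,
                 summary = c(mean_z = test$mean_z, sd_z = test$sd_z),
                 session_log = log, seed = seed),
            class = "loop_result")
}

#' @export
print.loop_result <- function(x, ...) {
  cat(sprintf("Closed-loop protocol (%s arm, seed %d)\n", x$arm, x$seed))
  cat(sprintf("  selected: %d Hz / %d deg (training best z = %.3f)\n",
              x$selected_params$frequency, x$selected_params$phase_diff,
              x$training$best_z))
  cat(sprintf("  test run: mean z = %.3f, SD = %.3f over %d blocks\n",
              x$summary[["mean_z"]], x$summary[["sd_z"]],
              length(x$test$z)))
  invisible(x)
}

#' Candidate control conditions for the closed-loop study design
#'
#' Enumerates the candidate control-arm designs considered for the
#' protocol as (training, test) pairs.  Only condition 7 -- training by
#' min-optimization, testing at the min-optimized parameters -- lets the
#' study test both whether training changes connectivity and whether the
#' selected parameters modulate it directionally, and it is the only one
#' implemented by [run_protocol()]'s control arm; the others are listed
#' for completeness.
#'
#' @return Data frame with columns `condition`, `training`, `test` and
#'   `implemented`.
#' @export
control_conditions <- function() {
  data.frame(
    condition = 1:8,
    training = c("real stimulation, fixed conservative parameters",
                 "real stimulation, arbitrary parameters",
                 "real stimulation, optimization",
                 "sham stimulation",
                 "sham stimulation",
                 "sham stimulation",
                 "real stimulation, min-optimization",
                 "sham stimulation"),
    test = c("conservative parameters", "arbitrary parameters",
             "lowest-connectivity parameters", "optimized parameters",
             "conservative parameters", "arbitrary parameters",
             "min-optimized parameters", "sham"),
    implemented = c(rep(FALSE, 6), TRUE, FALSE))
}

#' Pooled two-sample t comparison of the arms' test-run connectivity
#'
#' Equal-variance two-sample t test on the per-block test z values with
#' `df = n1 + n2 - 2` and a two-sided p value.
#'
#' @param z_experimental,z_control Numeric vectors of test-block z values.
#' @return List with `mean_diff`, `t`, `df`, `p`.
#' @export
compare_arms <- function(z_experimental, z_control) {
  x <- z_experimental[is.finite(z_experimental)]
  y <- z_control[is.finite(z_control)]
  if (length(x) < 2 || length(y) < 2)
    stop("each arm needs at least two finite values")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(mean_diff = mean(x) - mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pooled t statistic from published summary statistics
#'
#' The textbook pooled-variance formula applied to reported means, SDs
#' and group sizes (useful for checking published summaries).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Separation between the arms' best training connectivity
#'
#' The difference between the experimental arm's best (highest) and the
#' control arm's best (lowest) online connectivity z; antisymmetric under
#' swapping the arms.
#'
#' @param best_experimental,best_control Best training z per arm.
#' @return `best_experimental - best_control`.
#' @export
connectivity_separation <- function(best_experimental, best_control) {
  best_experimental - best_control
}

#' Summarize an optimization trajectory
#'
#' Per-block table (evaluation index, triangle index, move, parameters,
#' outcome, success/failure verdict, running best) taken from the
#' optimizer history, plus -- when both arms are supplied -- the
#' between-arm separation of the best training connectivity.
#'
#' @param result A `training_result` or `loop_result` (experimental arm).
#' @param control Optional second result (control arm).
#' @return List of class `trajectory_report` with `table`, `best_z`,
#'   `n_restarts`, and `separation` (NA without a control result).
#' @export
trajectory_report <- function(result, control = NULL) {
  tr <- function(x) if (inherits(x, "loop_result")) x$training else x
  res <- tr(result)
  stopifnot(inherits(res, "training_result"))
  tab <- res$history
  sep <- NA_real_
  if (!is.null(control)) {
    ctl <- tr(control)
    sep <- connectivity_separation(res$best_z, ctl$best_z)
  }
  structure(list(table = tab, best_z = res$best_z,
                 n_restarts = sum(tab$restarted), separation = sep),
            class = "trajectory_report")
}

#' @export
print.trajectory_report <- function(x, ...) {
  cat(sprintf("Trajectory: %d evaluations, %d restart(s), best z = %.3f\n",
              nrow(x$table), x$n_restarts, x$best_z))
  if (is.finite(x$separation))
    cat(sprintf("  arm separation (best exp - best ctrl): %.3f\n", x$separation))
  invisible(x)
}
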