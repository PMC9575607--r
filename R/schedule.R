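#' Build the timing skeleton of a training or test run
#'
#' A run is a sequence of stimulation blocks, each `stim_s` seconds of tACS
#' followed by `rest_s` seconds of rest, sampled at repetition time `tr`.
#' Defaults give the standard run: 15 blocks of 20 s stimulation + 10 s
#' rest at TR = 2 s (450 s, 225 volumes).
#'
#' @param n_blocks Number of stimulation blocks (default 15).
#' @param stim_s Stimulation duration per block, s (default 20).
#' @param rest_s Rest duration per block, s (default 10).
#' @param tr Repetition time, s (default 2).  A warning is emitted when
#'   `tr` does not divide the block durations.
#' @return An object of class `run_schedule`: list with `tr`, `blocks`
#'   (data frame: index, onset, stim_duration, rest_duration), `trials`
#'   (empty until [tile_trials()]), `total_duration` and `n_samples`.
#' @export
build_run_schedule <- function(n_blocks = 15, stim_s = 20, rest_s = 10, tr = 2) {
  if (!is.finite(n_blocks) || n_blocks <= 0) stop("n_blocks must be positive")
  stopifnot(stim_s > 0, rest_s > 0, tr > 0)
  n_blocks <- as.integer(n_blocks)
  block_s <- stim_s + rest_s
  if (abs(stim_s / tr - round(stim_s / tr)) > 1e-9 ||
      abs(rest_s / tr - round(rest_s / tr)) > 1e-9)
    warning("tr does not evenly divide the block durations; ",
            "window sample indices will be rounded")
  blocks <- data.frame(index = seq_len(n_blocks),
                       onset = (seq_len(n_blocks) - 1) * block_s,
                       stim_duration = stim_s,
                       rest_duration = rest_s)
  total <- n_blocks * block_s
  structure(list(tr = tr, blocks = blocks,
                 trials = data.frame(onset = numeric(0),
                                     stim_phase = numeric(0),
                                     feedback_phase = numeric(0)),
                 total_duration = total,
                 n_samples = as.integer(round(total / tr))),
            class = "run_schedule")
}

#' Tile a run with back-to-back task trials
#'
#' The working-memory task runs continuously, irrespective of the
#' stimulation blocks: trials start at 0, `trial_s`, `2*trial_s`, ... and
#' only complete trials (ending at or before the run end) are kept.  The
#' default 4-s trial splits into a 2.5-s presentation/response phase and a
#' 1.5-s feedback phase; a standard 450-s run holds 112 complete trials.
#'
#' @param run A `run_schedule`.
#' @param trial_s Trial duration, s (default 4).
#' @param stim_phase Presentation/response phase duration, s (default 2.5).
#' @param feedback_phase Feedback phase duration, s (default 1.5).
#' @return The run with its `trials` data frame filled.
#' @export
tile_trials <- function(run, trial_s = 4, stim_phase = 2.5,
                        feedback_phase = 1.5) {
  stopifnot(inherits(run, "run_schedule"), trial_s > 0)
  n <- floor(run$total_duration / trial_s)
  onsets <- (seq_len(n) - 1) * trial_s
  run$trials <- data.frame(onset = onsets,
                           stim_phase = stim_phase,
                           feedback_phase = feedback_phase)
  run
}

#' Sample-index window used to score a block's connectivity
#'
#' The connectivity window covers the block's 20-s stimulation period
#' shifted by the hemodynamic delay: samples from
#' `round((onset + shift_s)/tr)` for `round(window_s/tr)` samples,
#' reported 0-based and half-open (`[start, end)`), so the default window
#' runs from 6 s after block onset to 26 s after onset (10 samples at
#' TR = 2 s), extending 6 s into the rest period.
#'
#' @param run A `run_schedule`.
#' @param block_index Block number (1-based).
#' @param shift_s Hemodynamic shift, s (default 6).
#' @param window_s Window length, s (default `NULL`: the block's
#'   stimulation duration, 20 s in the standard schedule).
#' @return Integer vector `c(start, end)`, 0-based half-open sample range.
#' @export
block_window_samples <- function(run, block_index, shift_s = 6, window_s = NULL) {
  stopifnot(inherits(run, "run_schedule"), shift_s >= 0)
  b <- run$blocks[run$blocks$index == block_index, ]
  if (nrow(b) != 1) stop("no block with index ", block_index)
  if (is.null(window_s)) window_s <- b$stim_duration
  stopifnot(window_s >= 0)
  start <- as.integer(round((b$onset + shift_s) / run$tr))
  len <- as.integer(round(window_s / run$tr))
  if (start + len > run$n_samples)
    stop("connectivity window of block ", block_index,
         " extends past the end of the run")
  c(start, start + len)
}

#' @export
print.run_schedule <- function(x, ...) {
  cat(sprintf("Run schedule: %d blocks (%g s stim + %g s rest), TR %g s, %g s total (%d samples)\n",
              nrow(x$blocks), x$blocks$stim_duration[1], x$blocks$rest_duration[1],
              x$tr, x$total_duration, x$n_samples))
  if (nrow(x$trials))
    cat(sprintf("  %d task trials of %g s\n", nrow(x$trials),
                x$trials$stim_phase[1] + x$trials$feedback_phase[1]))
  invisible(x)
}

#' Export a schedule as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`
#' (`stim`/`rest`/`trial`), `frequency`, `phase` (`n/a` where not
#' applicable), sorted by onset.
#'
#' @param run A `run_schedule`.
#' @param path Output path (`.tsv`).
#' @param params_per_block Optional list of [stim_params()] (one per
#'   block) filled into the stimulation rows.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(run, path, params_per_block = NULL) {
  stopifnot(inherits(run, "run_schedule"))
  b <- run$blocks
  if (!is.null(params_per_block) && length(params_per_block) != nrow(b))
    stop("need one stim_params per block")
  freq <- if (is.null(params_per_block)) rep(NA_real_, nrow(b)) else
    vapply(params_per_block, function(p) p$frequency, numeric(1))
  phase <- if (is.null(params_per_block)) rep(NA_real_, nrow(b)) else
    vapply(params_per_block, device_phase, numeric(1))
  ev <- rbind(
    data.frame(onset = b$onset, duration = b$stim_duration,
               trial_type = "stim", frequency = freq, phase = phase),
    data.frame(onset = b$onset + b$stim_duration, duration = b$rest_duration,
               trial_type = "rest", frequency = NA_real_, phase = NA_real_))
  if (nrow(run$trials))
    ev <- rbind(ev, data.frame(
      onset = run$trials$onset,
      duration = run$trials$stim_phase + run$trials$feedback_phase,
      trial_type = "trial", frequency = NA_real_, phase = NA_real_))
  ev <- ev[order(ev$onset, ev$trial_type), ]
  ev$frequency[is.na(ev$frequency)] <- NA
  out <- ev
  out$frequency <- ifelse(is.na(ev$frequency), "n/a", ev$frequency)
  out$phase <- ifelse(is.na(ev$phase), "n/a", ev$phase)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
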