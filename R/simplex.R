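#' Round a continuous parameter point to a device setting
#'
#' The stimulator accepts only integer frequency and phase, so the
#' optimizer's continuous candidates are rounded half-away-from-zero
#' (the rule that reproduces the initial triangle (6,5)/(10,-3)/(2,-3)
#' from the exact equilateral construction), the frequency is clipped to
#' the device range [1, 150], and the phase keeps its unwrapped integer
#' value (wrapped into [0, 359] only by [device_phase()]).
#'
#' @param p Continuous `(frequency, phase)` point, numeric length 2.
#' @param freq_bounds Device frequency range (default `c(1, 150)`).
#' @return A [stim_params()].
#' @export
round_to_device <- function(p, freq_bounds = c(1, 150)) {
  stopifnot(length(p) == 2, all(is.finite(p)))
  r <- sign(p) * floor(abs(p) + 0.5)     # round half away from zero
  f <- min(max(r[1], freq_bounds[1]), freq_bounds[2])
  stim_params(frequency = f, phase_diff = r[2])
}

#' Initial equilateral triangle of stimulation parameters
#'
#' Vertices at `center + circumradius * (cos a, sin a)` for the three
#' `angles`, treating the Hz axis and the degree axis as equal units, then
#' rounded to device integers.  The defaults (centre 6 Hz / 0 deg,
#' circumradius 5, angles 90/210/330 deg) give the triangle
#' (6, 5), (2, -3), (10, -3).
#'
#' @param center Triangle centre `(frequency, phase)` (default `c(6, 0)`).
#' @param circumradius Centre-to-vertex distance (default 5).
#' @param angles Vertex angles, degrees (default `c(90, 210, 330)`).
#' @return List with `exact` (3 x 2 matrix of exact vertices) and
#'   `vertices` (3 x 2 matrix of device-rounded vertices).
#' @export
init_simplex <- function(center = c(6, 0), circumradius = 5,
                         angles = c(90, 210, 330)) {
  stopifnot(length(center) == 2, length(angles) == 3)
  if (!is.finite(circumradius) || circumradius <= 0)
    stop("circumradius must be positive (zero gives a degenerate simplex)")
  a <- angles * pi / 180
  exact <- cbind(center[1] + circumradius * cos(a),
                 center[2] + circumradius * sin(a))
  rounded <- t(apply(exact, 1, function(v) {
    p <- round_to_device(v)
    c(p$frequency, p$phase_diff)
  }))
  colnames(exact) <- colnames(rounded) <- c("frequency", "phase")
  list(exact = exact, vertices = rounded)
}

#' Named presets for the initial triangle
#'
#' Two vertex sets are in circulation for the standard start (centre
#' 6 Hz / 0 deg): `"figure12"`, (6,5)/(10,-3)/(2,-3), which matches the
#' equilateral circumradius-5 construction and is the default throughout;
#' and `"section44"`, (6,5)/(1,-3)/(2,-3), whose second vertex is not ~5
#' units from the centre and which is provided verbatim as an alternative
#' rather than silently corrected.
#'
#' @param name `"figure12"` or `"section44"`.
#' @return A 3 x 2 matrix of integer vertices.
#' @export
simplex_preset <- function(name = c("figure12", "section44")) {
  name <- match.arg(name)
  v <- switch(name,
              figure12 = rbind(c(6, 5), c(10, -3), c(2, -3)),
              section44 = rbind(c(6, 5), c(1, -3), c(2, -3)))
  colnames(v) <- c("frequency", "phase")
  v
}

better <- function(a, b, mode) if (mode == "maximize") a > b else a < b

# Rank vertex indices best -> worst under the mode; ties broken in favour
# of the earlier-evaluated vertex.
order_vertices <- function(outcomes, age, mode) {
  key <- if (mode == "maximize") -outcomes else outcomes
  order(key, age)
}

#' Create the optimizer state
#'
#' Nelder-Mead simplex search over the integer (frequency, phase) space,
#' driven one evaluation at a time: [propose_next()] yields the next
#' continuous candidate, the caller rounds it with [round_to_device()],
#' measures the block's connectivity z, and feeds it back through
#' [update()].  Alongside the standard reflect/expand/contract/shrink
#' moves (coefficients alpha/gamma/rho/sigma = 1/2/0.5/0.5) the state
#' tracks a failure counter: an outcome that does not strictly improve on
#' the best-so-far (under `mode`) is a failed block, and after two
#' consecutive failures the triangle is abandoned and a new one is seeded
#' around the best parameters with the circumradius halved (floored at
#' `min_radius`).
#'
#' @param center Initial triangle centre (default `c(6, 0)`).
#' @param circumradius Initial centre-to-vertex distance (default 5).
#' @param mode `"maximize"` (experimental arm) or `"minimize"` (control).
#' @param vertices Optional explicit 3 x 2 vertex matrix (e.g. a
#'   [simplex_preset()]); overrides the equilateral construction.
#' @param angles Vertex angles for the equilateral construction.
#' @param alpha,gamma,rho,sigma Nelder-Mead reflection, expansion,
#'   contraction and shrink coefficients.
#' @param fail_limit Consecutive failures that trigger a restart
#'   (default 2).
#' @param restart_shrink Circumradius multiplier at restart (default 0.5).
#' @param min_radius Smallest restart circumradius (default 1).
#' @param restart_rotation Rotation (degrees) added to the vertex angles
#'   at each restart (default 90), so that successive restart triangles
#'   at the radius floor probe different integer neighbours of the
#'   incumbent instead of re-evaluating the same two points forever.
#' @param failure_reference `"best"` (default: a block fails when it does
#'   not improve on the best-so-far) or `"previous"` (fails when it does
#'   not improve on the immediately preceding block).
#' @param freq_bounds Device frequency range.
#' @return An object of class `simplex_state`.
#' @export
simplex_state <- function(center = c(6, 0), circumradius = 5,
                          mode = c("maximize", "minimize"),
                          vertices = NULL, angles = c(90, 210, 330),
                          alpha = 1, gamma = 2, rho = 0.5, sigma = 0.5,
                          fail_limit = 2, restart_shrink = 0.5,
                          min_radius = 1, restart_rotation = 90,
                          failure_reference = c("best", "previous"),
                          freq_bounds = c(1, 150)) {
  mode <- match.arg(mode)
  failure_reference <- match.arg(failure_reference)
  if (is.null(vertices))
    vertices <- init_simplex(center, circumradius, angles)$vertices
  stopifnot(is.matrix(vertices), all(dim(vertices) == c(3, 2)))
  structure(list(
    vertices = vertices, outcomes = rep(NA_real_, 3), age = rep(NA_real_, 3),
    mode = mode, phase = "seed", nm = NULL,
    fail_count = 0L, fail_limit = as.integer(fail_limit),
    triangle_index = 1L, n_evals = 0L,
    best = list(params = NULL, outcome = NA_real_),
    prev_outcome = NA_real_,
    center = center, circumradius = circumradius, angles = angles,
    coef = list(alpha = alpha, gamma = gamma, rho = rho, sigma = sigma),
    restart_shrink = restart_shrink, min_radius = min_radius,
    restart_rotation = restart_rotation,
    failure_reference = failure_reference, freq_bounds = freq_bounds,
    history = data.frame()),
    class = "simplex_state")
}

simplex_area <- function(v) {
  abs((v[2, 1] - v[1, 1]) * (v[3, 2] - v[1, 2]) -
      (v[3, 1] - v[1, 1]) * (v[2, 2] - v[1, 2])) / 2
}

nm_geometry <- function(state) {
  ord <- order_vertices(state$outcomes, state$age, state$mode)
  worst <- ord[3]
  centroid <- colMeans(state$vertices[ord[1:2], , drop = FALSE])
  list(ord = ord, worst = worst, centroid = centroid,
       xw = state$vertices[worst, ])
}

#' Propose the next parameter point to evaluate
#'
#' Deterministic given the state.  During seeding returns the next
#' unevaluated initial vertex; afterwards applies the Nelder-Mead rules
#' to the outcome-ordered triangle (ties ranked in favour of the
#' earlier-evaluated vertex).  A zero-area triangle raises an error of
#' class `tacsloop_degenerate_simplex`; callers restart via
#' [restart_simplex()].
#'
#' @param state A `simplex_state`.
#' @return List with `point` (continuous `(frequency, phase)`) and `move`
#'   (label: `seed1..3`, `reflect`, `expand`, `contract_out`,
#'   `contract_in`, `shrink2`, `shrink3`).
#' @export
propose_next <- function(state) {
  stopifnot(inherits(state, "simplex_state"))
  if (state$phase == "seed") {
    i <- which(is.na(state$outcomes))[1]
    return(list(point = state$vertices[i, ], move = paste0("seed", i)))
  }
  if (simplex_area(state$vertices) < 1e-9)
    stop(structure(class = c("tacsloop_degenerate_simplex", "error", "condition"),
                   list(message = "degenerate (zero-area) simplex: restart required",
                        call = sys.call())))
  g <- nm_geometry(state)
  cf <- state$coef
  switch(state$phase,
    reflect = list(point = g$centroid + cf$alpha * (g$centroid - g$xw),
                   move = "reflect"),
    expand = list(point = g$centroid + cf$gamma * (state$nm$xr - g$centroid),
                  move = "expand"),
    contract_out = list(point = g$centroid + cf$rho * (state$nm$xr - g$centroid),
                        move = "contract_out"),
    contract_in = list(point = g$centroid + cf$rho * (g$xw - g$centroid),
                       move = "contract_in"),
    shrink2 = {
      best <- state$vertices[state$nm$shrink_ord[1], ]
      v <- state$vertices[state$nm$shrink_ord[2], ]
      list(point = best + cf$sigma * (v - best), move = "shrink2")
    },
    shrink3 = {
      best <- state$vertices[state$nm$shrink_ord[1], ]
      v <- state$vertices[state$nm$shrink_ord[3], ]
      list(point = best + cf$sigma * (v - best), move = "shrink3")
    },
    stop("unknown optimizer phase: ", state$phase))
}

replace_vertex <- function(state, idx, point, value) {
  state$vertices[idx, ] <- point
  state$outcomes[idx] <- value
  state$age[idx] <- state$n_evals
  state
}

#' Restart the search with a fresh triangle around the best parameters
#'
#' Used after two consecutive failed blocks (automatically, inside
#' [update()]) or when the triangle degenerates: a new equilateral
#' triangle is seeded at the best parameters found so far (the original
#' centre when nothing valid has been measured yet) with the circumradius
#' halved, floored at `min_radius`, and the vertex angles rotated by
#' `restart_rotation` degrees so repeated restarts at the radius floor
#' probe fresh integer neighbours.
#'
#' @param state A `simplex_state`.
#' @return The restarted state (`triangle_index` incremented,
#'   `fail_count` reset, seeding phase).
#' @export
restart_simplex <- function(state) {
  stopifnot(inherits(state, "simplex_state"))
  center <- if (!is.null(state$best$params))
    c(state$best$params$frequency, state$best$params$phase_diff)
  else state$center
  state$circumradius <- max(state$min_radius,
                            state$circumradius * state$restart_shrink)
  state$center <- center
  state$angles <- (state$angles + state$restart_rotation) %% 360
  state$vertices <- init_simplex(center, state$circumradius,
                                 state$angles)$vertices
  state$outcomes <- rep(NA_real_, 3)
  state$age <- rep(NA_real_, 3)
  state$phase <- "seed"
  state$nm <- NULL
  state$fail_count <- 0L
  state$triangle_index <- state$triangle_index + 1L
  state
}

#' Feed one measured outcome back into the optimizer
#'
#' `params` must be the device rounding of the last proposed point.  An
#' invalid outcome (`NA`/non-finite, e.g. a failed connectivity window)
#' is treated as the worst possible value for the simplex bookkeeping and
#' always counts as a failed block.  A block succeeds when its outcome
#' strictly improves on the best-so-far under the state's mode (or on the
#' previous block's outcome, with `failure_reference = "previous"`);
#' success resets the failure counter and updates the incumbent, failure
#' increments the counter, and at `fail_limit` consecutive failures the
#' triangle is restarted around the incumbent via [restart_simplex()].
#'
#' @param object A `simplex_state`.
#' @param params The evaluated [stim_params()].
#' @param outcome Measured connectivity z (or `NA` for an invalid block).
#' @param ... Unused.
#' @return The updated `simplex_state`.
#' @export
update.simplex_state <- function(object, params, outcome, ...) {
  state <- object
  stopifnot(inherits(params, "stim_params"))
  prop <- propose_next(state)
  expected <- round_to_device(prop$point, state$freq_bounds)
  if (params$frequency != expected$frequency ||
      params$phase_diff != expected$phase_diff)
    stop("outcome supplied for unknown params (", params$frequency, " Hz, ",
         params$phase_diff, " deg); expected the last proposal (",
         expected$frequency, " Hz, ", expected$phase_diff, " deg)")

  valid <- length(outcome) == 1 && is.finite(outcome)
  worst_val <- if (state$mode == "maximize") -Inf else Inf
  val <- if (valid) as.numeric(outcome) else worst_val
  state$n_evals <- state$n_evals + 1L

  reference <- if (state$failure_reference == "best") state$best$outcome
               else state$prev_outcome
  success <- valid && (is.na(reference) || better(val, reference, state$mode))
  if (success) {
    if (is.na(state$best$outcome) || better(val, state$best$outcome, state$mode))
      state$best <- list(params = params, outcome = val)
    state$fail_count <- 0L
  } else {
    state$fail_count <- state$fail_count + 1L
  }
  state$prev_outcome <- if (valid) val else state$prev_outcome

  # Nelder-Mead bookkeeping for the move the outcome belongs to
  move <- prop$move
  if (startsWith(move, "seed")) {
    i <- as.integer(substring(move, 5))
    state <- replace_vertex(state, i, prop$point, val)
    if (!anyNA(state$outcomes)) state$phase <- "reflect"
  } else {
    g <- nm_geometry(state)
    ord <- g$ord
    f1 <- state$outcomes[ord[1]]; f2 <- state$outcomes[ord[2]]
    fw <- state$outcomes[ord[3]]
    if (move == "reflect") {
      if (better(val, f1, state$mode)) {
        state$nm <- list(xr = prop$point, fr = val)
        state$phase <- "expand"
      } else if (better(val, f2, state$mode)) {
        state <- replace_vertex(state, g$worst, prop$point, val)
        state$phase <- "reflect"; state$nm <- NULL
      } else if (better(val, fw, state$mode)) {
        state$nm <- list(xr = prop$point, fr = val)
        state$phase <- "contract_out"
      } else {
        state$nm <- list(xr = prop$point, fr = val)
        state$phase <- "contract_in"
      }
    } else if (move == "expand") {
      if (better(val, state$nm$fr, state$mode))
        state <- replace_vertex(state, g$worst, prop$point, val)
      else
        state <- replace_vertex(state, g$worst, state$nm$xr, state$nm$fr)
      state$phase <- "reflect"; state$nm <- NULL
    } else if (move == "contract_out") {
      if (!better(state$nm$fr, val, state$mode)) {      # fc at least as good as fr
        state <- replace_vertex(state, g$worst, prop$point, val)
        state$phase <- "reflect"; state$nm <- NULL
      } else {
        state$nm <- list(shrink_ord = ord)
        state$phase <- "shrink2"
      }
    } else if (move == "contract_in") {
      if (better(val, fw, state$mode)) {
        state <- replace_vertex(state, g$worst, prop$point, val)
        state$phase <- "reflect"; state$nm <- NULL
      } else {
        state$nm <- list(shrink_ord = ord)
        state$phase <- "shrink2"
      }
    } else if (move == "shrink2") {
      state <- replace_vertex(state, state$nm$shrink_ord[2], prop$point, val)
      state$phase <- "shrink3"
    } else if (move == "shrink3") {
      state <- replace_vertex(state, state$nm$shrink_ord[3], prop$point, val)
      state$phase <- "reflect"; state$nm <- NULL
    }
  }

  restarted <- FALSE
  if (state$fail_count >= state$fail_limit) {
    state <- restart_simplex(state)
    restarted <- TRUE
  }

  state$history <- rbind(state$history, data.frame(
    evaluation_index = state$n_evals,
    triangle_index = if (restarted) state$triangle_index - 1L else state$triangle_index,
    move = move,
    frequency = params$frequency,
    device_phase = device_phase(params),
    unwrapped_phase = params$phase_diff,
    outcome_z = if (valid) val else NA_real_,
    verdict = ifelse(success, "success", "failure"),
    restarted = restarted,
    best_z = state$best$outcome))
  state
}

#' @export
print.simplex_state <- function(x, ...) {
  cat(sprintf("Simplex optimizer (%s): %d evaluations, triangle %d, fail count %d\n",
              x$mode, x$n_evals, x$triangle_index, x$fail_count))
  if (!is.null(x$best$params))
    cat(sprintf("  best: %d Hz / %d deg, z = %.3f\n",
                x$best$params$frequency, x$best$params$phase_diff,
                x$best$outcome))
  invisible(x)
}

#' Drive the optimizer against an objective function
#'
#' Convenience loop for testing and offline use: repeatedly proposes,
#' rounds to the device, evaluates `fn(params)` and updates, restarting
#' on degenerate triangles, for `budget` evaluations.
#'
#' @param state A `simplex_state`.
#' @param fn Function taking a [stim_params()] and returning an outcome z
#'   (may return `NA` for an invalid block).
#' @param budget Number of evaluations.
#' @return The final `simplex_state`.
#' @export
run_simplex <- function(state, fn, budget) {
  for (i in seq_len(budget)) {
    prop <- tryCatch(propose_next(state),
                     tacsloop_degenerate_simplex = function(e) NULL)
    if (is.null(prop)) {
      state <- restart_simplex(state)
      prop <- propose_next(state)
    }
    params <- round_to_device(prop$point, state$freq_bounds)
    state <- update(state, params, fn(params))
  }
  state
}

#' Write the optimizer trajectory as a tab-separated log
#'
#' @param state A `simplex_state` (or a `training_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_log <- function(state, path) {
  h <- if (inherits(state, "simplex_state")) state$history else state$history
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
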