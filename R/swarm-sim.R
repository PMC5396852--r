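#' Initial state of a swarm
#'
#' Cells are distributed uniformly at random in the box with uniformly random
#' headings, all quiescent.  Drawing uses the current R RNG stream; seed it
#' (or use [run_swarm()], which seeds from the config) for reproducibility.
#'
#' @param config a [swarm_config()].
#' @return An object of class `swarm_state`: per-cell position (um), unit
#'   heading, phase (`"quiescent"`, `"firing"`, `"refractory"`), phase clock
#'   (min), heading at last fire, current refractory duration, time `t`, the
#'   config, and an RNG token so replay from a stored state is exact.
#' @export
swarm_state <- function(config) {
  stopifnot(inherits(config, "swarm_config"))
  n <- config$n_cells
  if (n < 1) stop("n_cells must be at least 1")
  pos <- cbind(runif(n, 0, config$box_length), runif(n, 0, config$box_length))
  ang <- runif(n, 0, 2 * pi)
  heading <- cbind(cos(ang), sin(ang))
  st <- list(position = pos,
             heading = heading,
             phase = rep.int(0L, n),
             phase_clock = rep(0, n),
             heading_at_fire = heading,
             refr_duration = rep(config$refractory_min, n),
             t = 0,
             config = config,
             pending_perturbation = NULL,
             rng_state = .Random.seed)
  class(st) <- "swarm_state"
  st
}

#' @export
print.swarm_state <- function(x, ...) {
  ph <- table(factor(phase_labels(x$phase),
                     levels = c("quiescent", "firing", "refractory")))
  cat("swarm_state: n =", nrow(x$position), "t =", x$t, "min |",
      paste(names(ph), as.integer(ph), collapse = ", "), "\n")
  invisible(x)
}

phase_labels <- function(code) {
  c("quiescent", "firing", "refractory")[code + 1L]
}

null_perturbation <- function() {
  list(kind = 0L, amount = 0, x = 0, y = 0, step = -1L)
}

pert_as_list <- function(p, step = 0L) {
  if (is.null(p)) return(null_perturbation())
  list(kind = switch(p$kind, global = 1L, point = 2L),
       amount = p$amount,
       x = if (is.null(p$location)) 0 else p$location[1],
       y = if (is.null(p$location)) 0 else p$location[2],
       step = as.integer(step))
}

#' Sensed cAMP concentration and gradient at a point
#'
#' Sums the analytic secretion profiles of all cells (optionally excluding
#' one, normally the sensing cell itself):
#' `sum_k A_k exp(-lambda r_k) w(theta_k)` where `A_k` is the leak or
#' (time-decaying) pulse amplitude, `r_k` the boundary-aware distance and
#' `w` the rear-cosine weight (identically 1 for uniform secretion).  The
#' gradient is the analytic spatial derivative of the same sum.
#'
#' @param state a [swarm_state()].
#' @param query length-2 position, um; must lie inside the box.
#' @param exclude 1-based index of a cell to exclude, or `NULL`.
#' @param noise if `TRUE`, multiplicative Gaussian sensing noise (sd =
#'   `baseline_noise_sd * sensing_noise_sd`) is applied to the concentration
#'   and to the gradient magnitude.
#' @return `list(concentration =, gradient =)`.
#' @export
sensed_field <- function(state, query, exclude = NULL, noise = FALSE) {
  stopifnot(inherits(state, "swarm_state"))
  cfg <- state$config
  if (length(query) != 2 || any(!is.finite(query))) {
    stop("query must be a finite 2-vector")
  }
  if (any(query < 0) || any(query > cfg$box_length)) {
    stop("query position lies outside the box")
  }
  if (cfg$leak_amplitude < 0 || cfg$pulse_amplitude < 0) {
    stop("secretion amplitudes must be non-negative")
  }
  excl <- if (is.null(exclude)) -1L else {
    if (exclude < 1 || exclude > nrow(state$position)) {
      stop("exclude must index a cell")
    }
    as.integer(exclude) - 1L
  }
  pert <- pert_as_list(state$pending_perturbation, step = 0L)
  pert$kind <- if (is.null(state$pending_perturbation)) 0L else pert$kind
  out <- cpp_sensed_field(state$position, state$heading, state$phase,
                          state$phase_clock, unclass(cfg), as.numeric(query),
                          excl, pert)
  if (noise) {
    sdn <- cfg$baseline_noise_sd * cfg$sensing_noise_sd
    if (sdn > 0) {
      out$concentration <- out$concentration * (1 + sdn * rnorm(1))
      out$gradient <- out$gradient * (1 + sdn * rnorm(1))
    }
  }
  out
}

run_state_cpp <- function(state, cfg, n_steps, record_every_steps, pert) {
  cpp_swarm_run(state$position, state$heading, state$phase, state$phase_clock,
                state$heading_at_fire, state$refr_duration, unclass(cfg),
                as.integer(n_steps), as.integer(record_every_steps), state$t,
                pert)
}

state_from_cpp <- function(state, out, cfg, n_steps) {
  state$position <- out$position
  state$heading <- out$heading
  state$phase <- out$phase
  state$phase_clock <- out$phase_clock
  state$heading_at_fire <- out$heading_at_fire
  state$refr_duration <- out$refr_duration
  state$t <- state$t + n_steps * cfg$dt
  state$pending_perturbation <- NULL
  state$rng_state <- .Random.seed
  state
}

#' Advance a swarm by one time step
#'
#' Synchronous update: all cells sense the beginning-of-step field, the firing
#' and movement rules are applied, then adhesion (if enabled), volume
#' exclusion and the boundary condition.  Replaying from a stored state is
#' bitwise reproducible via the RNG token carried in the state.
#'
#' @param state a [swarm_state()].
#' @param config configuration; defaults to the one stored in the state.
#' @return The updated `swarm_state`.
#' @export
swarm_step <- function(state, config = state$config) {
  stopifnot(inherits(state, "swarm_state"))
  if (!is.null(state$rng_state)) {
    assign(".Random.seed", state$rng_state, envir = globalenv())
  }
  if (any(!is.finite(state$position))) {
    stop("non-finite position for cell ",
         which(!is.finite(rowSums(state$position)))[1])
  }
  pert <- pert_as_list(state$pending_perturbation, step = 0L)
  out <- run_state_cpp(state, config, 1L, 1L, pert)
  state$config <- config
  state_from_cpp(state, out, config, 1L)
}

#' Schedule a one-step cAMP perturbation
#'
#' A `"global"` perturbation adds `amount` to every cell's sensed
#' concentration for the next step; a `"point"` perturbation adds a source
#' `amount * exp(-lambda r)` centered at `location` (its gradient included).
#'
#' @param state a [swarm_state()].
#' @param kind `"global"` or `"point"`.
#' @param amount added concentration (or source amplitude); non-negative.
#' @param location length-2 position for `kind = "point"`.
#' @return The state with the perturbation pending for the next step.
#' @export
apply_perturbation <- function(state, kind = c("global", "point"), amount,
                               location = NULL) {
  stopifnot(inherits(state, "swarm_state"))
  kind <- match.arg(kind)
  if (amount < 0) stop("perturbation amount must be non-negative")
  if (kind == "point" && (is.null(location) || length(location) != 2)) {
    stop("a point perturbation requires a 2-vector location")
  }
  state$pending_perturbation <- list(kind = kind, amount = amount,
                                     location = location)
  state
}

#' Run an aggregation simulation
#'
#' Seeds the RNG from `config$seed`, draws a uniform initial configuration
#' and integrates for `t_end` minutes, recording every `record_every` minutes.
#' Recorded velocities are minimum-image displacements divided by the
#' recording interval (the first frame has `NA` velocities).
#'
#' @param config a [swarm_config()].
#' @param t_end simulated duration, min.
#' @param record_every recording interval, min; must be a multiple of `dt`.
#' @param perturb optional one-off perturbation,
#'   `list(kind = "global"|"point", amount =, time =, location =)` applied at
#'   the step containing `time`.
#' @return A `trajectory_log`: recorded times `t`, position arrays `x`, `y`
#'   (cells x frames), `phase` codes, velocity arrays `vx`, `vy`, plus the
#'   config.  Use [log_frames()] to extract per-frame positions/velocities or
#'   [as.data.frame()] for the long table.
#' @export
run_swarm <- function(config, t_end, record_every = 1, perturb = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (config$n_cells < 1) stop("n_cells must be at least 1")
  n_steps <- round(t_end / config$dt)
  rec_steps <- max(1L, round(record_every / config$dt))
  if (!is.null(perturb)) {
    if (perturb$amount < 0) stop("perturbation amount must be non-negative")
    pstep <- as.integer(round(perturb$time / config$dt))
    pert <- pert_as_list(perturb, step = pstep)
  } else {
    pert <- null_perturbation()
  }
  set.seed(config$seed)
  state <- swarm_state(config)
  out <- run_state_cpp(state, config, n_steps, rec_steps, pert)
  build_log(out, config, rec_steps * config$dt)
}

build_log <- function(out, config, rec_dt) {
  x <- out$rec_x
  y <- out$rec_y
  nf <- ncol(x)
  L <- config$box_length
  periodic <- config$boundary == "periodic"
  vx <- matrix(NA_real_, nrow(x), nf)
  vy <- matrix(NA_real_, nrow(x), nf)
  if (nf > 1) {
    dx <- x[, -1, drop = FALSE] - x[, -nf, drop = FALSE]
    dy <- y[, -1, drop = FALSE] - y[, -nf, drop = FALSE]
    if (periodic) {
      dx <- dx - L * round(dx / L)
      dy <- dy - L * round(dy / L)
    }
    vx[, -1] <- dx / rec_dt
    vy[, -1] <- dy / rec_dt
  }
  log <- list(t = out$rec_t, x = x, y = y, vx = vx, vy = vy,
              phase = out$rec_phase, config = config,
              box = L, periodic = periodic)
  class(log) <- "trajectory_log"
  log
}

#' @export
print.trajectory_log <- function(x, ...) {
  cat("trajectory_log:", nrow(x$x), "cells,", length(x$t), "frames, t =",
      min(x$t), "...", max(x$t), "min\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory_log <- function(x, ...) {
  nf <- length(x$t)
  n <- nrow(x$x)
  data.frame(frame = rep(seq_len(nf), each = n),
             t_min = rep(x$t, each = n),
             cell_id = rep(seq_len(n), nf),
             x_um = as.vector(x$x),
             y_um = as.vector(x$y),
             vx = as.vector(x$vx),
             vy = as.vector(x$vy),
             phase = phase_labels(as.vector(x$phase)))
}

#' Extract per-frame positions and velocities from a trajectory log
#'
#' @param log a `trajectory_log`.
#' @param frames frame indices; defaults to all frames with defined
#'   velocities (i.e. all but the first).
#' @return A list of [cell_frame()] objects.
#' @export
log_frames <- function(log, frames = NULL) {
  stopifnot(inherits(log, "trajectory_log"))
  if (is.null(frames)) frames <- seq_along(log$t)[-1]
  lapply(frames, function(f) {
    cell_frame(positions = cbind(log$x[, f], log$y[, f]),
               velocities = cbind(log$vx[, f], log$vy[, f]),
               t = log$t[f], box = log$box, periodic = log$periodic)
  })
}

#' Per-frame count of firing cells
#'
#' @param log a `trajectory_log` (phase labels required).
#' @return A data frame with columns `t` and `value` (number of firing
#'   cells), usable with [smooth_series()].
#' @export
count_firing <- function(log) {
  stopifnot(inherits(log, "trajectory_log"))
  if (is.null(log$phase)) stop("log has no phase labels")
  data.frame(t = log$t, value = colSums(log$phase == 1L))
}

#' Per-cell firing rate of a run
#'
#' Counts pulse onsets (frame-to-frame transitions into the firing phase) and
#' divides by cell count and duration.  Use it to match the asynchronous
#' variant's random pulsing rate to a paired wild-type run.
#'
#' @param log a `trajectory_log`.
#' @return Onset rate per cell per minute.
#' @export
matched_async_rate <- function(log) {
  stopifnot(inherits(log, "trajectory_log"))
  ph <- log$phase == 1L
  nf <- ncol(ph)
  if (nf < 2) stop("need at least two frames")
  onsets <- sum(ph[, -1] & !ph[, -nf])
  onsets / nrow(ph) / (max(log$t) - min(log$t))
}
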