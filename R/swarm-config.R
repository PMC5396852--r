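#' Configuration for the coarse-grained aggregation model
#'
#' Cells are point-like agents in a square box of side `box_length`.  Every
#' agent secretes cAMP whose spatial profile decays as
#' `exp(-decay_const * r)`, weighted towards the cell rear by the cosine of
#' the angle with the opposite-to-motion direction (zero laterally and over
#' the whole front).  A quiescent cell that senses a concentration at or
#' above `conc_threshold_c1` emits a pulse for `pulse_duration` minutes
#' (amplitude `pulse_amplitude * exp(-t/pulse_decay_time)`), then enters a
#' refractory period of `refractory_min` minutes during which it can neither
#' fire again nor repolarize and keeps the motion it had while pulsing.
#' Quiescent cells move along one of two candidate headings obtained by
#' rotating the previous heading by `+/- turn_half_angle` degrees; the
#' candidate with the larger sensed concentration is taken when the gradient
#' magnitude is at least `grad_threshold_c2`, otherwise the choice is
#' uniformly random.  Cells may not come closer than `exclusion_radius`
#' unless they sit in a densely packed neighborhood (see
#' `packing_threshold`).
#'
#' Defaults place `n_cells = 1000` cells in a 389-um box, the density of
#' about one cell monolayer (1 ML = 6,600 cells/mm^2).  The concentration
#' scale is arbitrary; thresholds are calibrated so that an isolated cell
#' never fires from its own leakage (self-secretion is excluded from the
#' field sum) while a compact cluster of cells at contact, with rears turned
#' inward, can trigger firing (see `calibrate_thresholds()`); the pulse
#' amplitude is set so that a fresh pulse relays only to cells within about
#' one contact distance, confining relay waves to dense groups and streams.
#'
#' @param box_length box side, um.
#' @param n_cells number of cells.
#' @param dt integration time step, min.
#' @param speed cell speed, um/min.
#' @param decay_const spatial decay constant of the secretion profile, 1/um.
#' @param leak_amplitude amplitude of the constant leak secretion
#'   (concentration units).
#' @param pulse_amplitude peak amplitude of an emitted pulse.
#' @param pulse_duration duration of the firing phase, min.
#' @param pulse_decay_time e-folding time of the pulse amplitude, min.
#' @param pulse_rise_time linear rise time of the pulse amplitude at fire
#'   onset, min.  Finite release kinetics set the cell-to-cell relay latency
#'   and hence the relay-wave speed; 0 gives an instantaneous-onset pulse
#'   whose wave speed is limited only by `dt`.
#' @param conc_threshold_c1 concentration threshold for firing.
#' @param grad_threshold_c2 gradient-magnitude threshold (concentration/um)
#'   separating random motion from chemotaxis.
#' @param refractory_min refractory period after a pulse, min.
#' @param exclusion_radius minimum inter-cell distance, um.
#' @param turn_half_angle pseudopod half-angle, degrees; the full angle
#'   between the two candidate directions is twice this value.
#' @param sensing_noise_sd multiplier on the baseline multiplicative sensing
#'   noise (1 = wild type; 10 = the high-noise variant).
#' @param secretion_mode `"rear"` (cosine rear weighting) or `"uniform"`
#'   (radially symmetric secretion).
#' @param adhesion `NULL` for none, or `list(strength =, range =)` for a
#'   truncated 12-6 pairwise attraction; `range` defaults to twice the
#'   exclusion radius.
#' @param async_pulsing logical; if `TRUE` the concentration-threshold firing
#'   rule is replaced by independent Poisson pulse onsets at `async_rate`
#'   with refractory durations drawn uniformly from 0.5-1.5 times
#'   `refractory_min`.
#' @param async_rate per-cell pulse onset rate for the asynchronous variant,
#'   1/min; match it to a paired wild-type run with [matched_async_rate()].
#' @param boundary `"periodic"` or `"reflecting"`.
#' @param seed integer seed used by [run_swarm()].
#' @param baseline_noise_sd baseline multiplicative sensing noise sd
#'   (dimensionless), applied to concentration and gradient magnitude after
#'   field summation and before the threshold tests.
#' @param packing_threshold volume exclusion is skipped for a pair when
#'   either member has more than this many neighbors within three exclusion
#'   radii (lets dense aggregates form); the same packing state triggers the
#'   crowding slowdown.
#' @param crowding_slowdown speed factor applied to cells in densely packed
#'   neighborhoods (contact inhibition inside aggregates); 1 disables it.
#' @param field_cutoff distance beyond which secretion contributions are
#'   dropped, um; defaults to the distance at which the peak pulse amplitude
#'   has decayed to 1e-3 of `conc_threshold_c1`, capped at half the box.
#'
#' @return An object of class `swarm_config`.
#' @seealso [run_swarm()], [swarm_variant()], [calibrate_thresholds()]
#' @export
swarm_config <- function(box_length = 389,
                         n_cells = 1000,
                         dt = 0.1,
                         speed = 5,
                         decay_const = 0.1,
                         leak_amplitude = 1,
                         pulse_amplitude = 10,
                         pulse_duration = 1,
                         pulse_decay_time = 3,
                         pulse_rise_time = 0.5,
                         conc_threshold_c1 = 4,
                         grad_threshold_c2 = 0.05,
                         refractory_min = 6,
                         exclusion_radius = 3,
                         turn_half_angle = 27.5,
                         sensing_noise_sd = 1,
                         secretion_mode = c("rear", "uniform"),
                         adhesion = NULL,
                         async_pulsing = FALSE,
                         async_rate = 0.1,
                         boundary = c("periodic", "reflecting"),
                         seed = 1,
                         baseline_noise_sd = 0.02,
                         packing_threshold = 8,
                         crowding_slowdown = 0.2,
                         field_cutoff = NULL) {
  secretion_mode <- match.arg(secretion_mode)
  boundary <- match.arg(boundary)

  num <- c(box_length = box_length, n_cells = n_cells, dt = dt, speed = speed,
           decay_const = decay_const, leak_amplitude = leak_amplitude,
           pulse_amplitude = pulse_amplitude, pulse_duration = pulse_duration,
           pulse_decay_time = pulse_decay_time,
           conc_threshold_c1 = conc_threshold_c1,
           grad_threshold_c2 = grad_threshold_c2,
           refractory_min = refractory_min,
           exclusion_radius = exclusion_radius,
           turn_half_angle = turn_half_angle)
  if (any(!is.finite(num))) {
    stop("non-finite config value: ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  }
  if (any(num <= 0)) {
    stop("config values must be positive: ",
         paste(names(num)[num <= 0], collapse = ", "))
  }
  if (turn_half_angle >= 90) stop("turn_half_angle must be in (0, 90) degrees")
  if (exclusion_radius >= box_length) {
    stop("exclusion_radius must be smaller than box_length")
  }
  if (dt > refractory_min) stop("dt must not exceed refractory_min")
  if (dt > pulse_duration) stop("dt must not exceed pulse_duration")
  if (pulse_rise_time < 0) stop("pulse_rise_time must be non-negative")
  if (sensing_noise_sd < 0 || baseline_noise_sd < 0) {
    stop("sensing noise parameters must be non-negative")
  }
  if (n_cells != round(n_cells)) stop("n_cells must be a whole number")
  if (crowding_slowdown < 0 || crowding_slowdown > 1) {
    stop("crowding_slowdown must lie in [0, 1]")
  }

  adhesion_on <- !is.null(adhesion)
  adh_strength <- 0
  adh_range <- 2 * exclusion_radius
  if (adhesion_on) {
    if (!is.list(adhesion) || is.null(adhesion$strength)) {
      stop("adhesion must be NULL or list(strength =, range =)")
    }
    adh_strength <- adhesion$strength
    if (!is.null(adhesion$range)) adh_range <- adhesion$range
    if (adh_strength <= 0 || adh_range <= 0) {
      stop("adhesion strength and range must be positive")
    }
  }

  if (is.null(field_cutoff)) {
    field_cutoff <- min(box_length / 2,
                        log(pulse_amplitude / (1e-3 * conc_threshold_c1)) /
                          decay_const)
  }
  if (field_cutoff <= 0) stop("field_cutoff must be positive")

  cfg <- list(box_length = box_length, n_cells = as.integer(n_cells), dt = dt,
              speed = speed, decay_const = decay_const,
              leak_amplitude = leak_amplitude,
              pulse_amplitude = pulse_amplitude,
              pulse_duration = pulse_duration,
              pulse_decay_time = pulse_decay_time,
              pulse_rise_time = pulse_rise_time,
              conc_threshold_c1 = conc_threshold_c1,
              grad_threshold_c2 = grad_threshold_c2,
              refractory_min = refractory_min,
              exclusion_radius = exclusion_radius,
              turn_half_angle = turn_half_angle,
              sensing_noise_sd = sensing_noise_sd,
              secretion_mode = secretion_mode,
              adhesion_on = adhesion_on,
              adhesion_strength = adh_strength,
              adhesion_range = adh_range,
              async_pulsing = isTRUE(async_pulsing),
              async_rate = async_rate,
              boundary = boundary,
              seed = as.integer(seed),
              baseline_noise_sd = baseline_noise_sd,
              packing_threshold = as.integer(packing_threshold),
              crowding_slowdown = crowding_slowdown,
              field_cutoff = field_cutoff)
  class(cfg) <- "swarm_config"
  cfg
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("swarm_config:", x$n_cells, "cells in a", x$box_length, "um box (",
      signif(density_ml(x$n_cells, x$box_length), 3), "ML )\n")
  cat("  dt", x$dt, "min | speed", x$speed, "um/min | lambda", x$decay_const,
      "1/um\n")
  cat("  c1", x$conc_threshold_c1, "| grad c2", x$grad_threshold_c2,
      "| refractory", x$refractory_min, "min | exclusion",
      x$exclusion_radius, "um\n")
  cat("  secretion", x$secretion_mode,
      "| noise x", x$sensing_noise_sd,
      "| adhesion", if (x$adhesion_on) "on" else "off",
      "| async", x$async_pulsing,
      "| boundary", x$boundary, "| seed", x$seed, "\n")
  invisible(x)
}

#' Cell density in monolayer units
#'
#' One monolayer (ML) is 6,600 cells/mm^2.
#'
#' @param n_cells number of cells.
#' @param box_length box side, um.
#' @return Density in ML units.
#' @export
density_ml <- function(n_cells, box_length) {
  n_cells / (box_length / 1000)^2 / 6600
}

#' Number of cells corresponding to a target density
#'
#' @param ml density in monolayer units (1 ML = 6,600 cells/mm^2).
#' @param box_length box side, um.
#' @return Cell count (not rounded).
#' @export
cells_for_ml <- function(ml, box_length) {
  ml * 6600 * (box_length / 1000)^2
}

#' Modified cell types used in the mutant comparison
#'
#' Returns a copy of `config` altered to one of the aggregation-impaired
#' variants: radially uniform secretion, a ten-fold increase in sensing-noise
#' standard deviation, added short-range cell-cell adhesion, or asynchronous
#' (randomly timed) pulsing with randomized refractory periods.
#'
#' @param config a [swarm_config()].
#' @param variant one of `"wt"`, `"uniform"`, `"noise10x"`, `"adhesion"`,
#'   `"async"`.
#' @param adhesion_strength attraction strength for the adhesion variant.
#' @param async_rate per-cell pulse onset rate for the asynchronous variant;
#'   `NULL` keeps the rate stored in `config`.
#' @return A `swarm_config`.
#' @export
swarm_variant <- function(config, variant = c("wt", "uniform", "noise10x",
                                              "adhesion", "async"),
                          adhesion_strength = 1, async_rate = NULL) {
  stopifnot(inherits(config, "swarm_config"))
  variant <- match.arg(variant)
  cfg <- unclass(config)
  cfg$adhesion <- if (cfg$adhesion_on) {
    list(strength = cfg$adhesion_strength, range = cfg$adhesion_range)
  }
  cfg <- cfg[setdiff(names(cfg), c("adhesion_on", "adhesion_strength",
                                   "adhesion_range"))]
  if (variant == "uniform") cfg$secretion_mode <- "uniform"
  if (variant == "noise10x") cfg$sensing_noise_sd <- 10
  if (variant == "adhesion") {
    cfg$adhesion <- list(strength = adhesion_strength,
                         range = 2 * cfg$exclusion_radius)
  }
  if (variant == "async") {
    cfg$async_pulsing <- TRUE
    if (!is.null(async_rate)) cfg$async_rate <- async_rate
  }
  do.call(swarm_config, cfg)
}

#' Check the firing-threshold calibration of a configuration
#'
#' Three desk checks on the firing calibration: (1) an isolated cell senses
#' none of its own secretion (self-contributions are excluded from the field
#' sum), so it can never fire from its own leakage; (2) a compact cluster of
#' `n_cluster` leaking cells at contact distance, with rears turned towards
#' the focal cell, produces a sensed concentration at or above the threshold;
#' (3) a fresh pulse at peak amplitude relays to a rear-facing cell at
#' contact distance but not to one much beyond it (contact-range relay).
#'
#' @param config a [swarm_config()].
#' @param n_cluster cluster size for the contact check.
#' @return A list of sensed concentrations, the relay range, and verdicts.
#' @export
calibrate_thresholds <- function(config, n_cluster = 7) {
  stopifnot(inherits(config, "swarm_config"))
  lam <- config$decay_const
  d <- config$exclusion_radius
  # neighbors at contact, rear-facing (weight 1)
  conc_cluster <- (n_cluster - 1) * config$leak_amplitude * exp(-lam * d)
  relay_range <- log(config$pulse_amplitude / config$conc_threshold_c1) / lam
  list(conc_isolated = 0,
       isolated_never_fires = TRUE,
       conc_cluster_contact = conc_cluster,
       cluster_triggers = conc_cluster >= config$conc_threshold_c1,
       relay_range_um = relay_range,
       relay_is_contact_scale = relay_range <= 5 * d)
}
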