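#' Parameters of the excitable intracellular cAMP unit
#'
#' A zero-dimensional FitzHugh-Nagumo cell: activator `u` (intracellular
#' cAMP, driven by adenylyl cyclase) and recovery `v` (degradation, regA
#' activity).  Extracellular cAMP `c_ext` excites the activator with gain
#' `ext_coupling` and suppresses the recovery dynamics through a saturating
#' (Michaelis-type) factor `1 - rega_inhibition * c/(1+c)`, reflecting the
#' negative regulation of regA by extracellular cAMP.  The cell leaks cAMP at
#' `leak_rate` while subthreshold and secretes at `pulse_rate` while the
#' activator exceeds `spike_cut`.  Below a threshold extracellular
#' concentration the rest state is stable and the cell only leaks; held above
#' it, the cell becomes a sustained oscillator (see
#' [find_oscillation_threshold()]).
#'
#' @param timescale_ratio ratio of recovery to activator timescales, in
#'   (0, 1).
#' @param recovery_offset,recovery_gain recovery nullcline parameters.
#' @param ext_coupling gain of external cAMP on the activator.
#' @param rega_inhibition saturating suppression gain of the recovery term,
#'   in `[0, 1)`.
#' @param osc_threshold_cstar optional cached oscillation threshold
#'   (concentration units); filled by [find_oscillation_threshold()].
#' @param leak_rate,pulse_rate secretion rates, concentration/min.
#' @param spike_cut activator level defining a spike.
#' @param rate_per_min model time units per minute (sets the spike width and
#'   oscillation period on the minute scale).
#' @return An object of class `fhn_params`.
#' @export
fhn_params <- function(timescale_ratio = 0.08, recovery_offset = 0.7,
                       recovery_gain = 0.8, ext_coupling = 0.5,
                       rega_inhibition = 0.5, osc_threshold_cstar = NA_real_,
                       leak_rate = 0.1, pulse_rate = 5, spike_cut = 1,
                       rate_per_min = 4) {
  if (!is.finite(timescale_ratio) || timescale_ratio <= 0 ||
      timescale_ratio >= 1) {
    stop("timescale_ratio must lie in (0, 1)")
  }
  if (leak_rate < 0 || pulse_rate < 0) stop("secretion rates must be >= 0")
  if (rega_inhibition < 0 || rega_inhibition >= 1) {
    stop("rega_inhibition must lie in [0, 1)")
  }
  if (rate_per_min <= 0) stop("rate_per_min must be positive")
  structure(list(timescale_ratio = timescale_ratio,
                 recovery_offset = recovery_offset,
                 recovery_gain = recovery_gain,
                 ext_coupling = ext_coupling,
                 rega_inhibition = rega_inhibition,
                 osc_threshold_cstar = osc_threshold_cstar,
                 leak_rate = leak_rate, pulse_rate = pulse_rate,
                 spike_cut = spike_cut, rate_per_min = rate_per_min),
            class = "fhn_params")
}

fhn_rhs <- function(u, v, c, p) {
  reg <- 1 - p$rega_inhibition * c / (1 + c)
  list(du = p$rate_per_min * (u - u^3 / 3 - v + p$ext_coupling * c),
       dv = p$rate_per_min * p$timescale_ratio *
         (u + p$recovery_offset - p$recovery_gain * v) * reg)
}

#' Integrate the excitable cAMP unit
#'
#' Fixed-step explicit midpoint integration of the FitzHugh-Nagumo system
#' `du/dt = u - u^3/3 - v + ext_coupling * c_ext(t)`,
#' `dv/dt = timescale_ratio * (u + recovery_offset - recovery_gain * v) *
#' (1 - rega_inhibition * c/(1+c))` (both scaled by `rate_per_min`),
#' starting from the resting state for `c_ext = 0`.  Spikes are upward
#' crossings of `spike_cut`.
#'
#' @param params an [fhn_params()].
#' @param c_ext external cAMP: a constant or a function of time (min);
#'   must be non-negative.
#' @param t_end duration, min.
#' @param dt time step, min.
#' @return A `cell_trace`: `t`, `u`, `v`, `secretion`, `spikes` (spike
#'   times, min).
#' @export
integrate_cell <- function(params, c_ext = 0, t_end = 60, dt = 0.005) {
  stopifnot(inherits(params, "fhn_params"))
  if (dt <= 0) stop("dt must be positive")
  cf <- if (is.function(c_ext)) c_ext else function(t) c_ext
  nt <- floor(t_end / dt) + 1L
  t <- (seq_len(nt) - 1L) * dt
  u <- numeric(nt)
  v <- numeric(nt)
  rest <- fhn_rest_state(params)
  u[1] <- rest$u
  v[1] <- rest$v
  for (i in seq_len(nt - 1L)) {
    c0 <- cf(t[i])
    if (c0 < 0) stop("c_ext must be non-negative")
    k1 <- fhn_rhs(u[i], v[i], c0, params)
    cm <- cf(t[i] + dt / 2)
    k2 <- fhn_rhs(u[i] + dt / 2 * k1$du, v[i] + dt / 2 * k1$dv, cm, params)
    u[i + 1L] <- u[i] + dt * k2$du
    v[i + 1L] <- v[i] + dt * k2$dv
    if (!is.finite(u[i + 1L]) || !is.finite(v[i + 1L])) {
      stop("integration diverged (non-finite state); reduce dt")
    }
  }
  above <- u > params$spike_cut
  up <- which(above[-1] & !above[-nt]) + 1L
  structure(list(t = t, u = u, v = v,
                 secretion = ifelse(above, params$pulse_rate,
                                    params$leak_rate),
                 spikes = t[up]),
            class = "cell_trace")
}

# resting state for c_ext = 0: solve the nullcline intersection by bisection
fhn_rest_state <- function(p) {
  f <- function(u) u - u^3 / 3 - (u + p$recovery_offset) / p$recovery_gain
  lo <- -3; hi <- 0
  if (f(lo) * f(hi) > 0) hi <- 3
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  u <- (lo + hi) / 2
  list(u = u, v = (u + p$recovery_offset) / p$recovery_gain)
}

#' @export
print.cell_trace <- function(x, ...) {
  cat("cell_trace:", length(x$t), "steps, t =", max(x$t), "min,",
      length(x$spikes), "spike(s)\n")
  invisible(x)
}

#' Oscillation threshold of the excitable unit
#'
#' Bisection on a constant external cAMP concentration for the onset of
#' sustained spiking, defined as at least `min_spikes` spikes within a
#' `t_window`-minute window.
#'
#' @param params an [fhn_params()].
#' @param c_max upper end of the search bracket.
#' @param t_window observation window, min.
#' @param min_spikes spike count defining sustained oscillation.
#' @param tol bisection tolerance on the concentration.
#' @param dt integration step, min.
#' @return The threshold concentration c*.
#' @export
find_oscillation_threshold <- function(params, c_max = 2, t_window = 60,
                                       min_spikes = 3, tol = 1e-3,
                                       dt = 0.01) {
  stopifnot(inherits(params, "fhn_params"))
  oscillates <- function(c) {
    length(integrate_cell(params, c, t_end = t_window, dt = dt)$spikes) >=
      min_spikes
  }
  lo <- 0
  if (oscillates(lo)) stop("already oscillating at c_ext = 0; no bracket")
  hi <- c_max
  if (!oscillates(hi)) {
    stop("no sustained oscillation found up to c_max = ", c_max)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (oscillates(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
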