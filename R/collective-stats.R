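#' A single frame of cell positions and velocities
#'
#' @param positions n x 2 matrix, um.
#' @param velocities n x 2 matrix, um/min, row-aligned with `positions`.
#' @param t frame time, min.
#' @param box box side for boundary-aware distances, um (`NULL` for open
#'   geometry).
#' @param periodic use minimum-image distances.
#' @return An object of class `cell_frame`.
#' @export
cell_frame <- function(positions, velocities = NULL, t = NA_real_,
                       box = NULL, periodic = FALSE) {
  positions <- as_xy(positions)
  if (is.null(velocities)) {
    velocities <- matrix(0, nrow(positions), 2)
  } else {
    velocities <- as_xy(velocities)
  }
  if (nrow(velocities) != nrow(positions)) {
    stop("velocities must be row-aligned with positions")
  }
  structure(list(positions = positions, velocities = velocities, t = t,
                 box = if (is.null(box)) NA_real_ else box,
                 periodic = isTRUE(periodic) && !is.null(box)),
            class = "cell_frame")
}

as_xy <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2) stop("expected an n x 2 matrix")
  storage.mode(m) <- "double"
  m
}

new_profile <- function(centers, values, counts) {
  structure(data.frame(bin_center = centers, value = values,
                       pair_count = counts),
            class = c("correlation_profile", "data.frame"))
}

#' Density pair-correlation function g(r)
#'
#' Ring-binned pair correlation
#' `g(r) = A / (N (N - 1)) * 1 / (2 pi r a) * sum_{i != j} delta(r - r_ij)`,
#' with ring radii at integer multiples of the bin width `a` (the ring at
#' radius `k a` collects pair distances in `[k a - a/2, k a + a/2)`).  For a
#' completely spatially random pattern g(r) averages to 1; clustering raises
#' it at short range.
#'
#' @param positions n x 2 matrix of positions, um.
#' @param area total area A of the observation window, um^2.
#' @param bin_width ring discretization constant a, um.
#' @param r_max largest ring radius, um.
#' @param periodic use minimum-image distances (requires `box`).
#' @param box box side, um (needed when `periodic = TRUE`).
#' @return A `correlation_profile` data frame: `bin_center`, `value` (g),
#'   `pair_count` (ordered pairs per ring).
#' @export
pair_correlation <- function(positions, area, bin_width, r_max,
                             periodic = FALSE, box = NULL) {
  positions <- as_xy(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 points")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (bin_width >= r_max) stop("bin_width must be smaller than r_max")
  if (periodic && is.null(box)) stop("periodic distances require box")
  nbin <- floor(r_max / bin_width)
  counts <- cpp_ring_counts(positions, bin_width, nbin,
                            if (is.null(box)) 0 else box, isTRUE(periodic))
  r <- bin_width * seq_len(nbin)
  g <- area / (n * (n - 1)) * counts / (2 * pi * r * bin_width)
  new_profile(r, g, counts)
}

velocity_directions <- function(frame) {
  v <- frame$velocities
  if (any(!is.finite(v))) stop("velocities must be finite")
  sp <- sqrt(rowSums(v^2))
  keep <- sp > 0
  if (!any(keep)) stop("all velocities are zero")
  list(u = v[keep, , drop = FALSE] / sp[keep],
       keep = keep)
}

#' Nonconnected directional correlation C_nc(r)
#'
#' Average of `u_i . u_j` over ordered cell pairs binned by distance, where
#' `u_i` is the unit direction of motion.  This is the order parameter of the
#' collective: 0 for independent random motion, 1 for perfectly aligned
#' motion.  Zero-velocity cells are excluded.  Bins are half-open
#' `[k a, (k+1) a)` with centers at `(k + 1/2) a`.
#'
#' @param frame a [cell_frame()].
#' @param bin_width bin width a, um.
#' @param r_max maximum distance; defaults to half the box (periodic) or the
#'   largest pair distance.
#' @return A `correlation_profile`; bins without pairs are dropped.
#' @export
nonconnected_correlation <- function(frame, bin_width, r_max = NULL) {
  stopifnot(inherits(frame, "cell_frame"))
  vd <- velocity_directions(frame)
  pos <- frame$positions[vd$keep, , drop = FALSE]
  if (nrow(pos) < 2) stop("need at least 2 moving cells")
  r_max <- default_rmax(frame, r_max)
  nbin <- ceiling(r_max / bin_width)
  out <- cpp_binned_dot(pos, vd$u, bin_width, nbin,
                        box_or_zero(frame), frame$periodic)
  centers <- (seq_len(nbin) - 0.5) * bin_width
  keep <- out$counts > 0
  new_profile(centers[keep], (out$sums / pmax(out$counts, 1))[keep],
              out$counts[keep])
}

default_rmax <- function(frame, r_max) {
  if (!is.null(r_max)) return(r_max)
  if (frame$periodic) return(frame$box / 2)
  d <- frame$positions
  sqrt(max((outer(d[, 1], d[, 1], "-"))^2 + (outer(d[, 2], d[, 2], "-"))^2))
}

box_or_zero <- function(frame) if (is.na(frame$box)) 0 else frame$box

#' Local velocity fluctuations
#'
#' For every focal cell the neighborhood is all cells within `r_c` (focal
#' included).  The fluctuation is the cell's velocity minus the neighborhood
#' mean, normalized by the root-mean-square fluctuation of that same
#' neighborhood.  Subtracting a local (rather than global) mean removes the
#' bulk drift towards the aggregate that would otherwise inflate the
#' connected correlations.  Cells with no neighbor within `r_c` are flagged
#' unusable; neighborhoods with identical velocities yield zero fluctuations
#' (usable, contributing 0).
#'
#' @param frame a [cell_frame()].
#' @param r_c neighborhood radius, um.
#' @return A `fluctuation_set`: `delta_u` (n x 2), `usable` flags,
#'   `n_neighbors`, and `r_c`.
#' @export
directional_fluctuations <- function(frame, r_c) {
  stopifnot(inherits(frame, "cell_frame"))
  if (r_c <= 0) stop("r_c must be positive")
  out <- cpp_fluctuations(frame$positions, frame$velocities, r_c,
                          box_or_zero(frame), frame$periodic)
  structure(list(delta_u = out$delta_u, usable = out$usable,
                 n_neighbors = out$n_neighbors, r_c = r_c),
            class = "fluctuation_set")
}

#' Connected directional correlation C_c(r)
#'
#' The nonconnected form evaluated on normalized local velocity fluctuations
#' (see [directional_fluctuations()]), with pairs restricted to each focal
#' cell's neighborhood (`r_ij <= r_c`).  It measures how much a cell's
#' direction change is matched by its neighbors — the cell-cell coupling that
#' distinguishes self-organization from following a leader.
#'
#' @param frame a [cell_frame()].
#' @param r_c neighborhood radius, um.
#' @param bin_width bin width, um.
#' @param fluct optionally a precomputed `fluctuation_set` for this frame.
#' @return A `correlation_profile`; bins without pairs are dropped.
#' @export
connected_correlation <- function(frame, r_c, bin_width, fluct = NULL) {
  stopifnot(inherits(frame, "cell_frame"))
  if (is.null(fluct)) fluct <- directional_fluctuations(frame, r_c)
  nbin <- ceiling(r_c / bin_width)
  out <- cpp_connected_binned(frame$positions, fluct$delta_u, fluct$usable,
                              r_c, bin_width, nbin, box_or_zero(frame),
                              frame$periodic)
  if (sum(out$counts) == 0) stop("no usable pairs within r_c")
  centers <- (seq_len(nbin) - 0.5) * bin_width
  keep <- out$counts > 0
  new_profile(centers[keep], (out$sums / pmax(out$counts, 1))[keep],
              out$counts[keep])
}

#' Correlation length xi0: first zero crossing of a correlation profile
#'
#' The smallest distance at which the profile crosses zero, located by linear
#' interpolation between adjacent bins.  A profile that never reaches zero
#' returns the largest bin center flagged with `attr(, "censored") = TRUE`.
#'
#' @param profile a `correlation_profile`.
#' @return xi0 in the profile's distance units, with attribute `censored`.
#' @export
correlation_length <- function(profile) {
  r <- profile$bin_center
  v <- profile$value
  if (length(r) < 2) stop("profile must have at least 2 bins")
  if (v[1] <= 0) {
    return(structure(r[1], censored = FALSE))
  }
  idx <- which(v <= 0)
  if (length(idx) == 0) {
    return(structure(r[length(r)], censored = TRUE))
  }
  k <- idx[1]
  xi <- r[k - 1] + (r[k] - r[k - 1]) * v[k - 1] / (v[k - 1] - v[k])
  structure(xi, censored = FALSE)
}

#' Susceptibility chi: integrated connected correlations
#'
#' `chi = (1/N) sum_{i != j} delta_u_i . delta_u_j theta(xi0 - r_ij)` over
#' usable cells — the number of correlated cells within one correlation
#' length, a proxy for how coherently the collective responds.  It peaks
#' during the streaming phase.
#'
#' @param fluct a `fluctuation_set`.
#' @param positions n x 2 positions, um.
#' @param xi0 correlation length, um.
#' @param periodic use minimum-image distances.
#' @param box box side, um.
#' @return chi (dimensionless).
#' @export
susceptibility <- function(fluct, positions, xi0, periodic = FALSE,
                           box = NULL) {
  stopifnot(inherits(fluct, "fluctuation_set"))
  if (xi0 <= 0) stop("xi0 must be positive")
  if (!any(fluct$usable)) stop("no usable cells")
  positions <- as_xy(positions)
  cpp_susceptibility(positions, fluct$delta_u, fluct$usable, xi0,
                     if (is.null(box)) 0 else box, isTRUE(periodic))
}

#' Mean nearest-neighbor distance
#'
#' Average over cells of the distance to the closest other cell.  Rescaling
#' by the cell-size parameter (the 3-um volume-exclusion length for
#' simulations) is left to the caller.
#'
#' @param positions n x 2 positions, um.
#' @param periodic use minimum-image distances.
#' @param box box side, um.
#' @return Mean nearest-neighbor distance, um.
#' @export
nn_distance <- function(positions, periodic = FALSE, box = NULL) {
  positions <- as_xy(positions)
  if (nrow(positions) < 2) stop("need at least 2 points")
  cpp_nn_distance(positions, if (is.null(box)) 0 else box, isTRUE(periodic))
}

#' Rescale correlation profiles by their correlation lengths and measure
#' their collapse
#'
#' Each profile is interpolated onto a common grid of `r / xi0` in
#' `[0.2, 1]` and normalized to 1 at the first grid point.  The dispersion is
#' the root-mean-square deviation of the curves from their pointwise mean;
#' near-zero dispersion means the profiles share one shape — the
#' self-similarity expected near a critical point.
#'
#' @param profiles list of `correlation_profile`s.
#' @param xi0s correlation lengths, one per profile (censored values are
#'   excluded with a warning).
#' @param grid common `r / xi0` grid.
#' @return `list(grid =, curves = matrix (profiles x grid), dispersion =)`.
#' @export
collapse_profiles <- function(profiles, xi0s,
                              grid = seq(0.2, 1, length.out = 33)) {
  stopifnot(length(profiles) == length(xi0s))
  cens <- vapply(xi0s, function(x) isTRUE(attr(x, "censored")), logical(1))
  if (any(cens)) {
    warning(sum(cens), " profile(s) with censored xi0 excluded from collapse")
    profiles <- profiles[!cens]
    xi0s <- xi0s[!cens]
  }
  if (length(profiles) < 2) stop("need at least 2 profiles with valid xi0")
  curves <- t(vapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    approx(p$bin_center / as.numeric(xi0s[[i]]), p$value, xout = grid,
           rule = 2)$y
  }, numeric(length(grid))))
  curves <- curves / curves[, 1]
  mid <- colMeans(curves)
  dispersion <- sqrt(mean(sweep(curves, 2, mid)^2))
  list(grid = grid, curves = curves, dispersion = dispersion)
}

#' Correlation length versus neighborhood radius (finite-size scaling)
#'
#' For each neighborhood radius `r_c`, the connected-correlation length is
#' computed for every frame in the time window and summarized as mean and
#' standard error over frames (frames treated as independent).  In a system
#' with an intrinsic correlation scale, xi0 saturates as `r_c` grows; near
#' criticality it keeps increasing with the observation scale.
#'
#' @param log a `trajectory_log`.
#' @param radii neighborhood radii, um (e.g. `box / c(10, 8, 6, 4, 2)`).
#' @param window `c(t1, t2)` time window, min.
#' @param bin_width profile bin width, um.
#' @return A `scaling_table` data frame: `n_cells`, `r_c`, `mean_xi0`, `se`,
#'   `n_frames`.
#' @export
scaling_analysis <- function(log, radii, window, bin_width = 3) {
  stopifnot(inherits(log, "trajectory_log"))
  if (any(radii <= 0)) stop("radii must be positive")
  idx <- which(log$t >= window[1] & log$t <= window[2])
  idx <- setdiff(idx, 1L)  # first frame has no velocities
  if (length(idx) == 0) stop("empty time window")
  frames <- log_frames(log, idx)
  rows <- lapply(sort(radii), function(rc) {
    xi <- vapply(frames, function(fr) {
      prof <- connected_correlation(fr, rc, bin_width)
      xi0 <- correlation_length(prof)
      if (isTRUE(attr(xi0, "censored"))) NA_real_ else as.numeric(xi0)
    }, numeric(1))
    xi <- xi[is.finite(xi)]
    data.frame(n_cells = nrow(log$x), r_c = rc,
               mean_xi0 = if (length(xi)) mean(xi) else NA_real_,
               se = if (length(xi) > 1) sd(xi) / sqrt(length(xi)) else 0,
               n_frames = length(xi))
  })
  structure(do.call(rbind, rows),
            class = c("scaling_table", "data.frame"))
}

#' Centered moving average
#'
#' Smooths a series with a centered moving-average filter of `window`
#' points, shrinking the window at the edges.
#'
#' @param series numeric vector, or a data frame with a `value` column.
#' @param window filter span in frames (>= 1).
#' @return Same shape as the input.
#' @export
smooth_series <- function(series, window) {
  if (is.data.frame(series)) {
    series$value <- smooth_series(series$value, window)
    return(series)
  }
  n <- length(series)
  if (window < 1 || window != round(window)) {
    stop("window must be a positive whole number")
  }
  if (window > n) stop("window exceeds series length")
  lo <- floor((window - 1) / 2)
  hi <- window - 1 - lo
  vapply(seq_len(n), function(i) {
    mean(series[max(1, i - lo):min(n, i + hi)])
  }, numeric(1))
}

#' Per-frame collective summary of a run
#'
#' Computes, for every recorded frame (after the first), the connected
#' correlation profile at neighborhood radius `r_c`, its correlation length
#' xi0, the susceptibility chi within xi0, and the mean nearest-neighbor
#' distance.
#'
#' @param log a `trajectory_log`.
#' @param r_c neighborhood radius, um; defaults to box/6.
#' @param bin_width profile bin width, um; defaults to the 3-um cell size.
#' @return A data frame with columns `t`, `xi0`, `censored`, `chi`, `nn`.
#' @export
collective_summary <- function(log, r_c = log$box / 6, bin_width = 3) {
  stopifnot(inherits(log, "trajectory_log"))
  frames <- log_frames(log)
  rows <- lapply(frames, function(fr) {
    fl <- directional_fluctuations(fr, r_c)
    res <- try(connected_correlation(fr, r_c, bin_width, fluct = fl),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      return(data.frame(t = fr$t, xi0 = NA_real_, censored = NA, chi = NA_real_,
                        nn = nn_distance(fr$positions, fr$periodic, fr$box)))
    }
    xi0 <- correlation_length(res)
    chi <- if (any(fl$usable) && as.numeric(xi0) > 0) {
      susceptibility(fl, fr$positions, as.numeric(xi0), fr$periodic, fr$box)
    } else NA_real_
    data.frame(t = fr$t, xi0 = as.numeric(xi0),
               censored = isTRUE(attr(xi0, "censored")), chi = chi,
               nn = nn_distance(fr$positions, fr$periodic, fr$box))
  })
  do.call(rbind, rows)
}

#' Locate the streaming window of a run
#'
#' A fixed-width time window centered on the maximum of the smoothed
#' susceptibility series chi(t).
#'
#' @param summary output of [collective_summary()].
#' @param width window width, min (50 for simulations, 150 for experimental
#'   tracks).
#' @param smooth_frames moving-average span applied to chi before locating
#'   the peak.
#' @return `c(t1, t2)`.
#' @export
streaming_window <- function(summary, width = 50, smooth_frames = 10) {
  chi <- summary$chi
  ok <- is.finite(chi)
  if (!any(ok)) stop("no finite chi values")
  sm <- rep(NA_real_, length(chi))
  sm[ok] <- smooth_series(chi[ok], min(smooth_frames, sum(ok)))
  center <- summary$t[which.max(sm)]
  lo <- max(min(summary$t), center - width / 2)
  c(lo, lo + width)
}
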