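# Literal double-loop reference implementations of the pairwise statistics.
# These are deliberately naive and independent of the package's C++ path.

oracle_dist <- function(p, i, j, box = NULL, periodic = FALSE) {
  d <- p[i, ] - p[j, ]
  if (periodic) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

# ring-binned pair correlation, ring radii at multiples of a
oracle_pair_correlation <- function(pos, area, a, r_max, box = NULL,
                                    periodic = FALSE) {
  n <- nrow(pos)
  nbin <- floor(r_max / a)
  counts <- numeric(nbin)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- oracle_dist(pos, i, j, box, periodic)
    k <- floor(d / a + 0.5)
    if (k >= 1 && k <= nbin) counts[k] <- counts[k] + 1
  }
  r <- a * seq_len(nbin)
  list(r = r, g = area / (n * (n - 1)) * counts / (2 * pi * r * a),
       counts = counts)
}

# nonconnected correlation, bins [k*a, (k+1)*a)
oracle_nonconnected <- function(pos, vel, a, r_max, box = NULL,
                                periodic = FALSE) {
  sp <- sqrt(rowSums(vel^2))
  keep <- sp > 0
  pos <- pos[keep, , drop = FALSE]
  u <- vel[keep, , drop = FALSE] / sp[keep]
  n <- nrow(pos)
  nbin <- ceiling(r_max / a)
  sums <- counts <- numeric(nbin)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- oracle_dist(pos, i, j, box, periodic)
    k <- floor(d / a) + 1
    if (k >= 1 && k <= nbin) {
      sums[k] <- sums[k] + sum(u[i, ] * u[j, ])
      counts[k] <- counts[k] + 1
    }
  }
  list(centers = (seq_len(nbin) - 0.5) * a, sums = sums, counts = counts,
       values = ifelse(counts > 0, sums / pmax(counts, 1), NA))
}

# per-cell normalized velocity fluctuations about the local neighborhood mean
oracle_fluctuations <- function(pos, vel, r_c, box = NULL, periodic = FALSE) {
  n <- nrow(pos)
  du <- matrix(0, n, 2)
  usable <- logical(n)
  for (i in seq_len(n)) {
    nb <- c(i, setdiff(which(sapply(seq_len(n), function(j) {
      j != i && oracle_dist(pos, i, j, box, periodic) <= r_c
    })), i))
    if (length(nb) < 2) next
    m <- colMeans(vel[nb, , drop = FALSE])
    fl <- sweep(vel[nb, , drop = FALSE], 2, m)
    rms <- sqrt(mean(rowSums(fl^2)))
    usable[i] <- TRUE
    if (rms > 0) du[i, ] <- (vel[i, ] - m) / rms
  }
  list(delta_u = du, usable = usable)
}

oracle_connected <- function(pos, du, usable, r_c, a, box = NULL,
                             periodic = FALSE) {
  n <- nrow(pos)
  nbin <- ceiling(r_c / a)
  sums <- counts <- numeric(nbin)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !usable[i] || !usable[j]) next
    d <- oracle_dist(pos, i, j, box, periodic)
    if (d > r_c) next
    k <- floor(d / a) + 1
    if (k >= 1 && k <= nbin) {
      sums[k] <- sums[k] + sum(du[i, ] * du[j, ])
      counts[k] <- counts[k] + 1
    }
  }
  list(sums = sums, counts = counts)
}

oracle_susceptibility <- function(pos, du, usable, xi0, box = NULL,
                                  periodic = FALSE) {
  n <- nrow(pos)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !usable[i] || !usable[j]) next
    if (oracle_dist(pos, i, j, box, periodic) < xi0) {
      total <- total + sum(du[i, ] * du[j, ])
    }
  }
  total / sum(usable)
}

oracle_nn <- function(pos, box = NULL, periodic = FALSE) {
  n <- nrow(pos)
  mean(sapply(seq_len(n), function(i) {
    min(sapply(setdiff(seq_len(n), i), function(j) {
      oracle_dist(pos, i, j, box, periodic)
    }))
  }))
}

# random frame with velocities, for oracle-equivalence sweeps
random_frame <- function(n, box = 100, seed = 1, periodic = FALSE) {
  set.seed(seed)
  cell_frame(positions = cbind(runif(n, 0, box), runif(n, 0, box)),
             velocities = matrix(rnorm(2 * n), n, 2),
             box = box, periodic = periodic)
}

new_test_profile <- function(centers, values) {
  structure(data.frame(bin_center = centers, value = values,
                       pair_count = rep(1, length(centers))),
            class = c("correlation_profile", "data.frame"))
}

# thin a point set so that all pairwise distances exceed min_d
nn_distance_filter <- function(pos, min_d) {
  keep <- rep(TRUE, nrow(pos))
  for (i in seq_len(nrow(pos))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pos))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_d) keep[j] <- FALSE
    }
  }
  pos[keep, , drop = FALSE]
}
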