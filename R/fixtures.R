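#' Completely spatially random (CSR) point pattern
#'
#' @param n number of points.
#' @param box box side, um.
#' @param seed RNG seed (mandatory: all generators are seed-deterministic).
#' @return n x 2 matrix of positions.
#' @export
sample_csr <- function(n, box, seed) {
  if (n < 1) stop("n must be at least 1")
  set.seed(seed)
  cbind(runif(n, 0, box), runif(n, 0, box))
}

#' Thomas cluster process
#'
#' Uniform parents, Poisson-distributed offspring counts, Gaussian
#' displacement of offspring around parents (wrapped into the box).  A
#' clustered null for pair-correlation tests.
#'
#' @param n_parents number of parent points.
#' @param offspring_mean mean offspring per parent.
#' @param sigma cluster spread, um.
#' @param box box side, um.
#' @param seed RNG seed.
#' @return n x 2 matrix of offspring positions.
#' @export
sample_thomas <- function(n_parents, offspring_mean, sigma, box, seed) {
  if (n_parents <= 0 || offspring_mean <= 0 || sigma < 0 || box <= 0) {
    stop("parameters must be positive")
  }
  set.seed(seed)
  parents <- cbind(runif(n_parents, 0, box), runif(n_parents, 0, box))
  counts <- rpois(n_parents, offspring_mean)
  pts <- do.call(rbind, lapply(seq_len(n_parents), function(k) {
    if (counts[k] == 0) return(NULL)
    cbind(parents[k, 1] + rnorm(counts[k], 0, sigma),
          parents[k, 2] + rnorm(counts[k], 0, sigma))
  }))
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  pts %% box
}

#' Unit direction field with known spatial correlation length
#'
#' Two independent Gaussian random field components with exponential spatial
#' covariance `exp(-d / zeta)` are sampled by covariance-matrix
#' factorization and normalized to unit vectors.  Ground truth for
#' correlation-length recovery tests.
#'
#' @param positions n x 2 matrix of points.
#' @param zeta covariance decay length, um.
#' @param seed RNG seed.
#' @return n x 2 matrix of unit directions.
#' @export
sample_correlated_directions <- function(positions, zeta, seed) {
  if (zeta <= 0) stop("zeta must be positive")
  positions <- as_xy(positions)
  n <- nrow(positions)
  set.seed(seed)
  d <- as.matrix(dist(positions))
  cv <- exp(-d / zeta)
  ch <- tryCatch(chol(cv + diag(1e-8, n)), error = function(e) {
    warning("covariance nearly degenerate; jitter-regularized")
    chol(cv + diag(1e-4, n))
  })
  g <- t(ch) %*% matrix(rnorm(2 * n), n, 2)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- 1
  g / nrm
}

#' Render cells as Gaussian spots in a grayscale image
#'
#' Emulates a fluorescence image of a marked subpopulation: each marked cell
#' becomes an additive Gaussian spot of width `spot_sigma`, additive Gaussian
#' pixel noise is applied, and the image is clipped to `[0, 1]`.  Pixel
#' `(i, j)` (row-major, origin top-left) has its center at
#' `((j - 0.5)/px_per_um, (i - 0.5)/px_per_um)` um.
#'
#' @param positions n x 2 positions, um.
#' @param box box side, um.
#' @param px_per_um resolution (default 1 px = 1 um).
#' @param spot_sigma spot standard deviation, um.
#' @param noise_sd additive pixel noise standard deviation.
#' @param marked_fraction fraction of cells rendered (Bernoulli marking).
#' @param seed RNG seed (marking and noise).
#' @return Grayscale matrix (rows = `box * px_per_um`).
#' @export
render_cells <- function(positions, box, px_per_um = 1, spot_sigma = 2,
                         noise_sd = 0, marked_fraction = 1, seed = 1) {
  if (px_per_um <= 0) stop("px_per_um must be positive")
  positions <- as_xy(positions)
  set.seed(seed)
  npix <- max(1L, round(box * px_per_um))
  img <- matrix(0, npix, npix)
  marked <- runif(nrow(positions)) <= marked_fraction
  sig_px <- spot_sigma * px_per_um
  half <- ceiling(4 * sig_px)
  for (k in which(marked)) {
    cx <- positions[k, 1] * px_per_um + 0.5  # pixel-space center (col)
    cy <- positions[k, 2] * px_per_um + 0.5  # (row)
    cols <- max(1, floor(cx - half)):min(npix, ceiling(cx + half))
    rows <- max(1, floor(cy - half)):min(npix, ceiling(cy + half))
    if (!length(cols) || !length(rows)) next
    gx <- exp(-((cols - cx)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - cy)^2) / (2 * sig_px^2))
    img[rows, cols] <- img[rows, cols] + outer(gy, gx)
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(npix^2, 0, noise_sd), npix)
  pmin(pmax(img, 0), 1)
}

#' Image sequence with monotonically increasing clustering
#'
#' Thomas-process frames sharing the same parents and offspring draws, with
#' the cluster spread shrinking along `tightness_ladder`; tightening is a
#' literal contraction of each cluster, so clustering increases
#' monotonically while the point count stays fixed.  A ladder for
#' monotonicity tests of [spatial_information()].
#'
#' @param box box side, um.
#' @param tightness_ladder nonincreasing vector of cluster spreads (um), one
#'   per frame.
#' @param n_parents,offspring_mean Thomas process parameters.
#' @param seed RNG seed.
#' @param ... passed to [render_cells()].
#' @return `list(images =, positions =, sigmas =)`.
#' @export
aggregation_sequence <- function(box, tightness_ladder, n_parents = 10,
                                 offspring_mean = 20, seed = 1, ...) {
  if (is.unsorted(rev(tightness_ladder), strictly = FALSE)) {
    stop("tightness_ladder must be nonincreasing")
  }
  set.seed(seed)
  parents <- cbind(runif(n_parents, 0, box), runif(n_parents, 0, box))
  counts <- rpois(n_parents, offspring_mean)
  offs <- do.call(rbind, lapply(seq_len(n_parents), function(k) {
    if (counts[k] == 0) return(NULL)
    cbind(parent = k, dx = rnorm(counts[k]), dy = rnorm(counts[k]))
  }))
  positions <- lapply(tightness_ladder, function(sg) {
    cbind(parents[offs[, "parent"], 1] + sg * offs[, "dx"],
          parents[offs[, "parent"], 2] + sg * offs[, "dy"]) %% box
  })
  images <- lapply(seq_along(positions), function(i) {
    render_cells(positions[[i]], box = box, seed = seed + i, ...)
  })
  list(images = images, positions = positions, sigmas = tightness_ladder)
}
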