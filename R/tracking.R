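# Centroid detection and nearest-neighbor frame linking, mirroring the
# extended-maxima segmentation + gated nearest-neighbor tracker used to build
# the experimental track tables.

# 8-neighbor grayscale dilation via shifted copies (padding with -Inf)
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- m
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- pmax(out, pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
    }
  }
  out
}

# grayscale reconstruction by dilation of `marker` under `mask`
reconstruct_dilation <- function(marker, mask, max_iter = 10000) {
  cur <- pmin(marker, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(dilate8(cur), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
  cur
}

# h-extended maxima: regional maxima of the h-maxima transform
extended_maxima <- function(image, h, eps = NULL) {
  hmax <- reconstruct_dilation(image - h, image)
  if (is.null(eps)) eps <- max(1e-7, 1e-6 * diff(range(image)))
  rec <- reconstruct_dilation(hmax - eps, hmax)
  (hmax - rec) > eps / 2
}

#' Detect cell centroids in a fluorescence-like image
#'
#' Computes the h-extended-maxima mask of the image (regional maxima that
#' stand at least `h` above their surroundings, via grayscale morphological
#' reconstruction), labels its connected components, and returns component
#' centroids; centroids closer than `min_sep` are merged (intensity-weighted).
#' Coordinates are in pixel units with pixel centers at `(col - 0.5,
#' row - 0.5)`, matching [render_cells()] at 1 px/um.
#'
#' @param image 2-D grayscale matrix.
#' @param h maxima depth; defaults to 10% of the image dynamic range.
#' @param min_sep merge distance, px.
#' @return m x 2 matrix of centroids (columns `x`, `y`); 0 rows for a
#'   featureless image.
#' @export
detect_centroids <- function(image, h = NULL, min_sep = 3) {
  image <- as.matrix(image)
  rng <- diff(range(image))
  if (rng == 0) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  if (is.null(h)) h <- 0.1 * rng
  if (h <= 0) stop("h must be positive")
  mask <- extended_maxima(image, h)
  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(labels)
  keep <- lab > 0
  if (!any(keep)) return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
  rows <- ((seq_along(lab) - 1) %% nrow(image)) + 1
  cols <- ((seq_along(lab) - 1) %/% nrow(image)) + 1
  w <- image[keep]
  w <- w - min(w) + 1e-9
  cx <- tapply(w * (cols[keep] - 0.5), lab[keep], sum) /
    tapply(w, lab[keep], sum)
  cy <- tapply(w * (rows[keep] - 0.5), lab[keep], sum) /
    tapply(w, lab[keep], sum)
  cents <- cbind(x = as.numeric(cx), y = as.numeric(cy))
  wt <- as.numeric(tapply(w, lab[keep], sum))
  merge_close(cents, wt, min_sep)
}

merge_close <- function(cents, weights, min_sep) {
  repeat {
    if (nrow(cents) < 2) break
    d <- as.matrix(dist(cents))
    diag(d) <- Inf
    m <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[m[1], m[2]] >= min_sep) break
    i <- min(m); j <- max(m)
    wsum <- weights[i] + weights[j]
    cents[i, ] <- (weights[i] * cents[i, ] + weights[j] * cents[j, ]) / wsum
    weights[i] <- wsum
    cents <- cents[-j, , drop = FALSE]
    weights <- weights[-j]
  }
  cents
}

#' Link centroids between consecutive frames
#'
#' For every point at time t the nearest point at t+1 is found; a link is
#' accepted only if its displacement is below `gate` (default 10.7 um, the
#' average cell minor axis).  When two sources claim the same target, links
#' are resolved greedily by ascending distance and losers are left unlinked;
#' ties break on the lower source index, so the result is independent of
#' input order.
#'
#' @param points_t m x 2 matrix of positions at time t.
#' @param points_t1 k x 2 matrix of positions at time t+1.
#' @param gate maximum accepted displacement (same units as the points).
#' @return Data frame with columns `x`, `y`, `x_next`, `y_next` (one row per
#'   accepted link).
#' @export
link_frames <- function(points_t, points_t1, gate = 10.7) {
  if (gate <= 0) stop("gate must be positive")
  empty <- data.frame(x = numeric(0), y = numeric(0), x_next = numeric(0),
                      y_next = numeric(0))
  if (NROW(points_t) == 0 || NROW(points_t1) == 0) return(empty)
  points_t <- as_xy(points_t)
  points_t1 <- as_xy(points_t1)
  d2 <- outer(points_t[, 1], points_t1[, 1], "-")^2 +
    outer(points_t[, 2], points_t1[, 2], "-")^2
  nearest <- apply(d2, 1, which.min)
  nd <- sqrt(d2[cbind(seq_len(nrow(points_t)), nearest)])
  ord <- order(nd, seq_along(nd))
  taken <- logical(nrow(points_t1))
  rows <- vector("list", length(ord))
  for (i in ord) {
    if (nd[i] >= gate) next
    tgt <- nearest[i]
    if (taken[tgt]) next
    taken[tgt] <- TRUE
    rows[[i]] <- data.frame(x = points_t[i, 1], y = points_t[i, 2],
                            x_next = points_t1[tgt, 1],
                            y_next = points_t1[tgt, 2])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty else out
}

#' Convert a linked-pair track table to analysis frames
#'
#' Velocities are forward differences of linked positions divided by the
#' frame interval; the output frames feed the correlation statistics
#' directly.
#'
#' @param links data frame with columns `frame`, `x`, `y`, `x_next`,
#'   `y_next` (see [read_tracks()]).
#' @param dt frame interval, min.
#' @param box,periodic geometry metadata forwarded to [cell_frame()].
#' @return List of [cell_frame()] objects, one per frame present.
#' @export
tracks_to_frames <- function(links, dt, box = NULL, periodic = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  if (nrow(links) == 0) return(list())
  need <- c("frame", "x", "y", "x_next", "y_next")
  if (!all(need %in% names(links))) {
    stop("links must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(links, links$frame), function(d) {
    cell_frame(positions = cbind(d$x, d$y),
               velocities = cbind((d$x_next - d$x) / dt,
                                  (d$y_next - d$y) / dt),
               t = d$frame[1] * dt, box = box, periodic = periodic)
  })
}

#' Track centroids through an image sequence
#'
#' Runs [detect_centroids()] on every image and [link_frames()] between
#' consecutive frames.
#'
#' @param images list of grayscale matrices.
#' @param gate link gate (pixel units unless images are calibrated).
#' @param h,min_sep forwarded to [detect_centroids()].
#' @return Data frame with columns `frame`, `x`, `y`, `x_next`, `y_next`.
#' @export
track_images <- function(images, gate = 10.7, h = NULL, min_sep = 3) {
  cents <- lapply(images, detect_centroids, h = h, min_sep = min_sep)
  rows <- lapply(seq_len(length(cents) - 1), function(f) {
    lk <- link_frames(cents[[f]], cents[[f + 1]], gate = gate)
    if (nrow(lk)) cbind(frame = f, lk) else NULL
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                      x_next = numeric(0), y_next = numeric(0))
  }
  out
}
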