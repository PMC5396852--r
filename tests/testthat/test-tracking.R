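test_that("centroid detection recovers rendered spots", {
  img <- render_cells(rbind(c(50, 50)), box = 100, spot_sigma = 2,
                      noise_sd = 0, seed = 1)
  cents <- detect_centroids(img)
  expect_equal(nrow(cents), 1)
  expect_lt(max(abs(cents[1, ] - c(50, 50))), 1)
  # blank image: empty set, not an error
  expect_equal(nrow(detect_centroids(matrix(0.3, 40, 40))), 0)
  # two well-separated spots
  img2 <- render_cells(rbind(c(30, 50), c(60, 50)), box = 100,
                       spot_sigma = 2, noise_sd = 0, seed = 1)
  cents2 <- detect_centroids(img2)
  expect_equal(nrow(cents2), 2)
  expect_error(detect_centroids(img2, h = -1), "positive")
})

test_that("detection tolerates pixel noise on a marked subpopulation", {
  set.seed(2)
  pos <- sample_csr(40, 150, 2)
  # enforce separation so ground truth is unambiguous
  keep <- nn_distance_filter(pos, 12)
  img <- render_cells(keep, box = 150, spot_sigma = 2, noise_sd = 0.03,
                      seed = 3)
  cents <- detect_centroids(img, min_sep = 4)
  matched <- sum(apply(keep, 1, function(p) {
    any(sqrt((cents[, 1] - p[1])^2 + (cents[, 2] - p[2])^2) < 3)
  }))
  expect_gte(matched / nrow(keep), 0.99)
})

test_that("frame linking applies the distance gate and greedy conflicts", {
  a <- rbind(c(10, 10), c(40, 40))
  # identity links with zero displacement
  lk <- link_frames(a, a)
  expect_equal(nrow(lk), 2)
  expect_equal(lk$x, lk$x_next)
  # 5 um displacement accepted under the 10.7 um gate; 15 um rejected
  lk2 <- link_frames(rbind(c(10, 10)), rbind(c(15, 10)))
  expect_equal(nrow(lk2), 1)
  lk3 <- link_frames(rbind(c(10, 10)), rbind(c(25, 10)))
  expect_equal(nrow(lk3), 0)
  # conflict: two sources, one target; the closer source wins, loser unlinked
  lk4 <- link_frames(rbind(c(0, 0), c(4, 0)), rbind(c(3, 0)))
  expect_equal(nrow(lk4), 1)
  expect_equal(lk4$x, 4)
  expect_error(link_frames(a, a, gate = 0), "positive")
  expect_equal(nrow(link_frames(matrix(numeric(0), 0, 2), a)), 0)
})

test_that("greedy resolution is order-independent for distinct distances", {
  set.seed(9)
  a <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  b <- a + matrix(rnorm(60, 0, 2), 30, 2)
  lk <- link_frames(a, b)
  perm <- sample(30)
  lk_perm <- link_frames(a[perm, ], b)
  o1 <- lk[order(lk$x, lk$y), ]
  o2 <- lk_perm[order(lk_perm$x, lk_perm$y), ]
  expect_equal(o1$x_next, o2$x_next)
  expect_equal(o1$y_next, o2$y_next)
})

test_that("linked tracks convert to analysis frames with forward-difference
           velocities", {
  links <- data.frame(frame = c(1, 1, 2), x = c(0, 10, 1), y = c(0, 0, 0),
                      x_next = c(1, 11, 2), y_next = c(0, 0, 0))
  fr <- tracks_to_frames(links, dt = 2)
  expect_equal(length(fr), 2)
  expect_equal(fr[[1]]$velocities[, 1], c(0.5, 0.5))
  expect_equal(fr[[1]]$velocities[, 2], c(0, 0))
  expect_error(tracks_to_frames(links, dt = 0), "positive")
  expect_equal(length(tracks_to_frames(links[0, ], 1)), 0)
})

test_that("tracking a rendered sequence achieves high link precision and
           recall", {
  set.seed(4)
  pos <- nn_distance_filter(sample_csr(35, 160, 4), 14)
  n <- nrow(pos)
  drift <- matrix(rnorm(2 * n, 0, 1.5), n, 2)
  frames <- list(pos, pos + drift, pos + 2 * drift)
  images <- lapply(seq_along(frames), function(i) {
    render_cells(frames[[i]], box = 160, spot_sigma = 2, noise_sd = 0.02,
                 seed = i)
  })
  tracks <- track_images(images, gate = 10.7, min_sep = 4)
  # every link should connect detections of the same ground-truth cell
  ok <- 0
  for (r in seq_len(nrow(tracks))) {
    f <- tracks$frame[r]
    i1 <- which.min((frames[[f]][, 1] - tracks$x[r])^2 +
                    (frames[[f]][, 2] - tracks$y[r])^2)
    i2 <- which.min((frames[[f + 1]][, 1] - tracks$x_next[r])^2 +
                    (frames[[f + 1]][, 2] - tracks$y_next[r])^2)
    if (i1 == i2) ok <- ok + 1
  }
  expect_gte(ok / nrow(tracks), 0.99)          # precision
  expect_gte(nrow(tracks) / (2 * n), 0.95)     # recall over 2 transitions
})

test_that("round trip from a simulated log through a track table reproduces
           the direct statistics", {
  cfg <- swarm_config(n_cells = 60, box_length = 150, seed = 21)
  log <- run_swarm(cfg, t_end = 12, record_every = 2)
  f <- 4
  # linked-pair table from the log: start positions + displacements
  links <- data.frame(frame = 1,
                      x = log$x[, f - 1], y = log$y[, f - 1],
                      x_next = log$x[, f - 1] + log$vx[, f] * 2,
                      y_next = log$y[, f - 1] + log$vy[, f] * 2)
  fr <- tracks_to_frames(links, dt = 2, box = log$box, periodic = TRUE)[[1]]
  direct <- cell_frame(cbind(log$x[, f - 1], log$y[, f - 1]),
                       cbind(log$vx[, f], log$vy[, f]),
                       box = log$box, periodic = TRUE)
  p1 <- nonconnected_correlation(direct, 5, r_max = 70)
  p2 <- nonconnected_correlation(fr, 5, r_max = 70)
  expect_equal(p2$value, p1$value, tolerance = 1e-12)
})
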