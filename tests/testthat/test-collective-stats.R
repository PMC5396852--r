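test_that("pair correlation reproduces the closed-form two-point case", {
  # two points 5 um apart in a 100 um^2 window, a = 1:
  # g(5) = 100/2 * 2 / (2 pi * 5 * 1)
  pos <- rbind(c(10, 10), c(15, 10))
  g <- pair_correlation(pos, area = 100, bin_width = 1, r_max = 10)
  expect_equal(g$value[g$bin_center == 5], 100 / (10 * pi), tolerance = 1e-12)
  expect_equal(g$pair_count[g$bin_center == 5], 2)
  expect_true(all(g$value[g$bin_center != 5] == 0))
})

test_that("CSR pair correlation averages to 1 over mid-range bins", {
  gs <- sapply(1:5, function(seed) {
    pos <- sample_csr(500, 200, seed)
    g <- pair_correlation(pos, area = 200^2, bin_width = 2, r_max = 60,
                          periodic = TRUE, box = 200)
    mean(g$value[g$bin_center >= 10 & g$bin_center <= 50])
  })
  se <- sd(gs) / sqrt(length(gs))
  expect_lt(abs(mean(gs) - 1), 3 * max(se, 1e-3))
})

test_that("Thomas clusters raise g(r) at short range", {
  pos <- sample_thomas(10, 20, sigma = 3, box = 200, seed = 4)
  g <- pair_correlation(pos, area = 200^2, bin_width = 2, r_max = 40)
  expect_gt(mean(g$value[g$bin_center < 6]), 1)
})

test_that("nonconnected correlation matches hand-computed configurations", {
  # aligned pair
  fr <- cell_frame(rbind(c(0, 0), c(5, 0)), rbind(c(1, 0), c(1, 0)))
  p <- nonconnected_correlation(fr, bin_width = 3)
  expect_equal(p$value[p$pair_count > 0], 1)
  # anti-aligned pair
  fr2 <- cell_frame(rbind(c(0, 0), c(5, 0)), rbind(c(1, 0), c(-1, 0)))
  p2 <- nonconnected_correlation(fr2, bin_width = 3)
  expect_equal(p2$value[p2$pair_count > 0], -1)
  # three near cells with headings 0, 0, 90 degrees: (2*1 + 4*0)/6 = 1/3
  fr3 <- cell_frame(rbind(c(0, 0), c(1, 0), c(0.5, 1)),
                    rbind(c(1, 0), c(1, 0), c(0, 1)))
  p3 <- nonconnected_correlation(fr3, bin_width = 3)
  expect_equal(sum(p3$value * p3$pair_count) / sum(p3$pair_count), 1 / 3,
               tolerance = 1e-12)
  # zero-velocity cells are excluded; all-zero errors
  fr4 <- cell_frame(rbind(c(0, 0), c(5, 0)), rbind(c(0, 0), c(0, 0)))
  expect_error(nonconnected_correlation(fr4, 3), "zero")
})

test_that("directional fluctuations handle the canonical cases", {
  # uniform velocity field: all fluctuations vanish but cells stay usable
  fr <- cell_frame(cbind(runif(10, 0, 20), runif(10, 0, 20)),
                   matrix(rep(c(1, 0), each = 10), 10, 2))
  fl <- directional_fluctuations(fr, r_c = 50)
  expect_true(all(fl$usable))
  expect_true(all(fl$delta_u == 0))
  # counter-moving pair: delta_u = +/- x, C_c(4) = -1
  fr2 <- cell_frame(rbind(c(0, 0), c(4, 0)), rbind(c(1, 0), c(-1, 0)))
  fl2 <- directional_fluctuations(fr2, r_c = 10)
  expect_true(all(fl2$usable))
  expect_equal(fl2$delta_u, rbind(c(1, 0), c(-1, 0)), tolerance = 1e-12)
  cc <- connected_correlation(fr2, r_c = 10, bin_width = 4, fluct = fl2)
  expect_equal(cc$value[cc$bin_center == 6], -1, tolerance = 1e-12)
  # isolated cell flagged unusable
  fr4 <- cell_frame(rbind(c(0, 0), c(100, 100), c(101, 100)),
                    matrix(rnorm(6), 3, 2))
  fl4 <- directional_fluctuations(fr4, r_c = 5)
  expect_false(fl4$usable[1])
})

test_that("binned statistics match the literal double-loop references", {
  for (seed in 1:6) {
    fr <- random_frame(80, box = 100, seed = seed, periodic = seed %% 2 == 0)
    a <- 4
    # nonconnected
    p <- nonconnected_correlation(fr, a, r_max = 50)
    o <- oracle_nonconnected(fr$positions, fr$velocities, a, 50,
                             box = fr$box, periodic = fr$periodic)
    keep <- o$counts > 0
    expect_equal(p$value, o$values[keep], tolerance = 1e-12)
    expect_equal(p$pair_count, o$counts[keep])
    # fluctuations + connected + susceptibility
    fl <- directional_fluctuations(fr, r_c = 30)
    of <- oracle_fluctuations(fr$positions, fr$velocities, 30,
                              box = fr$box, periodic = fr$periodic)
    expect_equal(as.logical(fl$usable), of$usable)
    expect_equal(fl$delta_u, of$delta_u, tolerance = 1e-12)
    cc <- connected_correlation(fr, r_c = 30, bin_width = a, fluct = fl)
    oc <- oracle_connected(fr$positions, of$delta_u, of$usable, 30, a,
                           box = fr$box, periodic = fr$periodic)
    keep <- oc$counts > 0
    expect_equal(cc$value, (oc$sums / pmax(oc$counts, 1))[keep],
                 tolerance = 1e-12)
    chi <- susceptibility(fl, fr$positions, 15, fr$periodic, fr$box)
    expect_equal(chi,
                 oracle_susceptibility(fr$positions, of$delta_u, of$usable,
                                       15, fr$box, fr$periodic),
                 tolerance = 1e-12)
    # nn distance
    expect_equal(nn_distance(fr$positions, fr$periodic, fr$box),
                 oracle_nn(fr$positions, fr$box, fr$periodic),
                 tolerance = 1e-12)
    # pair correlation counts
    g <- pair_correlation(fr$positions, 100^2, 2, 40,
                          periodic = fr$periodic, box = fr$box)
    og <- oracle_pair_correlation(fr$positions, 100^2, 2, 40,
                                  box = fr$box, periodic = fr$periodic)
    expect_equal(g$value, og$g, tolerance = 1e-12)
  }
})

test_that("correlation values respect their bounds", {
  for (seed in 1:5) {
    fr <- random_frame(60, seed = seed)
    p <- nonconnected_correlation(fr, 5)
    expect_true(all(p$value >= -1 - 1e-12 & p$value <= 1 + 1e-12))
    g <- pair_correlation(fr$positions, 100^2, 2, 40)
    expect_true(all(g$value >= 0))
  }
})

test_that("correlation length interpolates the first zero crossing", {
  prof <- new_test_profile(c(3, 6, 9), c(0.8, 0.2, -0.1))
  xi <- correlation_length(prof)
  expect_equal(as.numeric(xi), 8, tolerance = 1e-12)
  expect_false(attr(xi, "censored"))
  # exact root on the grid
  r <- 1:10
  prof2 <- new_test_profile(r, 1 - r / 5)
  expect_equal(as.numeric(correlation_length(prof2)), 5)
  # all-positive profile returns a censored sentinel
  prof3 <- new_test_profile(r, rep(0.5, 10))
  xi3 <- correlation_length(prof3)
  expect_true(attr(xi3, "censored"))
  expect_equal(as.numeric(xi3), 10)
  expect_error(correlation_length(new_test_profile(3, 1)), "2 bins")
})

test_that("susceptibility matches hand evaluations", {
  # 3 mutually close cells with identical unit delta_u: chi = 6/3 = 2
  fl <- structure(list(delta_u = matrix(rep(c(1, 0), each = 3), 3, 2),
                       usable = rep(TRUE, 3), n_neighbors = rep(2L, 3),
                       r_c = 10), class = "fluctuation_set")
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(susceptibility(fl, pos, 5), 2)
  # opposed pair: chi = -1
  fl2 <- structure(list(delta_u = rbind(c(1, 0), c(-1, 0)),
                        usable = rep(TRUE, 2), n_neighbors = rep(1L, 2),
                        r_c = 10), class = "fluctuation_set")
  expect_equal(susceptibility(fl2, rbind(c(0, 0), c(1, 0)), 5), -1)
  # independent random delta_u: chi near 0
  chis <- sapply(1:20, function(seed) {
    set.seed(seed)
    n <- 1000
    du <- matrix(rnorm(2 * n), n, 2)
    du <- du / sqrt(rowSums(du^2))
    flr <- structure(list(delta_u = du, usable = rep(TRUE, n),
                          n_neighbors = rep(5L, n), r_c = 50),
                     class = "fluctuation_set")
    susceptibility(flr, cbind(runif(n, 0, 200), runif(n, 0, 200)), 15)
  })
  expect_lt(abs(mean(chis)), 0.1)
})

test_that("nn distance matches hand cases", {
  expect_equal(nn_distance(cbind(c(0, 3, 9), 0)), (3 + 3 + 6) / 3)
  grid <- as.matrix(expand.grid(seq(0, 20, 4), seq(0, 20, 4)))
  expect_equal(nn_distance(grid), 4)
  expect_error(nn_distance(matrix(1, 1, 2)), "at least 2")
})

test_that("profile collapse is exact for self-similar exponentials", {
  x <- seq(0.05, 3, by = 0.05)
  profs <- lapply(c(5, 10, 20), function(z) new_test_profile(z * x, exp(-x)))
  cp <- collapse_profiles(profs, list(5, 10, 20))
  expect_lt(cp$dispersion, 1e-10)
  # identical profiles collapse with zero dispersion
  cp2 <- collapse_profiles(profs[c(1, 1)], list(5, 5))
  expect_equal(cp2$dispersion, 0)
  # censored xi0 values are excluded with a warning
  xi_c <- structure(60, censored = TRUE)
  expect_warning(collapse_profiles(profs, list(5, 10, xi_c)), "censored")
})

test_that("moving-average smoothing matches hand cases", {
  expect_equal(smooth_series(rep(2, 10), 4), rep(2, 10))
  expect_equal(smooth_series(1:5, 1), 1:5)
  w <- 5
  x <- rep(0, 11); x[6] <- w
  sm <- smooth_series(x, w)
  expect_equal(sm[4:8], rep(1, 5))
  expect_error(smooth_series(1:3, 5), "window")
  expect_error(smooth_series(1:3, 1.5), "whole number")
})

test_that("xi0 recovery increases with the generator correlation length", {
  xi_by_zeta <- sapply(c(5, 15, 45), function(zeta) {
    median(sapply(1:8, function(seed) {
      pos <- sample_csr(250, 150, seed)
      u <- sample_correlated_directions(pos, zeta, seed + 100)
      fr <- cell_frame(pos, u, box = 150)
      prof <- nonconnected_correlation(fr, bin_width = 3, r_max = 75)
      as.numeric(correlation_length(prof))
    }))
  })
  expect_true(all(diff(xi_by_zeta) > 0))
})

test_that("scaling analysis is flat for short-range fields and errors on an
           empty window", {
  # synthetic log with an intrinsically short correlation length
  set.seed(9)
  n <- 200; box <- 150
  pos <- sample_csr(n, box, 9)
  u <- sample_correlated_directions(pos, 5, 10)
  log <- structure(list(t = c(0, 1, 2),
                        x = cbind(pos[, 1], pos[, 1], pos[, 1]),
                        y = cbind(pos[, 2], pos[, 2], pos[, 2]),
                        vx = cbind(NA, u[, 1], u[, 1]),
                        vy = cbind(NA, u[, 2], u[, 2]),
                        phase = matrix(0L, n, 3), config = NULL,
                        box = box, periodic = FALSE),
                   class = "trajectory_log")
  sc <- scaling_analysis(log, radii = box / c(10, 6, 2), window = c(1, 2),
                         bin_width = 3)
  expect_equal(nrow(sc), 3)
  # short intrinsic range: xi0 stays bounded well below the neighborhood
  # radius and within a few intrinsic lengths (the local-mean estimator
  # carries a mild r_c-dependent component, so exact flatness is not expected)
  expect_true(all(sc$mean_xi0 < pmin(sc$r_c, 5 * 5)))
  # single-frame window: SE = 0
  sc1 <- scaling_analysis(log, radii = box / 6, window = c(0.5, 1.5),
                          bin_width = 3)
  expect_equal(sc1$se, 0)
  expect_error(scaling_analysis(log, box / 6, c(10, 20), 3), "empty")
})
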