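base_cfg <- function(...) {
  args <- modifyList(list(n_cells = 50, box_length = 120, seed = 7),
                     list(...))
  do.call(swarm_config, args)
}

test_that("config validation enforces the model invariants", {
  expect_s3_class(swarm_config(), "swarm_config")
  expect_error(swarm_config(turn_half_angle = 95), "90")
  expect_error(swarm_config(dt = 10, refractory_min = 6), "refractory")
  expect_error(swarm_config(dt = 2, pulse_duration = 1), "pulse_duration")
  expect_error(swarm_config(exclusion_radius = 500, box_length = 100),
               "exclusion_radius")
  expect_error(swarm_config(speed = -1), "positive")
  expect_error(swarm_config(box_length = NaN), "non-finite")
  expect_error(run_swarm(swarm_config(), t_end = -5), "positive")
})

test_that("monolayer arithmetic matches the reference density", {
  # 6,600 cells/mm^2 over a 389-um box is about 1,000 cells
  expect_equal(round(cells_for_ml(1, 389), -2), 1000)
  expect_equal(density_ml(1000, 389), 1000 / 389^2 * 1e6 / 6600)
})

test_that("the two pseudopod candidates span the expected full angle", {
  cfg <- base_cfg(conc_threshold_c1 = 1e6, grad_threshold_c2 = 1e6,
                  field_cutoff = 50, n_cells = 1, baseline_noise_sd = 0)
  set.seed(1)
  st <- swarm_state(cfg)
  st$position <- matrix(c(60, 60), 1)
  st$heading <- matrix(c(1, 0), 1)
  headings <- t(replicate(40, {
    st2 <- swarm_step(st)
    st <<- st2
    st2$heading[1, ]
  }))
  turns <- acos(pmin(pmax(rowSums(headings[-1, ] * headings[-40, ]), -1), 1))
  # every step turns by exactly the half-angle; the two candidates differ by
  # twice that
  expect_true(all(abs(turns * 180 / pi - 27.5) < 1e-6))
  expect_equal(2 * cfg$turn_half_angle, 55)
})

test_that("sensed field matches the analytic single-emitter profile", {
  cfg <- base_cfg(n_cells = 2, leak_amplitude = 1, decay_const = 0.1,
                  field_cutoff = 60)
  set.seed(1)
  st <- swarm_state(cfg)
  st$position <- rbind(c(60, 60), c(30, 30))
  st$heading <- rbind(c(1, 0), c(0, 1))  # emitter rear faces -x
  st$phase <- c(0L, 0L)
  # directly behind (theta = 0): concentration = exp(-lambda r)
  f <- sensed_field(st, c(50, 60), exclude = 2)
  expect_equal(f$concentration, exp(-0.1 * 10), tolerance = 1e-12)
  # gradient points towards the emitter from behind
  expect_gt(f$gradient[1], 0)
  # frontal half contributes zero
  f2 <- sensed_field(st, c(70, 60), exclude = 2)
  expect_equal(f2$concentration, 0)
  # lateral (theta = 90 degrees) contributes zero
  f3 <- sensed_field(st, c(60, 70), exclude = 2)
  expect_equal(f3$concentration, 0)
  # rear bias: behind >= lateral >= frontal at matched distances
  set.seed(42)
  for (ang in runif(20, 0, 2 * pi)) {
    r <- 15
    q <- c(60 + r * cos(ang), 60 + r * sin(ang))
    fc <- sensed_field(st, q, exclude = 2)$concentration
    behind <- sensed_field(st, c(60 - r, 60), exclude = 2)$concentration
    expect_lte(fc, behind + 1e-12)
    expect_gte(fc, 0)
  }
  # errors
  expect_error(sensed_field(st, c(-5, 10)), "outside")
  expect_error(sensed_field(st, c(10, 10), exclude = 99), "index")
})

test_that("uniform secretion is isotropic and conserves the emitted total", {
  cfg <- base_cfg(n_cells = 2, secretion_mode = "uniform", field_cutoff = 60)
  set.seed(1)
  st <- swarm_state(cfg)
  st$position <- rbind(c(60, 60), c(10, 10))
  st$heading <- rbind(c(1, 0), c(0, 1))
  vals <- sapply(seq(0, 2 * pi, length.out = 9)[-9], function(a) {
    sensed_field(st, c(60 + 15 * cos(a), 60 + 15 * sin(a)),
                 exclude = 2)$concentration
  })
  expect_lt(diff(range(vals)), 1e-12)
  # equal-total weight: uniform value = rear-mode peak / pi
  expect_equal(vals[1], exp(-0.1 * 15) / pi, tolerance = 1e-12)
})

test_that("the firing threshold calibration holds", {
  cal <- calibrate_thresholds(swarm_config())
  expect_true(cal$isolated_never_fires)
  expect_true(cal$cluster_triggers)
  expect_true(cal$relay_is_contact_scale)
})

test_that("a quiescent cell in zero field performs a turn-angle random walk", {
  cfg <- base_cfg(n_cells = 1, leak_amplitude = 1e-12, field_cutoff = 50,
                  baseline_noise_sd = 0)
  set.seed(3)
  st <- swarm_state(cfg)
  st$position <- matrix(c(60, 60), 1)
  st$heading <- matrix(c(1, 0), 1)
  pos0 <- st$position
  picks <- replicate(60, {
    h0 <- st$heading[1, ]
    st <<- swarm_step(st)
    # cross product sign distinguishes the +/- candidates
    sign(h0[1] * st$heading[1, 2] - h0[2] * st$heading[1, 1])
  })
  # step length is speed * dt and both directions occur
  expect_true(all(c(-1, 1) %in% picks))
  expect_gt(sum(picks > 0), 10)
  expect_lt(sum(picks > 0), 50)
})

test_that("volume exclusion separates overlapping pairs", {
  cfg <- base_cfg(n_cells = 2, leak_amplitude = 1e-12, field_cutoff = 50,
                  baseline_noise_sd = 0)
  set.seed(5)
  st <- swarm_state(cfg)
  st$position <- rbind(c(60, 60), c(62, 60))  # 2 um < 3 um apart
  st <- swarm_step(st)
  d <- sqrt(sum((st$position[1, ] - st$position[2, ])^2))
  expect_gte(d, 3 - 1e-9)
})

test_that("same seed gives bitwise-identical runs and conserved cell number", {
  cfg <- base_cfg(n_cells = 30)
  log1 <- run_swarm(cfg, t_end = 10, record_every = 1)
  log2 <- run_swarm(cfg, t_end = 10, record_every = 1)
  expect_identical(log1$x, log2$x)
  expect_identical(log1$phase, log2$phase)
  expect_equal(nrow(log1$x), 30)
  expect_true(all(colSums(!is.na(log1$x)) == 30))
  # positions stay inside the box
  expect_true(all(log1$x >= 0 & log1$x <= cfg$box_length))
  # step-level replay from a stored state is identical too
  set.seed(cfg$seed)
  st <- swarm_state(cfg)
  a <- swarm_step(st)
  b <- swarm_step(st)
  expect_identical(a$position, b$position)
})

test_that("firing counts and matched rate come from the phase labels", {
  cfg <- base_cfg(n_cells = 20)
  log <- run_swarm(cfg, t_end = 5, record_every = 1)
  fir <- count_firing(log)
  expect_equal(nrow(fir), length(log$t))
  # hand-built log: 3 firing of 10
  fake <- log
  fake$phase <- matrix(0L, 10, 2)
  fake$phase[1:3, 2] <- 1L
  fake$x <- fake$x[1:10, 1:2]; fake$y <- fake$y[1:10, 1:2]
  fake$t <- c(0, 1)
  expect_equal(count_firing(fake)$value, c(0, 3))
  expect_equal(matched_async_rate(fake), 3 / 10 / 1)
  fake$phase <- NULL
  expect_error(count_firing(fake), "phase")
})

test_that("relay activity requires sufficient density", {
  # around one monolayer: sustained firing appears during the run
  cfg_hi <- swarm_config(n_cells = 220, box_length = 180, seed = 11)
  log_hi <- run_swarm(cfg_hi, t_end = 150, record_every = 1)
  frac_hi <- mean(count_firing(log_hi)$value > 0)
  expect_gt(frac_hi, 0)
  # far below 1/3 ML: no sustained relay
  cfg_lo <- swarm_config(n_cells = 12, box_length = 300, seed = 11)
  log_lo <- run_swarm(cfg_lo, t_end = 150, record_every = 1)
  expect_lt(mean(count_firing(log_lo)$value > 0), 0.02)
})

test_that("aggregation raises the spatial information of the final frame", {
  cfg <- swarm_config(n_cells = 220, box_length = 180, seed = 3)
  log <- run_swarm(cfg, t_end = 250, record_every = 10)
  ks <- spatial_information_series(log)
  nf <- nrow(ks)
  expect_gt(median(ks$ksi[(nf - 3):nf]), median(ks$ksi[1:3]))
})

test_that("perturbations are validated and a zero pulse is a no-op", {
  cfg <- base_cfg(n_cells = 25)
  ctrl <- run_swarm(cfg, t_end = 8, record_every = 1)
  null_pert <- run_swarm(cfg, t_end = 8, record_every = 1,
                         perturb = list(kind = "global", amount = 0, time = 2))
  expect_identical(ctrl$x, null_pert$x)
  set.seed(1)
  st <- swarm_state(cfg)
  expect_error(apply_perturbation(st, "global", -1), "non-negative")
  expect_error(apply_perturbation(st, "point", 1), "location")
  # a scheduled point perturbation changes the sensed field
  st2 <- apply_perturbation(st, "point", 5, c(60, 60))
  f <- sensed_field(st2, c(70, 60))
  f0 <- sensed_field(st, c(70, 60))
  expect_equal(f$concentration - f0$concentration, 5 * exp(-0.1 * 10),
               tolerance = 1e-12)
})

test_that("mutant variants alter the intended parameters only", {
  cfg <- swarm_config()
  expect_equal(swarm_variant(cfg, "uniform")$secretion_mode, "uniform")
  expect_equal(swarm_variant(cfg, "noise10x")$sensing_noise_sd, 10)
  expect_true(swarm_variant(cfg, "adhesion")$adhesion_on)
  av <- swarm_variant(cfg, "async", async_rate = 0.05)
  expect_true(av$async_pulsing)
  expect_equal(av$async_rate, 0.05)
  expect_equal(swarm_variant(cfg, "wt")$secretion_mode, cfg$secretion_mode)
})

test_that("trajectory logs export and re-import faithfully", {
  cfg <- base_cfg(n_cells = 15)
  log <- run_swarm(cfg, t_end = 5, record_every = 1)
  d <- as.data.frame(log)
  expect_equal(nrow(d), 15 * length(log$t))
  dir <- tempfile()
  paths <- write_trajectory(log, dir)
  log2 <- read_trajectory(paths["csv"])
  expect_equal(log2$x, log$x, ignore_attr = TRUE)
  expect_equal(log2$phase, log$phase, ignore_attr = TRUE)
  expect_equal(log2$box, log$box)
})
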