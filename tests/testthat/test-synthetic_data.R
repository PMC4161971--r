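trk <- build_track_a()

test_that("schedules are reproducible, covering, and arm-independent", {
  s1 <- simulate_schedule(trk, n_moves = 40, seed = 5)
  s2 <- simulate_schedule(trk, n_moves = 40, seed = 5)
  expect_identical(s1$table, s2$table)
  expect_identical(nrow(s1$table), 41L)
  # every vertical section of each arm populated at least three times
  expect_gte(min(tabulate(s1$table$section_top, 12)), 3)
  expect_gte(min(tabulate(s1$table$section_bottom, 12)), 3)
  expect_false(s1$coverage_warning)
  # the two arms' extents are unrelated
  s3 <- simulate_schedule(trk, n_moves = 200, seed = 9)
  expect_lt(abs(cor(s3$table$top_extent_cm, s3$table$bottom_extent_cm)), 0.2)
  # too few moves for full coverage: flagged, not an error
  expect_warning(s4 <- simulate_schedule(trk, n_moves = 8, seed = 1,
                                         extent_sampler = "uniform"),
                 "section")
  expect_true(s4$coverage_warning)
})

test_that("trajectory alternates wells with realistic run timing", {
  run <- track_a_run("linear_fraction", 1)
  traj <- run$bundle$trajectory
  # strict F1, F2, F1, ... alternation of pause positions
  pauses <- traj[traj$phase == "pause", ]
  med_xl <- tapply(pauses$x_l_cm, pauses$epoch, median)
  expect_true(all(abs(med_xl[seq(1, length(med_xl), 2)]) < 5))
  expect_true(all(abs(med_xl[seq(2, length(med_xl), 2)] - 400) < 5))
  # mean well-to-well run duration close to the 34 s protocol
  runs <- traj[traj$phase == "run", ]
  dur <- tapply(runs$t_s, runs$epoch, function(z) max(z) - min(z))
  expect_lt(abs(mean(dur) - 34), 5)
  # lateral wander bounded by the rails
  expect_true(all(abs(traj$y_l_cm) <= trk$track_width_cm / 2))
  # configuration changes only at epoch boundaries
  expect_true(all(tapply(traj$config_id, traj$epoch,
                         function(z) length(unique(z))) == 1L))
})

test_that("place-cell populations sample their anchored ranges uniformly", {
  expect_identical(make_place_cells(0, "planar", trk), list())
  cells <- make_place_cells(500, "linear_fraction", trk, seed = 2)
  fr <- vapply(cells, function(cl) cl$centre$fraction, numeric(1))
  expect_true(all(fr >= 0 & fr <= 1))
  big <- make_place_cells(10000, "linear_fraction", trk, seed = 3)
  frb <- vapply(big, function(cl) cl$centre$fraction, numeric(1))
  expect_gt(suppressWarnings(ks.test(frb, "punif")$p.value), 0.01)
  expect_error(make_place_cells(5, "grid_cell", trk))
  # reproducibility
  a <- make_place_cells(5, "segment_bound", trk, seed = 4)
  b <- make_place_cells(5, "segment_bound", trk, seed = 4)
  expect_identical(a, b)
})

test_that("Gaussian tuning peaks at the anchored centre and decays to baseline", {
  cfg <- track_a_config(trk, 90, 90)
  cell <- make_place_cells(1, "linear_fraction", trk, seed = 1)[[1]]
  ctr <- cell$centre$fraction * 400
  xy <- planar_from_linear(trk, cfg, ctr)
  expect_equal(instantaneous_rate(cell, trk, cfg, xy[1], xy[2], ctr),
               cell$peak_hz)
  far <- instantaneous_rate(cell, trk, cfg, xy[1], xy[2], ctr + 1e6)
  expect_equal(far, cell$baseline_hz)
  # elastic-fraction tuning is identical across Track A configurations
  cfg2 <- track_a_config(trk, 40, 150)
  x <- seq(0, 400, by = 0.5)
  r1 <- instantaneous_rate(cell, trk, cfg, 0, 0, x)
  r2 <- instantaneous_rate(cell, trk, cfg2, 0, 0, x)
  expect_lt(max(abs(r1 - r2)), 1e-9)
})

test_that("rate remapping changes amplitude but not field location", {
  cfg <- track_a_config(trk, 90, 90, config_id = "c001")
  cell <- make_place_cells(1, "linear_fraction", trk, seed = 6)[[1]]
  cell$rate_gain <- c(c001 = 0.4)
  x <- seq(0, 400, by = 1)
  r <- instantaneous_rate(cell, trk, cfg, 0, 0, x)
  cell$rate_gain <- NULL
  r0 <- instantaneous_rate(cell, trk, cfg, 0, 0, x)
  expect_identical(which.max(r), which.max(r0))
  expect_equal(max(r) - cell$baseline_hz,
               0.4 * (max(r0) - cell$baseline_hz), tolerance = 1e-12)
})

test_that("Poisson spike generation matches its closed form", {
  traj <- const_speed_trajectory(n = 1200, speed = 10, hz = 20)
  sched <- protrusion_schedule(build_track_b(), "segments_3_4_5",
                               duration_s = 60)
  attr(traj, "schedule") <- sched
  trkb <- build_track_b()
  # effectively constant 5 Hz: enormous field width
  cell <- structure(list(cell_id = "c", anchoring = "linear_fraction",
                         centre = list(fraction = 0.5), sigma_cm = 1e9,
                         peak_hz = 5, baseline_hz = 0, rate_gain = NULL),
                    class = "place_cell")
  T_tot <- max(traj$t_s)
  counts <- vapply(1:100, function(s)
    nrow(simulate_spikes(trkb, traj, list(cell), seed = s)), numeric(1))
  lambda_T <- 5 * T_tot
  se <- sqrt(lambda_T / 100)
  expect_lt(abs(mean(counts) - lambda_T), 3 * se)
  # vanishing rate: no spikes
  cell0 <- cell; cell0$peak_hz <- 1e-12
  expect_identical(nrow(simulate_spikes(trkb, traj, list(cell0), seed = 1)), 0L)
  # determinism
  s1 <- simulate_spikes(trkb, traj, list(cell), seed = 42)
  s2 <- simulate_spikes(trkb, traj, list(cell), seed = 42)
  expect_identical(s1, s2)
})
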