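trkb <- build_track_b()

test_that("pairing rejects same-side sessions", {
  run <- track_b_pair_run("linear_fraction", 1)
  p <- run$pair
  expect_error(protrusion_pair(p$session1, p$session1), "same side")
  expect_identical(sort(p$sides), c("segments_3_4_5", "segments_7_8_9"))
})

test_that("active-cell inclusion equals brute-force thresholding", {
  run <- track_b_pair_run("linear_fraction", 1)
  p <- run$pair
  cfg <- analysis_config()
  ids <- include_active_cells(p, threshold_hz = 2, config = cfg)
  g <- linear_grid(trkb)
  sh <- make_shifts(cfg$n_shifts, cfg$bin_cm, seed = cfg$seed)
  brute <- vapply(p$session1$cells, function(cell) {
    pk <- vapply(list(p$session1, p$session2), function(s) {
      f <- speed_filter(s$trajectory, s$spikes)
      m <- compute_rate_map(f$trajectory,
                            f$spikes[f$spikes$cell_id == cell$cell_id, ],
                            g, shifts = sh)
      if (!any(m$visited)) 0 else peak_rate(m)
    }, numeric(1))
    max(pk)
  }, numeric(1))
  expect_identical(sort(ids),
                   sort(vapply(p$session1$cells, `[[`, "", "cell_id")[brute >= 2]))
  # a very high threshold empties the set with a warning
  expect_warning(none <- include_active_cells(p, threshold_hz = 1e6,
                                              config = cfg),
                 "threshold")
  expect_length(none, 0)
})

test_that("a span correlated with itself is exactly 1", {
  run <- track_b_pair_run("linear_fraction", 1)
  p <- run$pair
  prep <- trackmorph:::.prep_session(p$session1, analysis_config())
  sp <- protrusion_spans(trkb, prep$cfg)
  g <- span_grid(0, 120)
  sh <- make_shifts(25, 3, seed = 1)
  side <- trackmorph:::.span_side(prep, sp$protrusion, g, 1, sh)
  active <- names(sort(table(side$cell), decreasing = TRUE))[1]
  m <- trackmorph:::.side_map(side, active, sh)
  expect_equal(pair_correlation(m, m), 1)
})

test_that("rescaling conserves spike count and occupancy", {
  run <- track_b_pair_run("linear_fraction", 1)
  p <- run$pair
  prep <- trackmorph:::.prep_session(p$session1, analysis_config())
  spn <- protrusion_spans(trkb, prep$cfg)
  sh <- make_shifts(25, 3, seed = 1)
  plain <- trackmorph:::.span_side(prep, spn$protrusion, span_grid(0, 120), 1, sh)
  resc <- trackmorph:::.span_side(prep, spn$protrusion, span_grid(0, 40), 3, sh)
  cid <- plain$cell[1]
  m1 <- trackmorph:::.side_map(plain, cid, sh)
  m3 <- trackmorph:::.side_map(resc, cid, sh)
  expect_identical(sum(m1$count), sum(m3$count))
  expect_equal(sum(m1$occupancy_s), sum(m3$occupancy_s))
})

test_that("a mid-slot elastic field lands at the matching fraction after rescaling", {
  # analytic coordinate map: a field at fraction f of the protrusion span
  # must appear at fraction f of the replacing straight section
  f_slot <- 0.6
  cell <- structure(list(
    cell_id = "probe", anchoring = "linear_fraction",
    centre = list(fraction = (80 + f_slot * 40) / 280),  # canonical slot A
    sigma_cm = 6, peak_hz = 25, baseline_hz = 0.05, rate_gain = NULL),
    class = "place_cell")
  beh <- behavior_params(mean_speed_cms = 360 / 30)
  mk <- function(side, sd) {
    sch <- protrusion_schedule(trkb, side, duration_s = 600)
    traj <- simulate_trajectory(trkb, sch, beh, seed = sd)
    spikes <- simulate_spikes(trkb, traj, list(cell), seed = sd)
    session_bundle(trkb, traj, spikes, list(cell))
  }
  p <- protrusion_pair(mk("segments_3_4_5", 3), mk("segments_7_8_9", 4))
  cfgn <- analysis_config()
  prep1 <- trackmorph:::.prep_session(p$session1, cfgn)
  prep2 <- trackmorph:::.prep_session(p$session2, cfgn)
  sh <- make_shifts(25, 3, seed = 1)
  sp1 <- protrusion_spans(trkb, prep1$cfg)
  sp2 <- protrusion_spans(trkb, prep2$cfg)
  g <- span_grid(0, 40)
  m_resc <- trackmorph:::.side_map(
    trackmorph:::.span_side(prep1, sp1$protrusion, g, 3, sh), "probe", sh)
  m_straight <- trackmorph:::.side_map(
    trackmorph:::.span_side(prep2, sp2$straight, g, 1, sh), "probe", sh)
  bin_w <- g$bin_cm
  expect_lt(abs(peak_bin(m_resc)[1] - f_slot * 40), 1.5 * bin_w)
  expect_lt(abs(peak_bin(m_resc)[1] - peak_bin(m_straight)[1]), bin_w + 1e-9)
})

test_that("comparison statistics match their closed forms", {
  set.seed(31)
  jit <- function(m, n = 40) m + rnorm(n, 0, 1e-3)
  same <- jit(0.3)    # four identical value sets
  vals <- data.frame(cell_id = sprintf("c%02d", 1:40),
                     flip = same, distance = same,
                     segment = same, rescaled = same)
  st <- comparison_stats(vals)
  expect_gt(st$anova_p, 0.5)
  sep <- data.frame(cell_id = sprintf("c%02d", 1:50),
                    flip = jit(0.9, 50), distance = jit(0, 50),
                    segment = jit(0.4, 50), rescaled = jit(0.5, 50))
  st2 <- comparison_stats(sep)
  expect_lt(st2$pairwise$p_utest[st2$pairwise$a == "flip" &
                                   st2$pairwise$b == "distance"], 1e-5)
  expect_identical(as.character(st2$argmax), "flip")
  expect_identical(identified_hypothesis(st2), "segment_bound")
  # rank-sum statistic by hand: W = #{(x_i, y_j): x_i > y_j}
  x <- c(1, 3, 5); y <- c(2, 4)
  W <- sum(outer(x, y, ">"))
  expect_identical(unname(stats::wilcox.test(x, y)$statistic), as.numeric(W))
})
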