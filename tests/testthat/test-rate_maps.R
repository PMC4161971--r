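test_that("speed filter keeps fast samples and drops slow ones", {
  fast <- speed_filter(const_speed_trajectory(speed = 5))
  expect_true(all(fast$included))
  slow <- speed_filter(const_speed_trajectory(speed = 2))
  expect_false(any(slow$included))
  # mixed-speed fixture equals the per-sample brute-force check
  tr <- const_speed_trajectory(n = 200, speed = 5)
  tr$x_cm <- c(seq(0, 49.5, by = 0.5), rep(49.5, 50) + rnorm(50, 0, 0.01),
               seq(50, 74.75, by = 0.25))[1:200]
  tr$x_l_cm <- tr$x_cm
  out <- speed_filter(tr)
  expect_identical(out$included, estimate_speed(tr) >= 3)
  expect_warning(speed_filter(tr[0, ]), "empty")
})

test_that("occupancy conserves time and matches a hand tally", {
  g <- bin_grid("linear", origin = c(0, -4.5), bin_cm = 3, n_x = 10, n_y = 3)
  # 10 samples at 2 Hz: first 6 in bin 1 (x < 3), last 4 in bin 2
  tr <- data.frame(t_s = seq(0.5, 5, by = 0.5),
                   x_l_cm = c(rep(1, 6), rep(4, 4)), y_l_cm = 0,
                   included = TRUE)
  occ <- compute_occupancy(tr, g)
  expect_equal(sum(occ), 5)                        # total duration
  expect_equal(occ[(1 - 1) * 3 + 2], 3)            # 6 intervals of 0.5 s
  expect_equal(occ[(2 - 1) * 3 + 2], 2)            # 4 intervals of 0.5 s
  # all samples in one bin
  tr1 <- data.frame(t_s = 1:20 / 4, x_l_cm = 1, y_l_cm = 0, included = TRUE)
  occ1 <- compute_occupancy(tr1, g)
  expect_equal(max(occ1), sum(occ1))
})

test_that("unshifted rate map is exactly count over occupancy", {
  g <- bin_grid("linear", origin = c(-3, -4.5), bin_cm = 3, n_x = 7, n_y = 3)
  tr <- data.frame(t_s = seq(0.1, 10, by = 0.1),
                   x_l_cm = rep(seq(0.5, 14.5, by = 3), 20)[1:100],
                   y_l_cm = 0, included = TRUE)
  sp <- data.frame(x_l_cm = c(0.5, 0.5, 3.5, 12.5), y_l_cm = 0,
                   included = TRUE)
  m <- compute_rate_map(tr, sp, g, shifts = matrix(0, 1, 2))
  occ <- compute_occupancy(tr, g)
  expect_equal(sum(m$count), nrow(sp))
  for (b in which(m$visited)) expect_equal(m$rate[b], m$count[b] / occ[b])
  expect_true(all(is.na(m$rate[!m$visited])))
  # spike-count conservation for every random shift
  cnts <- trackmorph:::count_stack(cbind(sp$x_l_cm, sp$y_l_cm), g,
                                   make_shifts(10, 3, seed = 1))
  expect_true(all(colSums(cnts) == nrow(sp)))
})

test_that("homogeneous firing recovers the true rate after shift averaging", {
  set.seed(21)
  n <- 4000; hz <- 20
  tr <- data.frame(t_s = seq_len(n) / hz,
                   x_l_cm = runif(n, 0, 30), y_l_cm = runif(n, -4, 4),
                   included = TRUE)
  lam <- 5
  counts <- rpois(n, lam / hz)
  ix <- rep.int(seq_len(n), counts)
  sp <- data.frame(x_l_cm = tr$x_l_cm[ix], y_l_cm = tr$y_l_cm[ix],
                   included = TRUE)
  g <- bin_grid("linear", origin = c(0, -4.5), bin_cm = 3, n_x = 10, n_y = 3)
  m <- compute_rate_map(tr, sp, g, n_shifts = 25, seed = 2)
  mean_rate <- mean(m$rate[m$visited])
  se <- sqrt(lam / (n / hz))    # Poisson SE of the overall mean rate
  expect_lt(abs(mean_rate - lam), 3 * se)
})

test_that("peak extraction matches a direct scan", {
  m <- mk_map(c(1, 4, 2, 0), count = c(1, 3, 1, 0))
  expect_equal(peak_rate(m), 4)
  expect_equal(peak_bin(m)[1], 1.5 + 3)
  m0 <- mk_map(rep(0, 4), count = rep(0, 4))
  expect_equal(peak_rate(m0), 0)
  set.seed(5)
  r <- runif(30)
  expect_equal(peak_rate(mk_map(r)), max(r))
  m2 <- mk_map(c(1, NA, 3), visited = c(TRUE, FALSE, TRUE))
  expect_equal(peak_rate(m2), 3)
  expect_error(peak_rate(mk_map(NA_real_, visited = FALSE)), "no visited")
})

test_that("activity vector follows the top-right, downward flattening", {
  g <- bin_grid("planar", origin = c(0, 0), bin_cm = 1, n_x = 2, n_y = 2)
  # storage order: (ix-1)*n_y + iy
  m <- structure(list(grid = g, rate = c(11, 12, 21, 22),
                      visited = rep(TRUE, 4), occupancy_s = rep(1, 4),
                      count = rep(1, 4), n_shifts = 1), class = "rate_map")
  # m = 1 is the top-right bin (ix=2, iy=2) = 22, then below it 21,
  # then the left column top-down: 12, 11
  expect_identical(activity_vector(m), c(22, 21, 12, 11))
})

test_that("both frames keep the same spikes and similar peak rates", {
  # within one track configuration the two frames re-bin the same data, so
  # spike counts agree exactly and peak rates roughly
  run <- track_a_run("linear_fraction", 1)
  b <- run$bundle
  f <- speed_filter(b$trajectory, b$spikes)
  tr <- f$trajectory; sp <- f$spikes
  lin <- linear_grid(b$track); pla <- planar_grid(b$track)
  # pool the configurations of one vertical-section group, as the analysis
  # does, and use the cells with enough spikes there to estimate a peak
  gr <- group_by_section(b$track, b$schedule, "top")[[6]]
  ids <- vapply(b$cells, `[[`, "", "cell_id")
  n_in <- vapply(ids, function(cid)
    sum(sp$cell_id == cid & sp$included & sp$config_id %in% gr$config_ids),
    numeric(1))
  ids <- ids[order(-n_in)][1:10]
  ratio <- vapply(ids, function(cid) {
    spc <- sp[sp$cell_id == cid, ]
    ml <- pooled_rate_map(tr, spc, gr, lin, n_shifts = 25, seed = 1)
    mp <- pooled_rate_map(tr, spc, gr, pla, n_shifts = 25, seed = 1)
    # linearization never drops an on-track spike that one frame keeps
    expect_identical(sum(ml$count), sum(mp$count))
    abs(peak_rate(ml) - peak_rate(mp)) /
      max(peak_rate(ml), peak_rate(mp))
  }, numeric(1))
  expect_lt(mean(ratio), 0.2)
})

test_that("lateral-marginalized field peak finds a known centre", {
  run <- track_a_run("linear_fraction", 1)
  b <- run$bundle
  f <- speed_filter(b$trajectory, b$spikes)
  g <- linear_grid(b$track)
  sh <- make_shifts(25, 3, seed = 1)
  cell <- b$cells[[3]]
  fp <- linear_field_peak(f$trajectory,
                          f$spikes[f$spikes$cell_id == cell$cell_id, ], g, sh)
  expect_lt(abs(fp$peak_xl - cell$centre$fraction * 400), 4.5)
})
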