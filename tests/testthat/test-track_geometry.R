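test_that("default Track A build matches the physical track", {
  trk <- build_track_a()
  expect_identical(total_length(trk), 400)
  expect_identical(nrow(trk$segments), 10L)
  expect_identical(trk$segments$mobility[trk$segments$segment_index %in% 5:6],
                   c("static", "static"))
  expect_true(all(trk$segments$mobility[-(5:6)] == "mobile"))
  # joints: one connector per junction, zero length by default
  expect_identical(total_length(build_track_a(joint_connector_cm = 2)),
                   400 + 9 * 2)
  expect_error(build_track_a(segment_length_cm = 0), "positive")
})

test_that("planar layout obeys the accordion constraints", {
  trk <- build_track_a()
  # fully extended arm: straight runway, alpha = 180 degrees
  cfg <- track_a_config(trk, 160, 160)
  expect_equal(cfg$alpha_deg, 180)
  lay <- layout_planar(trk, cfg)
  top <- lay[lay$segment_index %in% as.character(1:4), ]
  expect_true(all(abs(c(top$y_start, top$y_end) - 80) < 1e-9))

  # static base is identical across configurations
  cfg2 <- track_a_config(trk, 40, 95)
  for (cc in list(cfg, cfg2)) {
    l <- layout_planar(trk, cc)
    base <- l[l$segment_index %in% c("5", "6"), ]
    expect_equal(base$x_start, c(0, 0))
    expect_equal(base$y_start, c(80, 40))
    expect_equal(base$y_end, c(40, 0))
  }

  # rigid segments: every planar piece length equals the model length
  set.seed(11)
  for (e in runif(20, 20, 160)) {
    l <- layout_planar(trk, track_a_config(trk, e, 180 - e))
    lens <- sqrt((l$x_end - l$x_start)^2 + (l$y_end - l$y_start)^2)
    expect_true(all(abs(lens - 40) < 1e-9))
  }
})

test_that("well position agrees with a closed-form trigonometric oracle", {
  trk <- build_track_a()
  for (e in c(25, 70, 101.5, 160)) {
    cfg <- track_a_config(trk, e, 60)
    # independent computation: four segment projections at the fold angle
    theta <- acos(e / 160)
    f1_oracle <- c(4 * 40 * cos(theta), 80)
    expect_lt(max(abs(cfg$F1 - f1_oracle)), 1e-6)
    expect_equal(cfg$alpha_deg, 180 - 2 * theta * 180 / pi)
  }
})

test_that("linearization conventions and round trip hold", {
  trk <- build_track_a()
  cfg <- track_a_config(trk, 93, 51)
  expect_equal(unname(linearize_point(trk, cfg, cfg$F1)[1]), 0, tolerance = 1e-9)
  expect_equal(unname(linearize_point(trk, cfg, cfg$F2)[1]), 400,
               tolerance = 1e-9)
  # planar -> linear -> planar on 1000 on-track points
  set.seed(3)
  for (cc in list(cfg, track_a_config(trk, 152, 24))) {
    pts <- planar_from_linear(trk, cc, runif(1000, 0, 400), runif(1000, -4, 4))
    lin <- linearize_points(trk, cc, pts[, 1], pts[, 2])
    expect_true(all(lin$on_track))
    back <- planar_from_linear(trk, cc, lin$x_l, lin$y_l)
    expect_lt(max(abs(back - pts)), 0.1)
  }
  # x_l of a material point is configuration-invariant: a point generated
  # at arc s in any configuration linearizes back to s
  s <- seq(5, 395, by = 7)
  for (cc in list(cfg, track_a_config(trk, 30, 140))) {
    pts <- planar_from_linear(trk, cc, s)
    expect_lt(max(abs(linearize_points(trk, cc, pts[, 1], pts[, 2])$x_l - s)),
              1e-6)
  }
  expect_error(linearize_point(trk, cfg, c(200, -90)), "off-track")
})

test_that("vertical sections form a clamped 12-level step function of extent", {
  trk <- build_track_a()
  expect_identical(section_of_extent(trk, extent_range(trk)[1]), 1L)
  expect_identical(section_of_extent(trk, extent_range(trk)[2]), 12L)
  # arbitrary extents match the direct floor arithmetic
  e <- seq(20.5, 127.5, by = 1.3)
  oracle <- pmin(pmax(floor((e - 20) / 9) + 1, 1), 12)
  expect_identical(section_of_extent(trk, e), as.integer(oracle))
  # exactly 12 levels over the section-covered sweep
  grid <- seq(section_extent_range(trk)[1], section_extent_range(trk)[2] - 1e-9,
              length.out = 500)
  secs <- section_of_extent(trk, grid)
  expect_identical(sort(unique(secs)), 1:12)
  expect_true(all(diff(secs) >= 0))
  cfg <- track_a_config(trk, 100, 100)
  expect_identical(vertical_section_of(trk, cfg, "top"),
                   section_of_extent(trk, 100))
  trkb <- build_track_b()
  expect_error(vertical_section_of(trkb, with_protrusion(trkb), "top"),
               "Track A")
})

test_that("Track B geometry: 11 segments, symmetric detour, equal path length", {
  trk <- build_track_b()
  expect_identical(nrow(trk$segments), 11L)
  expect_identical(total_length(trk), 440)
  c345 <- with_protrusion(trk, "segments_3_4_5")
  c789 <- with_protrusion(trk, "segments_7_8_9")
  p1 <- path_polyline(trk, c345)
  p2 <- path_polyline(trk, c789)
  expect_equal(p1$path_length, p2$path_length)
  # detour segments off-axis, replaced slot in line
  l1 <- layout_planar(trk, c345)
  det <- l1[l1$segment_index %in% c("3", "4", "5"), ]
  expect_true(all(c(det$y_start, det$y_end) >= 40))
  straight <- l1[l1$segment_index == "7-9", ]
  expect_true(all(c(straight$y_start, straight$y_end) == 0))
  expect_error(with_protrusion(trk, "segments_2_3_4"))
})

test_that("segment spans alias the mobile trio across the flip", {
  trk <- build_track_b()
  c345 <- with_protrusion(trk, "segments_3_4_5")
  c789 <- with_protrusion(trk, "segments_7_8_9")
  # positional labels 3/7, 4/8, 5/9 denote the same physical segments
  expect_identical(segment_xl_span(trk, c345, 3), segment_xl_span(trk, c345, 7))
  expect_identical(segment_xl_span(trk, c789, 4), segment_xl_span(trk, c789, 8))
  # the centre segment stays the centre third of the deployed detour
  expect_equal(segment_xl_span(trk, c345, 4), c(120, 160))
  expect_equal(segment_xl_span(trk, c789, 8), c(200, 240))
  # base segment keeps its planar position but shifts in x_l
  expect_equal(segment_xl_span(trk, c345, 6), c(200, 240))
  expect_equal(segment_xl_span(trk, c789, 6), c(120, 160))
})

test_that("canonical coordinate stretches the slots and inverts exactly", {
  trk <- build_track_b()
  for (side in c("segments_3_4_5", "segments_7_8_9")) {
    cfg <- with_protrusion(trk, side)
    x <- seq(0, 360, by = 0.5)
    s <- canonical_coord(trk, cfg, x)
    expect_true(all(diff(s) >= 0))
    expect_equal(range(s), c(0, canonical_length(trk)))
    expect_lt(max(abs(xl_from_canonical(trk, cfg, s) - x)), 1e-9)
    # the deployed detour maps onto one canonical segment length
    sp <- protrusion_spans(trk, cfg)
    expect_equal(diff(canonical_coord(trk, cfg, sp$protrusion)), 40)
    expect_equal(diff(canonical_coord(trk, cfg, sp$straight)), 40)
  }
  # Track A: canonical coordinate is x_l itself
  trka <- build_track_a()
  cfga <- track_a_config(trka, 80, 80)
  expect_identical(canonical_coord(trka, cfga, c(0, 123, 400)), c(0, 123, 400))
})
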