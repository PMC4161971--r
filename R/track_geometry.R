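N_TOT_SECTIONS <- 12L
SECTION_WIDTH_CM <- 9
TRAVEL_SPAN_CM <- 140

#' Build the accordion U-track (Track A)
#'
#' Track A is an elevated U-shaped runway of 10 rigid straight segments.
#' Segments 1--4 form the top arm and 7--10 the bottom arm; both arms can
#' fold accordion-style at their joints so that the food well at the arm tip
#' sweeps horizontally. Segments 5 and 6 form the static base of the U.
#' Joints are circular areas on the midline and carry no arc length, so the
#' total linearized length equals the sum of the segment lengths
#' (400 cm at the default segment length).
#'
#' @param segment_length_cm Length of each straight segment, cm. The build
#'   is intended for lengths in \[35, 40\]; the default of 40 gives a 4 m
#'   track.
#' @param joint_connector_cm Arc length assigned to each inter-segment
#'   joint on the midline (default 0).
#' @param track_width_cm Width of the runway, cm.
#' @return A `track_model` object.
#' @export
#' @examples
#' trk <- build_track_a()
#' total_length(trk) # 400
build_track_a <- function(segment_length_cm = 40, joint_connector_cm = 0,
                          track_width_cm = 8) {
  if (!is.numeric(segment_length_cm) || segment_length_cm <= 0)
    stop("segment_length_cm must be a positive number", call. = FALSE)
  if (segment_length_cm < 35 || segment_length_cm > 40)
    warning("Track A is designed for segment lengths between 35 and 40 cm")
  if (joint_connector_cm < 0) stop("joint_connector_cm must be >= 0", call. = FALSE)
  if (track_width_cm <= 0) stop("track_width_cm must be > 0", call. = FALSE)
  if (4 * segment_length_cm <= TRAVEL_SPAN_CM)
    stop("segment length too short for the 140 cm endpoint travel span", call. = FALSE)
  segs <- data.frame(
    segment_index = 1:10,
    length_cm = segment_length_cm,
    arm = c(rep("top", 4), rep("base", 2), rep("bottom", 4)),
    mobility = c(rep("mobile", 4), rep("static", 2), rep("mobile", 4)),
    stringsAsFactors = FALSE
  )
  structure(list(
    track_id = "A",
    segments = segs,
    joint_connector_cm = joint_connector_cm,
    track_width_cm = track_width_cm,
    travel_span_cm = TRAVEL_SPAN_CM,
    n_sections = N_TOT_SECTIONS,
    section_width_cm = SECTION_WIDTH_CM,
    wells = c("F1", "F2")
  ), class = "track_model")
}

#' Build the protrusion-flip track (Track B)
#'
#' Track B is a U-shaped track of 11 segments. Three of them form a mobile
#' trio that protrudes as a rectangular detour (out, across, back) on one
#' side of the track; between sessions the trio is flipped to the matching
#' slot on the other side, and the vacated slot is spanned by a single
#' straight in-line section of one segment length. Each configuration
#' therefore deploys a 360 cm path (at the default 40 cm segments) while
#' the model-level linearized length over all 11 segments is 440 cm.
#'
#' @inheritParams build_track_a
#' @return A `track_model` object.
#' @export
build_track_b <- function(segment_length_cm = 40, joint_connector_cm = 0,
                          track_width_cm = 8) {
  if (!is.numeric(segment_length_cm) || segment_length_cm <= 0)
    stop("segment_length_cm must be a positive number", call. = FALSE)
  if (joint_connector_cm < 0) stop("joint_connector_cm must be >= 0", call. = FALSE)
  if (track_width_cm <= 0) stop("track_width_cm must be > 0", call. = FALSE)
  segs <- data.frame(
    segment_index = 1:11,
    length_cm = segment_length_cm,
    arm = c("top", "top", "top", "top", "top", "base",
            "bottom", "bottom", "bottom", "bottom", "bottom"),
    mobility = c("static", "static", "mobile", "mobile", "mobile", "static",
                 "mobile", "mobile", "mobile", "static", "static"),
    stringsAsFactors = FALSE
  )
  structure(list(
    track_id = "B",
    segments = segs,
    joint_connector_cm = joint_connector_cm,
    track_width_cm = track_width_cm,
    wells = c("F1", "F2")
  ), class = "track_model")
}

#' Total linearized length of a track model
#'
#' Sum of all segment lengths plus one joint connector per junction.
#' For Track B this is the model-level length over all 11 segments; the
#' per-configuration deployed path is shorter (see [path_polyline()]).
#'
#' @param track A `track_model`.
#' @return Length in cm.
#' @export
total_length <- function(track) {
  stopifnot(inherits(track, "track_model"))
  n <- nrow(track$segments)
  sum(track$segments$length_cm) + (n - 1L) * track$joint_connector_cm
}

#' @export
print.track_model <- function(x, ...) {
  cat(sprintf("<track_model %s: %d segments, %.0f cm linearized, width %.0f cm>\n",
              x$track_id, nrow(x$segments), total_length(x), x$track_width_cm))
  invisible(x)
}

seg_len <- function(track) track$segments$length_cm[1]

#' Extent range reachable by a Track A arm tip
#'
#' The food well of a fully stretched arm sits at four segment lengths from
#' the base; the accordion fold lets it travel 140 cm inward.
#'
#' @param track Track A model.
#' @return Numeric vector `c(min, max)` of horizontal well extents, cm.
#' @export
extent_range <- function(track) {
  stopifnot(identical(track$track_id, "A"))
  L4 <- 4 * seg_len(track)
  c(L4 - track$travel_span_cm, L4)
}

#' Range of extents covered by the 12 vertical sections
#'
#' The section grid is anchored at the contracted end of the sweep
#' (section 1 = most contracted). Sections are 9 cm wide, so the grid
#' covers 108 cm of the 140 cm physical travel span; extents beyond the
#' grid clamp to the terminal sections.
#'
#' @param track Track A model.
#' @return `c(min, max)` extents covered by sections 1..12, cm.
#' @export
section_extent_range <- function(track) {
  r <- extent_range(track)
  c(r[1], r[1] + N_TOT_SECTIONS * SECTION_WIDTH_CM)
}

#' Vertical section index of an arm extent
#'
#' @param track Track A model.
#' @param extent Horizontal well extent(s), cm.
#' @return Integer section index in 1..12 (step function of extent,
#'   clamped at the grid ends).
#' @export
section_of_extent <- function(track, extent) {
  r <- extent_range(track)
  idx <- floor((extent - r[1]) / SECTION_WIDTH_CM) + 1L
  pmin(pmax(as.integer(idx), 1L), N_TOT_SECTIONS)
}

#' Freeze one Track A configuration
#'
#' A configuration is defined by the horizontal extents of the two food
#' wells. The fold angles follow from the equal-angle accordion constraint:
#' all joint angles on an arm are equal, so
#' `alpha = 180 - 2*acos(extent / (4 L))` degrees for the top arm, and the
#' same for `beta` on the bottom arm.
#'
#' @param track Track A model.
#' @param top_extent,bottom_extent Horizontal well extents in cm, within
#'   [extent_range()].
#' @param config_id Optional identifier string.
#' @return A `track_config` object.
#' @export
track_a_config <- function(track, top_extent, bottom_extent,
                           config_id = NULL) {
  stopifnot(inherits(track, "track_model"), identical(track$track_id, "A"))
  r <- extent_range(track)
  eps <- 1e-9
  for (e in c(top_extent, bottom_extent))
    if (!is.finite(e) || e < r[1] - eps || e > r[2] + eps)
      stop(sprintf("extent %.2f cm outside reachable range [%.1f, %.1f]",
                   e, r[1], r[2]), call. = FALSE)
  L <- seg_len(track)
  theta_t <- acos(min(top_extent / (4 * L), 1))
  theta_b <- acos(min(bottom_extent / (4 * L), 1))
  cfg <- structure(list(
    config_id = if (is.null(config_id)) "cfg" else config_id,
    track_id = "A",
    top_extent = top_extent,
    bottom_extent = bottom_extent,
    alpha_deg = 180 - 2 * theta_t * 180 / pi,
    beta_deg = 180 - 2 * theta_b * 180 / pi,
    section_top = section_of_extent(track, top_extent),
    section_bottom = section_of_extent(track, bottom_extent)
  ), class = "track_config")
  wells <- well_positions(track, cfg)
  cfg$F1 <- wells$F1
  cfg$F2 <- wells$F2
  cfg
}

#' Freeze one Track B configuration
#'
#' @param track Track B model.
#' @param side Which slot hosts the protrusion: `"segments_3_4_5"` (top
#'   arm) or `"segments_7_8_9"` (bottom arm).
#' @param config_id Optional identifier string.
#' @return A `track_config` object.
#' @export
with_protrusion <- function(track, side = c("segments_3_4_5", "segments_7_8_9"),
                            config_id = NULL) {
  stopifnot(inherits(track, "track_model"), identical(track$track_id, "B"))
  side <- match.arg(side)
  cfg <- structure(list(
    config_id = if (is.null(config_id)) side else config_id,
    track_id = "B",
    protrusion_side = side
  ), class = "track_config")
  wells <- well_positions(track, cfg)
  cfg$F1 <- wells$F1
  cfg$F2 <- wells$F2
  cfg
}

#' @export
print.track_config <- function(x, ...) {
  if (x$track_id == "A") {
    cat(sprintf(
      "<track_config %s: Track A, extents top %.1f cm (section %d), bottom %.1f cm (section %d)>\n",
      x$config_id, x$top_extent, x$section_top, x$bottom_extent, x$section_bottom))
  } else {
    cat(sprintf("<track_config %s: Track B, protrusion on %s>\n",
                x$config_id, x$protrusion_side))
  }
  invisible(x)
}

# Vertices of the midline polyline in path order (from well F1 to F2),
# with one row per polyline vertex. Rigid segments; alternating fold signs
# give the equal-angle accordion on each Track A arm.
.track_a_vertices <- function(track, cfg) {
  L <- seg_len(track)
  th_t <- acos(min(cfg$top_extent / (4 * L), 1))
  th_b <- acos(min(cfg$bottom_extent / (4 * L), 1))
  top0 <- c(0, 2 * L)   # inner joint of the top arm
  # outward from the joint: segments 4,3,2,1 with alternating +/- fold
  sgn <- c(1, -1, 1, -1)
  pts_top <- matrix(NA_real_, 5, 2)
  pts_top[1, ] <- top0
  for (k in 1:4)
    pts_top[k + 1, ] <- pts_top[k, ] + L * c(cos(th_t), sgn[k] * sin(th_t))
  bot0 <- c(0, 0)
  sgnb <- c(-1, 1, -1, 1)
  pts_bot <- matrix(NA_real_, 5, 2)
  pts_bot[1, ] <- bot0
  for (k in 1:4)
    pts_bot[k + 1, ] <- pts_bot[k, ] + L * c(cos(th_b), sgnb[k] * sin(th_b))
  # path order from F1: top arm tip -> inner joint, base down, bottom out
  v <- rbind(pts_top[5:1, ], c(0, L), pts_bot[1:5, ])
  labels <- c(1:4, 5, 6, 7:10)
  list(vertices = v, segment_index = labels)
}

.track_b_vertices <- function(track, cfg) {
  L <- seg_len(track)
  top_y <- L
  if (cfg$protrusion_side == "segments_3_4_5") {
    v <- rbind(
      c(3 * L, top_y), c(2 * L, top_y), c(L, top_y),       # segs 1, 2
      c(L, 2 * L), c(0, 2 * L), c(0, top_y),               # detour 3,4,5
      c(0, 0),                                             # base seg 6
      c(L, 0),                                             # in-line straight
      c(2 * L, 0), c(3 * L, 0)                             # segs 10, 11
    )
    labels <- c("1", "2", "3", "4", "5", "6", "7-9", "10", "11")
  } else {
    v <- rbind(
      c(3 * L, top_y), c(2 * L, top_y), c(L, top_y),       # segs 1, 2
      c(0, top_y),                                         # in-line straight
      c(0, 0),                                             # base seg 6
      c(0, -L), c(L, -L), c(L, 0),                         # detour 7,8,9
      c(2 * L, 0), c(3 * L, 0)                             # segs 10, 11
    )
    labels <- c("1", "2", "3-5", "6", "7", "8", "9", "10", "11")
  }
  list(vertices = v, segment_index = labels)
}

#' Midline polyline of a configuration, in path order from well F1
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @return List with `vertices` (n x 2 matrix), `segment_index` (label per
#'   polyline piece), `cum` (cumulative arc length at piece starts) and
#'   `path_length` (total deployed path, cm).
#' @export
path_polyline <- function(track, cfg) {
  stopifnot(inherits(track, "track_model"), inherits(cfg, "track_config"),
            identical(track$track_id, cfg$track_id))
  pl <- if (track$track_id == "A") .track_a_vertices(track, cfg)
        else .track_b_vertices(track, cfg)
  v <- pl$vertices
  d <- diff(v)
  lens <- sqrt(rowSums(d^2))
  pl$piece_lengths <- lens
  pl$cum <- c(0, cumsum(lens))
  pl$path_length <- sum(lens)
  pl
}

#' Planar layout of a configuration
#'
#' Places every deployed segment in room coordinates. Room frame: origin at
#' the outer corner of the base arm, x to the right (toward the wells),
#' y toward the top arm; all units cm.
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @return A `planar_layout`: data frame with columns `segment_index`
#'   (label), `x_start`, `y_start`, `x_end`, `y_end`, plus the midline
#'   polyline as attribute `"path"`.
#' @export
layout_planar <- function(track, cfg) {
  pl <- path_polyline(track, cfg)
  v <- pl$vertices
  n <- nrow(v) - 1L
  out <- data.frame(
    segment_index = as.character(pl$segment_index),
    x_start = v[seq_len(n), 1], y_start = v[seq_len(n), 2],
    x_end = v[seq_len(n) + 1L, 1], y_end = v[seq_len(n) + 1L, 2],
    stringsAsFactors = FALSE
  )
  attr(out, "path") <- pl
  class(out) <- c("planar_layout", "data.frame")
  out
}

#' Planar well positions of a configuration
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @return List with numeric `F1` and `F2` planar positions (cm).
#' @export
well_positions <- function(track, cfg) {
  pl <- path_polyline(track, cfg)
  v <- pl$vertices
  list(F1 = v[1, ], F2 = v[nrow(v), ])
}

#' Vertical section occupied by an arm's food well
#'
#' Track A only: index of the 9 cm vertical section containing the arm's
#' food well, 1 (most contracted) to 12 (most extended).
#'
#' @param track A `track_model` (must be Track A).
#' @param cfg A `track_config` for Track A.
#' @param arm `"top"` or `"bottom"`.
#' @return Integer section index.
#' @export
vertical_section_of <- function(track, cfg, arm = c("top", "bottom")) {
  if (!identical(track$track_id, "A"))
    stop("vertical sections are defined for Track A only", call. = FALSE)
  arm <- match.arg(arm)
  ext <- if (arm == "top") cfg$top_extent else cfg$bottom_extent
  section_of_extent(track, ext)
}

#' Map planar points to the linear (track-centric) frame
#'
#' `x_l` is arc length along the midline measured from well F1; `y_l` is
#' the signed perpendicular offset from the midline (positive to the left
#' of the direction of increasing `x_l`).
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @param x,y Planar coordinates, cm (vectors of equal length).
#' @param tolerance Maximum distance beyond the half-width at which a point
#'   still counts as on-track, cm.
#' @return Data frame with `x_l`, `y_l`, `dist` (distance to the midline)
#'   and logical `on_track`. Off-track points keep their projection but are
#'   flagged so the caller can drop them.
#' @export
linearize_points <- function(track, cfg, x, y, tolerance = 3) {
  stopifnot(length(x) == length(y))
  pl <- path_polyline(track, cfg)
  v <- pl$vertices
  np <- length(x)
  best_d2 <- rep(Inf, np)
  best_xl <- numeric(np)
  best_yl <- numeric(np)
  for (k in seq_len(nrow(v) - 1L)) {
    a <- v[k, ]; b <- v[k + 1L, ]
    dx <- b[1] - a[1]; dy <- b[2] - a[2]
    len2 <- dx * dx + dy * dy
    tt <- ((x - a[1]) * dx + (y - a[2]) * dy) / len2
    tt <- pmin(pmax(tt, 0), 1)
    fx <- a[1] + tt * dx
    fy <- a[2] + tt * dy
    d2 <- (x - fx)^2 + (y - fy)^2
    upd <- d2 < best_d2
    if (any(upd)) {
      len <- sqrt(len2)
      # signed offset: positive on the left of the travel direction
      yl <- (-(dy) * (x - fx) + dx * (y - fy)) / len
      best_xl[upd] <- pl$cum[k] + tt[upd] * len
      best_yl[upd] <- yl[upd]
      best_d2[upd] <- d2[upd]
    }
  }
  dist <- sqrt(best_d2)
  data.frame(x_l = best_xl, y_l = best_yl, dist = dist,
             on_track = dist <= track$track_width_cm / 2 + tolerance)
}

#' Map a single planar point to the linear frame
#'
#' Scalar convenience wrapper around [linearize_points()]; errors if the
#' point lies farther from the midline than the tolerance allows.
#'
#' @inheritParams linearize_points
#' @param p Planar point `c(x, y)`, cm.
#' @return Numeric `c(x_l, y_l)`.
#' @export
linearize_point <- function(track, cfg, p, tolerance = 3) {
  res <- linearize_points(track, cfg, p[1], p[2], tolerance)
  if (!res$on_track)
    stop(sprintf("point (%.1f, %.1f) is %.1f cm from the track midline (off-track)",
                 p[1], p[2], res$dist), call. = FALSE)
  c(x_l = res$x_l, y_l = res$y_l)
}

#' Map linear-frame coordinates back to the plane
#'
#' Inverse of [linearize_points()] for on-track coordinates.
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @param x_l Arc length(s) from well F1, cm.
#' @param y_l Signed lateral offset(s), cm (default 0 = midline).
#' @return Matrix with columns `x`, `y`.
#' @export
planar_from_linear <- function(track, cfg, x_l, y_l = 0) {
  pl <- path_polyline(track, cfg)
  if (length(y_l) == 1L) y_l <- rep(y_l, length(x_l))
  stopifnot(length(x_l) == length(y_l))
  xl <- pmin(pmax(x_l, 0), pl$path_length)
  k <- findInterval(xl, pl$cum, rightmost.closed = TRUE)
  k <- pmin(pmax(k, 1L), nrow(pl$vertices) - 1L)
  a <- pl$vertices[k, , drop = FALSE]
  b <- pl$vertices[k + 1L, , drop = FALSE]
  lens <- pl$piece_lengths[k]
  ux <- (b[, 1] - a[, 1]) / lens
  uy <- (b[, 2] - a[, 2]) / lens
  s <- xl - pl$cum[k]
  cbind(x = a[, 1] + s * ux - uy * y_l,
        y = a[, 2] + s * uy + ux * y_l)
}

#' Linearized span of a physical segment in a given configuration
#'
#' Returns the `x_l` interval occupied by a segment. On Track A every
#' segment keeps a fixed arc-length span in all configurations. On Track B
#' the mobile trio occupies the thirds of whichever protrusion slot is
#' deployed; the labels 3,4,5 and 7,8,9 are positional aliases for the same
#' three physical segments (7 = 3, 8 = 4, 9 = 5 after the flip, with path
#' order preserved so the centre segment stays central). Returns `NULL` for
#' a span that does not exist in this configuration.
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @param segment_index Integer segment label.
#' @return `c(start, end)` in cm of `x_l`, or `NULL`.
#' @export
segment_xl_span <- function(track, cfg, segment_index) {
  L <- seg_len(track)
  if (track$track_id == "A") {
    i <- as.integer(segment_index)
    stopifnot(i >= 1, i <= 10)
    return(c((i - 1) * L, i * L))
  }
  i <- as.integer(segment_index)
  stopifnot(i >= 1, i <= 11)
  sp <- protrusion_spans(track, cfg)
  if (i %in% c(1L, 2L)) return(c((i - 1) * L, i * L))
  if (i %in% c(10L, 11L)) return(c((i - 3) * L, (i - 2) * L))
  if (i == 6L) return(sp$base)
  # trio (aliased labels): thirds of the deployed protrusion span
  third <- switch(as.character(i), "3" = 1L, "7" = 1L, "4" = 2L, "8" = 2L,
                  "5" = 3L, "9" = 3L)
  a <- sp$protrusion[1] + (third - 1L) * L
  c(a, a + L)
}

#' Key linearized spans of a Track B configuration
#'
#' @param track Track B model.
#' @param cfg A Track B `track_config`.
#' @return List of `x_l` intervals (cm): `protrusion` (the 3-segment
#'   detour), `centre_segment` (its middle third), `straight` (the single
#'   in-line section spanning the vacated slot on the other arm),
#'   `base` (segment 6) and `path_length`.
#' @export
protrusion_spans <- function(track, cfg) {
  stopifnot(identical(track$track_id, "B"), inherits(cfg, "track_config"))
  L <- seg_len(track)
  if (cfg$protrusion_side == "segments_3_4_5") {
    prot <- c(2 * L, 5 * L)            # [80, 200]
    base <- c(5 * L, 6 * L)            # [200, 240]
    straight <- c(6 * L, 7 * L)        # [240, 280]
  } else {
    straight <- c(2 * L, 3 * L)        # [80, 120]
    base <- c(3 * L, 4 * L)            # [120, 160]
    prot <- c(4 * L, 7 * L)            # [160, 280]
  }
  list(protrusion = prot,
       centre_segment = prot[1] + c(L, 2 * L),
       straight = straight,
       base = base,
       path_length = 9 * L)
}

#' Canonical (elastic) track coordinate
#'
#' Track B's protrusion slots stretch threefold when the detour is
#' deployed. The canonical coordinate maps each configuration's `x_l` onto
#' a common elastic axis in which each slot always has one segment length:
#' fields anchored in canonical coordinates stretch and shrink with the
#' slot, which is the topological (sequence-preserving) coding hypothesis.
#' On Track A the deployed path never changes length, so the canonical
#' coordinate is `x_l` itself.
#'
#' @param track A `track_model`.
#' @param cfg A matching `track_config`.
#' @param x_l Arc length(s) from F1 in this configuration, cm.
#' @return Canonical coordinate(s), cm, in `[0, canonical_length(track)]`.
#' @export
canonical_coord <- function(track, cfg, x_l) {
  if (track$track_id == "A") return(x_l)
  b <- .b_boundaries(track, cfg)
  stats::approx(b$current, b$canonical, xout = pmin(pmax(x_l, 0), max(b$current)),
                rule = 2)$y
}

#' Inverse of [canonical_coord()]
#' @inheritParams canonical_coord
#' @param s Canonical coordinate(s), cm.
#' @return `x_l` in the given configuration, cm.
#' @export
xl_from_canonical <- function(track, cfg, s) {
  if (track$track_id == "A") return(s)
  b <- .b_boundaries(track, cfg)
  stats::approx(b$canonical, b$current, xout = pmin(pmax(s, 0), max(b$canonical)),
                rule = 2)$y
}

#' Canonical track length
#' @param track A `track_model`.
#' @return Length of the canonical axis, cm (Track A: the full path;
#'   Track B: path with both slots at one segment length).
#' @export
canonical_length <- function(track) {
  L <- seg_len(track)
  if (track$track_id == "A") 10 * L else 7 * L
}

.b_boundaries <- function(track, cfg) {
  L <- seg_len(track)
  canonical <- c(0, 2 * L, 3 * L, 4 * L, 5 * L, 7 * L)
  current <- if (cfg$protrusion_side == "segments_3_4_5")
    c(0, 2 * L, 5 * L, 6 * L, 7 * L, 9 * L)
  else
    c(0, 2 * L, 3 * L, 4 * L, 7 * L, 9 * L)
  list(canonical = canonical, current = current)
}

#' Arc-length span of the static base segments of Track A
#'
#' Segments 5 and 6 (the left, fixed part of the U). Cells whose linear
#' field peak falls in this span are classified static.
#'
#' @param track Track A model.
#' @return `c(start, end)` of `x_l`, cm.
#' @export
static_span <- function(track) {
  stopifnot(identical(track$track_id, "A"))
  L <- seg_len(track)
  c(4 * L, 6 * L)
}
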