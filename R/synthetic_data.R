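# Synthetic sessions: configuration schedules, alternation trajectories and
# inhomogeneous Poisson place-cell spike trains under selectable anchoring
# hypotheses.

#' Behavioural parameters of the simulated animal
#'
#' Calibrated so that a full well-to-well run on the 4 m accordion track
#' takes about 34 s. Speeds follow a smooth autoregressive profile around
#' the mean; lateral position wanders around the midline within the rails.
#'
#' @param mean_speed_cms Mean running speed, cm/s.
#' @param speed_sd_cms Standard deviation of the speed fluctuation, cm/s.
#' @param pause_mean_s,pause_sd_s Duration of the reward pause at a well, s
#'   (the track is reconfigured during this pause).
#' @param lateral_sd_cm Standard deviation of lateral wander, cm.
#' @param sampling_hz Position sampling rate, Hz.
#' @return A `behavior_params` list.
#' @export
behavior_params <- function(mean_speed_cms = 400 / 34, speed_sd_cms = 2,
                            pause_mean_s = 10, pause_sd_s = 2,
                            lateral_sd_cm = 1.2, sampling_hz = 25) {
  stopifnot(mean_speed_cms > 0, sampling_hz > 0, pause_mean_s > 0,
            speed_sd_cms >= 0, lateral_sd_cm >= 0)
  structure(list(mean_speed_cms = mean_speed_cms, speed_sd_cms = speed_sd_cms,
                 pause_mean_s = pause_mean_s, pause_sd_s = pause_sd_s,
                 lateral_sd_cm = lateral_sd_cm, sampling_hz = sampling_hz),
            class = "behavior_params")
}

# Deterministic sub-stream seeds below 2^31, so one master seed drives
# schedule, trajectory, cells and spikes independently.
sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2000000011
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(expr)
}

.sample_extents <- function(track, n, sampler = c("stratified", "uniform")) {
  sampler <- match.arg(sampler)
  r <- extent_range(track)
  w <- track$section_width_cm
  ns <- track$n_sections
  cover_ok <- function(e) min(tabulate(section_of_extent(track, e), ns)) >= 3
  draw_uniform <- function() stats::runif(n, r[1], r[1] + ns * w)
  if (sampler == "uniform") {
    e <- draw_uniform()
    if (n >= 3 * ns) {
      tries <- 1L
      while (!cover_ok(e) && tries < 200L) { e <- draw_uniform(); tries <- tries + 1L }
    }
    return(e)
  }
  # stratified: guarantee >= 3 extents per section when n allows, shuffled
  base <- rep(seq_len(ns), length.out = min(n, 3 * ns))
  extra <- if (n > 3 * ns) sample.int(ns, n - 3 * ns, replace = TRUE) else integer(0)
  sec <- sample(c(base, extra))
  r[1] + (sec - 1) * w + stats::runif(n) * w
}

#' Simulate a Track A configuration schedule
#'
#' Each track move sets new extents for both arms independently (the two
#' arms' motions are unrelated: one arm may contract while the other
#' expands). The default stratified sampler guarantees that every vertical
#' section of each arm is populated by at least three configurations when
#' `n_moves >= 35`; the `"uniform"` sampler draws iid extents and resamples
#' a bounded number of times, flagging the schedule if coverage fails.
#'
#' @param track Track A model.
#' @param n_moves Number of track moves (10--80 in the emulated protocol;
#'   default 40). The session has `n_moves + 1` configurations.
#' @param extent_sampler `"stratified"` (default) or `"uniform"`.
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param behavior Used only to set nominal epoch durations.
#' @return A `config_schedule` object: a table of configurations with
#'   nominal epoch times, plus the `track_config` objects themselves.
#' @export
simulate_schedule <- function(track, n_moves = 40,
                              extent_sampler = c("stratified", "uniform"),
                              seed = 1, behavior = behavior_params()) {
  stopifnot(identical(track$track_id, "A"), n_moves >= 1)
  extent_sampler <- match.arg(extent_sampler)
  n_cfg <- n_moves + 1L
  .with_seed(sub_seed(seed, 1), {
    top <- .sample_extents(track, n_cfg, extent_sampler)
    bottom <- .sample_extents(track, n_cfg, extent_sampler)
  })
  warn_top <- min(tabulate(section_of_extent(track, top), track$n_sections)) < 3
  warn_bot <- min(tabulate(section_of_extent(track, bottom), track$n_sections)) < 3
  coverage_warning <- warn_top || warn_bot
  if (coverage_warning)
    warning("schedule does not populate every vertical section >= 3 times")
  ids <- sprintf("c%03d", seq_len(n_cfg))
  cfgs <- lapply(seq_len(n_cfg), function(i)
    track_a_config(track, top[i], bottom[i], config_id = ids[i]))
  epoch <- behavior$pause_mean_s + total_length(track) / behavior$mean_speed_cms
  tab <- data.frame(
    config_id = ids,
    top_extent_cm = top, bottom_extent_cm = bottom,
    section_top = vapply(cfgs, `[[`, 1L, "section_top"),
    section_bottom = vapply(cfgs, `[[`, 1L, "section_bottom"),
    t_start_s = (seq_len(n_cfg) - 1) * epoch,
    t_end_s = seq_len(n_cfg) * epoch,
    stringsAsFactors = FALSE
  )
  structure(list(track_id = "A", table = tab, configs = cfgs,
                 n_moves = n_moves, coverage_warning = coverage_warning,
                 seed = seed),
            class = "config_schedule")
}

#' Single-configuration schedule (Track B sessions)
#'
#' @param track Track B model.
#' @param side Protrusion side for the whole session.
#' @param duration_s Session duration, s (the emulated protocol uses
#'   20-minute runs).
#' @return A `config_schedule` with one epoch.
#' @export
protrusion_schedule <- function(track, side, duration_s = 1200) {
  stopifnot(identical(track$track_id, "B"))
  cfg <- with_protrusion(track, side, config_id = "c001")
  tab <- data.frame(config_id = "c001", protrusion_side = side,
                    t_start_s = 0, t_end_s = duration_s,
                    stringsAsFactors = FALSE)
  structure(list(track_id = "B", table = tab, configs = list(cfg),
                 n_moves = 0L, coverage_warning = FALSE, seed = NA),
            class = "config_schedule")
}

#' @export
print.config_schedule <- function(x, ...) {
  cat(sprintf("<config_schedule: track %s, %d configurations%s>\n",
              x$track_id, nrow(x$table),
              if (isTRUE(x$coverage_warning)) ", COVERAGE WARNING" else ""))
  invisible(x)
}

.ar1 <- function(n, sd, rho = 0.9) {
  if (n <= 0) return(numeric(0))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

#' Simulate an alternation trajectory
#'
#' The agent alternates between the two food wells (F1, F2, F1, ...),
#' following the midline of the current configuration with smooth lateral
#' wander. Each epoch consists of a reward pause at the current well --
#' during which the track assumes the epoch's configuration -- followed by
#' one run to the opposite well. Track moves therefore happen only while
#' the agent is stationary at a well, as in the emulated protocol.
#'
#' For Track A the session consumes the whole schedule (one run per
#' configuration); for Track B the single configuration is run repeatedly
#' until the scheduled session ends.
#'
#' @param track A `track_model`.
#' @param schedule A matching `config_schedule`.
#' @param behavior A `behavior_params` object.
#' @param seed Integer seed.
#' @return A `trajectory`: data frame with `t_s`, `x_cm`, `y_cm`,
#'   `x_l_cm`, `y_l_cm`, `config_id`, `epoch`, `phase` ("pause"/"run"),
#'   with the realized schedule attached as attribute `"schedule"`.
#' @export
simulate_trajectory <- function(track, schedule, behavior = behavior_params(),
                                seed = 1) {
  stopifnot(inherits(schedule, "config_schedule"),
            identical(track$track_id, schedule$track_id))
  dt <- 1 / behavior$sampling_hz
  session_cap <- if (track$track_id == "B") max(schedule$table$t_end_s) else Inf
  cfgs <- schedule$configs
  n_epochs <- if (track$track_id == "B") 10000L else length(cfgs)
  half_w <- track$track_width_cm / 2 - 0.5

  out <- vector("list", 2L * n_epochs)
  realized <- matrix(NA_real_, length(cfgs), 2)
  t_now <- 0
  at_f1 <- TRUE
  oi <- 0L
  .with_seed(sub_seed(seed, 2), {
    for (e in seq_len(n_epochs)) {
      cfg <- cfgs[[if (track$track_id == "B") 1L else e]]
      pl <- path_polyline(track, cfg)
      Ltot <- pl$path_length
      t_ep0 <- t_now
      # reward pause at the current well (track already in configuration e)
      p_dur <- max(3, stats::rnorm(1, behavior$pause_mean_s, behavior$pause_sd_s))
      np <- max(1L, round(p_dur / dt))
      xl_well <- if (at_f1) 0 else Ltot
      xl_p <- rep(xl_well, np) + pmin(pmax(.ar1(np, 0.3), -1), 1)
      xl_p <- pmin(pmax(xl_p, 0), Ltot)
      yl_p <- pmin(pmax(.ar1(np, 0.3), -half_w), half_w)
      # run to the opposite well
      nmax <- ceiling(Ltot / behavior$mean_speed_cms / dt * 3) + 50L
      v <- behavior$mean_speed_cms + .ar1(nmax, behavior$speed_sd_cms)
      v <- pmin(pmax(v, 0.35 * behavior$mean_speed_cms),
                2 * behavior$mean_speed_cms)
      s <- cumsum(v * dt)
      nr <- which(s >= Ltot)[1]
      if (is.na(nr)) nr <- nmax
      prog <- pmin(s[seq_len(nr)], Ltot)
      xl_r <- if (at_f1) prog else Ltot - prog
      yl_r <- pmin(pmax(.ar1(nr, behavior$lateral_sd_cm, rho = 0.95),
                        -half_w), half_w)
      xl <- c(xl_p, xl_r)
      yl <- c(yl_p, yl_r)
      xy <- planar_from_linear(track, cfg, xl, yl)
      n_i <- length(xl)
      out[[e]] <- data.frame(
        t_s = t_now + seq_len(n_i) * dt,
        x_cm = xy[, 1], y_cm = xy[, 2],
        x_l_cm = xl, y_l_cm = yl,
        config_id = cfg$config_id,
        epoch = e,
        phase = rep(c("pause", "run"), c(np, nr)),
        stringsAsFactors = FALSE
      )
      t_now <- t_now + n_i * dt
      at_f1 <- !at_f1
      oi <- e
      if (track$track_id == "A") {
        realized[e, ] <- c(t_ep0, t_now)
      }
      if (t_now >= session_cap) break
    }
  })
  traj <- do.call(rbind, out[seq_len(oi)])
  sched <- schedule
  if (track$track_id == "A") {
    sched$table$t_start_s <- realized[, 1]
    sched$table$t_end_s <- realized[, 2]
  } else {
    sched$table$t_end_s <- max(traj$t_s)
  }
  attr(traj, "schedule") <- sched
  attr(traj, "track_id") <- track$track_id
  class(traj) <- c("trajectory", "data.frame")
  traj
}

#' Construct a population of model place cells
#'
#' Each cell has a single, roughly Gaussian field defined in one anchored
#' coordinate system -- the experimental variable of the synthetic module:
#' \describe{
#'   \item{planar}{field centre fixed in room coordinates; firing depends
#'     on Euclidean distance to that point, wherever the track happens to
#'     pass.}
#'   \item{linear_fraction}{field centre fixed on the elastic canonical
#'     track coordinate (see [canonical_coord()]); fields keep their
#'     relative position along the track and stretch with local
#'     deformations.}
#'   \item{segment_bound}{field tied to a material point on a physical
#'     segment, wherever that segment currently lies.}
#'   \item{distance_from_well}{field at a fixed arc distance from one food
#'     well.}
#' }
#'
#' @param n Number of cells (0 allowed).
#' @param anchoring One of `"planar"`, `"linear_fraction"`,
#'   `"segment_bound"`, `"distance_from_well"`.
#' @param track The `track_model` the cells live on.
#' @param seed Integer seed.
#' @param peak_hz,baseline_hz In-field peak and out-of-field baseline
#'   rates, Hz.
#' @param sigma_cm Field standard deviation in the anchored coordinate, cm.
#' @param rate_gain Optional named numeric vector of per-configuration
#'   multiplicative gains on the field amplitude (rate remapping); names
#'   are config ids, unlisted configs get gain 1.
#' @return List of `place_cell` objects.
#' @export
make_place_cells <- function(n, anchoring = c("linear_fraction", "planar",
                                              "segment_bound",
                                              "distance_from_well"),
                             track, seed = 1, peak_hz = 15, baseline_hz = 0.1,
                             sigma_cm = 10, rate_gain = NULL) {
  anchoring <- match.arg(anchoring)
  stopifnot(n >= 0, peak_hz > baseline_hz, baseline_hz >= 0, sigma_cm > 0)
  if (n == 0) return(list())
  cells <- .with_seed(sub_seed(seed, 3), {
    lapply(seq_len(n), function(i) {
      centre <- switch(anchoring,
        linear_fraction = list(fraction = stats::runif(1)),
        planar = {
          # a room point the track can actually reach: a random arc position
          # of a random configuration
          cfg <- if (track$track_id == "A") {
            r <- section_extent_range(track)
            track_a_config(track, stats::runif(1, r[1], r[2]),
                           stats::runif(1, r[1], r[2]))
          } else {
            with_protrusion(track, sample(c("segments_3_4_5",
                                            "segments_7_8_9"), 1))
          }
          pl <- path_polyline(track, cfg)
          xy <- planar_from_linear(track, cfg,
                                   stats::runif(1, 0, pl$path_length))
          list(x = xy[1, 1], y = xy[1, 2])
        },
        segment_bound = {
          ids <- if (track$track_id == "A") 1:10 else c(1:6, 10:11)
          list(segment = sample(ids, 1), fraction = stats::runif(1))
        },
        distance_from_well = {
          pl0 <- if (track$track_id == "A") 10 * seg_len(track) else 9 * seg_len(track)
          list(well = sample(c("F1", "F2"), 1),
               distance = stats::runif(1, 0, pl0))
        })
      structure(list(cell_id = sprintf("cell%03d", i), anchoring = anchoring,
                     centre = centre, sigma_cm = sigma_cm, peak_hz = peak_hz,
                     baseline_hz = baseline_hz, rate_gain = rate_gain),
                class = "place_cell")
    })
  })
  cells
}

#' @export
print.place_cell <- function(x, ...) {
  cat(sprintf("<place_cell %s: %s, peak %.1f Hz, sigma %.1f cm>\n",
              x$cell_id, x$anchoring, x$peak_hz, x$sigma_cm))
  invisible(x)
}

#' Instantaneous firing rate of a place cell
#'
#' Gaussian tuning in the cell's anchored coordinate:
#' `baseline + gain * (peak - baseline) * exp(-delta^2 / (2 sigma^2))`,
#' where `delta` is the distance from the sample to the field centre in
#' that coordinate. Vectorized over samples within one configuration.
#'
#' @param cell A `place_cell`.
#' @param track A `track_model`.
#' @param cfg The `track_config` the samples were recorded in.
#' @param x,y Planar coordinates, cm.
#' @param x_l Linearized coordinate, cm.
#' @return Rates in Hz.
#' @export
instantaneous_rate <- function(cell, track, cfg, x, y, x_l) {
  delta <- switch(cell$anchoring,
    planar = sqrt((x - cell$centre$x)^2 + (y - cell$centre$y)^2),
    linear_fraction = {
      s <- canonical_coord(track, cfg, x_l)
      s - cell$centre$fraction * canonical_length(track)
    },
    segment_bound = {
      span <- segment_xl_span(track, cfg, cell$centre$segment)
      if (is.null(span)) rep(Inf, length(x_l))
      else x_l - (span[1] + cell$centre$fraction * (span[2] - span[1]))
    },
    distance_from_well = {
      pl <- path_polyline(track, cfg)
      d <- if (cell$centre$well == "F1") x_l else pl$path_length - x_l
      d - cell$centre$distance
    },
    stop("unknown anchoring: ", cell$anchoring))
  gain <- 1
  if (!is.null(cell$rate_gain) && !is.null(cfg$config_id)) {
    g <- cell$rate_gain[cfg$config_id]
    if (!is.na(g)) gain <- as.numeric(g)
  }
  cell$baseline_hz +
    gain * (cell$peak_hz - cell$baseline_hz) * exp(-delta^2 / (2 * cell$sigma_cm^2))
}

#' Simulate spike trains along a trajectory
#'
#' Inhomogeneous Poisson spiking with the rate held piecewise constant over
#' each position sample: the count in each inter-sample interval is Poisson
#' with mean `rate * dt` and spike times are placed uniformly within the
#' interval. Deterministic given the seed.
#'
#' @param track A `track_model`.
#' @param trajectory A `trajectory` (see [simulate_trajectory()]).
#' @param cells List of `place_cell` objects.
#' @param seed Integer seed.
#' @return A `spike_trains` data frame: `cell_id`, `t_s`, planar and linear
#'   spike positions, `config_id` and `sample_ix` (the trajectory row the
#'   spike falls in).
#' @export
simulate_spikes <- function(track, trajectory, cells, seed = 1) {
  sched <- attr(trajectory, "schedule")
  stopifnot(!is.null(sched))
  tt <- trajectory$t_s
  n <- length(tt)
  dt <- c(diff(tt), stats::median(diff(tt)))
  cfg_of <- match(trajectory$config_id, vapply(sched$configs, `[[`, "", "config_id"))
  res <- .with_seed(sub_seed(seed, 4), {
    lapply(cells, function(cell) {
      lam <- numeric(n)
      for (ci in unique(cfg_of)) {
        sel <- cfg_of == ci
        lam[sel] <- instantaneous_rate(cell, track, sched$configs[[ci]],
                                       trajectory$x_cm[sel],
                                       trajectory$y_cm[sel],
                                       trajectory$x_l_cm[sel])
      }
      counts <- stats::rpois(n, lam * dt)
      ix <- rep.int(seq_len(n), counts)
      if (length(ix) == 0L) return(NULL)
      data.frame(cell_id = cell$cell_id,
                 t_s = tt[ix] + stats::runif(length(ix)) * dt[ix],
                 x_cm = trajectory$x_cm[ix], y_cm = trajectory$y_cm[ix],
                 x_l_cm = trajectory$x_l_cm[ix], y_l_cm = trajectory$y_l_cm[ix],
                 config_id = trajectory$config_id[ix],
                 sample_ix = ix,
                 stringsAsFactors = FALSE)
    })
  })
  res <- res[!vapply(res, is.null, TRUE)]
  spikes <- if (length(res)) do.call(rbind, res)
  else data.frame(cell_id = character(), t_s = numeric(), x_cm = numeric(),
                  y_cm = numeric(), x_l_cm = numeric(), y_l_cm = numeric(),
                  config_id = character(), sample_ix = integer(),
                  stringsAsFactors = FALSE)
  rownames(spikes) <- NULL
  class(spikes) <- c("spike_trains", "data.frame")
  spikes
}

#' Simulate a complete Track A session
#'
#' Chains [simulate_schedule()], [simulate_trajectory()],
#' [make_place_cells()] and [simulate_spikes()] from one master seed and
#' packages the result as a [session_bundle()].
#'
#' @param track Track A model (built if missing).
#' @param n_moves Number of track moves.
#' @param n_cells Number of place cells.
#' @param anchoring Field anchoring hypothesis for the whole population.
#' @param seed Master seed.
#' @param behavior A `behavior_params` object.
#' @param ... Passed to [make_place_cells()] (field parameters).
#' @return A `session_bundle`.
#' @export
simulate_session <- function(track = build_track_a(), n_moves = 40,
                             n_cells = 50, anchoring = "linear_fraction",
                             seed = 1, behavior = behavior_params(), ...) {
  schedule <- simulate_schedule(track, n_moves, seed = seed,
                                behavior = behavior)
  traj <- simulate_trajectory(track, schedule, behavior, seed = seed)
  cells <- make_place_cells(n_cells, anchoring, track, seed = seed, ...)
  spikes <- simulate_spikes(track, traj, cells, seed = seed)
  session_bundle(track, traj, spikes, cells,
                 manifest = list(seed = seed, n_moves = n_moves,
                                 n_cells = n_cells, anchoring = anchoring))
}

#' Simulate a Track B session pair (protrusion flip)
#'
#' Two consecutive sessions with the same cell population and opposite
#' protrusion sides, as in the alternating-day flip protocol.
#'
#' @param track Track B model (built if missing).
#' @param n_cells Number of place cells.
#' @param anchoring Field anchoring hypothesis.
#' @param seed Master seed.
#' @param first_side Protrusion side of session 1.
#' @param session_s Duration of each run session, s.
#' @param behavior A `behavior_params` object.
#' @param ... Passed to [make_place_cells()].
#' @return A `protrusion_pair` of two `session_bundle`s sharing one cell
#'   population.
#' @export
simulate_protrusion_pair <- function(track = build_track_b(), n_cells = 100,
                                     anchoring = "linear_fraction", seed = 1,
                                     first_side = "segments_3_4_5",
                                     session_s = 1200,
                                     behavior = behavior_params(), ...) {
  other <- setdiff(c("segments_3_4_5", "segments_7_8_9"), first_side)
  cells <- make_place_cells(n_cells, anchoring, track, seed = seed, ...)
  mk <- function(side, k) {
    sch <- protrusion_schedule(track, side, duration_s = session_s)
    traj <- simulate_trajectory(track, sch, behavior, seed = seed + 17 * k)
    spikes <- simulate_spikes(track, traj, cells, seed = seed + 31 * k)
    session_bundle(track, traj, spikes, cells,
                   manifest = list(seed = seed, side = side,
                                   anchoring = anchoring))
  }
  protrusion_pair(mk(first_side, 1L), mk(other, 2L))
}
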