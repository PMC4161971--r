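# Occupancy-normalized rate maps on a 3 cm grid in either reference frame,
# with random half-bin grid-shift averaging and no other smoothing.

#' Define a binning grid
#'
#' @param frame `"planar"` (room x/y) or `"linear"` (x_l/y_l).
#' @param origin Lower-left corner `c(x, y)`, cm.
#' @param bin_cm Bin side; bins are `[left, right)` half-open intervals.
#' @param n_x,n_y Number of bins along each axis.
#' @return A `bin_grid` object.
#' @export
bin_grid <- function(frame = c("planar", "linear"), origin, bin_cm = 3,
                     n_x, n_y) {
  frame <- match.arg(frame)
  stopifnot(bin_cm > 0, n_x >= 1, n_y >= 1, length(origin) == 2)
  structure(list(frame = frame, origin = as.numeric(origin),
                 bin_cm = bin_cm, n_x = as.integer(n_x),
                 n_y = as.integer(n_y),
                 n_bins = as.integer(n_x) * as.integer(n_y)),
            class = "bin_grid")
}

#' Default linear-frame grid for a track
#'
#' Spans the deployed path length by `[-4.5, 4.5]` cm laterally, so the
#' ~8 cm runway maps onto three lateral bins, plus one guard bin on every
#' edge so that no sample or spike is lost under the half-bin grid shifts.
#'
#' @param track A `track_model`.
#' @param bin_cm Bin side, cm.
#' @return A `bin_grid`.
#' @export
linear_grid <- function(track, bin_cm = 3) {
  L <- seg_len(track)
  path_len <- if (track$track_id == "A") 10 * L else 9 * L
  bin_grid("linear", origin = c(-bin_cm, -2.5 * bin_cm), bin_cm = bin_cm,
           n_x = ceiling(path_len / bin_cm) + 2L, n_y = 5)
}

#' Default planar-frame grid for a track
#'
#' Covers the room area swept by all configurations, with margin for the
#' track width and the half-bin grid shifts.
#'
#' @inheritParams linear_grid
#' @return A `bin_grid`.
#' @export
planar_grid <- function(track, bin_cm = 3) {
  L <- seg_len(track)
  m <- 6
  if (track$track_id == "A") {
    xr <- c(-m, 4 * L + m); yr <- c(-L - m, 3 * L + m)
  } else {
    xr <- c(-m, 3 * L + m); yr <- c(-L - m, 2 * L + m)
  }
  bin_grid("planar", origin = c(xr[1], yr[1]), bin_cm = bin_cm,
           n_x = ceiling(diff(xr) / bin_cm), n_y = ceiling(diff(yr) / bin_cm))
}

#' One-dimensional grid over a linearized span
#'
#' Used for the Track B span comparisons: `n` bins of equal width over
#' `[origin, origin + length]` of `x_l` (a single lateral bin).
#'
#' @param origin_xl Span start, cm of `x_l`.
#' @param length_cm Span length, cm.
#' @param bin_cm Target bin side; the actual width is `length / n` with
#'   `n = round(length / bin_cm)` so the span is tiled exactly. One guard
#'   bin is added at each end for the grid shifts.
#' @return A `bin_grid` in the linear frame.
#' @export
span_grid <- function(origin_xl, length_cm, bin_cm = 3) {
  n <- max(1L, round(length_cm / bin_cm))
  w <- length_cm / n
  bin_grid("linear", origin = c(origin_xl - w, -100), bin_cm = w,
           n_x = n + 2L, n_y = 1)
}

grid_coords <- function(traj_like, grid) {
  if (grid$frame == "planar") cbind(traj_like$x_cm, traj_like$y_cm)
  else cbind(traj_like$x_l_cm, traj_like$y_l_cm)
}

# Flattened bin index (NA outside the grid) for coordinates under a grid
# shifted by `shift`; shifting the grid by +s bins the value v into the
# bin of v - s on the reference grid.
bin_index <- function(xy, grid, shift = c(0, 0)) {
  ix <- floor((xy[, 1] - grid$origin[1] - shift[1]) / grid$bin_cm) + 1
  iy <- if (grid$n_y == 1L) rep(1, nrow(xy))
        else floor((xy[, 2] - grid$origin[2] - shift[2]) / grid$bin_cm) + 1
  ok <- ix >= 1 & ix <= grid$n_x & iy >= 1 & iy <= grid$n_y
  idx <- (ix - 1) * grid$n_y + iy
  idx[!ok] <- NA
  as.integer(idx)
}

#' Random half-bin grid shifts
#'
#' @param n_shifts Number of shifts.
#' @param bin_cm Bin side, cm; offsets are uniform in `[-bin/2, +bin/2]`
#'   per axis.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return An `n_shifts` x 2 matrix of offsets, cm.
#' @export
make_shifts <- function(n_shifts = 25, bin_cm = 3, seed = NULL) {
  stopifnot(n_shifts >= 1)
  .with_seed(if (is.null(seed)) NULL else sub_seed(seed, 9),
             matrix(stats::runif(2 * n_shifts, -bin_cm / 2, bin_cm / 2),
                    ncol = 2))
}

.weighted_tab <- function(idx, w, n_bins) {
  keep <- !is.na(idx)
  out <- numeric(n_bins)
  if (!any(keep)) return(out)
  agg <- rowsum(w[keep], idx[keep])
  out[as.integer(rownames(agg))] <- agg
  out
}

# occupancy seconds per bin for each shift: n_bins x n_shifts
occ_stack <- function(xy, dt, grid, shifts) {
  vapply(seq_len(nrow(shifts)), function(s)
    .weighted_tab(bin_index(xy, grid, shifts[s, ]), dt, grid$n_bins),
    numeric(grid$n_bins))
}

count_stack <- function(xy, grid, shifts) {
  vapply(seq_len(nrow(shifts)), function(s) {
    idx <- bin_index(xy, grid, shifts[s, ])
    tabulate(idx[!is.na(idx)], grid$n_bins)
  }, numeric(grid$n_bins))
}

#' Per-sample speed estimate
#'
#' Positions are box-smoothed over `smooth_n` samples and speed is the
#' central difference of the smoothed path.
#'
#' @param trajectory A `trajectory` data frame.
#' @param smooth_n Box window length, samples (odd).
#' @return Speeds in cm/s, one per sample.
#' @export
estimate_speed <- function(trajectory, smooth_n = 5) {
  n <- nrow(trajectory)
  if (n < 3) return(rep(0, n))
  box <- function(z) {
    f <- as.numeric(stats::filter(z, rep(1 / smooth_n, smooth_n), sides = 2))
    f[is.na(f)] <- z[is.na(f)]
    f
  }
  xs <- box(trajectory$x_cm); ys <- box(trajectory$y_cm)
  i0 <- c(1, seq_len(n - 2), n - 2)
  i1 <- c(3, seq_len(n - 2) + 2, n)
  d <- sqrt((xs[i1] - xs[i0])^2 + (ys[i1] - ys[i0])^2)
  d / (trajectory$t_s[i1] - trajectory$t_s[i0])
}

#' Speed-filter a trajectory and its spikes
#'
#' Samples (and the spikes falling in them) taken while moving slower than
#' `v_min` are excluded from all downstream computation, mirroring the
#' standard immobility filter for place-field analysis.
#'
#' @param trajectory A `trajectory`.
#' @param spikes Optional `spike_trains` to flag alongside.
#' @param v_min Speed threshold, cm/s.
#' @param smooth_n Box window for the speed estimate, samples.
#' @return The trajectory with `speed_cms` and logical `included` columns;
#'   if `spikes` is given, a list `list(trajectory, spikes)` with spike
#'   `included` flags.
#' @export
speed_filter <- function(trajectory, spikes = NULL, v_min = 3, smooth_n = 5) {
  if (nrow(trajectory) == 0) {
    warning("empty trajectory")
    trajectory$speed_cms <- numeric(0)
    trajectory$included <- logical(0)
    if (is.null(spikes)) return(trajectory)
    spikes$included <- logical(0)
    return(list(trajectory = trajectory, spikes = spikes))
  }
  trajectory$speed_cms <- estimate_speed(trajectory, smooth_n)
  trajectory$included <- trajectory$speed_cms >= v_min
  if (is.null(trajectory$dt_s)) {
    dt <- c(diff(trajectory$t_s), stats::median(diff(trajectory$t_s)))
    if (nrow(trajectory) == 1) dt <- 0
    trajectory$dt_s <- dt
  }
  if (is.null(spikes)) return(trajectory)
  six <- spikes$sample_ix
  if (is.null(six)) six <- findInterval(spikes$t_s, trajectory$t_s)
  six <- pmin(pmax(six, 1L), nrow(trajectory))
  spikes$included <- trajectory$included[six]
  list(trajectory = trajectory, spikes = spikes)
}

#' Occupancy seconds per bin
#'
#' Each inter-sample interval is assigned to the bin of its first sample;
#' the sum over bins equals the total included duration.
#'
#' @param trajectory A (filtered) `trajectory`; rows with `included ==
#'   FALSE` are skipped.
#' @param grid A `bin_grid`.
#' @param shift Grid offset `c(dx, dy)`, cm.
#' @return Numeric vector of seconds, length `grid$n_bins`.
#' @export
compute_occupancy <- function(trajectory, grid, shift = c(0, 0)) {
  dt <- trajectory$dt_s
  if (is.null(dt)) {
    dt <- c(diff(trajectory$t_s), stats::median(diff(trajectory$t_s)))
    if (nrow(trajectory) == 1) dt <- 0
  }
  keep <- if (!is.null(trajectory$included)) trajectory$included
          else rep(TRUE, nrow(trajectory))
  xy <- grid_coords(trajectory[keep, , drop = FALSE], grid)
  .weighted_tab(bin_index(xy, grid, shift), dt[keep], grid$n_bins)
}

#' Occupancy-normalized rate map with grid-shift averaging
#'
#' For each random half-bin grid offset the spike count over occupancy is
#' computed per bin and re-registered to the reference grid; the final
#' rate in a bin is the mean over the shifts in which the bin was visited.
#' No other smoothing is applied. With `n_shifts = 1` and a zero shift the
#' map is exactly count/occupancy.
#'
#' @param trajectory A speed-filtered `trajectory`.
#' @param spikes `spike_trains` rows for one cell (flagged by
#'   [speed_filter()]; rows with `included == FALSE` are dropped).
#' @param grid A `bin_grid`.
#' @param n_shifts Number of random grid shifts (ignored when `shifts`
#'   is supplied).
#' @param seed Seed for the shifts.
#' @param shifts Optional explicit shift matrix (n x 2, cm), e.g. shared
#'   between the two maps of a correlation pair.
#' @return A `rate_map`: list with the shift-averaged `rate` (Hz, NA on
#'   unvisited bins), logical `visited`, and the unshifted `occupancy_s`
#'   and `count` vectors.
#' @export
compute_rate_map <- function(trajectory, spikes = NULL, grid,
                             n_shifts = 25, seed = NULL, shifts = NULL) {
  if (is.null(shifts))
    shifts <- make_shifts(n_shifts, grid$bin_cm, seed)
  keep_t <- if (!is.null(trajectory$included)) trajectory$included
            else rep(TRUE, nrow(trajectory))
  tr <- trajectory[keep_t, , drop = FALSE]
  dt_all <- trajectory$dt_s
  if (is.null(dt_all)) {
    dt_all <- c(diff(trajectory$t_s), stats::median(diff(trajectory$t_s)))
    if (nrow(trajectory) <= 1) dt_all <- rep(0, nrow(trajectory))
  }
  dt <- dt_all[keep_t]
  xy_t <- grid_coords(tr, grid)
  if (is.null(spikes)) spikes <- data.frame(x_cm = numeric(), y_cm = numeric(),
                                            x_l_cm = numeric(), y_l_cm = numeric())
  keep_s <- if (!is.null(spikes$included)) spikes$included
            else rep(TRUE, nrow(spikes))
  sp <- spikes[keep_s, , drop = FALSE]
  xy_s <- grid_coords(sp, grid)
  occ <- occ_stack(xy_t, dt, grid, shifts)
  cnt <- count_stack(xy_s, grid, shifts)
  rate_map_from_stacks(occ, cnt, grid,
                       occupancy0 = .weighted_tab(bin_index(xy_t, grid), dt, grid$n_bins),
                       count0 = {
                         i0 <- bin_index(xy_s, grid)
                         tabulate(i0[!is.na(i0)], grid$n_bins)
                       })
}

# Assemble a rate_map from per-shift occupancy and count stacks.
rate_map_from_stacks <- function(occ, cnt, grid, occupancy0 = NULL,
                                 count0 = NULL) {
  visited_s <- occ > 0
  r <- cnt / occ
  r[!visited_s] <- NA
  nvis <- rowSums(visited_s)
  rate <- rowSums(r, na.rm = TRUE) / nvis
  rate[nvis == 0] <- NA
  structure(list(grid = grid, rate = rate, visited = nvis > 0,
                 occupancy_s = if (is.null(occupancy0)) occ[, 1] else occupancy0,
                 count = if (is.null(count0)) cnt[, 1] else count0,
                 n_shifts = ncol(occ)),
            class = "rate_map")
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map %s: %dx%d bins, %d visited, peak %.2f Hz>\n",
              x$grid$frame, x$grid$n_x, x$grid$n_y, sum(x$visited),
              tryCatch(peak_rate(x), error = function(e) NA)))
  invisible(x)
}

#' Peak occupancy-normalized rate of a map
#'
#' Bins grazed for a fraction of a single sample interval produce wildly
#' unstable rate estimates (one spike over a few hundredths of a second),
#' so the peak is taken over bins with at least `min_occupancy_s` of
#' occupancy; if no bin qualifies the floor is dropped and all visited
#' bins are used.
#'
#' @param map A `rate_map`.
#' @param min_occupancy_s Minimum unshifted occupancy for a bin to enter
#'   the peak estimate, s.
#' @return Maximum rate over eligible bins, Hz.
#' @export
peak_rate <- function(map, min_occupancy_s = 0.2) {
  el <- .peak_eligible(map, min_occupancy_s)
  max(map$rate[el], na.rm = TRUE)
}

.peak_eligible <- function(map, min_occupancy_s) {
  if (!any(map$visited)) stop("rate map has no visited bins", call. = FALSE)
  el <- map$visited & map$occupancy_s >= min_occupancy_s & !is.na(map$rate)
  if (!any(el)) el <- map$visited & !is.na(map$rate)
  if (!any(el)) el <- map$visited
  el
}

#' Coordinates of the peak-rate bin centre
#'
#' @inheritParams peak_rate
#' @return Numeric `c(x, y)` of the bin centre in the map's frame, cm.
#' @export
peak_bin <- function(map, min_occupancy_s = 0.2) {
  el <- .peak_eligible(map, min_occupancy_s)
  i <- which.max(ifelse(el, map$rate, -Inf))
  ix <- (i - 1) %/% map$grid$n_y + 1
  iy <- (i - 1) %% map$grid$n_y + 1
  c(map$grid$origin[1] + (ix - 0.5) * map$grid$bin_cm,
    map$grid$origin[2] + (iy - 0.5) * map$grid$bin_cm)
}

#' Flattened activity vector of a rate map
#'
#' Bins are sequenced column-wise starting at the top-right square and
#' moving down, then stepping one column to the left, matching the
#' convention used to build the correlation activity vectors.
#'
#' @param map A `rate_map`.
#' @return Numeric vector of rates (NA on unvisited bins) of length
#'   `n_x * n_y`.
#' @export
activity_vector <- function(map) {
  g <- map$grid
  ix <- rep(g$n_x:1, each = g$n_y)
  iy <- rep(g$n_y:1, times = g$n_x)
  map$rate[(ix - 1) * g$n_y + iy]
}

#' Linear field-peak estimate, marginalized over the lateral bins
#'
#' Estimates the `x_l` of a cell's field centre from the shift-averaged
#' occupancy-normalized rate profile along the track, pooling occupancy
#' and counts over the lateral bins first (the field centre is a
#' one-dimensional quantity, so the lateral split only adds noise).
#'
#' @param trajectory A speed-filtered `trajectory` (included rows only
#'   are used).
#' @param spikes One cell's flagged spikes.
#' @param grid A linear-frame `bin_grid`.
#' @param shifts Shift matrix from [make_shifts()].
#' @return List with `peak_xl` (cm) and the averaged rate `profile`
#'   (NA where never visited), or NULL when the cell never spiked on
#'   included samples.
#' @export
linear_field_peak <- function(trajectory, spikes, grid, shifts) {
  keep_t <- if (!is.null(trajectory$included)) trajectory$included
            else rep(TRUE, nrow(trajectory))
  tr <- trajectory[keep_t, , drop = FALSE]
  dt <- tr$dt_s
  if (is.null(dt)) dt <- rep(stats::median(diff(tr$t_s)), nrow(tr))
  keep_s <- if (!is.null(spikes$included)) spikes$included
            else rep(TRUE, nrow(spikes))
  sx <- spikes$x_l_cm[keep_s]
  if (length(sx) == 0) return(NULL)
  col_of <- function(v, s) {
    i <- floor((v - grid$origin[1] - s) / grid$bin_cm) + 1
    i[i < 1 | i > grid$n_x] <- NA
    i
  }
  acc <- matrix(NA_real_, grid$n_x, nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    occ <- .weighted_tab(col_of(tr$x_l_cm, shifts[s, 1]), dt, grid$n_x)
    ci <- col_of(sx, shifts[s, 1])
    cnt <- tabulate(ci[!is.na(ci)], grid$n_x)
    acc[, s] <- ifelse(occ > 0, cnt / occ, NA)
  }
  nvis <- rowSums(!is.na(acc))
  profile <- rowSums(acc, na.rm = TRUE) / nvis
  profile[nvis == 0] <- NA
  if (all(is.na(profile))) return(NULL)
  list(peak_xl = grid$origin[1] + (which.max(profile) - 0.5) * grid$bin_cm,
       profile = profile)
}

#' Export a rate map as a plain table
#'
#' @param map A `rate_map`.
#' @return Data frame with `bin_ix`, `bin_iy`, `occupancy_s`, `count`,
#'   `rate_hz` rows for every bin, plus grid descriptors as attributes.
#' @export
rate_map_table <- function(map) {
  g <- map$grid
  out <- data.frame(
    bin_ix = rep(seq_len(g$n_x), each = g$n_y),
    bin_iy = rep(seq_len(g$n_y), times = g$n_x),
    occupancy_s = map$occupancy_s,
    count = map$count,
    rate_hz = map$rate
  )
  attr(out, "descriptor") <- list(frame = g$frame, origin = g$origin,
                                  bin_cm = g$bin_cm,
                                  flattening = "top-right, down, then left")
  out
}
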