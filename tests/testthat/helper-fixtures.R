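# Shared fixtures: simulation results are cached so several test files can
# reuse the same sessions without re-simulating.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Full-size Track A run at the study conditions (50 cells, 40 moves).
track_a_run <- function(anchoring, seed) {
  cached(sprintf("A_%s_%d", anchoring, seed), {
    bundle <- simulate_session(n_moves = 40, n_cells = 50,
                               anchoring = anchoring, seed = seed)
    list(bundle = bundle, result = run_track_a(bundle))
  })
}

# Full-size Track B pair (100 cells, two 20-minute sessions).
track_b_pair_run <- function(anchoring, seed) {
  cached(sprintf("B_%s_%d", anchoring, seed), {
    pair <- simulate_protrusion_pair(n_cells = 100, anchoring = anchoring,
                                     seed = seed)
    list(pair = pair, result = run_track_b(pair))
  })
}

# A quick Track A session for structural tests: full move count (so the
# section groups are populated) but a faster, coarser-sampled animal.
quick_session <- function(n_cells = 6, anchoring = "linear_fraction",
                          seed = 7) {
  cached(sprintf("quick_%s_%d_%d", anchoring, seed, n_cells), {
    beh <- behavior_params(mean_speed_cms = 25, pause_mean_s = 3,
                           sampling_hz = 10)
    simulate_session(n_moves = 40, n_cells = n_cells, anchoring = anchoring,
                     seed = seed, behavior = beh)
  })
}

# Hand-built trajectory moving at constant speed along x in the planar
# frame (x_l mirrors x so either frame can be used).
const_speed_trajectory <- function(n = 100, speed = 5, hz = 10) {
  t <- seq_len(n) / hz
  x <- speed * t
  structure(data.frame(t_s = t, x_cm = x, y_cm = 0, x_l_cm = x, y_l_cm = 0,
                       config_id = "c001", epoch = 1L, phase = "run",
                       stringsAsFactors = FALSE),
            class = c("trajectory", "data.frame"))
}

# Minimal rate_map with explicit rate/count/visited vectors on a 1-D grid.
mk_map <- function(rate, count = rep(1, length(rate)),
                   visited = rep(TRUE, length(rate)),
                   occupancy = rep(1, length(rate))) {
  g <- bin_grid("linear", origin = c(0, -1.5), bin_cm = 3,
                n_x = length(rate), n_y = 1)
  structure(list(grid = g, rate = rate, visited = visited,
                 occupancy_s = occupancy, count = count, n_shifts = 1),
            class = "rate_map")
}
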