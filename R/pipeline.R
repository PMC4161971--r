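# Session containers, delimited-text I/O and the end-to-end drivers for
# the two track analyses.

#' Analysis parameters
#'
#' Defaults reproduce the emulated protocol's printed parameters: 3 cm
#' bins, 3 cm/s speed filter, 12 vertical sections with a group floor of
#' three configurations, and a 2 Hz peak-rate inclusion threshold.
#'
#' @param bin_cm Spatial bin side, cm.
#' @param v_min_cms Speed filter threshold, cm/s.
#' @param n_shifts Random half-bin grid shifts averaged per map.
#' @param min_bins Minimum valid bins for a defined pair correlation.
#' @param n_tot Number of vertical sections per arm.
#' @param n_v_floor Minimum configurations per section group.
#' @param peak_threshold_hz Peak-rate inclusion threshold, Hz.
#' @param seed Seed for the grid shifts.
#' @param mask_rule Bin-inclusion rule, `"either"` or `"both"` (see
#'   [valid_bin_mask()]).
#' @param speed_smooth_n Box window for the speed estimate, samples.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(bin_cm = 3, v_min_cms = 3, n_shifts = 25,
                            min_bins = 10, n_tot = 12, n_v_floor = 3,
                            peak_threshold_hz = 2, seed = 1,
                            mask_rule = c("either", "both"),
                            speed_smooth_n = 5) {
  mask_rule <- match.arg(mask_rule)
  stopifnot(bin_cm > 0, v_min_cms > 0, n_shifts >= 1, min_bins >= 1,
            n_tot >= 1, n_v_floor >= 1, peak_threshold_hz > 0)
  structure(list(bin_cm = bin_cm, v_min_cms = v_min_cms, n_shifts = n_shifts,
                 min_bins = min_bins, n_tot = n_tot, n_v_floor = n_v_floor,
                 peak_threshold_hz = peak_threshold_hz, seed = seed,
                 mask_rule = mask_rule, speed_smooth_n = speed_smooth_n),
            class = "analysis_config")
}

#' Bundle one recorded (or simulated) session
#'
#' @param track The `track_model`.
#' @param trajectory A `trajectory` with a realized schedule attribute (or
#'   pass `schedule` explicitly).
#' @param spikes A `spike_trains` data frame.
#' @param cells Optional list of `place_cell` ground-truth models.
#' @param manifest Named list of provenance values (seeds, parameters).
#' @param schedule Optional `config_schedule` overriding the trajectory
#'   attribute.
#' @return A `session_bundle`.
#' @export
session_bundle <- function(track, trajectory, spikes, cells = NULL,
                           manifest = list(), schedule = NULL) {
  if (is.null(schedule)) schedule <- attr(trajectory, "schedule")
  stopifnot(!is.null(schedule), inherits(track, "track_model"))
  known <- schedule$table$config_id
  bad <- setdiff(unique(c(trajectory$config_id, spikes$config_id)), known)
  if (length(bad))
    stop("referential-integrity error: unknown config_id ", bad[1],
         call. = FALSE)
  if (nrow(trajectory) > 1 && any(diff(trajectory$t_s) <= 0))
    stop(sprintf("positions row %d: time not strictly increasing",
                 which(diff(trajectory$t_s) <= 0)[1] + 1L), call. = FALSE)
  structure(list(track = track, trajectory = trajectory, spikes = spikes,
                 schedule = schedule, cells = cells, manifest = manifest),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle: track %s, %.0f s, %d samples, %d spikes, %d cells>\n",
              x$track$track_id, max(x$trajectory$t_s), nrow(x$trajectory),
              nrow(x$spikes), length(unique(x$spikes$cell_id))))
  invisible(x)
}

.fmt_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(.fmt_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.read_tsv <- function(path, numeric_cols) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (nm in intersect(numeric_cols, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  df
}

#' Write a session bundle as delimited text
#'
#' Produces `positions.tsv`, `spikes.tsv`, `schedule.tsv`, `cells.tsv`
#' (when ground-truth cells are present) and a human-readable
#' `manifest.txt` under `dir`. Numeric values are written with 17
#' significant digits so a read/write cycle is lossless.
#'
#' @param bundle A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos_cols <- c("t_s", "x_cm", "y_cm", "x_l_cm", "y_l_cm", "config_id")
  paths <- c(positions = file.path(dir, "positions.tsv"),
             spikes = file.path(dir, "spikes.tsv"),
             schedule = file.path(dir, "schedule.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  .write_tsv(bundle$trajectory[, pos_cols], paths["positions"])
  spk_cols <- intersect(c("cell_id", "t_s", "x_cm", "y_cm", "x_l_cm",
                          "y_l_cm", "config_id", "sample_ix"),
                        names(bundle$spikes))
  .write_tsv(bundle$spikes[, spk_cols], paths["spikes"])
  .write_tsv(bundle$schedule$table, paths["schedule"])
  if (!is.null(bundle$cells)) {
    paths <- c(paths, cells = file.path(dir, "cells.tsv"))
    .write_tsv(.cells_table(bundle$cells), paths["cells"])
  }
  trk <- bundle$track
  man <- c(list(track_id = trk$track_id,
                segment_length_cm = seg_len(trk),
                joint_connector_cm = trk$joint_connector_cm,
                track_width_cm = trk$track_width_cm),
           bundle$manifest)
  writeLines(sprintf("%s: %s", names(man),
                     vapply(man, function(v) paste(format(v), collapse = ","), "")),
             paths["manifest"])
  invisible(paths)
}

.cells_table <- function(cells) {
  do.call(rbind, lapply(cells, function(cl) {
    ctr <- cl$centre
    data.frame(cell_id = cl$cell_id, anchoring = cl$anchoring,
               sigma_cm = cl$sigma_cm, peak_hz = cl$peak_hz,
               baseline_hz = cl$baseline_hz,
               c1 = as.numeric(ctr[[1]]),
               c2 = if (length(ctr) > 1) as.numeric(ctr[[2]]) else NA_real_,
               label = if (is.character(ctr[[1]])) ctr[[1]] else "",
               stringsAsFactors = FALSE)
  }))
}

.cells_from_table <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    centre <- switch(r$anchoring,
      linear_fraction = list(fraction = r$c1),
      planar = list(x = r$c1, y = r$c2),
      segment_bound = list(segment = as.integer(r$c1), fraction = r$c2),
      distance_from_well = list(well = r$label, distance = r$c2))
    structure(list(cell_id = r$cell_id, anchoring = r$anchoring,
                   centre = centre, sigma_cm = r$sigma_cm,
                   peak_hz = r$peak_hz, baseline_hz = r$baseline_hz,
                   rate_gain = NULL), class = "place_cell")
  })
}

#' Read a session bundle written by [write_session()]
#'
#' Malformed input is rejected with a diagnostic naming the offending
#' record: non-monotone position times, missing columns and unknown
#' config ids all raise errors.
#'
#' @param dir Directory containing the session files.
#' @return A `session_bundle`.
#' @export
read_session <- function(dir) {
  man_lines <- readLines(file.path(dir, "manifest.txt"))
  man <- strsplit(man_lines, ": ", fixed = TRUE)
  manifest <- stats::setNames(lapply(man, `[`, 2), vapply(man, `[`, "", 1))
  track <- if (manifest$track_id == "A")
    build_track_a(as.numeric(manifest$segment_length_cm),
                  as.numeric(manifest$joint_connector_cm),
                  as.numeric(manifest$track_width_cm))
  else
    build_track_b(as.numeric(manifest$segment_length_cm),
                  as.numeric(manifest$joint_connector_cm),
                  as.numeric(manifest$track_width_cm))
  sched_tab <- .read_tsv(file.path(dir, "schedule.tsv"),
                         c("top_extent_cm", "bottom_extent_cm", "t_start_s",
                           "t_end_s"))
  cfgs <- if (track$track_id == "A") {
    lapply(seq_len(nrow(sched_tab)), function(i)
      track_a_config(track, sched_tab$top_extent_cm[i],
                     sched_tab$bottom_extent_cm[i],
                     config_id = sched_tab$config_id[i]))
  } else {
    lapply(seq_len(nrow(sched_tab)), function(i)
      with_protrusion(track, sched_tab$protrusion_side[i],
                      config_id = sched_tab$config_id[i]))
  }
  schedule <- structure(list(track_id = track$track_id, table = sched_tab,
                             configs = cfgs, n_moves = nrow(sched_tab) - 1L,
                             coverage_warning = FALSE, seed = NA),
                        class = "config_schedule")
  num <- c("t_s", "x_cm", "y_cm", "x_l_cm", "y_l_cm")
  pos <- .read_tsv(file.path(dir, "positions.tsv"), num)
  need <- c(num, "config_id")
  if (!all(need %in% names(pos)))
    stop("positions.tsv: missing column(s) ",
         paste(setdiff(need, names(pos)), collapse = ", "), call. = FALSE)
  spikes <- .read_tsv(file.path(dir, "spikes.tsv"), c(num, "sample_ix"))
  if (!all(c("cell_id", "t_s") %in% names(spikes)))
    stop("spikes.tsv: missing cell_id/t_s column", call. = FALSE)
  if (!is.null(spikes$sample_ix)) spikes$sample_ix <- as.integer(spikes$sample_ix)
  cells_path <- file.path(dir, "cells.tsv")
  cells <- if (file.exists(cells_path))
    .cells_from_table(.read_tsv(cells_path, c("sigma_cm", "peak_hz",
                                              "baseline_hz", "c1", "c2")))
  attr(pos, "schedule") <- schedule
  class(pos) <- c("trajectory", "data.frame")
  class(spikes) <- c("spike_trains", "data.frame")
  session_bundle(track, pos, spikes, cells,
                 manifest = manifest, schedule = schedule)
}

#' Run the full accordion-track (Track A) analysis
#'
#' Speed-filters the session, classifies each cell as mobile (top or
#' bottom arm) or static from its session-pooled linear field, pools
#' configurations by vertical section, builds per-cell correlation
#' matrices over section pairs in both reference frames, and summarizes
#' them as subdiagonal decay curves with per-`d` Welch tests between the
#' frames.
#'
#' @param bundle A Track A `session_bundle`.
#' @param config An [analysis_config()].
#' @return A `track_a_result` list: `cells` (classification table),
#'   `matrices` (per cell, per frame), `ensemble` (`mobile`/`static`
#'   curves, per-cell r_d matrices and frame tests) and `counters`.
#' @export
run_track_a <- function(bundle, config = analysis_config()) {
  track <- bundle$track
  stopifnot(identical(track$track_id, "A"))
  f <- speed_filter(bundle$trajectory, bundle$spikes,
                    v_min = config$v_min_cms, smooth_n = config$speed_smooth_n)
  traj <- f$trajectory; spikes <- f$spikes
  lin_g <- linear_grid(track, config$bin_cm)
  pla_g <- planar_grid(track, config$bin_cm)
  grids <- list(linear = lin_g, planar = pla_g)
  shifts <- list(linear = make_shifts(config$n_shifts, config$bin_cm,
                                      seed = config$seed),
                 planar = make_shifts(config$n_shifts, config$bin_cm,
                                      seed = config$seed + 1))
  # first column = unshifted grid, used for the bin-inclusion mask
  shifts0 <- lapply(shifts, function(s) rbind(c(0, 0), s))
  tr <- traj[traj$included, , drop = FALSE]
  sp <- spikes[spikes$included, , drop = FALSE]
  cell_ids <- if (!is.null(bundle$cells))
    vapply(bundle$cells, `[[`, "", "cell_id") else sort(unique(sp$cell_id))

  # --- session-pooled linear maps: classification ---
  occ_all <- occ_stack(grid_coords(tr, lin_g), tr$dt_s, lin_g, shifts0$linear)
  sp_rows <- split(seq_len(nrow(sp)), sp$cell_id)
  cls <- lapply(cell_ids, function(cid) {
    rows <- sp_rows[[cid]]
    xy <- grid_coords(sp[rows, , drop = FALSE], lin_g)
    m <- rate_map_from_stacks(occ_all[, -1, drop = FALSE],
                              count_stack(xy, lin_g, shifts$linear), lin_g)
    fp <- if (is.null(rows)) NULL
          else linear_field_peak(tr, sp[rows, , drop = FALSE], lin_g,
                                 shifts$linear)
    if (is.null(rows) || is.null(fp) || !any(m$visited) || all(m$count == 0))
      return(data.frame(cell_id = cid, class = "unclassified",
                        arm = NA_character_, peak_xl_cm = NA_real_,
                        peak_rate_hz = NA_real_, stringsAsFactors = FALSE))
    k <- classify_mobile_static(track, fp$peak_xl)
    data.frame(cell_id = cid, class = k$class, arm = k$arm,
               peak_xl_cm = fp$peak_xl,
               peak_rate_hz = max(ifelse(m$visited, m$rate, NA), na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, cls)

  # --- section grouping ---
  groups <- list(top = group_by_section(track, bundle$schedule, "top",
                                        config$n_v_floor),
                 bottom = group_by_section(track, bundle$schedule, "bottom",
                                           config$n_v_floor))
  sec_lookup <- function(arm) {
    tab <- bundle$schedule$table
    stats::setNames(if (arm == "top") tab$section_top else tab$section_bottom,
                    tab$config_id)
  }
  combos <- list(
    mobile_top = list(arm = "top", region = "top"),
    mobile_bottom = list(arm = "bottom", region = "bottom"),
    static = list(arm = "top", region = "static"))
  combo_of <- function(row) {
    if (row$class == "static") "static"
    else if (row$class == "mobile" && row$arm == "top") "mobile_top"
    else if (row$class == "mobile") "mobile_bottom"
    else NA_character_
  }

  # --- shared occupancy stacks per (combo, frame, section) ---
  occs <- lapply(combos, function(cb) {
    span <- region_span(track, cb$region)
    smap <- sec_lookup(cb$arm)
    samp_sec <- unname(smap[tr$config_id])
    in_region <- tr$x_l_cm >= span[1] & tr$x_l_cm <= span[2]
    secs <- vapply(groups[[cb$arm]], `[[`, 0L, "section")
    lapply(stats::setNames(secs, secs), function(s) {
      rows <- which(in_region & samp_sec == s)
      lapply(grids, function(g) {
        sh <- shifts0[[g$frame]]
        occ_stack(grid_coords(tr[rows, , drop = FALSE], g),
                  tr$dt_s[rows], g, sh)
      })
    })
  })

  # --- per-cell correlation matrices ---
  sec_maps <- function(cid, cb_name) {
    cb <- combos[[cb_name]]
    span <- region_span(track, cb$region)
    smap <- sec_lookup(cb$arm)
    rows <- sp_rows[[cid]]
    if (is.null(rows)) rows <- integer(0)
    spc <- sp[rows, , drop = FALSE]
    spc_sec <- unname(smap[spc$config_id])
    in_region <- spc$x_l_cm >= span[1] & spc$x_l_cm <= span[2]
    lapply(grids, function(g) {
      sh0 <- shifts0[[g$frame]]
      maps <- vector("list", config$n_tot)
      for (s_chr in names(occs[[cb_name]])) {
        s <- as.integer(s_chr)
        o <- occs[[cb_name]][[s_chr]][[g$frame]]
        srows <- which(in_region & spc_sec == s)
        cnt <- count_stack(grid_coords(spc[srows, , drop = FALSE], g), g, sh0)
        maps[[s]] <- rate_map_from_stacks(
          o[, -1, drop = FALSE], cnt[, -1, drop = FALSE], g,
          occupancy0 = o[, 1], count0 = cnt[, 1])
      }
      maps
    })
  }
  matrices <- stats::setNames(vector("list", length(cell_ids)), cell_ids)
  for (i in seq_len(nrow(cls))) {
    cb_name <- combo_of(cls[i, ])
    if (is.na(cb_name)) next
    maps2 <- sec_maps(cls$cell_id[i], cb_name)
    matrices[[cls$cell_id[i]]] <- lapply(maps2, function(m)
      section_corr_matrix(m, config$n_tot, config$min_bins, config$mask_rule))
  }

  # --- ensembles ---
  ens <- function(ids) {
    ids <- ids[!vapply(matrices[ids], is.null, TRUE)]
    if (length(ids) == 0) return(NULL)
    lin <- ensemble_curve(lapply(matrices[ids], `[[`, "linear"))
    pla <- ensemble_curve(lapply(matrices[ids], `[[`, "planar"))
    list(linear = lin, planar = pla, n_cells = length(ids),
         tests = frame_comparison_test(attr(lin, "per_cell"),
                                       attr(pla, "per_cell")))
  }
  mobile_ids <- cls$cell_id[cls$class == "mobile"]
  static_ids <- cls$cell_id[cls$class == "static"]
  counters <- list(
    n_samples = nrow(traj), n_samples_excluded = sum(!traj$included),
    n_spikes = nrow(spikes), n_spikes_excluded = sum(!spikes$included),
    n_mobile = length(mobile_ids), n_static = length(static_ids),
    n_unclassified = sum(cls$class == "unclassified"))
  structure(list(cells = cls, matrices = matrices,
                 ensemble = list(mobile = ens(mobile_ids),
                                 static = ens(static_ids)),
                 groups = groups, counters = counters, config = config),
            class = "track_a_result")
}

#' @export
print.track_a_result <- function(x, ...) {
  cat("Accordion-track dual-frame analysis\n")
  cat(sprintf("  cells: %d mobile, %d static, %d unclassified\n",
              x$counters$n_mobile, x$counters$n_static,
              x$counters$n_unclassified))
  em <- x$ensemble$mobile
  if (!is.null(em)) {
    d10 <- which(em$linear$d == 10)
    cat(sprintf("  mobile ensemble r_10: linear %.3f, planar %.3f (gap %.3f)\n",
                em$linear$r_d[d10], em$planar$r_d[d10],
                em$linear$r_d[d10] - em$planar$r_d[d10]))
    stable <- !is.na(em$linear$r_d[d10]) && !is.na(em$planar$r_d[d10]) &&
      em$linear$r_d[d10] > em$planar$r_d[d10] + 0.2
    cat(sprintf("  frame pattern: %s\n",
                if (stable) "linear-stable (fields track the linearized frame)"
                else "not linear-stable"))
  }
  invisible(x)
}

#' Run the protrusion-flip (Track B) analysis
#'
#' Applies the 2 Hz inclusion threshold, computes the four-comparison
#' battery and its statistics.
#'
#' @param pair A `protrusion_pair`.
#' @param config An [analysis_config()].
#' @return A list with `values` (per-cell correlations), `stats`
#'   (a `comparison_result`), `included` cell ids and the identified
#'   hypothesis label.
#' @export
run_track_b <- function(pair, config = analysis_config()) {
  stopifnot(inherits(pair, "protrusion_pair"))
  ids <- include_active_cells(pair, config$peak_threshold_hz, config)
  values <- compare_protrusion(pair, config, cell_ids = ids)
  stats <- comparison_stats(values)
  list(values = values, stats = stats, included = ids,
       hypothesis = identified_hypothesis(stats))
}
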