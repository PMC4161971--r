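# Track B analysis: the four linearized cross-session correlations (Flip,
# Distance, Segment, Rescaled) quantifying how place fields respond to the
# protrusion flip, with their statistics.

#' Pair two Track B sessions with opposite protrusion sides
#'
#' @param session1,session2 `session_bundle`s from the same cell
#'   population, recorded with the protrusion on opposite sides.
#' @return A `protrusion_pair` object.
#' @export
protrusion_pair <- function(session1, session2) {
  for (s in list(session1, session2))
    stopifnot(inherits(s, "session_bundle"),
              identical(s$track$track_id, "B"))
  side1 <- session1$schedule$configs[[1]]$protrusion_side
  side2 <- session2$schedule$configs[[1]]$protrusion_side
  if (identical(side1, side2))
    stop("protocol error: both sessions have the protrusion on the same side",
         call. = FALSE)
  structure(list(session1 = session1, session2 = session2,
                 track = session1$track, sides = c(side1, side2)),
            class = "protrusion_pair")
}

#' @export
print.protrusion_pair <- function(x, ...) {
  cat(sprintf("<protrusion_pair: %s -> %s, %d cells>\n",
              x$sides[1], x$sides[2], length(x$session1$cells)))
  invisible(x)
}

# Filtered trajectory/spikes and the session's single configuration.
.prep_session <- function(bundle, config) {
  f <- speed_filter(bundle$trajectory, bundle$spikes, v_min = config$v_min_cms,
                    smooth_n = config$speed_smooth_n)
  list(traj = f$trajectory, spikes = f$spikes,
       cfg = bundle$schedule$configs[[1]])
}

# Rate map over a linearized span, in span-local coordinates
# u = (x_l - span[1]) / scale, so two spans of different physical length
# can be laid on a common grid (the Rescaled comparison uses scale > 1).
span_map <- function(prep, span, grid, cell_id = NULL, scale = 1,
                     shifts) {
  tr <- prep$traj
  kt <- tr$included & tr$x_l_cm >= span[1] & tr$x_l_cm <= span[2]
  trs <- data.frame(t_s = tr$t_s[kt], dt_s = tr$dt_s[kt],
                    x_l_cm = (tr$x_l_cm[kt] - span[1]) / scale,
                    y_l_cm = 0, included = TRUE)
  sp <- prep$spikes
  ks <- sp$included & sp$x_l_cm >= span[1] & sp$x_l_cm <= span[2]
  if (!is.null(cell_id)) ks <- ks & sp$cell_id == cell_id
  sps <- data.frame(x_l_cm = (sp$x_l_cm[ks] - span[1]) / scale, y_l_cm = 0,
                    included = TRUE)
  compute_rate_map(trs, sps, grid, shifts = shifts)
}

#' Cells active enough to enter the protrusion analysis
#'
#' Keeps cells whose peak occupancy-normalized linearized rate exceeds the
#' threshold in at least one of the two sessions (a deliberately inclusive
#' criterion).
#'
#' @param pair A `protrusion_pair`.
#' @param threshold_hz Peak-rate threshold, Hz.
#' @param config An [analysis_config()].
#' @return Character vector of included cell ids (possibly empty, with a
#'   warning).
#' @export
include_active_cells <- function(pair, threshold_hz = 2,
                                 config = analysis_config()) {
  grid <- linear_grid(pair$track, config$bin_cm)
  shifts <- make_shifts(config$n_shifts, config$bin_cm, seed = config$seed)
  peaks <- lapply(1:2, function(k) {
    prep <- .prep_session(pair[[k]], config)
    tr <- prep$traj[prep$traj$included, , drop = FALSE]
    occ <- occ_stack(grid_coords(tr, grid), tr$dt_s, grid, shifts)
    sp <- prep$spikes[prep$spikes$included, , drop = FALSE]
    vapply(pair$session1$cells, function(cell) {
      xy <- grid_coords(sp[sp$cell_id == cell$cell_id, , drop = FALSE], grid)
      m <- rate_map_from_stacks(occ, count_stack(xy, grid, shifts), grid)
      if (!any(m$visited)) NA_real_ else peak_rate(m)
    }, numeric(1))
  })
  ids <- vapply(pair$session1$cells, `[[`, "", "cell_id")
  keep <- pmax(peaks[[1]], peaks[[2]], na.rm = TRUE) >= threshold_hz
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no cell exceeds the peak-rate threshold")
  ids[keep]
}

# Shared-occupancy machinery for one (session, span, scale): the occupancy
# stack does not depend on the cell, so it is computed once and reused for
# every cell's count stack.
.span_side <- function(prep, span, grid, scale, shifts) {
  shifts0 <- rbind(c(0, 0), shifts)
  tr <- prep$traj
  kt <- which(tr$included & tr$x_l_cm >= span[1] & tr$x_l_cm <= span[2])
  xy_t <- cbind((tr$x_l_cm[kt] - span[1]) / scale, 0)
  occ <- occ_stack(xy_t, tr$dt_s[kt], grid, shifts0)
  sp <- prep$spikes
  ks <- which(sp$included & sp$x_l_cm >= span[1] & sp$x_l_cm <= span[2])
  u <- (sp$x_l_cm[ks] - span[1]) / scale
  list(occ = occ, u = u, cell = sp$cell_id[ks], grid = grid)
}

.side_map <- function(side, cell_id, shifts) {
  shifts0 <- rbind(c(0, 0), shifts)
  xy <- cbind(side$u[side$cell == cell_id], 0)
  cnt <- count_stack(xy, side$grid, shifts0)
  rate_map_from_stacks(side$occ[, -1, drop = FALSE],
                       cnt[, -1, drop = FALSE], side$grid,
                       occupancy0 = side$occ[, 1], count0 = cnt[, 1])
}

# The four comparisons for one direction: `prot` is the session whose
# protrusion defines the spans, `other` the opposite-side session.
.direction_comparisons <- function(track, prot, other, cell_ids, config,
                                   shifts) {
  L <- seg_len(track)
  sp_p <- protrusion_spans(track, prot$cfg)
  sp_o <- protrusion_spans(track, other$cfg)
  g_long <- span_grid(0, 3 * L, config$bin_cm)
  g_short <- span_grid(0, L, config$bin_cm)
  specs <- list(
    flip = list(a = .span_side(prot, sp_p$protrusion, g_long, 1, shifts),
                b = .span_side(other, sp_o$protrusion, g_long, 1, shifts)),
    distance = list(a = .span_side(prot, sp_p$protrusion, g_long, 1, shifts),
                    b = .span_side(other, sp_p$protrusion, g_long, 1, shifts)),
    segment = list(a = .span_side(prot, sp_p$centre_segment, g_short, 1, shifts),
                   b = .span_side(other, sp_o$straight, g_short, 1, shifts)),
    rescaled = list(a = .span_side(prot, sp_p$protrusion, g_short, 3, shifts),
                    b = .span_side(other, sp_o$straight, g_short, 1, shifts))
  )
  out <- matrix(NA_real_, length(cell_ids), length(specs),
                dimnames = list(cell_ids, names(specs)))
  for (cmp in names(specs)) {
    s <- specs[[cmp]]
    for (ci in seq_along(cell_ids)) {
      ma <- .side_map(s$a, cell_ids[ci], shifts)
      mb <- .side_map(s$b, cell_ids[ci], shifts)
      out[ci, cmp] <- pair_correlation(ma, mb, min_bins = config$min_bins,
                                       rule = config$mask_rule)
    }
  }
  out
}

#' The four protrusion-flip correlation comparisons, per cell
#'
#' For each included cell, Pearson correlations between linearized firing
#' rates across the two sessions under four alignments of the protruding
#' region:
#' \describe{
#'   \item{flip}{rates on the physical protrusion segments in session 1
#'     against the same material segments after the flip, aligned by
#'     position along the trio (tests feature-bound fields).}
#'   \item{distance}{rates on session 1's protrusion span against the
#'     bins at the same arc distance from the corresponding food well in
#'     session 2 (tests distance-coding fields).}
#'   \item{segment}{rates on the protruding centre segment against the
#'     in-line section it projects onto after the flip, aligned
#'     proportionally.}
#'   \item{rescaled}{rates on the whole protrusion span, linearly rescaled
#'     onto the single in-line section that replaces it, against that
#'     section's rates (tests elastic stretching).}
#' }
#' Each comparison is evaluated in both directions (session 1's protrusion
#' and session 2's) and the per-cell values averaged over the defined
#' directions.
#'
#' @param pair A `protrusion_pair`.
#' @param config An [analysis_config()].
#' @param cell_ids Cells to analyse; default [include_active_cells()].
#' @return Data frame `cell_id`, `flip`, `distance`, `segment`,
#'   `rescaled` (NA where undefined).
#' @export
compare_protrusion <- function(pair, config = analysis_config(),
                               cell_ids = NULL) {
  if (is.null(cell_ids))
    cell_ids <- include_active_cells(pair, config$peak_threshold_hz, config)
  prep1 <- .prep_session(pair$session1, config)
  prep2 <- .prep_session(pair$session2, config)
  shifts <- make_shifts(config$n_shifts, config$bin_cm, seed = config$seed)
  d1 <- .direction_comparisons(pair$track, prep1, prep2, cell_ids, config, shifts)
  d2 <- .direction_comparisons(pair$track, prep2, prep1, cell_ids, config, shifts)
  avg <- (ifelse(is.na(d1), 0, d1) + ifelse(is.na(d2), 0, d2)) /
    ((!is.na(d1)) + (!is.na(d2)))
  avg[is.nan(avg)] <- NA
  out <- data.frame(cell_id = cell_ids, avg, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summary statistics for the four-comparison battery
#'
#' Means and SEM per comparison (cells with undefined values excluded),
#' Mann-Whitney u-tests for every pairwise comparison, and a one-way
#' ANOVA across the four groups with Tukey-Kramer post-hoc contrasts.
#'
#' @param values Data frame from [compare_protrusion()].
#' @return A `comparison_result` object.
#' @export
comparison_stats <- function(values) {
  comps <- c("flip", "distance", "segment", "rescaled")
  stopifnot(all(comps %in% names(values)))
  summ <- do.call(rbind, lapply(comps, function(cmp) {
    v <- values[[cmp]]; v <- v[!is.na(v)]
    data.frame(comparison = cmp, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA,
               n = length(v))
  }))
  pw <- expand.grid(a = comps, b = comps, stringsAsFactors = FALSE)
  pw <- pw[match(pw$a, comps) < match(pw$b, comps), ]
  pw$p_utest <- mapply(function(a, b) {
    va <- values[[a]]; vb <- values[[b]]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(va, vb)$p.value)
  }, pw$a, pw$b)
  long <- stats::na.omit(data.frame(
    value = unlist(values[comps], use.names = FALSE),
    comparison = factor(rep(comps, each = nrow(values)), levels = comps)))
  anova_fit <- if (length(unique(long$comparison)) > 1 && nrow(long) > 4) {
    fit <- stats::aov(value ~ comparison, data = long)
    list(p = summary(fit)[[1]][["Pr(>F)"]][1],
         tukey = stats::TukeyHSD(fit)$comparison)
  } else list(p = NA_real_, tukey = NULL)
  structure(list(summary = summ, pairwise = pw, anova_p = anova_fit$p,
                 tukey = anova_fit$tukey,
                 argmax = summ$comparison[which.max(summ$mean)]),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("Protrusion-flip comparison battery\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-9s mean r = %+.3f (SEM %.3f, n = %d)\n",
                x$summary$comparison[i], x$summary$mean[i],
                x$summary$sem[i], x$summary$n[i]))
  cat(sprintf("  highest: %s; one-way ANOVA p = %.3g\n",
              x$argmax, x$anova_p))
  invisible(x)
}

#' Which anchoring hypothesis a comparison battery points to
#'
#' The comparison with the highest mean correlation identifies the
#' generating hypothesis: `rescaled` (or `segment`) for elastic
#' linear-fraction coding, `flip` for segment-bound coding, `distance`
#' for distance-from-well coding.
#'
#' @param result A `comparison_result`.
#' @return One of `"linear_fraction"`, `"segment_bound"`,
#'   `"distance_from_well"`.
#' @export
identified_hypothesis <- function(result) {
  switch(as.character(result$argmax),
         rescaled = "linear_fraction",
         segment = "linear_fraction",
         flip = "segment_bound",
         distance = "distance_from_well")
}
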