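# Track A analysis: pool configurations by vertical section, correlate
# rate maps across section pairs in both reference frames, and summarize
# the decay of correlation with geometric dissimilarity.

#' Group configurations by vertical section
#'
#' Configurations whose arm extent falls in the same 9 cm vertical section
#' are pooled; groups populated by fewer than `floor` configurations are
#' dropped (with a notice), mirroring the N_V >= 3 inclusion rule.
#'
#' @param track Track A model.
#' @param schedule A `config_schedule` (or its table).
#' @param arm `"top"` or `"bottom"`: which arm's section index groups the
#'   configurations.
#' @param floor Minimum group size.
#' @return A `section_groups` object: list of `list(section, config_ids,
#'   n)` for surviving sections.
#' @export
group_by_section <- function(track, schedule, arm = c("top", "bottom"),
                             floor = 3) {
  arm <- match.arg(arm)
  tab <- if (inherits(schedule, "config_schedule")) schedule$table else schedule
  sec <- if (arm == "top") tab$section_top else tab$section_bottom
  if (is.null(sec)) stop("schedule has no section indices (Track A only)",
                         call. = FALSE)
  sp <- split(tab$config_id, factor(sec, levels = seq_len(track$n_sections)))
  groups <- lapply(seq_along(sp), function(s)
    list(section = s, config_ids = sp[[s]], n = length(sp[[s]])))
  dropped <- vapply(groups, function(g) g$n < floor, TRUE)
  if (any(dropped & vapply(groups, function(g) g$n > 0, TRUE)))
    message(sprintf("dropping %d section group(s) with fewer than %d configurations",
                    sum(dropped & vapply(groups, function(g) g$n > 0, TRUE)), floor))
  out <- groups[!dropped]
  if (length(out) == 0) stop("no section group meets the size floor", call. = FALSE)
  structure(out, class = "section_groups", arm = arm)
}

#' Pooled rate map over a configuration group
#'
#' Occupancy seconds and spike counts are pooled across all member epochs
#' before normalization (not an average of per-epoch maps).
#'
#' @param trajectory A speed-filtered `trajectory`.
#' @param spikes One cell's flagged `spike_trains` rows.
#' @param group An element of [group_by_section()] output (or any list
#'   with a `config_ids` field), or a character vector of config ids.
#' @param grid A `bin_grid`.
#' @param xl_range Optional `c(min, max)`: restrict to samples and spikes
#'   with `x_l` in this interval (mobile/static region split).
#' @param ... Passed to [compute_rate_map()] (`n_shifts`, `shifts`, `seed`).
#' @return A `rate_map`.
#' @export
pooled_rate_map <- function(trajectory, spikes, group, grid,
                            xl_range = NULL, ...) {
  ids <- if (is.character(group)) group else group$config_ids
  keep_t <- trajectory$config_id %in% ids
  keep_s <- spikes$config_id %in% ids
  if (!is.null(xl_range)) {
    keep_t <- keep_t & trajectory$x_l_cm >= xl_range[1] &
      trajectory$x_l_cm <= xl_range[2]
    keep_s <- keep_s & spikes$x_l_cm >= xl_range[1] &
      spikes$x_l_cm <= xl_range[2]
  }
  tr <- trajectory[keep_t, , drop = FALSE]
  if (!any(if (!is.null(tr$included)) tr$included else TRUE) || nrow(tr) == 0)
    stop("pooled occupancy is empty for this group", call. = FALSE)
  compute_rate_map(tr, spikes[keep_s, , drop = FALSE], grid, ...)
}

#' Bins entering a pairwise map correlation
#'
#' A bin is included iff it was visited in both maps and carries at least
#' one spike. The default `"either"` rule requires a spike in at least one
#' of the two maps; `"both"` is the stricter reading requiring a spike in
#' each.
#'
#' @param map_i,map_j Two `rate_map`s on the same grid.
#' @param rule `"either"` or `"both"`.
#' @return Logical vector over bins.
#' @export
valid_bin_mask <- function(map_i, map_j, rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(map_i$grid$n_bins == map_j$grid$n_bins)
  spik <- if (rule == "either") (map_i$count + map_j$count) > 0
          else map_i$count > 0 & map_j$count > 0
  map_i$visited & map_j$visited & spik
}

#' Pearson correlation between two rate maps
#'
#' Computed over the [valid_bin_mask()] bins only; undefined (NA) when the
#' mask is smaller than `min_bins` or either masked vector has zero
#' variance.
#'
#' @inheritParams valid_bin_mask
#' @param min_bins Minimum number of valid bins.
#' @return Correlation coefficient, or NA.
#' @export
pair_correlation <- function(map_i, map_j, min_bins = 10,
                             rule = c("either", "both")) {
  mask <- valid_bin_mask(map_i, map_j, rule)
  mask <- mask & !is.na(map_i$rate) & !is.na(map_j$rate)
  if (sum(mask) < min_bins) return(NA_real_)
  a <- map_i$rate[mask]; b <- map_j$rate[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Correlation matrix over section-group rate maps
#'
#' @param maps List of `rate_map`s indexed by section (NULL entries for
#'   missing sections).
#' @param n_sections Matrix dimension.
#' @param min_bins,rule Passed to [pair_correlation()].
#' @return A symmetric `n_sections` x `n_sections` matrix with NA for
#'   undefined entries.
#' @export
section_corr_matrix <- function(maps, n_sections = 12, min_bins = 10,
                                rule = "either") {
  C <- matrix(NA_real_, n_sections, n_sections)
  present <- which(!vapply(maps[seq_len(min(length(maps), n_sections))],
                           is.null, TRUE))
  for (i in present) for (j in present[present >= i]) {
    C[i, j] <- C[j, i] <- pair_correlation(maps[[i]], maps[[j]],
                                           min_bins = min_bins, rule = rule)
  }
  C
}

#' Subdiagonal decay curve of a correlation matrix
#'
#' `r_d` is the mean of the defined entries `C[i, i+d]`; its dispersion is
#' the SEM over the same entries. `r_0` is the diagonal mean (1 for a
#' per-cell matrix with defined diagonals).
#'
#' @param C A square correlation matrix (NA = undefined entry).
#' @return A `decay_curve` data frame: `d`, `r_d`, `sem`, `n`.
#' @export
decay_curve <- function(C) {
  n <- nrow(C)
  out <- lapply(0:(n - 1), function(d) {
    i <- seq_len(n - d)
    v <- C[cbind(i, i + d)]
    v <- v[!is.na(v)]
    data.frame(d = d, r_d = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, out)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Element-wise ensemble average of per-cell correlation matrices
#'
#' @param mats List of equal-sized matrices (NA = undefined entries, which
#'   are excluded from the average).
#' @return Matrix of means; NA where no cell had a defined entry.
#' @export
ensemble_matrix <- function(mats) {
  stopifnot(length(mats) >= 1)
  arr <- simplify2array(mats)
  apply(arr, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Ensemble decay curve across cells
#'
#' Averages the per-cell correlation matrices element-wise, takes
#' subdiagonal means, and attaches the across-cell SEM of the per-cell
#' `r_d` values.
#'
#' @param mats List of per-cell correlation matrices.
#' @return A `decay_curve` with SEM computed across contributing cells,
#'   plus the per-cell `r_d` matrix as attribute `"per_cell"`.
#' @export
ensemble_curve <- function(mats) {
  EC <- decay_curve(ensemble_matrix(mats))
  per_cell <- t(vapply(mats, function(C) decay_curve(C)$r_d,
                       numeric(nrow(mats[[1]]))))
  sem <- apply(per_cell, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  })
  EC$sem <- sem
  EC$n <- apply(per_cell, 2, function(v) sum(!is.na(v)))
  attr(EC, "per_cell") <- per_cell
  EC
}

#' Classify a cell as mobile or static
#'
#' A cell is static iff its linear field peak falls within the arc-length
#' span of the fixed base segments (5--6), using the half-open convention
#' `[4L, 6L)`; otherwise it is mobile on the top arm (`x_l < 4L`) or the
#' bottom arm (`x_l >= 6L`).
#'
#' @param track Track A model.
#' @param peak_xl Peak `x_l` of the cell's session-pooled linear map, cm
#'   (NA for a silent cell).
#' @return List with `class` ("mobile", "static" or "unclassified") and
#'   `arm` ("top", "bottom" or NA).
#' @export
classify_mobile_static <- function(track, peak_xl) {
  if (is.na(peak_xl)) return(list(class = "unclassified", arm = NA_character_))
  sp <- static_span(track)
  if (peak_xl >= sp[1] && peak_xl < sp[2])
    list(class = "static", arm = NA_character_)
  else if (peak_xl < sp[1]) list(class = "mobile", arm = "top")
  else list(class = "mobile", arm = "bottom")
}

#' Welch tests comparing frames at each dissimilarity step
#'
#' Two-sample unequal-variance t-tests between the per-cell subdiagonal
#' values of the two frames at each `d`.
#'
#' @param rd_1d,rd_2d Matrices of per-cell `r_d` values (cells x d), e.g.
#'   the `"per_cell"` attribute of [ensemble_curve()].
#' @return Data frame `d`, `t`, `p`, `n_1d`, `n_2d` (NA where fewer than
#'   two defined values on a side).
#' @export
frame_comparison_test <- function(rd_1d, rd_2d) {
  stopifnot(ncol(rd_1d) == ncol(rd_2d))
  out <- lapply(seq_len(ncol(rd_1d)), function(j) {
    a <- rd_1d[, j]; a <- a[!is.na(a)]
    b <- rd_2d[, j]; b <- b[!is.na(b)]
    ht <- if (length(a) < 2 || length(b) < 2) NULL
          else tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(ht))
      return(data.frame(d = j - 1, t = NA_real_, p = NA_real_,
                        n_1d = length(a), n_2d = length(b)))
    data.frame(d = j - 1, t = unname(ht$statistic), p = ht$p.value,
               n_1d = length(a), n_2d = length(b))
  })
  do.call(rbind, out)
}

# x_l interval of an analysis region
region_span <- function(track, region) {
  L <- seg_len(track)
  switch(region,
         top = c(0, 4 * L),
         static = c(4 * L, 6 * L),
         bottom = c(6 * L, 10 * L),
         stop("unknown region"))
}
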