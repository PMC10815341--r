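#' Cell-sheet morphometry
#'
#' Deformation quantification from tracked cell polygons: displacement
#' cosines against the AP axis (the order parameter), the spatial domain
#' split of that order parameter, integral-ROI equivalent-ellipse axis
#' changes, per-cell and small-ROI apical area indices, major-axis
#' orientation statistics, and the start-vs-end Mann-Whitney comparison.
#'
#' @name cell-morphometry
NULL

ap_unit <- function(ap_direction) ap_direction / sqrt(sum(ap_direction^2))

#' Displacement cosines over initial and terminal windows
#'
#' For each cell, the net displacement summed over the first and over the
#' last `window_frames` inter-frame steps, and the cosine of its angle to
#' the anterior direction: +1 = displacement straight toward the anterior
#' pole, -1 = toward the posterior. Cells with zero displacement in a
#' window have an undefined cosine and are dropped with a count attribute.
#'
#' @param tracks a `cell_tracks` object (or anything [cell_geometry()]
#'   accepts) with at least `window_frames + 1` frames.
#' @param ap_direction anterior unit vector; default `c(0, -1)` (anterior at
#'   low ordinate).
#' @param window_frames inter-frame steps per window (default 2: the two
#'   initial and two terminal frames of the series).
#' @return Tibble: `cell_id`, `ordinate` (centroid y at the window start),
#'   `cosine`, `window` in `{"initial", "terminal"}`; attribute
#'   `n_zero_displacement`.
#' @export
displacement_cosines <- function(tracks, ap_direction = c(0, -1),
                                 window_frames = 2L) {
  geom <- cell_geometry(tracks)
  n_frames <- max(geom$frame)
  if (n_frames < window_frames + 1L) stop("too few frames for the window")
  ap <- ap_unit(ap_direction)
  one_window <- function(f0, f1, label) {
    g0 <- geom[geom$frame == f0, ]
    g1 <- geom[geom$frame == f1, ]
    m <- merge(g0, g1, by = "cell_id", suffixes = c("0", "1"))
    dx <- m$cx1 - m$cx0
    dy <- m$cy1 - m$cy0
    len <- sqrt(dx^2 + dy^2)
    tibble::tibble(cell_id = m$cell_id, ordinate = m$cy0,
                   cosine = ifelse(len > 0, (dx * ap[1L] + dy * ap[2L]) / len,
                                   NA_real_),
                   window = label)
  }
  rec <- rbind(one_window(1L, 1L + window_frames, "initial"),
               one_window(n_frames - window_frames, n_frames, "terminal"))
  n_zero <- sum(is.na(rec$cosine))
  if (n_zero > 0L) {
    message(sprintf("%d zero-displacement cosines excluded", n_zero))
  }
  rec <- rec[!is.na(rec$cosine), ]
  attr(rec, "n_zero_displacement") <- n_zero
  rec
}

#' Order-parameter profile and domain split
#'
#' Sorts displacement records by ordinate and scans all two-segment splits
#' of the axis, scoring each by how much the two-domain fit improves on the
#' one-domain fit in mean absolute cosine deviation (one-domain: every
#' record predicted by the global mean cosine; two-domain: by its segment's
#' mean). When the best improvement falls short of `margin` the verdict is
#' `"uniform"` — the translation-like regime; otherwise `"split"`, the
#' bidirectional regime. Spatially unstructured cosines (e.g. alternating
#' signs at random ordinates) barely improve under any split and stay
#' uniform.
#'
#' @param records tibble from [displacement_cosines()] (>= 10 rows); pass a
#'   single window's records to reproduce the per-window plots.
#' @param margin minimum between-segment mean-cosine difference required to
#'   declare a split.
#' @param min_segment minimum records per segment considered.
#' @return List of class `order_profile`: `profile` (records sorted by
#'   ordinate), `verdict`, `split_ordinate` (NA when uniform),
#'   `mean_cosine_anterior`, `mean_cosine_posterior`, `split_difference`.
#' @export
order_profile <- function(records, margin = 0.2, min_segment = 5L) {
  if (nrow(records) < 10L) stop("need at least 10 displacement records")
  if (all(is.na(records$cosine))) stop("all cosines undefined")
  rec <- records[order(records$ordinate), ]
  y <- rec$ordinate
  cs <- cumsum(rec$cosine)
  n <- nrow(rec)
  tot <- cs[n]
  ks <- seq.int(min_segment, n - min_segment)
  if (length(ks) == 0L) stop("too few records for a split scan")
  mean_lo <- cs[ks] / ks
  mean_hi <- (tot - cs[ks]) / (n - ks)
  mae_one <- mean(abs(rec$cosine - tot / n))
  improvement <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    mae_two <- (sum(abs(rec$cosine[seq_len(k)] - mean_lo[i])) +
                sum(abs(rec$cosine[seq.int(k + 1L, n)] - mean_hi[i]))) / n
    mae_one - mae_two
  }, numeric(1))
  best <- which.max(improvement)
  k <- ks[best]
  is_split <- improvement[best] >= margin
  structure(list(
    profile = rec,
    verdict = if (is_split) "split" else "uniform",
    split_ordinate = if (is_split) (y[k] + y[k + 1L]) / 2 else NA_real_,
    mean_cosine_anterior = if (is_split) mean_lo[best] else mean(rec$cosine),
    mean_cosine_posterior = if (is_split) mean_hi[best] else mean(rec$cosine),
    split_improvement = improvement[best]
  ), class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  if (x$verdict == "split") {
    cat(sprintf(
      "order profile: SPLIT at ordinate %.1f (mean cos %.2f anterior | %.2f posterior)\n",
      x$split_ordinate, x$mean_cosine_anterior, x$mean_cosine_posterior))
  } else {
    cat(sprintf("order profile: uniform (mean cos %.2f)\n",
                x$mean_cosine_anterior))
  }
  invisible(x)
}

#' Integral-ROI series and axis percent changes
#'
#' Per frame, the union of all cell polygons summarized by its
#' equivalent-ellipse axes (and the AP/lateral axis-aligned extents), plus
#' the percent change of each axis between the first and last frame:
#' 100 * (last - first) / first. Assumes non-overlapping cell polygons (see
#' [union_ellipse()]).
#'
#' @param tracks a `cell_tracks` object with every cell present in the
#'   first and last frame.
#' @param ap_direction anterior unit vector.
#' @return List of class `integral_roi_series`: `per_frame` tibble (`frame`,
#'   `area`, `major_axis`, `minor_axis`, `ap_axis`, `lateral_axis`) and
#'   percent changes `major_change_pct`, `minor_change_pct`,
#'   `ap_change_pct`, `lateral_change_pct`, `area_change_pct`.
#' @export
integral_roi_series <- function(tracks, ap_direction = c(0, -1)) {
  frames <- sort(unique(tracks$vertices$frame))
  per <- lapply(frames, function(f) {
    e <- union_ellipse(frame_polygons(tracks, f), ap_direction)
    tibble::tibble(frame = f, area = e$area,
                   major_axis = e$major_axis, minor_axis = e$minor_axis,
                   ap_axis = e$ap_axis, lateral_axis = e$lateral_axis)
  })
  per <- do.call(rbind, per)
  pc <- function(col) 100 * (per[[col]][nrow(per)] - per[[col]][1L]) / per[[col]][1L]
  structure(list(per_frame = per,
                 major_change_pct = pc("major_axis"),
                 minor_change_pct = pc("minor_axis"),
                 ap_change_pct = pc("ap_axis"),
                 lateral_change_pct = pc("lateral_axis"),
                 area_change_pct = pc("area")),
            class = "integral_roi_series")
}

#' @export
print.integral_roi_series <- function(x, ...) {
  cat(sprintf(
    "integral ROI: major %+.2f%%, minor %+.2f%% (AP %+.2f%%, lateral %+.2f%%) first->last\n",
    x$major_change_pct, x$minor_change_pct, x$ap_change_pct, x$lateral_change_pct))
  invisible(x)
}

#' Partition a sheet into small contiguous ROIs of 10-11 cells
#'
#' Greedy region growing on the cell adjacency graph (cells sharing a
#' polygon edge in the first frame), seeded at the unassigned cell with the
#' most extreme ordinate. Every cell lands in exactly one ROI; when the cell
#' count cannot be written as 10a + 11b the last ROI absorbs the remainder
#' with a warning.
#'
#' @param tracks a `cell_tracks` object.
#' @param sizes admissible ROI sizes.
#' @return Integer vector of ROI labels, named by cell id.
#' @export
small_roi_partition <- function(tracks, sizes = c(10L, 11L)) {
  polys <- frame_polygons(tracks, 1L)
  ids <- as.integer(names(polys))
  n <- length(ids)
  adj <- polygon_adjacency(polys)
  geom <- cell_geometry(tracks)
  ord <- geom$cy[geom$frame == 1L][match(ids, geom$cell_id[geom$frame == 1L])]
  cxs <- geom$cx[geom$frame == 1L][match(ids, geom$cell_id[geom$frame == 1L])]
  plan <- roi_size_plan(n, sizes)
  labels <- rep(NA_integer_, n)
  for (r in seq_along(plan)) {
    target <- plan[r]
    free <- which(is.na(labels))
    seed <- free[which.min(ord[free])]
    members <- seed
    labels[seed] <- r
    while (length(members) < target) {
      free <- which(is.na(labels))
      nb <- free[vapply(free, function(f) any(adj[f, members]), logical(1))]
      if (length(nb) == 0L) nb <- free  # disconnected remainder: jump to nearest
      cm <- c(mean(cxs[members]), mean(ord[members]))
      dist2 <- (cxs[nb] - cm[1L])^2 + (ord[nb] - cm[2L])^2
      pick <- nb[which.min(dist2)]
      labels[pick] <- r
      members <- c(members, pick)
    }
  }
  stats::setNames(labels, ids)
}

roi_size_plan <- function(n, sizes = c(10L, 11L)) {
  lo <- min(sizes); hi <- max(sizes)
  for (b in 0:(n %/% hi)) {
    rem <- n - hi * b
    if (rem %% lo == 0L) return(c(rep(lo, rem %/% lo), rep(hi, b)))
  }
  warning(sprintf("cannot partition %d cells into ROIs of %s; last ROI absorbs the remainder",
                  n, paste(sizes, collapse = "-")))
  k <- n %/% lo
  c(rep(lo, max(k - 1L, 1L)), n - lo * max(k - 1L, 0L))
}

# Adjacency by shared polygon edges: two cells are neighbours when they
# share at least two vertices (coordinates rounded to 1e-6 px).
polygon_adjacency <- function(polys) {
  n <- length(polys)
  keysets <- lapply(polys, function(p) {
    unique(paste(round(p[, 1L], 6), round(p[, 2L], 6), sep = "_"))
  })
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (sum(keysets[[i]] %in% keysets[[j]]) >= 2L) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  adj
}

#' Apical area indices of cells and small ROIs
#'
#' Per-cell area index = area at the last frame / area at the first frame;
#' the small-ROI variant aggregates 10-11 contiguous cells
#' ([small_roi_partition()]) and takes the ratio of summed (union) areas.
#'
#' @param tracks a `cell_tracks` object.
#' @return List of class `area_index`: `cells` tibble (`cell_id`,
#'   `area_first`, `area_last`, `index`) and `rois` tibble (`roi`,
#'   `n_cells`, `index`).
#' @export
area_index <- function(tracks) {
  geom <- cell_geometry(tracks)
  f0 <- min(geom$frame); f1 <- max(geom$frame)
  g0 <- geom[geom$frame == f0, ]
  g1 <- geom[geom$frame == f1, ]
  m <- merge(g0[, c("cell_id", "area")], g1[, c("cell_id", "area")],
             by = "cell_id", suffixes = c("_first", "_last"))
  if (any(m$area_first <= 0 | m$area_last <= 0)) {
    bad <- m$cell_id[m$area_first <= 0 | m$area_last <= 0]
    stop(sprintf("non-positive cell area for cell(s) %s",
                 paste(bad, collapse = ", ")))
  }
  cells <- tibble::tibble(cell_id = m$cell_id,
                          area_first = m$area_first, area_last = m$area_last,
                          index = m$area_last / m$area_first)
  part <- small_roi_partition(tracks)
  rois <- lapply(sort(unique(part)), function(r) {
    members <- as.integer(names(part)[part == r])
    sel <- cells$cell_id %in% members
    tibble::tibble(roi = r, n_cells = sum(sel),
                   index = sum(cells$area_last[sel]) / sum(cells$area_first[sel]))
  })
  structure(list(cells = cells, rois = do.call(rbind, rois)),
            class = "area_index")
}

#' Median equivalent-circle cell diameter
#'
#' @param tracks a `cell_tracks` object.
#' @param frame 1-based frame.
#' @return Median of 2*sqrt(area/pi) over cells, pixels.
#' @export
median_cell_diameter <- function(tracks, frame = 1L) {
  geom <- cell_geometry(tracks)
  stats::median(2 * sqrt(geom$area[geom$frame == frame] / pi))
}

#' Major-axis orientation distribution
#'
#' Equivalent-ellipse orientations relative to the AP axis, folded to
#' \[0, 90\] degrees, for one frame. Near-circular cells (eccentricity below
#' `min_eccentricity`) have no meaningful direction and are excluded with a
#' message.
#'
#' @param tracks a `cell_tracks` object with >= 10 cells.
#' @param frame 1-based frame index.
#' @param ap_direction anterior unit vector.
#' @param bin_width histogram bin width, degrees.
#' @param min_eccentricity exclusion threshold for near-circular cells.
#' @return List of class `orientation_distribution`: `orientations` tibble,
#'   `histogram` tibble (`bin_lo`, `bin_hi`, `count`), `fraction_within_30`,
#'   `n_excluded`.
#' @export
orientation_distribution <- function(tracks, frame = 1L,
                                     ap_direction = c(0, -1),
                                     bin_width = 10, min_eccentricity = 0.1) {
  polys <- frame_polygons(tracks, frame)
  if (length(polys) < 10L) stop("need at least 10 cells")
  fits <- lapply(polys, fit_ellipse, ap_direction = ap_direction)
  ecc <- vapply(fits, `[[`, numeric(1), "eccentricity")
  ang <- vapply(fits, `[[`, numeric(1), "orientation")
  keep <- ecc >= min_eccentricity
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(sprintf("%d near-circular cells excluded from orientation", n_excluded))
  }
  if (!any(keep)) {
    return(structure(list(
      orientations = tibble::tibble(cell_id = integer(), orientation = numeric(),
                                    eccentricity = numeric()),
      histogram = tibble::tibble(bin_lo = numeric(), bin_hi = numeric(),
                                 count = integer()),
      fraction_within_30 = NA_real_, n_excluded = n_excluded
    ), class = "orientation_distribution"))
  }
  a <- ang[keep]
  breaks <- seq(0, 90, by = bin_width)
  nb <- length(breaks) - 1L
  counts <- tabulate(pmin(floor(a / bin_width) + 1L, nb), nbins = nb)
  structure(list(
    orientations = tibble::tibble(cell_id = as.integer(names(polys))[keep],
                                  orientation = a, eccentricity = ecc[keep]),
    histogram = tibble::tibble(bin_lo = breaks[-length(breaks)],
                               bin_hi = breaks[-1L], count = counts),
    fraction_within_30 = mean(a <= 30),
    n_excluded = n_excluded
  ), class = "orientation_distribution")
}

#' Start-vs-end sample comparison
#'
#' Two-sided Mann-Whitney U test ([mann_whitney_u()]) with per-sample means
#' and t-based 95% confidence intervals — the summary used to compare cell
#' eccentricities or area indices between the first and last frame.
#'
#' @param values_start,values_end numeric samples, each with n >= 5.
#' @param conf_level confidence level for the mean CIs.
#' @return List of class `start_end_comparison`: `u`, `p_value`, `method`,
#'   `mean_start`, `ci_start`, `mean_end`, `ci_end`, `n_start`, `n_end`.
#' @export
compare_start_end <- function(values_start, values_end, conf_level = 0.95) {
  if (length(values_start) < 5L || length(values_end) < 5L) {
    stop("each sample needs at least 5 values")
  }
  mw <- mann_whitney_u(values_start, values_end)
  ci <- function(v) {
    m <- mean(v)
    half <- stats::qt(1 - (1 - conf_level) / 2, length(v) - 1L) *
      stats::sd(v) / sqrt(length(v))
    c(m - half, m + half)
  }
  structure(list(u = mw$u, p_value = mw$p_value, method = mw$method,
                 mean_start = mean(values_start), ci_start = ci(values_start),
                 mean_end = mean(values_end), ci_end = ci(values_end),
                 n_start = length(values_start), n_end = length(values_end)),
            class = "start_end_comparison")
}

#' @export
print.start_end_comparison <- function(x, ...) {
  cat(sprintf(
    "start %0.3f [%0.3f, %0.3f] (n=%d) vs end %0.3f [%0.3f, %0.3f] (n=%d): U = %g, p = %.4g (%s)\n",
    x$mean_start, x$ci_start[1L], x$ci_start[2L], x$n_start,
    x$mean_end, x$ci_end[1L], x$ci_end[2L], x$n_end,
    x$u, x$p_value, x$method))
  invisible(x)
}

#' Cell eccentricities at one frame
#'
#' @param tracks a `cell_tracks` object.
#' @param frame 1-based frame index.
#' @return Named numeric vector of eccentricities.
#' @export
cell_eccentricities <- function(tracks, frame = 1L) {
  polys <- frame_polygons(tracks, frame)
  vapply(polys, function(p) fit_ellipse(p)$eccentricity, numeric(1))
}

#' Whole-sheet deformation summary
#'
#' Integral-ROI axis percent changes, mean start/end eccentricities with a
#' Mann-Whitney comparison, and mean cell and small-ROI area indices with
#' 95% CIs — the per-region deformation scorecard.
#'
#' @param tracks a `cell_tracks` object.
#' @param ap_direction anterior unit vector.
#' @return List of class `deformation_summary`.
#' @export
deformation_summary <- function(tracks, ap_direction = c(0, -1)) {
  roi <- integral_roi_series(tracks, ap_direction)
  ecc0 <- cell_eccentricities(tracks, 1L)
  ecc1 <- cell_eccentricities(tracks, tracks$n_frames)
  cmp <- compare_start_end(ecc0, ecc1)
  ai <- area_index(tracks)
  ci_mean <- function(v) {
    half <- stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
    c(mean(v) - half, mean(v) + half)
  }
  structure(list(
    major_change_pct = roi$major_change_pct,
    minor_change_pct = roi$minor_change_pct,
    ap_change_pct = roi$ap_change_pct,
    lateral_change_pct = roi$lateral_change_pct,
    mean_eccentricity_start = cmp$mean_start,
    ci_eccentricity_start = cmp$ci_start,
    mean_eccentricity_end = cmp$mean_end,
    ci_eccentricity_end = cmp$ci_end,
    mannwhitney_p = cmp$p_value,
    mean_cell_area_index = mean(ai$cells$index),
    ci_cell_area_index = ci_mean(ai$cells$index),
    mean_roi_area_index = mean(ai$rois$index),
    ci_roi_area_index = ci_mean(ai$rois$index),
    roi_series = roi, area_index = ai
  ), class = "deformation_summary")
}

#' @export
print.deformation_summary <- function(x, ...) {
  cat(sprintf("integral ROI: major %+.2f%%, minor %+.2f%%\n",
              x$major_change_pct, x$minor_change_pct))
  cat(sprintf("eccentricity: %.3f -> %.3f (Mann-Whitney p = %.4g)\n",
              x$mean_eccentricity_start, x$mean_eccentricity_end,
              x$mannwhitney_p))
  cat(sprintf("area index: cells %.3f, small ROIs %.3f\n",
              x$mean_cell_area_index, x$mean_roi_area_index))
  invisible(x)
}
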