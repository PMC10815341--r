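#' Synthetic deforming cell sheets
#'
#' Seeded generation of tracked epithelial cell polygons: frame 0 is a
#' Lloyd-relaxed bounded Voronoi tessellation of the ROI rectangle, and each
#' later frame applies the per-frame deformation map composed t times. Cells
#' persist through all frames with no rearrangement — the regime in which
#' tissue deformation reflects passive cell deformation, matching the short
#' (20 min, 1-min interval) windows the morphometry is designed for.
#'
#' @name synthetic-sheet
NULL

#' Specify a cell sheet
#'
#' @param n_cells number of cells (>= 4).
#' @param roi_width,roi_height ROI rectangle dimensions, pixels.
#' @param lloyd_iterations centroidal (Lloyd) relaxation sweeps applied to
#'   the seed points; 2 gives realistically regular epithelial cells.
#' @return List of class `sheet_spec`.
#' @export
sheet_spec <- function(n_cells = 100L, roi_width = 300, roi_height = 400,
                       lloyd_iterations = 2L) {
  stopifnot(n_cells >= 4L, roi_width > 0, roi_height > 0, lloyd_iterations >= 0L)
  structure(list(n_cells = as.integer(n_cells), roi_width = roi_width,
                 roi_height = roi_height,
                 lloyd_iterations = as.integer(lloyd_iterations)),
            class = "sheet_spec")
}

#' Specify a tissue deformation
#'
#' The per-20-min (whole-series) axis scale factors are `lambda_major`
#' (along the AP axis, the image ordinate) and `lambda_minor` (lateral);
#' each frame applies the (n_frames - 1)-th root of the total map so that
#' composing the per-frame map across the series reproduces the stated
#' totals exactly.
#'
#' Modes: `"identity"` (no motion); `"translation"` (rigid shift by
#' `translation_vector` per frame, plus optional axis scaling about the ROI
#' center); `"bidirectional_stretch"` (axis scaling about the fixation line
#' `y = fixation_ordinate`, so material on opposite sides of the line moves
#' apart — the trunk-like kinematics); `"apical_constriction"` (each cell
#' scales about its own initial centroid; centroids stay put while apical
#' areas change by `lambda_major * lambda_minor`).
#'
#' @param mode one of `"identity"`, `"translation"`,
#'   `"bidirectional_stretch"`, `"apical_constriction"`.
#' @param lambda_major,lambda_minor total AP/lateral scale factors (> 0).
#' @param fixation_ordinate split line for the bidirectional mode, pixels.
#' @param translation_vector per-frame shift `c(dx, dy)`, pixels.
#' @param n_frames number of frames (>= 2; default 21 = 20 min at 1-min
#'   intervals).
#' @param frame_interval minutes between frames.
#' @return List of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("identity", "translation",
                                      "bidirectional_stretch",
                                      "apical_constriction"),
                             lambda_major = 1, lambda_minor = 1,
                             fixation_ordinate = NULL,
                             translation_vector = c(0, 0),
                             n_frames = 21L, frame_interval = 1) {
  mode <- match.arg(mode)
  stopifnot(lambda_major > 0, lambda_minor > 0, n_frames >= 2L,
            length(translation_vector) == 2L)
  if (mode == "bidirectional_stretch" && is.null(fixation_ordinate)) {
    stop("bidirectional_stretch needs a fixation_ordinate")
  }
  structure(list(mode = mode, lambda_major = lambda_major,
                 lambda_minor = lambda_minor,
                 fixation_ordinate = fixation_ordinate,
                 translation_vector = translation_vector,
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval),
            class = "deformation_spec")
}

#' Deformation presets mirroring head- and trunk-region kinematics
#'
#' `"head"`: anteriorward translation with mild lateral shrink and an
#' essentially unchanged AP extent. `"trunk"`: bidirectional AP elongation
#' about the sheet midline with lateral shrink. `"constriction"`: uniform
#' per-cell apical shrink of about 16.5% in area.
#'
#' @param region `"head"`, `"trunk"` or `"constriction"`.
#' @param roi_height sheet height, used to place the trunk fixation line at
#'   mid-sheet.
#' @return A [deformation_spec()].
#' @export
deformation_preset <- function(region = c("head", "trunk", "constriction"),
                               roi_height = 400) {
  switch(match.arg(region),
    head = deformation_spec("translation", lambda_major = 0.9983,
                            lambda_minor = 0.8796,
                            translation_vector = c(0, -2)),
    trunk = deformation_spec("bidirectional_stretch", lambda_major = 1.1343,
                             lambda_minor = 0.8638,
                             fixation_ordinate = roi_height / 2),
    constriction = deformation_spec("apical_constriction",
                                    lambda_major = sqrt(0.835),
                                    lambda_minor = sqrt(0.835))
  )
}

# Map frame-0 points to frame index t (0-based): closed form of the
# per-frame map composed t times.
deform_points <- function(xy, deformation, t, center, cell_center = NULL) {
  n_steps <- deformation$n_frames - 1L
  sx <- deformation$lambda_minor^(t / n_steps)
  sy <- deformation$lambda_major^(t / n_steps)
  switch(deformation$mode,
    identity = xy,
    translation = {
      out <- xy
      out[, 1L] <- center[1L] + sx * (xy[, 1L] - center[1L])
      out[, 2L] <- center[2L] + sy * (xy[, 2L] - center[2L])
      out + matrix(t * deformation$translation_vector, nrow(xy), 2L, byrow = TRUE)
    },
    bidirectional_stretch = {
      out <- xy
      out[, 1L] <- center[1L] + sx * (xy[, 1L] - center[1L])
      out[, 2L] <- deformation$fixation_ordinate +
        sy * (xy[, 2L] - deformation$fixation_ordinate)
      out
    },
    apical_constriction = {
      out <- xy
      out[, 1L] <- cell_center[1L] + sx * (xy[, 1L] - cell_center[1L])
      out[, 2L] <- cell_center[2L] + sy * (xy[, 2L] - cell_center[2L])
      out
    })
}

#' Generate a tracked, deforming cell sheet
#'
#' @param sheet a [sheet_spec()].
#' @param deformation a [deformation_spec()].
#' @param seed integer seed (tessellation layout).
#' @return Object of class `cell_tracks`: list with `vertices` (tibble:
#'   `cell_id`, `frame` 1-based, `vertex_index`, `x`, `y`), `n_frames`,
#'   `frame_interval`, and the generating specs.
#' @export
generate_cell_sheet <- function(sheet, deformation = deformation_spec("identity"),
                                seed = 1L) {
  stopifnot(inherits(sheet, "sheet_spec"), inherits(deformation, "deformation_spec"))
  polys0 <- withr::with_seed(seed, {
    pts <- cbind(stats::runif(sheet$n_cells, 0, sheet$roi_width),
                 stats::runif(sheet$n_cells, 0, sheet$roi_height))
    for (it in seq_len(sheet$lloyd_iterations)) {
      cells <- voronoi_polygons(pts, sheet$roi_width, sheet$roi_height)
      pts <- t(vapply(cells, poly_centroid, numeric(2)))
    }
    voronoi_polygons(pts, sheet$roi_width, sheet$roi_height)
  })
  if (any(vapply(polys0, nrow, integer(1)) < 3L)) {
    stop("tessellation failed: degenerate cell produced")
  }
  center <- c(sheet$roi_width / 2, sheet$roi_height / 2)
  centers0 <- lapply(polys0, poly_centroid)
  rows <- vector("list", sheet$n_cells * deformation$n_frames)
  k <- 0L
  for (t in seq_len(deformation$n_frames) - 1L) {
    for (i in seq_len(sheet$n_cells)) {
      p <- deform_points(polys0[[i]], deformation, t, center, centers0[[i]])
      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        cell_id = i, frame = t + 1L, vertex_index = seq_len(nrow(p)),
        x = p[, 1L], y = p[, 2L])
    }
  }
  structure(list(
    vertices = do.call(rbind, rows),
    n_frames = deformation$n_frames,
    frame_interval = deformation$frame_interval,
    sheet = sheet, deformation = deformation, seed = seed
  ), class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("cell_tracks: %d cells x %d frames (%g min interval), mode '%s'\n",
              length(unique(x$vertices$cell_id)), x$n_frames,
              x$frame_interval, x$deformation$mode))
  invisible(x)
}

#' Extract one cell's polygon at one frame
#'
#' @param tracks a `cell_tracks` object.
#' @param cell_id,frame identifiers (frame is 1-based).
#' @return Two-column vertex matrix.
#' @export
cell_polygon <- function(tracks, cell_id, frame) {
  v <- tracks$vertices
  sel <- v$cell_id == cell_id & v$frame == frame
  if (!any(sel)) stop("no such cell/frame")
  cbind(v$x[sel], v$y[sel])[order(v$vertex_index[sel]), , drop = FALSE]
}

#' Per-cell centroids and areas for every frame
#'
#' @param tracks a `cell_tracks` object.
#' @return Tibble: `cell_id`, `frame`, `cx`, `cy`, `area` (pixel^2).
#' @export
cell_geometry <- function(tracks) {
  v <- tracks$vertices
  keys <- unique(v[, c("cell_id", "frame")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    p <- cell_polygon(tracks, keys$cell_id[i], keys$frame[i])
    m <- poly_moments(p)
    tibble::tibble(cell_id = keys$cell_id[i], frame = keys$frame[i],
                   cx = m$cx, cy = m$cy, area = m$area)
  })
  do.call(rbind, res)
}

#' All cell polygons of one frame
#'
#' @param tracks a `cell_tracks` object.
#' @param frame 1-based frame index.
#' @return Named list of vertex matrices, one per cell.
#' @export
frame_polygons <- function(tracks, frame) {
  ids <- sort(unique(tracks$vertices$cell_id))
  stats::setNames(lapply(ids, function(i) cell_polygon(tracks, i, frame)),
                  as.character(ids))
}
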