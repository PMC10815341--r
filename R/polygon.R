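#' Polygon geometry primitives
#'
#' Analytic area, centroid and second central moments of simple polygons
#' (Green's theorem contour integrals), the equivalent-ellipse fit built on
#' them, and a bounded Voronoi tessellation used by the synthetic cell-sheet
#' generator. Coordinates are pixels, origin top-left; the anteroposterior
#' (AP) axis runs along the image ordinate with the anterior pole at low y.
#'
#' @name polygon-geometry
NULL

#' Signed area of a simple polygon
#'
#' @param xy two-column matrix of vertices in order (open ring; the closing
#'   edge back to the first vertex is implied).
#' @return Signed area in pixel^2; positive for counter-clockwise vertex
#'   order in a y-down coordinate system the sign is flipped, so callers that
#'   need a magnitude should take `abs()`.
#' @export
poly_area <- function(xy) {
  xy <- as_vertex_matrix(xy)
  i <- seq_len(nrow(xy))
  j <- c(i[-1L], 1L)
  sum(xy[i, 1L] * xy[j, 2L] - xy[j, 1L] * xy[i, 2L]) / 2
}

#' Centroid of a simple polygon
#'
#' @inheritParams poly_area
#' @return Numeric length-2 vector `c(x, y)`.
#' @export
poly_centroid <- function(xy) {
  m <- poly_moments(xy)
  c(m$cx, m$cy)
}

#' Raw and central moments of a simple polygon
#'
#' Contour-integral (Green's theorem) moments up to order two. The central
#' second moments are returned normalized by area, i.e. as the covariance
#' matrix of the uniform density over the polygon interior.
#'
#' @inheritParams poly_area
#' @return List with `area` (unsigned), `signed_area`, `cx`, `cy`, and `cov`
#'   (2x2 covariance matrix, pixel^2).
#' @export
poly_moments <- function(xy) {
  xy <- as_vertex_matrix(xy)
  if (nrow(xy) < 3L) stop("polygon needs at least 3 vertices")
  x0 <- xy[, 1L]
  y0 <- xy[, 2L]
  x1 <- c(x0[-1L], x0[1L])
  y1 <- c(y0[-1L], y0[1L])
  cross <- x0 * y1 - x1 * y0
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * 100 * max(1, max(abs(xy)))^2) {
    stop("degenerate (zero-area) polygon")
  }
  cx <- sum((x0 + x1) * cross) / (6 * a)
  cy <- sum((y0 + y1) * cross) / (6 * a)
  # second moments about the origin, then shifted to the centroid
  ixx <- sum((y0^2 + y0 * y1 + y1^2) * cross) / 12       # integral of y^2 dA
  iyy <- sum((x0^2 + x0 * x1 + x1^2) * cross) / 12       # integral of x^2 dA
  ixy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cross) / 24
  var_x <- iyy / a - cx^2
  var_y <- ixx / a - cy^2
  cov_xy <- ixy / a - cx * cy
  list(
    area = abs(a), signed_area = a, cx = cx, cy = cy,
    cov = matrix(c(var_x, cov_xy, cov_xy, var_y), 2L, 2L,
                 dimnames = list(c("x", "y"), c("x", "y")))
  )
}

#' Equivalent-ellipse fit of a polygon
#'
#' The ellipse with the same area-normalized second central moments as the
#' polygon. For an elliptical polygon the recovered axes equal the true axis
#' lengths, so eccentricity closed forms (axis ratio 0.8 -> eccentricity 0.6)
#' hold exactly; a w x h rectangle has variances w^2/12 and h^2/12, giving an
#' axis ratio h/w.
#'
#' @inheritParams poly_area
#' @param ap_direction unit vector of the anterior direction used to express
#'   the orientation; default `c(0, -1)` (anterior at low ordinate).
#' @return List of class `ellipse_fit`: `major_axis`, `minor_axis` (full
#'   lengths, pixels), `orientation` (degrees from the AP axis, folded to
#'   \[0, 90\]), `eccentricity` in \[0, 1), `centroid`, `area`.
#' @export
fit_ellipse <- function(xy, ap_direction = c(0, -1)) {
  m <- poly_moments(xy)
  e <- eigen(m$cov, symmetric = TRUE)
  l <- pmax(e$values, 0)
  if (l[1L] <= 0) stop("degenerate (collinear) polygon")
  major <- 4 * sqrt(l[1L])
  minor <- 4 * sqrt(l[2L])
  v <- e$vectors[, 1L]
  ap <- ap_direction / sqrt(sum(ap_direction^2))
  ang <- acos(min(1, abs(sum(v * ap)) / sqrt(sum(v^2)))) * 180 / pi
  structure(list(
    major_axis = major, minor_axis = minor,
    orientation = ang,
    eccentricity = sqrt(1 - (minor / major)^2),
    centroid = c(m$cx, m$cy), area = m$area
  ), class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "equivalent ellipse: major %.2f px, minor %.2f px, ecc %.3f, %.1f deg from AP\n",
    x$major_axis, x$minor_axis, x$eccentricity, x$orientation))
  invisible(x)
}

#' Equivalent ellipse of a union of non-overlapping polygons
#'
#' Raw moments are additive over regions with disjoint interiors, so the
#' union's covariance is assembled from per-polygon moments without any
#' polygon clipping. The polygons must not overlap (true for segmentation
#' output and for tessellations and their affine images); overlaps would be
#' double counted.
#'
#' @param polys list of vertex matrices.
#' @inheritParams fit_ellipse
#' @return As [fit_ellipse()], plus `ap_axis` and `lateral_axis`: the
#'   axis-aligned extents `4*sqrt(var)` along and across the AP direction,
#'   stable when the union is nearly isotropic.
#' @export
union_ellipse <- function(polys, ap_direction = c(0, -1)) {
  if (length(polys) == 0L) stop("empty union")
  area <- 0; sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (p in polys) {
    m <- poly_moments(p)
    a <- m$area
    area <- area + a
    sx <- sx + a * m$cx
    sy <- sy + a * m$cy
    sxx <- sxx + a * (m$cov[1L, 1L] + m$cx^2)
    syy <- syy + a * (m$cov[2L, 2L] + m$cy^2)
    sxy <- sxy + a * (m$cov[1L, 2L] + m$cx * m$cy)
  }
  cx <- sx / area; cy <- sy / area
  cv <- matrix(c(sxx / area - cx^2, sxy / area - cx * cy,
                 sxy / area - cx * cy, syy / area - cy^2), 2L, 2L)
  e <- eigen(cv, symmetric = TRUE)
  l <- pmax(e$values, 0)
  v <- e$vectors[, 1L]
  ap <- ap_direction / sqrt(sum(ap_direction^2))
  lat <- c(-ap[2L], ap[1L])
  structure(list(
    major_axis = 4 * sqrt(l[1L]), minor_axis = 4 * sqrt(l[2L]),
    orientation = acos(min(1, abs(sum(v * ap)))) * 180 / pi,
    eccentricity = sqrt(1 - l[2L] / l[1L]),
    centroid = c(cx, cy), area = area,
    ap_axis = 4 * sqrt(drop(t(ap) %*% cv %*% ap)),
    lateral_axis = 4 * sqrt(drop(t(lat) %*% cv %*% lat))
  ), class = "ellipse_fit")
}

# --- bounded Voronoi tessellation ------------------------------------------

# Clip a convex polygon by the half-plane {p : (p - m) . d <= 0}
# (Sutherland-Hodgman step against a single line).
clip_halfplane <- function(xy, m, d) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  s <- (xy[, 1L] - m[1L]) * d[1L] + (xy[, 2L] - m[2L]) * d[2L]
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi_in <- s[i] <= 0
    pj_in <- s[j] <= 0
    if (pi_in) out <- rbind(out, xy[i, ])
    if (xor(pi_in, pj_in)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, xy[i, ] + t * (xy[j, ] - xy[i, ]))
    }
  }
  out
}

#' Voronoi tessellation of a rectangle
#'
#' Voronoi cells of `points` clipped to the rectangle `[0, width] x
#' [0, height]`, computed by intersecting half-planes (each cell is the
#' intersection of the rectangle with the half-planes nearer its seed than
#' any other seed). O(n^2) in the number of seeds, which is ample for the
#' sheet sizes used here (tens to hundreds of cells).
#'
#' @param points two-column matrix of seed coordinates inside the rectangle.
#' @param width,height rectangle dimensions, pixels.
#' @return List of vertex matrices, one convex polygon per seed, jointly
#'   tiling the rectangle.
#' @export
voronoi_polygons <- function(points, width, height) {
  points <- as_vertex_matrix(points)
  n <- nrow(points)
  rect <- matrix(c(0, 0, width, 0, width, height, 0, height), 4L, 2L, byrow = TRUE)
  lapply(seq_len(n), function(i) {
    cell <- rect
    for (j in seq_len(n)[-i]) {
      d <- points[j, ] - points[i, ]
      m <- (points[i, ] + points[j, ]) / 2
      cell <- clip_halfplane(cell, m, d)
      if (nrow(cell) < 3L) break
    }
    cell
  })
}

as_vertex_matrix <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("vertices must be a two-column (x, y) matrix")
  storage.mode(xy) <- "double"
  xy
}
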