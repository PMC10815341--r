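# Small fixtures shared across tests. Everything is built in code.

# Regular n-gon (optionally anisotropic -> an ellipse-shaped polygon).
ellipse_polygon <- function(n = 64L, rx = 1, ry = 1, cx = 0, cy = 0,
                            rotate = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- rx * cos(th)
  y <- ry * sin(th)
  xr <- x * cos(rotate) - y * sin(rotate)
  yr <- x * sin(rotate) + y * cos(rotate)
  cbind(cx + xr, cy + yr)
}

rect_polygon <- function(w, h, cx = 0, cy = 0) {
  cbind(cx + c(-w, w, w, -w) / 2, cy + c(-h, -h, h, h) / 2)
}

# Build a cell_tracks object directly from per-frame polygon lists:
# polys_by_frame[[t]][[i]] is cell i's vertex matrix at frame t.
tracks_from_polygons <- function(polys_by_frame, frame_interval = 1) {
  rows <- list()
  for (t in seq_along(polys_by_frame)) {
    for (i in seq_along(polys_by_frame[[t]])) {
      p <- polys_by_frame[[t]][[i]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell_id = i, frame = t, vertex_index = seq_len(nrow(p)),
        x = p[, 1], y = p[, 2])
    }
  }
  structure(list(vertices = do.call(rbind, rows),
                 n_frames = length(polys_by_frame),
                 frame_interval = frame_interval,
                 sheet = NULL, deformation = NULL, seed = NA_integer_),
            class = "cell_tracks")
}

# Apply an affine map (2x2 matrix + offset) to every polygon of a tracks
# object, all frames alike.
transform_tracks <- function(tracks, A = diag(2), b = c(0, 0)) {
  v <- tracks$vertices
  xy <- cbind(v$x, v$y) %*% t(A)
  tracks$vertices$x <- xy[, 1] + b[1]
  tracks$vertices$y <- xy[, 2] + b[2]
  tracks
}

# Uniform-intensity image set.
uniform_images <- function(donor, acceptor, nr = 16L, nc = 16L) {
  fret_image_set(matrix(donor, nr, nc), matrix(acceptor, nr, nc))
}
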