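#' File formats
#'
#' Plain interchange formats for every stage: per-channel 16-bit TIFF for
#' images, long-format CSV for cell polygons (`cell_id, frame,
#' vertex_index, x, y`), CSV for counts/Ct/DE tables, and a JSON
#' ground-truth sidecar per synthetic dataset.
#'
#' @name tensiomap-io
NULL

TIFF_SCALE <- 65535

#' Write a donor/acceptor pair as 16-bit TIFFs
#'
#' Intensities are stored as 16-bit samples; values are clamped to
#' \[0, 65535\] intensity units.
#'
#' @param images a [fret_image_set()].
#' @param donor_path,acceptor_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_fret_tiff <- function(images, donor_path, acceptor_path) {
  enc <- function(m) round(pmin(pmax(m, 0), TIFF_SCALE)) / TIFF_SCALE
  tiff::writeTIFF(enc(images$donor), donor_path, bits.per.sample = 16L)
  tiff::writeTIFF(enc(images$acceptor), acceptor_path, bits.per.sample = 16L)
  invisible(c(donor_path, acceptor_path))
}

#' Read a donor/acceptor pair from TIFFs
#'
#' @param donor_path,acceptor_path file paths (first page of multipage
#'   files is used).
#' @return A [fret_image_set()] in intensity units.
#' @export
read_fret_tiff <- function(donor_path, acceptor_path) {
  rd <- function(p) {
    img <- tiff::readTIFF(p, all = FALSE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img * TIFF_SCALE
  }
  fret_image_set(rd(donor_path), rd(acceptor_path))
}

#' Write/read cell tracks as long-format CSV
#'
#' @param tracks a `cell_tracks` object.
#' @param path CSV path.
#' @return Invisibly, the path.
#' @export
write_cell_tracks <- function(tracks, path) {
  utils::write.csv(tracks$vertices, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_tracks
#' @param frame_interval minutes between frames (the CSV does not carry it).
#' @return For the reader, a `cell_tracks` object.
#' @export
read_cell_tracks <- function(path, frame_interval = 1) {
  v <- utils::read.csv(path)
  need <- c("cell_id", "frame", "vertex_index", "x", "y")
  if (!all(need %in% names(v))) {
    stop(sprintf("cell CSV needs columns: %s", paste(need, collapse = ", ")))
  }
  structure(list(vertices = tibble::as_tibble(v[, need]),
                 n_frames = max(v$frame), frame_interval = frame_interval,
                 sheet = NULL, deformation = NULL, seed = NA_integer_),
            class = "cell_tracks")
}

#' Write a ground-truth sidecar
#'
#' @param truth any list of ground-truth values (profiles, specs, seeds).
#' @param path JSON path.
#' @return Invisibly, the path.
#' @export
write_truth_sidecar <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
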