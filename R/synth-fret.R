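#' Synthetic tension-sensor imagery
#'
#' Seeded generators for two-channel (FRET donor/acceptor) embryo images
#' with a known tension ground truth. The forward model per pixel is
#'
#'   donor    = density * (1 - f) * k_d + background_donor    + noise
#'   acceptor = density *      f  * k_a + background_acceptor + noise
#'
#' where `f` is the local FRET index (fraction of sensor emission routed to
#' the acceptor; high f = high FRET = low tension), `density` is the local
#' sensor concentration, and k_d/k_a are arbitrary channel brightness
#' constants that cancel in the acceptor/donor ratio. The FRET index varies
#' only along the AP axis (the image ordinate, anterior at row 0), so the
#' noise-free per-line ratio f*k_a / ((1-f)*k_d) is the analytic gradient
#' profile that the tensiometry pipeline must recover.
#'
#' @name synthetic-fret
NULL

#' Specify a ground-truth tension (FRET) field
#'
#' @param fret_min,fret_max FRET index bounds, both strictly inside (0, 1).
#'   `profile_shape = "linear"` runs from `fret_max` at the anterior pole
#'   (row 0) down to `fret_min` at the posterior edge — the tensed, stretched
#'   posterior tissue shows the low FRET index. `"constant"` uses `fret_max`
#'   everywhere (the tension-insensitive control sensor reports a constant
#'   high FRET); `"sigmoid"` interpolates with a logistic step at mid-axis.
#' @param profile_shape one of `"constant"`, `"linear"`, `"sigmoid"`.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param density_unevenness fold-range (>= 1) of the smooth multiplicative
#'   sensor-density field; 1 means perfectly even expression.
#' @param background_donor,background_acceptor autofluorescence offsets,
#'   intensity units.
#' @param k_d,k_a channel brightness constants, intensity units.
#' @return List of class `tension_field_spec`.
#' @export
tension_field_spec <- function(fret_min = 0.25, fret_max = 0.45,
                               profile_shape = c("linear", "constant", "sigmoid"),
                               noise_sd = 20, density_unevenness = 2,
                               background_donor = 0, background_acceptor = 0,
                               k_d = 1000, k_a = 1000) {
  profile_shape <- match.arg(profile_shape)
  stopifnot(
    fret_min > 0, fret_max < 1, fret_min <= fret_max,
    noise_sd >= 0, density_unevenness >= 1,
    background_donor >= 0, background_acceptor >= 0, k_d > 0, k_a > 0
  )
  structure(as.list(environment()), class = "tension_field_spec")
}

fret_index_profile <- function(spec, n_rows) {
  u <- if (n_rows == 1L) 0 else (seq_len(n_rows) - 1) / (n_rows - 1)
  switch(spec$profile_shape,
    constant = rep(spec$fret_max, n_rows),
    linear   = spec$fret_max + (spec$fret_min - spec$fret_max) * u,
    sigmoid  = spec$fret_max + (spec$fret_min - spec$fret_max) *
                 stats::plogis((u - 0.5) * 12)
  )
}

# Smooth multiplicative density field in [1, unevenness]: a low-resolution
# uniform grid bilinearly interpolated to the full frame.
density_field <- function(n_rows, n_cols, unevenness, grid = 6L) {
  if (unevenness <= 1) return(matrix(1, n_rows, n_cols))
  g <- matrix(stats::runif(grid * grid), grid, grid)
  ri <- seq(1, grid, length.out = n_rows)
  ci <- seq(1, grid, length.out = n_cols)
  r0 <- pmin(floor(ri), grid - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), grid - 1L); fc <- ci - c0
  top <- g[r0, c0, drop = FALSE] * (1 - fr) + g[r0 + 1L, c0, drop = FALSE] * fr
  bot <- g[r0, c0 + 1L, drop = FALSE] * (1 - fr) + g[r0 + 1L, c0 + 1L, drop = FALSE] * fr
  f <- top * rep(1 - fc, each = n_rows) + bot * rep(fc, each = n_rows)
  f <- (f - min(f)) / max(max(f) - min(f), .Machine$double.eps)
  1 + (unevenness - 1) * f
}

# Elliptical embryo footprint inscribed in the frame with a fractional margin.
footprint_mask <- function(n_rows, n_cols, margin = 0.05) {
  cy <- (n_rows + 1) / 2; cx <- (n_cols + 1) / 2
  ry <- (0.5 - margin) * n_rows; rx <- (0.5 - margin) * n_cols
  row <- matrix(seq_len(n_rows), n_rows, n_cols)
  col <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1
}

#' Generate a synthetic donor/acceptor image pair
#'
#' Renders the forward model of the ground-truth FRET field over an
#' elliptical tissue footprint; outside the footprint only backgrounds and
#' noise are present. The returned ground truth is computed before noise is
#' added and is identical across seeds.
#'
#' @param tension a [tension_field_spec()].
#' @param shape image dimensions `c(rows, cols)`; each must be >= 4.
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return List of class `fret_dataset` with `images` (a [fret_image_set()]),
#'   `truth` (tibble: `coordinate` = 0-based AP line, `fret_index`, `ratio` =
#'   noise-free acceptor/donor, `n_pixels` footprint pixels per line),
#'   `footprint` (logical matrix), `density`, and the generating `spec`.
#' @export
generate_fret_pair <- function(tension, shape = c(256L, 512L), seed = 1L) {
  stopifnot(inherits(tension, "tension_field_spec"))
  if (length(shape) != 2L || any(shape < 4L)) {
    stop("degenerate image shape: both dimensions must be >= 4")
  }
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  withr::with_seed(seed, {
    f_line <- fret_index_profile(tension, nr)
    f <- matrix(f_line, nr, nc)
    dens <- density_field(nr, nc, tension$density_unevenness)
    foot <- footprint_mask(nr, nc)
    donor_sig <- ifelse(foot, dens * (1 - f) * tension$k_d, 0)
    acc_sig <- ifelse(foot, dens * f * tension$k_a, 0)
    donor <- donor_sig + tension$background_donor
    acceptor <- acc_sig + tension$background_acceptor
    if (tension$noise_sd > 0) {
      donor <- donor + matrix(stats::rnorm(nr * nc, 0, tension$noise_sd), nr, nc)
      acceptor <- acceptor + matrix(stats::rnorm(nr * nc, 0, tension$noise_sd), nr, nc)
    }
    truth <- tibble::tibble(
      coordinate = seq_len(nr) - 1,
      fret_index = f_line,
      ratio = (f_line * tension$k_a) / ((1 - f_line) * tension$k_d),
      n_pixels = rowSums(foot)
    )
    truth <- truth[truth$n_pixels > 0L, ]
    structure(list(
      images = fret_image_set(donor, acceptor),
      truth = truth, footprint = foot, density = dens, spec = tension,
      seed = seed
    ), class = "fret_dataset")
  })
}

#' Generate uninjected-control image pairs
#'
#' Autofluorescence-only embryos used for background estimation: each image
#' holds its channel's constant background plus Gaussian noise, with no
#' sensor signal. Protocol takes 3-4 controls.
#'
#' @param backgrounds length-2 vector `c(donor, acceptor)` intensities.
#' @param n number of control embryos, 3 or 4.
#' @param shape image dimensions `c(rows, cols)`.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @param seed integer seed.
#' @return List of `n` [fret_image_set()] objects.
#' @export
generate_uninjected_controls <- function(backgrounds, n = 3L,
                                         shape = c(256L, 512L),
                                         noise_sd = 0, seed = 1L) {
  stopifnot(length(backgrounds) == 2L, all(backgrounds >= 0), noise_sd >= 0)
  if (!n %in% c(3L, 4L)) stop("n must be 3 or 4 control embryos")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      d <- matrix(backgrounds[1L], nr, nc)
      a <- matrix(backgrounds[2L], nr, nc)
      if (noise_sd > 0) {
        d <- d + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
        a <- a + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      }
      fret_image_set(d, a)
    })
  })
}
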