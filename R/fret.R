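#' FRET ratio tensiometry
#'
#' Background estimation from uninjected controls, ratiometric FRET index
#' maps, acceptor-channel tissue masks, mask-normalized AP-axis gradient
#' profiles, control comparison, and the channel-correlation diagnostic that
#' separates expression-driven from tension-driven intensity variation.
#'
#' Convention: the FRET index is (acceptor - background) / (donor -
#' background), so a higher index means more energy transfer, i.e. a less
#' stretched sensor and lower mechanical tension. Set `invert = TRUE` in
#' [ratio_image()] for the donor/acceptor convention.
#'
#' @name fret-tensiometry
NULL

#' Bundle a registered donor/acceptor image pair
#'
#' @param donor,acceptor numeric matrices of equal dimensions (cyan and
#'   green channel intensities).
#' @param background_donor,background_acceptor per-channel scalar background
#'   estimates; 0 until estimated.
#' @return List of class `fret_image_set`.
#' @export
fret_image_set <- function(donor, acceptor,
                           background_donor = 0, background_acceptor = 0) {
  donor <- as.matrix(donor); acceptor <- as.matrix(acceptor)
  if (!identical(dim(donor), dim(acceptor))) {
    stop("donor and acceptor images must have identical dimensions")
  }
  stopifnot(background_donor >= 0, background_acceptor >= 0)
  structure(list(donor = donor, acceptor = acceptor,
                 background_donor = background_donor,
                 background_acceptor = background_acceptor),
            class = "fret_image_set")
}

#' Estimate per-channel backgrounds from uninjected controls
#'
#' The background is the mean pixel intensity of each channel across all
#' control embryos — a per-channel scalar, not a spatial field.
#'
#' @param controls list of 1 to 10 [fret_image_set()] objects of equal
#'   dimensions.
#' @return Named numeric vector `c(donor = ..., acceptor = ...)`.
#' @export
estimate_background <- function(controls) {
  if (length(controls) == 0L) stop("at least one control image set required")
  if (length(controls) > 10L) stop("at most 10 control image sets supported")
  dims <- lapply(controls, function(s) dim(s$donor))
  if (length(unique(dims)) != 1L) stop("control images must share dimensions")
  c(donor = mean(vapply(controls, function(s) mean(s$donor), numeric(1))),
    acceptor = mean(vapply(controls, function(s) mean(s$acceptor), numeric(1))))
}

#' Apply estimated backgrounds to an image set
#'
#' @param images a [fret_image_set()].
#' @param backgrounds named vector as returned by [estimate_background()].
#' @return The image set with background fields set.
#' @export
set_background <- function(images, backgrounds) {
  images$background_donor <- unname(backgrounds[["donor"]])
  images$background_acceptor <- unname(backgrounds[["acceptor"]])
  images
}

#' Background-corrected FRET ratio image
#'
#' Per pixel, FRET index = (acceptor - background_acceptor) /
#' (donor - background_donor). Pixels whose corrected donor falls below
#' `min_signal` are marked invalid rather than zeroed, and stay excluded
#' from every downstream profile; this guards against ratio blow-up at the
#' tissue margin.
#'
#' @param images a [fret_image_set()] (backgrounds may be zero).
#' @param min_signal corrected-donor validity threshold, intensity units;
#'   default `max(5, background_donor)`.
#' @param invert if `TRUE` compute donor/acceptor instead (the alternative
#'   reading of the ratio convention; validity is then gated on the
#'   corrected acceptor).
#' @return List of class `ratio_image` with `values` (matrix, NA where
#'   invalid) and `valid_mask` (logical matrix).
#' @export
ratio_image <- function(images, min_signal = NULL, invert = FALSE) {
  stopifnot(inherits(images, "fret_image_set"))
  if (is.null(min_signal)) min_signal <- max(5, images$background_donor)
  d <- images$donor - images$background_donor
  a <- images$acceptor - images$background_acceptor
  denom <- if (invert) a else d
  valid <- denom >= min_signal
  vals <- matrix(NA_real_, nrow(d), ncol(d))
  vals[valid] <- if (invert) d[valid] / a[valid] else a[valid] / d[valid]
  structure(list(values = vals, valid_mask = valid,
                 invert = invert, min_signal = min_signal),
            class = "ratio_image")
}

#' Tissue mask from the acceptor (green) channel
#'
#' Thresholds the background-corrected acceptor channel, which shows the
#' distributed sensor, to delimit the tissue. Otsu's method by default; a
#' fixed intensity threshold is available when automatic thresholding is
#' unsuitable.
#'
#' @param images a [fret_image_set()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold for `method = "fixed"`.
#' @return Logical matrix; errors if no pixel passes (no tissue found).
#' @export
binary_mask <- function(images, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(images, "fret_image_set"))
  method <- match.arg(method)
  a <- images$acceptor - images$background_acceptor
  thr <- switch(method,
    otsu = EBImage::otsu(a, range = range(a)),
    fixed = {
      if (is.null(threshold)) stop("method = 'fixed' needs a threshold")
      threshold
    })
  mask <- a > thr
  if (!any(mask)) stop("no tissue found: binary mask is empty")
  mask
}

#' Mask-normalized AP-axis FRET profile
#'
#' Per AP coordinate (image line), the mean FRET index over pixels that are
#' both inside the mask and valid in the ratio image — the integral FRET
#' signal per line divided by the mask profile. Lines with no contributing
#' pixel carry no value and are dropped.
#'
#' @param ratio a [ratio_image()].
#' @param mask logical matrix from [binary_mask()] (or any mask of the same
#'   dimensions).
#' @return Tibble of class `axis_profile`: `coordinate` (0-based line index,
#'   anterior = 0), `mean_fret`, `n_pixels`.
#' @export
axis_profile <- function(ratio, mask) {
  stopifnot(inherits(ratio, "ratio_image"))
  if (!identical(dim(mask), dim(ratio$values))) {
    stop("mask and ratio image dimensions differ")
  }
  use <- mask & ratio$valid_mask
  if (!any(use)) stop("mask and valid region are disjoint: empty profile")
  v <- ratio$values
  v[!use] <- 0
  n <- rowSums(use)
  s <- rowSums(v)
  keep <- n > 0L
  structure(tibble::tibble(
    coordinate = which(keep) - 1,
    mean_fret = s[keep] / n[keep],
    n_pixels = n[keep]
  ), class = c("axis_profile", class(tibble::tibble())))
}

#' Gradient statistics of an AP profile
#'
#' Weighted least-squares slope of mean FRET on AP coordinate (weights =
#' per-line pixel counts) plus the Spearman rank correlation of the profile
#' with the coordinate. Positive slope = FRET increasing anterior to
#' posterior. A constant profile has zero slope and, by convention, rho = 0.
#'
#' @param profile an [axis_profile()] with at least 10 defined lines.
#' @return List of class `gradient_stat`: `slope` (FRET units per pixel),
#'   `intercept`, `spearman_rho`, `n_lines`.
#' @export
gradient_stat <- function(profile) {
  if (nrow(profile) < 10L) stop("need at least 10 defined profile lines")
  fit <- stats::lm(mean_fret ~ coordinate, data = profile,
                   weights = profile$n_pixels)
  rho <- if (stats::sd(profile$mean_fret) == 0) 0 else
    suppressWarnings(stats::cor(profile$coordinate, profile$mean_fret,
                                method = "spearman"))
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 spearman_rho = rho, n_lines = nrow(profile)),
            class = "gradient_stat")
}

#' @export
print.gradient_stat <- function(x, ...) {
  cat(sprintf("AP gradient: slope %.3g per px, Spearman rho %.3f (%d lines)\n",
              x$slope, x$spearman_rho, x$n_lines))
  invisible(x)
}

#' Normalized FRET comparison of sensor vs control profiles
#'
#' Ratio of the pixel-weighted grand mean FRET of a tension-insensitive
#' control (the truncated-sensor analogue, constant high FRET) to that of
#' the tension sensor. Values above 1 are expected when the control reports
#' the unloaded, high-FRET state.
#'
#' @param sensor_profile,control_profile [axis_profile()] objects.
#' @return Scalar: control grand mean / sensor grand mean.
#' @export
normalized_fret_compare <- function(sensor_profile, control_profile) {
  if (nrow(sensor_profile) == 0L || nrow(control_profile) == 0L) {
    stop("profiles must be non-empty")
  }
  gm <- function(p) sum(p$mean_fret * p$n_pixels) / sum(p$n_pixels)
  ms <- gm(sensor_profile)
  if (ms == 0) stop("sensor grand mean FRET is zero")
  gm(control_profile) / ms
}

#' Channel correlation diagnostic
#'
#' Pearson correlation of the background-corrected acceptor and donor
#' channels over masked pixels. The green channel tracks the amount of
#' injected sensor, so a high correlation combined with a flat FRET ratio
#' profile indicates that intensity variation reflects sensor expression,
#' not tension.
#'
#' @param images a [fret_image_set()].
#' @param mask non-empty logical matrix.
#' @return List of class `correlation_report`: `pearson_r` (NA when a
#'   channel is constant under the mask), `n_pixels`, `channel_pair`.
#' @export
channel_correlation <- function(images, mask) {
  stopifnot(inherits(images, "fret_image_set"))
  if (!any(mask)) stop("mask is empty")
  a <- (images$acceptor - images$background_acceptor)[mask]
  d <- (images$donor - images$background_donor)[mask]
  r <- if (stats::sd(a) == 0 || stats::sd(d) == 0) NA_real_ else
    stats::cor(a, d)
  structure(list(pearson_r = r, n_pixels = sum(mask),
                 channel_pair = c("acceptor(green)", "donor(cyan)")),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("channel correlation %s vs %s: r = %s over %d px\n",
              x$channel_pair[1L], x$channel_pair[2L],
              ifelse(is.na(x$pearson_r), "undefined (constant channel)",
                     sprintf("%.3f", x$pearson_r)),
              x$n_pixels))
  invisible(x)
}

#' Convert a ratio profile to FRET-index units
#'
#' For equal channel brightness constants the acceptor/donor ratio r maps
#' back to the FRET index f = r / (1 + r); useful to compare recovered
#' gradients against index-space ground truth.
#'
#' @param profile an [axis_profile()] in ratio units.
#' @return The profile with `mean_fret` transformed to index units.
#' @export
ratio_to_index <- function(profile) {
  profile$mean_fret <- profile$mean_fret / (1 + profile$mean_fret)
  profile
}

#' Pseudocolor rendering of a ratio image
#'
#' Maps valid FRET values through a monotone blue-yellow-red colormap with
#' red at the maximum FRET index (lowest tension); invalid pixels render
#' black.
#'
#' @param ratio a [ratio_image()].
#' @param n_colors palette resolution.
#' @return `rows x cols x 3` RGB array in \[0, 1\].
#' @export
render_pseudocolor <- function(ratio, n_colors = 256L) {
  stopifnot(inherits(ratio, "ratio_image"))
  v <- ratio$values
  pal <- grDevices::colorRampPalette(c("blue", "yellow", "red"))(n_colors)
  rgbmat <- grDevices::col2rgb(pal) / 255
  rng <- range(v, na.rm = TRUE)
  idx <- if (diff(rng) == 0) matrix(n_colors, nrow(v), ncol(v)) else
    matrix(pmin(n_colors, 1L + floor((v - rng[1L]) / diff(rng) * (n_colors - 1e-9))),
           nrow(v), ncol(v))
  out <- array(0, c(nrow(v), ncol(v), 3L))
  ok <- !is.na(v)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- rgbmat[ch, idx[ok]]
    out[, , ch] <- plane
  }
  out
}
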