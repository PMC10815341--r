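test_that("background estimation averages control embryos per channel", {
  ctl3 <- lapply(1:3, function(i) uniform_images(10, 20))
  expect_equal(estimate_background(ctl3), c(donor = 10, acceptor = 20))

  ctl <- lapply(c(8, 10, 12), function(d) uniform_images(d, 2 * d))
  expect_equal(estimate_background(ctl)[["donor"]], 10)

  expect_error(estimate_background(list()), "at least one")

  # noisy: estimate within 3*sd/sqrt(3*N) of truth
  noisy <- generate_uninjected_controls(c(50, 70), n = 3L,
                                        shape = c(256L, 256L), noise_sd = 2,
                                        seed = 4)
  bg <- estimate_background(noisy)
  bound <- 3 * 2 / sqrt(3 * 256 * 256)
  expect_lt(abs(bg[["donor"]] - 50), bound)
  expect_lt(abs(bg[["acceptor"]] - 70), bound)
})

test_that("ratio image implements background-corrected acceptor/donor", {
  expect_true(all(ratio_image(uniform_images(100, 200))$values == 2))

  img <- uniform_images(110, 220)
  img <- set_background(img, c(donor = 10, acceptor = 20))
  expect_true(all(ratio_image(img)$values == 2))

  # low-donor pixels become invalid, not zero
  d <- matrix(100, 8, 8); d[1, 1] <- 2
  ri <- ratio_image(fret_image_set(d, matrix(200, 8, 8)), min_signal = 5)
  expect_false(ri$valid_mask[1, 1])
  expect_true(is.na(ri$values[1, 1]))
  expect_equal(sum(ri$valid_mask), 63)

  expect_error(fret_image_set(matrix(1, 4, 4), matrix(1, 4, 5)), "dimensions")
})

test_that("binary mask finds the tissue footprint", {
  zeros <- fret_image_set(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(binary_mask(zeros, method = "fixed", threshold = 1), "no tissue")

  two <- matrix(0, 10, 10); two[4:7, 4:7] <- 1000
  m <- binary_mask(fret_image_set(two, two), method = "otsu")
  expect_identical(m, two == 1000)

  ds <- generate_fret_pair(tension_field_spec(density_unevenness = 2),
                           c(128L, 128L), seed = 6)
  mask <- binary_mask(ds$images)
  coverage <- sum(mask & ds$footprint) / sum(ds$footprint)
  expect_gte(coverage, 0.99)
})

test_that("axis profile is the masked per-line mean and matches ground truth", {
  ri <- ratio_image(uniform_images(100, 200))
  mask <- matrix(TRUE, 16, 16)
  prof <- axis_profile(ri, mask)
  expect_true(all(prof$mean_fret == 2))
  expect_equal(prof$n_pixels, rep(16, 16))

  # noise-free linear gradient reproduces the generator's analytic profile
  ds <- generate_fret_pair(tension_field_spec(noise_sd = 0), c(96L, 96L),
                           seed = 2)
  prof <- axis_profile(ratio_image(ds$images), binary_mask(ds$images))
  merged <- merge(prof, ds$truth, by = "coordinate")
  expect_equal(nrow(merged), nrow(ds$truth))
  expect_lt(max(abs(merged$mean_fret / merged$ratio - 1)), 1e-9)

  # anterior half masked out -> only posterior coordinates defined
  half <- matrix(TRUE, 16, 16); half[1:8, ] <- FALSE
  ph <- axis_profile(ri, half)
  expect_true(all(ph$coordinate >= 8))

  expect_error(axis_profile(ri, matrix(FALSE, 16, 16)), "disjoint")
})

test_that("gradient statistics behave on constant, monotone and short profiles", {
  const <- structure(tibble::tibble(coordinate = 0:19, mean_fret = 2,
                                    n_pixels = 10),
                     class = c("axis_profile", class(tibble::tibble())))
  gs <- gradient_stat(const)
  expect_equal(gs$slope, 0, tolerance = 1e-12)
  expect_equal(gs$spearman_rho, 0)

  dec <- const; dec$mean_fret <- seq(2, 1, length.out = 20)
  expect_equal(gradient_stat(dec)$spearman_rho, -1)

  expect_error(gradient_stat(const[1:9, ]), "at least 10")
})

test_that("gradient slope recovery in index units matches the linear truth", {
  spec <- tension_field_spec(fret_min = 0.25, fret_max = 0.45, noise_sd = 0)
  ds <- generate_fret_pair(spec, c(200L, 128L), seed = 3)
  prof <- axis_profile(ratio_image(ds$images), binary_mask(ds$images))
  gs <- gradient_stat(ratio_to_index(prof))
  expect_equal(gs$slope, (0.25 - 0.45) / 199, tolerance = 0.05)
})

test_that("normalized FRET comparison is a weighted grand-mean ratio", {
  prof <- function(v, n = 10) {
    structure(tibble::tibble(coordinate = seq_along(v) - 1, mean_fret = v,
                             n_pixels = n),
              class = c("axis_profile", class(tibble::tibble())))
  }
  p <- prof(rep(0.45, 20))
  expect_equal(normalized_fret_compare(p, p), 1)
  expect_equal(normalized_fret_compare(prof(rep(0.45, 20)), prof(rep(0.9, 20))), 2)
  expect_error(normalized_fret_compare(prof(rep(0, 20)), p), "zero")

  # constant-high-FRET control vs gradient sensor -> ratio above 1
  ctl <- generate_fret_pair(
    tension_field_spec(fret_min = 0.7, fret_max = 0.7,
                       profile_shape = "constant", noise_sd = 0),
    c(96L, 96L), seed = 5)
  sen <- generate_fret_pair(tension_field_spec(noise_sd = 0), c(96L, 96L),
                            seed = 5)
  ps <- axis_profile(ratio_image(sen$images), binary_mask(sen$images))
  pc <- axis_profile(ratio_image(ctl$images), binary_mask(ctl$images))
  expect_gt(normalized_fret_compare(ps, pc), 1)
})

test_that("channel correlation flags proportional channels and independence", {
  d <- matrix(runif(64 * 64, 50, 150), 64, 64)
  expect_equal(channel_correlation(fret_image_set(d, 2 * d),
                                   matrix(TRUE, 64, 64))$pearson_r, 1)

  set.seed(21)
  a <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  b <- matrix(rnorm(128 * 128, 100, 10), 128, 128)
  r <- channel_correlation(fret_image_set(a, b), matrix(TRUE, 128, 128))
  expect_lt(abs(r$pearson_r), 0.1)
  expect_gte(r$n_pixels, 1e4)

  const <- channel_correlation(uniform_images(5, 7), matrix(TRUE, 16, 16))
  expect_true(is.na(const$pearson_r))
  expect_error(channel_correlation(uniform_images(5, 7), matrix(FALSE, 16, 16)),
               "empty")
})

test_that("ratio, profile and gradient are scale and background invariant", {
  spec <- tension_field_spec(noise_sd = 2)
  ds <- generate_fret_pair(spec, c(96L, 96L), seed = 8)
  mask <- binary_mask(ds$images)
  prof0 <- axis_profile(ratio_image(ds$images), mask)
  gs0 <- gradient_stat(prof0)

  # global intensity scaling cancels exactly
  scaled <- fret_image_set(ds$images$donor * 3.7, ds$images$acceptor * 3.7)
  prof_s <- axis_profile(ratio_image(scaled, min_signal = 5 * 3.7),
                         binary_mask(scaled))
  expect_equal(prof_s$mean_fret, prof0$mean_fret, tolerance = 1e-12)
  expect_equal(gradient_stat(prof_s)$slope, gs0$slope, tolerance = 1e-12)

  # estimated constant background subtracts back out within 1% (noise 2 of
  # signal ~ 650, i.e. well under 2% noise)
  spec_bg <- tension_field_spec(noise_sd = 2, background_donor = 40,
                                background_acceptor = 60)
  ds_bg <- generate_fret_pair(spec_bg, c(96L, 96L), seed = 8)
  ctl <- generate_uninjected_controls(c(40, 60), n = 3L, shape = c(96L, 96L),
                                      noise_sd = 2, seed = 10)
  img <- set_background(ds_bg$images, estimate_background(ctl))
  prof_bg <- axis_profile(ratio_image(img), binary_mask(img))
  m <- merge(prof0, prof_bg, by = "coordinate")
  expect_lt(max(abs(m$mean_fret.y / m$mean_fret.x - 1)), 0.01)
})

test_that("pseudocolor rendering is monotone with red at maximum FRET", {
  v <- matrix(seq(0.5, 2, length.out = 64), 8, 8)
  v[1, 1] <- NA
  ri <- structure(list(values = v, valid_mask = !is.na(v)),
                  class = "ratio_image")
  rgb <- render_pseudocolor(ri)
  mx <- which(v == max(v, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(rgb[mx[1], mx[2], 1], 1)        # red channel maximal
  expect_equal(rgb[1, 1, ], c(0, 0, 0))        # invalid -> black
  # monotone ordering along the ramp: red nondecreasing, blue nonincreasing
  ramp <- sort(v[!is.na(v)])
  ord <- order(v[!is.na(v)])
  red <- rgb[, , 1][!is.na(v)][ord]
  blue <- rgb[, , 3][!is.na(v)][ord]
  expect_true(all(diff(red) > -1e-9))
  expect_true(all(diff(blue) < 1e-9))
})
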