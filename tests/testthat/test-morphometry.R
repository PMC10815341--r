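test_that("displacement cosines hit the compass closed forms", {
  sq <- function(cx, cy) rect_polygon(2, 2, cx, cy)
  # three frames: cell 1 moves anterior (-y), cell 2 posterior, cell 3
  # laterally, cell 4 not at all
  frames <- lapply(0:2, function(t) {
    list(sq(10, 10 - t), sq(30, 10 + t), sq(50, 10 + 0 * t) + cbind(rep(t, 4), 0),
         sq(70, 10))
  })
  rec <- suppressMessages(
    displacement_cosines(tracks_from_polygons(frames), window_frames = 2L))
  ini <- rec[rec$window == "initial", ]
  expect_equal(ini$cosine[ini$cell_id == 1], 1)
  expect_equal(ini$cosine[ini$cell_id == 2], -1)
  expect_equal(ini$cosine[ini$cell_id == 3], 0)
  expect_false(4 %in% ini$cell_id)  # zero displacement excluded
  expect_equal(attr(rec, "n_zero_displacement"), 2L)
})

test_that("order profile separates translation from bidirectional kinematics", {
  tr_uni <- generate_cell_sheet(
    sheet_spec(60L, 150, 200),
    deformation_spec("translation", translation_vector = c(0, -2)), seed = 1)
  op_uni <- order_profile(displacement_cosines(tr_uni))
  expect_equal(op_uni$verdict, "uniform")
  expect_true(all(op_uni$profile$cosine > 0.99))

  y0 <- 100
  tr_bi <- generate_cell_sheet(
    sheet_spec(60L, 150, 200),
    deformation_spec("bidirectional_stretch", lambda_major = 1.15,
                     lambda_minor = 0.9, fixation_ordinate = y0), seed = 2)
  op_bi <- order_profile(displacement_cosines(tr_bi))
  expect_equal(op_bi$verdict, "split")
  expect_lt(abs(op_bi$split_ordinate - y0), 2 * median_cell_diameter(tr_bi))
  expect_gt(op_bi$mean_cosine_anterior, 0)
  expect_lt(op_bi$mean_cosine_posterior, 0)

  # alternating signs with no spatial structure -> uniform
  set.seed(3)
  rec <- tibble::tibble(cell_id = 1:40, ordinate = runif(40, 0, 100),
                        cosine = rep(c(1, -1), 20), window = "initial")
  expect_equal(order_profile(rec)$verdict, "uniform")
})

test_that("integral ROI percent changes follow the affine oracle", {
  tr <- generate_cell_sheet(sheet_spec(50L, 120, 160),
                            deformation_spec("identity", n_frames = 3L),
                            seed = 5)
  roi_id <- integral_roi_series(tr)
  expect_equal(roi_id$major_change_pct, 0, tolerance = 1e-9)
  expect_equal(roi_id$minor_change_pct, 0, tolerance = 1e-9)

  tr_s <- generate_cell_sheet(
    sheet_spec(50L, 120, 160),
    deformation_spec("translation", lambda_major = 1.15, lambda_minor = 1),
    seed = 5)
  roi_s <- integral_roi_series(tr_s)
  expect_equal(roi_s$ap_change_pct, 15, tolerance = 1)     # percentage points
  expect_equal(roi_s$lateral_change_pct, 0, tolerance = 1)
  expect_equal(roi_s$major_change_pct, 15, tolerance = 1)

  # trunk-like factors mirror the bidirectional elongation readout
  tr_t <- generate_cell_sheet(
    sheet_spec(50L, 120, 160),
    deformation_spec("bidirectional_stretch", lambda_major = 1.1343,
                     lambda_minor = 0.8638, fixation_ordinate = 80),
    seed = 5)
  roi_t <- integral_roi_series(tr_t)
  expect_equal(roi_t$major_change_pct, 13.43, tolerance = 1)
  expect_equal(roi_t$minor_change_pct, -13.62, tolerance = 1)
})

test_that("area indices track the determinant of the deformation", {
  tr_id <- generate_cell_sheet(sheet_spec(40L, 100, 140),
                               deformation_spec("identity", n_frames = 3L),
                               seed = 6)
  ai_id <- suppressWarnings(area_index(tr_id))
  expect_true(all(abs(ai_id$cells$index - 1) < 1e-9))
  expect_true(all(abs(ai_id$rois$index - 1) < 1e-9))

  tr_c <- generate_cell_sheet(sheet_spec(40L, 100, 140),
                              deformation_preset("constriction"), seed = 6)
  ai_c <- suppressWarnings(area_index(tr_c))
  expect_equal(mean(ai_c$cells$index), 0.835, tolerance = 0.002)

  tr_p <- generate_cell_sheet(
    sheet_spec(40L, 100, 140),
    deformation_spec("bidirectional_stretch", lambda_major = 1.2,
                     lambda_minor = 1 / 1.2, fixation_ordinate = 70),
    seed = 6)
  ai_p <- suppressWarnings(area_index(tr_p))
  expect_true(all(abs(ai_p$cells$index - 1) < 1e-6))
})

test_that("small-ROI partition covers every cell once with sizes 10-11", {
  tr <- generate_cell_sheet(sheet_spec(100L, 150, 200), seed = 7)
  part <- small_roi_partition(tr)
  expect_length(part, 100L)
  expect_true(all(table(part) %in% c(10L, 11L)))
  expect_setequal(as.integer(names(part)), 1:100)
  # union of small ROIs = integral ROI (same total area)
  ai <- area_index(tr)
  expect_equal(sum(ai$cells$area_first),
               sum(ai$cells$area_first[ai$cells$cell_id %in% as.integer(names(part))]))

  # 56 cells cannot be split into 10s and 11s: remainder is absorbed
  tr56 <- generate_cell_sheet(sheet_spec(56L, 120, 160), seed = 8)
  expect_warning(p56 <- small_roi_partition(tr56), "remainder")
  expect_length(p56, 56L)
  expect_setequal(as.integer(names(p56)), 1:56)
})

test_that("orientation distribution reflects AP stretch and isotropy", {
  tr_iso <- generate_cell_sheet(sheet_spec(300L, 400, 400), seed = 9)
  od_iso <- suppressMessages(orientation_distribution(tr_iso))
  expect_equal(od_iso$fraction_within_30, 1 / 3, tolerance = 0.12)

  # AP stretch reorients major axes toward the AP direction; at the
  # generator's realistic cell anisotropy (median eccentricity ~ 0.65) a
  # 1.3-fold stretch concentrates ~70% of cells within 30 degrees
  # (simulation-derived), roughly double the isotropic 1/3; a strong
  # stretch pulls nearly all cells in
  tr_ap <- generate_cell_sheet(
    sheet_spec(100L, 200, 200),
    deformation_spec("translation", lambda_major = 1.3, n_frames = 2L),
    seed = 10)
  od_ap <- suppressMessages(orientation_distribution(tr_ap, frame = 2L))
  expect_gte(od_ap$fraction_within_30, 0.6)
  expect_gt(od_ap$fraction_within_30, od_iso$fraction_within_30 + 0.2)

  tr_strong <- generate_cell_sheet(
    sheet_spec(100L, 200, 200),
    deformation_spec("translation", lambda_major = 1.8, n_frames = 2L),
    seed = 10)
  od_strong <- suppressMessages(orientation_distribution(tr_strong, frame = 2L))
  expect_gte(od_strong$fraction_within_30, 0.8)

  # all-circular cells: empty histogram with diagnostic
  circ <- lapply(seq_len(12), function(i) {
    ellipse_polygon(64L, rx = 5, ry = 5, cx = 20 * i, cy = 10)
  })
  tr_c <- tracks_from_polygons(list(circ))
  expect_message(od_c <- orientation_distribution(tr_c), "near-circular")
  expect_equal(nrow(od_c$orientations), 0L)
  expect_equal(od_c$n_excluded, 12L)
})

test_that("morphometry is invariant under rigid motion of sheet and axis", {
  tr <- generate_cell_sheet(sheet_spec(40L, 100, 140),
                            deformation_preset("trunk", roi_height = 140),
                            seed = 11)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr_rot <- transform_tracks(tr, R, b = c(37, -12))
  ap_rot <- drop(R %*% c(0, -1))

  expect_equal(cell_eccentricities(tr_rot, 1L), cell_eccentricities(tr, 1L),
               tolerance = 1e-9)
  a1 <- suppressWarnings(area_index(tr))$cells$index
  a2 <- suppressWarnings(area_index(tr_rot))$cells$index
  expect_equal(a1, a2, tolerance = 1e-9)
  r1 <- integral_roi_series(tr)
  r2 <- integral_roi_series(tr_rot, ap_direction = ap_rot)
  expect_equal(r1$major_change_pct, r2$major_change_pct, tolerance = 1e-9)
  expect_equal(r1$ap_change_pct, r2$ap_change_pct, tolerance = 1e-9)
  c1 <- displacement_cosines(tr)
  c2 <- displacement_cosines(tr_rot, ap_direction = ap_rot)
  expect_equal(c1$cosine, c2$cosine, tolerance = 1e-9)
})

test_that("start/end comparison reports means, CIs and the U test", {
  set.seed(12)
  a <- rnorm(20); b <- rnorm(20) + 2
  cmp <- compare_start_end(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$ci_start[1], cmp$ci_start[2])
  expect_equal(mean(a), cmp$mean_start)
  expect_error(compare_start_end(1:4, 1:10), "at least 5")
})
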