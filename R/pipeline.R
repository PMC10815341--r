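#' Configuration-driven pipeline
#'
#' One seeded configuration drives synthetic-data generation and all three
#' analysis stages (tension mapping, morphometry, expression statistics),
#' writing every table under one output directory together with a run
#' manifest (config snapshot, output checksums, per-stage diagnostics,
#' package version). Deterministic stages are byte-reproducible from the
#' manifest; stochastic stages are reproducible from the recorded seed.
#'
#' @name pipeline
NULL

#' Default demonstration configuration
#'
#' A complete config that generates a gradient-sensor embryo, a control
#' embryo, head/trunk cell sheets, a qPCR plate and a DE table, and runs
#' every analysis stage on them.
#'
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @return Nested configuration list (class `run_config`).
#' @export
demo_config <- function(seed = 1L, out_dir = tempfile("tensiomap_run_")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("synth", "fret", "morpho", "expr"),
    synth = list(
      fret = list(fret_min = 0.25, fret_max = 0.45, profile_shape = "linear",
                  noise_sd = 20, density_unevenness = 2,
                  background_donor = 30, background_acceptor = 50,
                  shape = c(256L, 512L)),
      control = list(fret_constant = 0.70),
      sheet = list(n_cells = 100L, roi_width = 300, roi_height = 400)
    ),
    fret = list(mask_method = "otsu", min_signal = NULL),
    morpho = list(ap_axis = "y-", window_frames = 2L),
    expr = list(lfc_min = 1, p_max = 0.05, use_adjusted = TRUE,
                true_E = 2, fold_changes = c(cdx4 = 3.0, gsc = 0.33, nullg = 1.0),
                ct_noise_sd = 0.1)
  ), class = "run_config")
}

ap_vector <- function(ap_axis) {
  switch(ap_axis,
    "y-" = c(0, -1), "y+" = c(0, 1), "x-" = c(-1, 0), "x+" = c(1, 0),
    stop(sprintf("unknown ap_axis '%s' (use y-/y+/x-/x+)", ap_axis)))
}

#' Validate a run configuration
#'
#' @param config a config list (see [demo_config()]) or a path to a JSON
#'   config file.
#' @return Character vector of diagnostics, each naming the offending field
#'   and stage; empty iff the config is runnable.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(
      suppressWarnings(jsonlite::read_json(config, simplifyVector = TRUE)),
      error = function(e) NULL)
    if (is.null(config)) return("config: unreadable config file")
  }
  diag <- character()
  if (is.null(config$seed)) diag <- c(diag, "config: missing seed")
  if (is.null(config$out_dir)) diag <- c(diag, "config: missing out_dir")
  known <- c("synth", "fret", "morpho", "expr")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0L) {
    diag <- c(diag, sprintf("config: unknown stage '%s'", bad))
  }
  if ("synth" %in% config$stages) {
    ns <- config$synth$fret$noise_sd
    if (!is.null(ns) && ns < 0) {
      diag <- c(diag, "synth: noise_sd must be nonnegative")
    }
    du <- config$synth$fret$density_unevenness
    if (!is.null(du) && du < 1) {
      diag <- c(diag, "synth: density_unevenness must be >= 1")
    }
  }
  if ("morpho" %in% config$stages) {
    ax <- config$morpho$ap_axis
    if (is.null(ax)) {
      diag <- c(diag, "morpho: missing ap_axis convention")
    } else if (!ax %in% c("y-", "y+", "x-", "x+")) {
      diag <- c(diag, sprintf("morpho: invalid ap_axis '%s'", ax))
    }
  }
  if ("expr" %in% config$stages) {
    if (is.null(config$expr$lfc_min) || is.null(config$expr$p_max)) {
      diag <- c(diag, "expr: candidate filter thresholds (lfc_min, p_max) are mandatory")
    }
  }
  diag
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order (synth, then
#' fret/morpho, then expr), writes each stage's tables as CSV under the
#' output directory, and writes `manifest.json` last. A stage failure
#' aborts downstream stages; the manifest records the partial state.
#'
#' @inheritParams validate_config
#' @return The manifest, invisibly (list of class `run_manifest`).
#' @export
run_pipeline <- function(config = demo_config()) {
  diag <- validate_config(config)
  if (length(diag) > 0L) {
    stop(sprintf("invalid config:\n  %s", paste(diag, collapse = "\n  ")))
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "tensiomap",
                   version = as.character(utils::packageVersion("tensiomap")),
                   config = config, stages = list(), outputs = character())
  state <- new.env(parent = emptyenv())
  failed <- FALSE
  for (stage in intersect(c("synth", "fret", "morpho", "expr"), config$stages)) {
    if (failed) {
      manifest$stages[[stage]] <- list(status = "skipped (upstream failure)")
      next
    }
    res <- tryCatch(
      run_stage(stage, config, state, out),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[stage]] <- list(status = "failed",
                                       error = conditionMessage(res))
      failed <- TRUE
    } else {
      manifest$stages[[stage]] <- c(list(status = "ok"), res)
    }
  }
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest$outputs <- as.list(tools::md5sum(file.path(out, files)))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

run_stage <- function(stage, config, state, out) {
  switch(stage,
    synth = {
      sf <- config$synth$fret
      spec <- tension_field_spec(
        fret_min = sf$fret_min, fret_max = sf$fret_max,
        profile_shape = sf$profile_shape, noise_sd = sf$noise_sd,
        density_unevenness = sf$density_unevenness,
        background_donor = sf$background_donor,
        background_acceptor = sf$background_acceptor)
      state$sensor <- generate_fret_pair(spec, shape = sf$shape,
                                         seed = config$seed)
      ctl_spec <- tension_field_spec(
        fret_min = config$synth$control$fret_constant,
        fret_max = config$synth$control$fret_constant,
        profile_shape = "constant", noise_sd = sf$noise_sd,
        density_unevenness = sf$density_unevenness,
        background_donor = sf$background_donor,
        background_acceptor = sf$background_acceptor)
      state$control <- generate_fret_pair(ctl_spec, shape = sf$shape,
                                          seed = config$seed + 1L)
      state$uninjected <- generate_uninjected_controls(
        c(sf$background_donor, sf$background_acceptor), n = 3L,
        shape = sf$shape, noise_sd = sf$noise_sd, seed = config$seed + 2L)
      sh <- config$synth$sheet
      spec_sheet <- sheet_spec(sh$n_cells, sh$roi_width, sh$roi_height)
      state$sheet_head <- generate_cell_sheet(
        spec_sheet, deformation_preset("head"), seed = config$seed)
      state$sheet_trunk <- generate_cell_sheet(
        spec_sheet, deformation_preset("trunk", roi_height = sh$roi_height),
        seed = config$seed + 1L)
      state$plate <- generate_qpcr_plate(
        true_E = config$expr$true_E, fold_changes = config$expr$fold_changes,
        ct_noise_sd = config$expr$ct_noise_sd, seed = config$seed)
      state$de <- generate_de_table(seed = config$seed)
      utils::write.csv(state$sensor$truth,
                       file.path(out, "synth_fret_truth.csv"), row.names = FALSE)
      write_cell_tracks(state$sheet_head, file.path(out, "synth_cells_head.csv"))
      write_cell_tracks(state$sheet_trunk, file.path(out, "synth_cells_trunk.csv"))
      utils::write.csv(state$plate, file.path(out, "synth_qpcr_plate.csv"),
                       row.names = FALSE)
      write_truth_sidecar(
        list(seed = config$seed,
             fret = config$synth$fret,
             control_fret = config$synth$control$fret_constant,
             qpcr = list(true_E = config$expr$true_E,
                         fold_changes = as.list(config$expr$fold_changes))),
        file.path(out, "synth_truth.json"))
      list(n_cells = config$synth$sheet$n_cells)
    },
    fret = {
      bg <- estimate_background(state$uninjected)
      img <- set_background(state$sensor$images, bg)
      mask <- binary_mask(img, method = config$fret$mask_method)
      prof <- axis_profile(ratio_image(img, min_signal = config$fret$min_signal),
                           mask)
      gs <- gradient_stat(prof)
      ctl_img <- set_background(state$control$images, bg)
      ctl_prof <- axis_profile(
        ratio_image(ctl_img, min_signal = config$fret$min_signal),
        binary_mask(ctl_img, method = config$fret$mask_method))
      corr <- channel_correlation(img, mask)
      utils::write.csv(prof, file.path(out, "fret_profile_sensor.csv"),
                       row.names = FALSE)
      utils::write.csv(ctl_prof, file.path(out, "fret_profile_control.csv"),
                       row.names = FALSE)
      summary <- tibble::tibble(
        slope = gs$slope, spearman_rho = gs$spearman_rho,
        control_slope = gradient_stat(ctl_prof)$slope,
        control_sensor_ratio = normalized_fret_compare(prof, ctl_prof),
        channel_pearson_r = corr$pearson_r,
        background_donor = bg[["donor"]], background_acceptor = bg[["acceptor"]],
        mask_coverage = mean(mask))
      utils::write.csv(summary, file.path(out, "fret_summary.csv"),
                       row.names = FALSE)
      list(mask_coverage = mean(mask), spearman_rho = gs$spearman_rho)
    },
    morpho = {
      ap <- ap_vector(config$morpho$ap_axis)
      res <- lapply(list(head = state$sheet_head, trunk = state$sheet_trunk),
                    function(tr) {
        ds <- deformation_summary(tr, ap_direction = ap)
        rec <- displacement_cosines(tr, ap_direction = ap,
                                    window_frames = config$morpho$window_frames)
        op <- order_profile(rec)
        list(summary = ds, order = op)
      })
      sumtab <- do.call(rbind, lapply(names(res), function(r) {
        ds <- res[[r]]$summary
        tibble::tibble(region = r,
                       major_change_pct = ds$major_change_pct,
                       minor_change_pct = ds$minor_change_pct,
                       mean_ecc_start = ds$mean_eccentricity_start,
                       mean_ecc_end = ds$mean_eccentricity_end,
                       mannwhitney_p = ds$mannwhitney_p,
                       mean_cell_area_index = ds$mean_cell_area_index,
                       mean_roi_area_index = ds$mean_roi_area_index,
                       order_verdict = res[[r]]$order$verdict,
                       split_ordinate = res[[r]]$order$split_ordinate)
      }))
      utils::write.csv(sumtab, file.path(out, "morpho_summary.csv"),
                       row.names = FALSE)
      for (r in names(res)) {
        utils::write.csv(res[[r]]$order$profile,
                         file.path(out, sprintf("morpho_order_%s.csv", r)),
                         row.names = FALSE)
      }
      list(regions = names(res))
    },
    expr = {
      qr <- qpcr_results(state$plate)
      qr$label <- classify_response(qr$fold_change)
      utils::write.csv(qr, file.path(out, "expr_qpcr.csv"), row.names = FALSE)
      cand <- candidate_filter(state$de, lfc_min = config$expr$lfc_min,
                               p_max = config$expr$p_max,
                               use_adjusted = config$expr$use_adjusted)
      utils::write.csv(cand, file.path(out, "expr_candidates.csv"),
                       row.names = FALSE)
      list(n_candidates = nrow(cand))
    })
}
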