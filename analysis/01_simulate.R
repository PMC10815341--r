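#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input with known ground truth.
#
# One seeded run of the synthetic-embryo generator produces the raw material
# for all downstream analyses: a gradient-sensor embryo (linear FRET index
# 0.45 -> 0.25 anterior to posterior, 2-fold uneven sensor expression, noise
# 2% of signal, autofluorescence backgrounds), a tension-insensitive control
# embryo (constant index 0.70), three uninjected background embryos,
# head-like (translating) and trunk-like (bidirectionally elongating) cell
# sheets at the study's per-region cell counts (136 / 56), a qPCR plate
# (E = 2, fold changes 3.0 / 0.33 / 1.0), and a DE table with 84 planted
# stretch-responsive genes among 10,000 nulls.

library(tensiomap)

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("generating FRET image pairs (256 x 512)...")
sensor <- generate_fret_pair(
  tension_field_spec(fret_min = 0.25, fret_max = 0.45,
                     profile_shape = "linear", noise_sd = 20,
                     density_unevenness = 2,
                     background_donor = 40, background_acceptor = 60),
  shape = c(256L, 512L), seed = seed)
control <- generate_fret_pair(
  tension_field_spec(fret_min = 0.70, fret_max = 0.70,
                     profile_shape = "constant", noise_sd = 20,
                     density_unevenness = 2,
                     background_donor = 40, background_acceptor = 60),
  shape = c(256L, 512L), seed = seed + 1L)

write_fret_tiff(sensor$images, file.path(out, "sensor_donor.tif"),
                file.path(out, "sensor_acceptor.tif"))
write_fret_tiff(control$images, file.path(out, "control_donor.tif"),
                file.path(out, "control_acceptor.tif"))
write.csv(sensor$truth, file.path(out, "sensor_truth_profile.csv"),
          row.names = FALSE)

message("generating cell sheets (head 136 cells, trunk 56 cells)...")
head_tr <- generate_cell_sheet(sheet_spec(136L, 300, 400),
                               deformation_preset("head"), seed = seed)
trunk_tr <- generate_cell_sheet(sheet_spec(56L, 300, 400),
                                deformation_preset("trunk", roi_height = 400),
                                seed = seed + 1L)
write_cell_tracks(head_tr, file.path(out, "cells_head.csv"))
write_cell_tracks(trunk_tr, file.path(out, "cells_trunk.csv"))

message("generating qPCR plate and DE table...")
plate <- generate_qpcr_plate(true_E = 2,
                             fold_changes = c(cdx4 = 3.0, gsc = 0.33,
                                              nullg = 1.0),
                             ct_noise_sd = 0.1, seed = seed)
write.csv(plate, file.path(out, "qpcr_plate.csv"), row.names = FALSE)
de <- generate_de_table(n_genes = 10000L, n_signal = 84L, seed = seed)
write.csv(de, file.path(out, "de_table.csv"), row.names = FALSE)

write_truth_sidecar(
  list(seed = seed,
       sensor = list(fret = c(0.45, 0.25), noise_sd = 20,
                     density_unevenness = 2, backgrounds = c(40, 60)),
       control_fret = 0.70,
       head = list(n_cells = 136L, mode = "translation",
                   lambda = c(0.9983, 0.8796)),
       trunk = list(n_cells = 56L, mode = "bidirectional_stretch",
                    lambda = c(1.1343, 0.8638), fixation_ordinate = 200),
       qpcr = list(true_E = 2, fold_changes = c(3.0, 0.33, 1.0)),
       de = list(n_genes = 10000L, n_signal = 84L)),
  file.path(out, "ground_truth.json"))

message("wrote synthetic datasets under ", out)
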