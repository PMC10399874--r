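#!/usr/bin/env Rscript

# Generate the example dataset for the downstream analysis scripts:
#  - N&B image stacks for monomer and tandem-dimer constructs (2 "days",
#    4 cells each), with per-subunit fluorescence probability 0.7
#  - one membrane line-scan kymograph (5e4 lines)
#  - ten point-FCS dye acquisitions (2 measurements x 5 x 4 s)
# Everything is written in the pipeline's exchange formats (TIFF + JSON
# sidecar, CSV), so the later scripts only ever see files.

library(fluctr)

out <- "results/example_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

p_true <- 0.7
cells_per_day <- 4L

cat("-- N&B stacks (lambda = 0.5 counts/dwell, occupancy 5) --\n")
meta <- NULL
seed <- 100L
for (day in c("day1", "day2")) {
  for (species in c("monomer", "dimer")) {
    for (i in seq_len(cells_per_day)) {
      seed <- seed + 1L
      cfg <- sim_config(seed = seed,
                        subunits = if (species == "dimer") 2L else 1L,
                        fluorescence_probability =
                          if (species == "dimer") p_true else 1)
      st <- simulate_nb_stack(cfg)
      f <- file.path(out, sprintf("nb_%s_%s_c%d.tif", day, species, i))
      write_stack(st, f)
      meta <- rbind(meta, data.frame(file = basename(f), day = day,
                                     species = species,
                                     cell_id = sprintf("%s_%s_c%d", day,
                                                       species, i)))
    }
  }
}
write.csv(meta, file.path(out, "nb_cells.csv"), row.names = FALSE)
cat("wrote", nrow(meta), "stacks\n")

cat("-- sFCS kymograph (D = 1 um^2/s, tau_d = 10 ms) --\n")
# same instrument geometry (S = 3) as the calibration below
cfg_m <- sim_config(seed = 500L, geometry = "membrane2d",
                    structure_parameter = 3)
tr <- simulate_membrane_trace(cfg_m, duration = 5e4 * cfg_m$line_time)
ky <- simulate_kymograph(tr, cfg_m)
write_kymograph(ky, file.path(out, "sfcs_cell1.tif"))
cat("ground truth: N =", attr(tr, "truth")$apparent_N,
    ", tau_d =", attr(tr, "truth")$tau_d * 1e3, "ms, B =",
    attr(tr, "truth")$apparent_brightness, "counts/s/molecule\n")

cat("-- point-FCS dye calibration traces (tau_d = 312.5 us, S = 3) --\n")
for (i in 1:10) {
  cfg_p <- sim_config(seed = 600L + i, geometry = "point3d",
                      diffusion_coefficient = 50, waist_w0 = 0.25,
                      structure_parameter = 3, n_particles_mean = 0.5,
                      molecular_brightness = 5e4)
  trp <- simulate_point_trace(cfg_p, duration = 4, dt = 4e-5)
  write_trace(trp, file.path(out, sprintf("calib_m%d_a%d.csv",
                                          (i - 1) %/% 5 + 1,
                                          (i - 1) %% 5 + 1)))
}
cat("done; dataset under", out, "\n")
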