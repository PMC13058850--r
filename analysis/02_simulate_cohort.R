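#!/usr/bin/env Rscript
# Stage 2: simulate a demonstration cohort and run the full pipeline.
#
# Two age-like groups with different planted 6-fold modulation amplitudes
# (a stronger grid signal in the younger group), two runs per participant
# on shared fixed trajectories, voxel orientations concentrated around a
# participant-specific group orientation. The full two-stage analysis runs
# for the 1-, 5-, 6- and 7-fold symmetries, with tSNR screening, temporal
# and spatial stability, and group statistics; everything lands under
# results/study/.

library(gridls)

cfg <- study_config(
  n_runs = 2,
  env = environment_config(),
  sim = simulation_config(n_voxels = 24, orientation_concentration = 8,
                          noise_sd = 1, ar1_coefficient = 0.3),
  groups = list(young = list(n = 12, modulation_amplitude = 0.5),
                older = list(n = 12, modulation_amplitude = 0.2)),
  folds = c(1, 5, 6, 7),
  seed = 7L)

res <- run_study(cfg, out_dir = file.path("results", "study"))

cat("cohort:", cfg$n_participants, "participants x", cfg$n_runs, "runs,",
    cfg$sim$n_voxels, "voxels (two hemispheres)\n\n")
cat("group statistics (run-averaged magnitudes):\n")
print(res$group_stats[, c("id", "family", "t", "df", "p", "d", "bf10",
                          "bf01", "significant")], digits = 3)
cat("\nmean temporal stability:",
    sprintf("%.3f", mean(res$stability$temporal_fraction)),
    "(chance 0.5); Rayleigh significant in",
    sprintf("%.0f%%", 100 * mean(res$stability$rayleigh_p < 0.05)),
    "of hemisphere x run cells\n")
cat("outputs under results/study/ (see manifest.json)\n")
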