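#!/usr/bin/env Rscript
# Stage 3: parameter recovery and fold specificity on a shared trajectory.
#
# Simulates participants with a planted 6-fold signal (kappa = 8 voxel
# concentration, amplitude 0.5, AR(1) noise of unit sd) on the fixed run-1
# trajectory and asks: how accurately does the split-half pipeline recover
# each participant's group orientation, and how much of the planted 6-fold
# signal appears in the 5- and 7-fold control analyses?

library(gridls)

dir.create("results", showWarnings = FALSE)
traj <- generate_trajectory(environment_config(), seed = 20101L)
probe <- simulate_bold(traj, simulation_config(n_voxels = 2), seed = 1)
halves <- split_run(probe, traj$events, warn_sparse = FALSE)
n1 <- halves$estimation$run$n_scans

folds <- c(5, 6, 7)
d_est <- lapply(folds, function(k)
  build_design(halves$estimation$events, k, n1, 1))
d_test <- lapply(folds, function(k)
  build_design(halves$test$events, k, halves$test$run$n_scans, 1,
               carryover_events = halves$test$carryover))
names(d_est) <- names(d_test) <- folds

n_subj <- 60
rows <- list()
for (i in seq_len(n_subj)) {
  sim <- simulation_config(orientation_concentration = 8,
                           modulation_amplitude = 0.5, noise_sd = 1,
                           n_voxels = 20)
  run <- simulate_bold(traj, sim, seed = 3000 + i)
  test_run <- structure(list(data = run$data[, (n1 + 1):run$n_scans],
                             TR = 1, n_scans = run$n_scans - n1),
                        class = "bold_run")
  for (k in folds) {
    mo <- mean_orientation(estimate_orientations(
      fit_glm(run$data[, seq_len(n1)], d_est[[as.character(k)]]), k = k),
      k = k)
    mag <- gls_magnitude(test_run, phi_bar = mo$phi_bar, k = k,
                         design = d_test[[as.character(k)]])$magnitude
    rows[[length(rows) + 1L]] <- data.frame(
      subject = i, fold = k, phi_bar = mo$phi_bar, magnitude = mag,
      orientation_error = if (k == 6)
        abs(circ_dist_fold(mo$phi_bar, run$ground_truth$group_orientation, 6))
      else NA_real_)
  }
}
rec <- do.call(rbind, rows)
write.csv(rec, "results/parameter_recovery.csv", row.names = FALSE)

err <- rec$orientation_error[rec$fold == 6]
cat(sprintf("orientation recovery (n = %d): median |error| %.2f deg in 60-deg space\n",
            n_subj, median(err)))
for (k in folds) {
  m <- rec$magnitude[rec$fold == k]
  ts <- one_sample_test(m)
  cat(sprintf("fold %d: mean magnitude %+.4f (SE %.4f), one-sided p = %.3g\n",
              k, mean(m), sd(m) / sqrt(length(m)), ts$p))
}
cat("\nNote: control-fold means reflect deterministic cross-fold leakage of\n")
cat("the planted 6-fold signal on a single fixed trajectory (see the methods\n")
cat("vignette); their sign and size are properties of the path, not noise.\n")
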