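# Shared fixtures, built once per test run.

.fixtures <- new.env()

# Default-design trajectory (the fixed path of one run), cached.
default_traj <- function(seed = 101) {
  key <- paste0("traj_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_trajectory(environment_config(), seed = seed)
  .fixtures[[key]]
}

# A short trajectory for design/GLM tests where full-length runs are
# unnecessary: 12 direction bins, 24 segments, 200 s.
quick_traj <- function(seed = 7) {
  key <- paste0("quick_", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- environment_config(run_length = 200, n_segments = 24,
                              bin_width = 30, segment_length_range = c(15, 30))
    .fixtures[[key]] <- generate_trajectory(cfg, seed = seed)
  }
  .fixtures[[key]]
}

# Noiseless run with a planted orientation: every voxel at theta_star.
planted_run <- function(traj, theta_star = 23, amplitude = 0.8,
                        n_voxels = 4, k = 6, seed = 5, noise_sd = 0,
                        kappa = Inf, drift_slope = 0.05, ...) {
  sim <- simulation_config(k = k, group_orientation = theta_star,
                           orientation_concentration = kappa,
                           modulation_amplitude = amplitude,
                           n_voxels = n_voxels, noise_sd = noise_sd,
                           ar1_coefficient = if (noise_sd > 0) 0.3 else 0,
                           drift_slope = drift_slope, ...)
  simulate_bold(traj, sim, seed = seed)
}

# Hand-rolled OLS for oracle comparisons.
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
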