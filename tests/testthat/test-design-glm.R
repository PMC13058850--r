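test_that("quadrature modulators weight events by sin/cos of k*direction", {
  # well-separated translations: at phi = 0 the sin modulator carries no
  # weight (sin 0 = 0); at phi = 15 with k = 6 the cos modulator carries none
  # (a third, oblique event keeps the design full-rank)
  ev <- data.frame(onset = c(5, 60, 115), duration = 2,
                   trial_type = "translation", direction = c(0, 15, 40))
  des <- build_design(ev, k = 6, n_scans = 170, TR = 1)
  X <- des$matrix
  w1 <- seq(1, 45)     # scans dominated by event 1's response
  w2 <- seq(56, 100)
  expect_equal(max(abs(X[w1, "sin"])), 0, tolerance = 1e-12)
  expect_equal(X[w2, "sin"], X[w2, "translation"], tolerance = 1e-9)
  expect_equal(max(abs(X[w2, "cos"])), 0, tolerance = 1e-9)
  expect_equal(X[w1, "cos"], X[w1, "translation"], tolerance = 1e-9)
})

test_that("a brief event's regressor reproduces the HRF shape", {
  got <- gridls:::.convolved_regressor(onsets = 10, durations = 0.1,
                                       weights = 1, n_scans = 60, TR = 1)
  t <- seq_len(60) - 1
  expected <- hrf_double_gamma(t - 10) * 0.1
  expect_gt(cor(got, expected), 0.9999)
  expect_lte(abs(which.max(got) - which.max(expected)), 1)
})

test_that("test design modulator aligns, opposes and quadratures correctly", {
  phi_bar <- 12
  ev <- data.frame(onset = c(5, 60, 115), duration = 2,
                   trial_type = "translation",
                   direction = c(phi_bar,            # aligned: weight 1
                                 phi_bar + 180 / 6,  # anti-phase: weight -1
                                 phi_bar + 90 / 6))  # quadrature: weight 0
  des <- build_test_design(ev, k = 6, phi_bar = phi_bar, n_scans = 170, TR = 1)
  X <- des$matrix
  w <- function(idx) X[idx, "aligned"] / X[idx, "translation"]
  expect_equal(unname(w(8:20)), rep(1, 13), tolerance = 1e-9)
  expect_equal(unname(w(63:75)), rep(-1, 13), tolerance = 1e-9)
  expect_equal(max(abs(X[118:130, "aligned"])), 0, tolerance = 1e-9)
})

test_that("events outside the scan window and rank-deficiency are rejected", {
  ev <- data.frame(onset = 100, duration = 30,
                   trial_type = "translation", direction = 0)
  expect_error(build_design(ev, 6, n_scans = 110, TR = 1), "100")
  # a single direction at phi = 0 makes the sin column identically zero
  expect_error(build_design(ev, 6, n_scans = 200, TR = 1), "sin")
})

test_that("glm betas match an independent normal-equations solver", {
  traj <- quick_traj()
  run <- planted_run(traj, theta_star = 30, amplitude = 0.6, n_voxels = 5,
                     noise_sd = 0.8, kappa = 8)
  des <- build_design(traj$events, 6, run$n_scans, run$TR)
  fit <- fit_glm(run, des)
  for (v in 1:5) {
    oracle <- ols_oracle(des$matrix, run$data[v, ])
    expect_equal(unname(fit$betas[v, ]), as.vector(oracle), tolerance = 1e-8)
  }
  expect_equal(fit$df, run$n_scans - ncol(des$matrix))
})

test_that("pure-noise quadrature betas are centred on zero", {
  traj <- quick_traj()
  sim <- simulation_config(modulation_amplitude = 0, n_voxels = 1000,
                           noise_sd = 1, ar1_coefficient = 0.3)
  run <- simulate_bold(traj, sim, seed = 77)
  des <- build_design(traj$events, 6, run$n_scans, run$TR)
  fit <- fit_glm(run, des)
  for (col in c("sin", "cos")) {
    m <- mean(fit$betas[, col])
    se <- sd(fit$betas[, col]) / sqrt(1000)
    expect_lt(abs(m), 4 * se + 1e-12)
  }
})

test_that("shifting all directions rotates betas in the quadrature plane", {
  traj <- quick_traj()
  run <- planted_run(traj, theta_star = 25, amplitude = 1, n_voxels = 2,
                     noise_sd = 0)
  delta <- 14
  ev2 <- traj$events
  sel <- ev2$trial_type == "translation"
  ev2$direction[sel] <- (ev2$direction[sel] + delta) %% 360
  des1 <- build_design(traj$events, 6, run$n_scans, run$TR)
  des2 <- build_design(ev2, 6, run$n_scans, run$TR)
  b1 <- fit_glm(run, des1)$betas[1, c("sin", "cos")]
  b2 <- fit_glm(run, des2)$betas[1, c("sin", "cos")]
  a <- deg2rad(6 * delta)
  rotated <- c(b1["sin"] * cos(a) + b1["cos"] * sin(a),
               b1["cos"] * cos(a) - b1["sin"] * sin(a))
  expect_equal(unname(b2), unname(rotated), tolerance = 1e-8)
})

test_that("linear trends in the data leave quadrature betas unchanged", {
  traj <- quick_traj()
  run <- planted_run(traj, theta_star = 25, amplitude = 1, n_voxels = 2,
                     noise_sd = 0.5, kappa = 20)
  des <- build_design(traj$events, 6, run$n_scans, run$TR)
  b0 <- fit_glm(run, des)$betas
  run$data <- run$data + matrix(rep(0.7 * seq_len(run$n_scans), each = 2), 2)
  b1 <- fit_glm(run, des)$betas
  expect_lt(max(abs(b1[, c("sin", "cos")] - b0[, c("sin", "cos")])), 1e-6)
})

test_that("run/design size mismatches are caught", {
  traj <- quick_traj()
  run <- planted_run(traj, n_voxels = 2)
  des <- build_design(traj$events, 6, run$n_scans, run$TR)
  run$data <- run$data[, 1:190]
  expect_error(fit_glm(run, des), "scans")
})
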