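test_that("orientations derive from quadrature betas by atan2/k", {
  est <- estimate_orientations(c(0, 1, -1, 3), c(1, 0, 0, 4), k = 6)
  expect_equal(est$theta, c(0, 15, 45, rad2deg(atan2(3, 4)) / 6),
               tolerance = 1e-12)
  expect_equal(est$amplitude, c(1, 1, 1, 5))
  expect_true(all(est$valid))

  # both betas zero: orientation undefined, voxel flagged
  est0 <- estimate_orientations(c(0, 1), c(0, 0), k = 6)
  expect_false(est0$valid[1])
  expect_true(is.na(est0$theta[1]))
  expect_equal(est0$theta[2], 15)
})

test_that("the mean orientation is the amplitude-weighted circular mean", {
  expect_equal(mean_orientation(10, 1, k = 6)$phi_bar, 10)
  expect_equal(mean_orientation(c(0, 10), c(1, 1), k = 6)$phi_bar, 5)
  # antipodal pair in 6-fold space: no defined mean
  expect_error(mean_orientation(c(0, 30), c(1, 1), k = 6), "dispersed")

  # weighted mean matches a dense maximisation of sum(w * cos(k(theta - phi)))
  th <- c(0, 10); w <- c(3, 1)
  got <- mean_orientation(th, w, k = 6)$phi_bar
  grid <- seq(0, 60, by = 0.01)
  score <- vapply(grid, function(p) sum(w * cos(deg2rad(6 * (th - p)))),
                  numeric(1))
  expect_equal(got, grid[which.max(score)], tolerance = 0.01)

  # invalid voxels and zero weights drop out
  expect_equal(mean_orientation(c(5, NA, 40), c(1, 1, 0), k = 6)$phi_bar, 5)
})

test_that("runs split at the midpoint with boundary-straddling truncation", {
  traj <- default_traj()
  run <- planted_run(traj, n_voxels = 2)
  halves <- split_run(run, traj$events, warn_sparse = FALSE)
  expect_equal(halves$estimation$run$n_scans, 310)
  expect_equal(halves$test$run$n_scans, 310)
  expect_equal(halves$boundary_time, 310)

  ev1 <- halves$estimation$events; ev2 <- halves$test$events
  # partition: every event lands in exactly one half
  expect_equal(nrow(ev1) + nrow(ev2), nrow(traj$events))
  expect_true(all(ev1$onset < 310))
  expect_true(all(ev1$onset + ev1$duration <= 310 + 1e-9))
  expect_true(all(ev2$onset >= 0))
  # carry-over copy holds the estimation events on the test clock
  expect_equal(nrow(halves$test$carryover), nrow(ev1))
  expect_true(all(halves$test$carryover$onset < 0))

  # an explicit straddling event is truncated, not moved
  ev <- data.frame(onset = c(1, 299.5), duration = c(2, 3),
                   trial_type = "translation", direction = c(10, 50))
  run600 <- structure(list(data = matrix(0, 1, 600), TR = 1, n_scans = 600),
                      class = "bold_run")
  h <- split_run(run600, ev, warn_sparse = FALSE)
  expect_equal(nrow(h$estimation$events), 2)
  expect_equal(h$estimation$events$duration[2], 0.5)
  expect_equal(nrow(h$test$events), 0)

  # sparse direction sampling in a half is flagged, not fatal
  expect_warning(split_run(run600, ev), "empty")
})

test_that("noiseless planted runs are recovered exactly end to end", {
  traj <- default_traj()
  theta_star <- 23; A <- 0.8
  run <- planted_run(traj, theta_star = theta_star, amplitude = A,
                     n_voxels = 4)
  halves <- split_run(run, traj$events, warn_sparse = FALSE)
  d1 <- build_design(halves$estimation$events, 6,
                     halves$estimation$run$n_scans, run$TR)
  mo <- mean_orientation(estimate_orientations(
    fit_glm(halves$estimation$run, d1), k = 6))
  expect_equal(mo$phi_bar, theta_star, tolerance = 1e-6)

  gls <- gls_magnitude(halves$test$run, halves$test$events,
                       phi_bar = mo$phi_bar, k = 6,
                       carryover_events = halves$test$carryover)
  expect_equal(gls$magnitude, A, tolerance = 1e-6)

  anti <- gls_magnitude(halves$test$run, halves$test$events,
                        phi_bar = wrap_fold(mo$phi_bar + 30, 6), k = 6,
                        carryover_events = halves$test$carryover)
  expect_equal(anti$magnitude, -A, tolerance = 1e-6)
})

test_that("diagnostic same-half scoring of planted data is non-negative", {
  traj <- default_traj()
  run <- planted_run(traj, theta_star = 51, amplitude = 0.5, n_voxels = 6,
                     noise_sd = 1, kappa = 8, seed = 31)
  halves <- split_run(run, traj$events, warn_sparse = FALSE)
  d1 <- build_design(halves$estimation$events, 6,
                     halves$estimation$run$n_scans, run$TR)
  mo <- mean_orientation(estimate_orientations(
    fit_glm(halves$estimation$run, d1), k = 6))
  self <- gls_magnitude(halves$estimation$run, halves$estimation$events,
                        phi_bar = mo$phi_bar, k = 6)
  expect_gte(self$magnitude, 0)
})

test_that("orientation estimates equal a brute-force grid search", {
  # the quadrature solution must coincide with the least-squares optimum
  # over (amplitude >= 0, orientation) found by scanning orientations
  traj <- quick_traj()
  run <- planted_run(traj, theta_star = 33, amplitude = 0.5, n_voxels = 10,
                     noise_sd = 1, kappa = 5, seed = 21)
  des <- build_design(traj$events, 6, run$n_scans, run$TR)
  fit <- fit_glm(run, des)
  est <- estimate_orientations(fit, k = 6)

  X <- des$matrix
  nuis <- X[, !colnames(X) %in% c("sin", "cos"), drop = FALSE]
  Q <- qr.Q(qr(nuis))
  resid <- function(v) v - Q %*% (t(Q) %*% v)
  Ct <- resid(X[, "cos"]); St <- resid(X[, "sin"])
  grid <- seq(0, 60, by = 0.02)
  for (v in 1:10) {
    y <- resid(run$data[v, ])
    rss <- vapply(grid, function(th) {
      m <- cos(deg2rad(6 * th)) * Ct + sin(deg2rad(6 * th)) * St
      a <- max(0, sum(m * y) / sum(m * m))
      sum((y - a * m)^2)
    }, numeric(1))
    best <- grid[which.min(rss)]
    expect_lt(abs(circ_dist_fold(best, est$theta[v], 6)), 0.05)
  }
})

test_that("participant-level analysis averages runs and respects labels", {
  traj <- default_traj()
  sim <- simulation_config(group_orientation = 12, n_voxels = 12,
                           modulation_amplitude = 0.5, noise_sd = 0.5)
  runA <- simulate_bold(traj, sim, seed = 61)
  runB <- simulate_bold(traj, sim, seed = 62)
  masks <- list(left = 1:6, right = 7:12)

  # two identical runs: the run-average equals either run
  res_same <- run_participant(list(runA, runA),
                              list(traj$events, traj$events),
                              masks, folds = 6)
  expect_equal(res_same$participant_level$magnitude,
               res_same$cells$magnitude[res_same$cells$run == 1],
               tolerance = 1e-12)

  res <- run_participant(list(runA, runB), list(traj$events, traj$events),
                         masks, folds = c(5, 6))
  expect_equal(nrow(res$cells), 2 * 2 * 2)   # hemisphere x run x fold
  avg <- res$participant_level
  for (i in seq_len(nrow(avg))) {
    sel <- res$cells$hemisphere == avg$hemisphere[i] &
      res$cells$fold == avg$fold[i]
    expect_equal(avg$magnitude[i], mean(res$cells$magnitude[sel]))
  }

  # swapping hemisphere masks swaps labels exactly
  res_sw <- run_participant(list(runA, runB), list(traj$events, traj$events),
                            list(left = 7:12, right = 1:6), folds = c(5, 6))
  a <- res$cells[order(res$cells$hemisphere, res$cells$run, res$cells$fold), ]
  b <- res_sw$cells[res_sw$cells$hemisphere == "right", ]
  b2 <- res$cells[res$cells$hemisphere == "left", ]
  expect_equal(b$magnitude[order(b$run, b$fold)],
               b2$magnitude[order(b2$run, b2$fold)], tolerance = 1e-12)
})
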