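test_that("default trajectory matches the passive-navigation task design", {
  traj <- default_traj()
  ev <- traj$events
  trans <- ev[ev$trial_type == "translation", ]
  rot <- ev[ev$trial_type == "rotation", ]

  expect_equal(nrow(trans), 112)
  bins <- tabulate(floor(trans$direction / 10) + 1L, 36)
  expect_true(all(bins %in% c(3L, 4L)))
  expect_equal(sum(bins), 112)

  expect_true(all(abs(rot$direction) >= 10 - 1e-9))
  expect_true(all(abs(rot$direction) <= 170 + 1e-9))
  # consecutive translations have distinct directions by construction
  expect_true(all(diff(trans$direction) != 0))

  expect_equal(sum(ev$duration), 620)
  expect_true(is.unsorted(ev$onset) == FALSE)
  expect_equal(ev$onset[-1], (ev$onset + ev$duration)[-nrow(ev)],
               tolerance = 1e-12)

  pos <- c(ev$x_start, ev$x_end, ev$y_start, ev$y_end)
  expect_true(all(pos >= 2 - 1e-9 & pos <= 158 + 1e-9))

  # durations follow the stated speeds
  seg_len <- sqrt((trans$x_end - trans$x_start)^2 +
                    (trans$y_end - trans$y_start)^2)
  expect_equal(trans$duration, seg_len / 15, tolerance = 1e-9)
  expect_equal(rot$duration, abs(rot$direction) / 50, tolerance = 1e-9)
})

test_that("direction balance holds across seeds and configurations", {
  for (seed in c(2, 3, 4)) {
    traj <- generate_trajectory(environment_config(), seed = seed)
    d <- traj$events$direction[traj$events$trial_type == "translation"]
    bins <- tabulate(floor(d / 10) + 1L, 36)
    expect_true(all(bins %in% c(3L, 4L)))
  }
  # 36 bins x exactly 3 each
  cfg <- environment_config(n_segments = 108)
  traj <- generate_trajectory(cfg, seed = 1)
  d <- traj$events$direction[traj$events$trial_type == "translation"]
  expect_equal(length(d), 108)
  expect_true(all(tabulate(floor(d / 10) + 1L, 36) == 3L))
})

test_that("trajectory generation is deterministic in (config, seed)", {
  a <- generate_trajectory(environment_config(), seed = 33)
  b <- generate_trajectory(environment_config(), seed = 33)
  expect_identical(a$events, b$events)
  c0 <- generate_trajectory(environment_config(), seed = 34)
  expect_false(identical(a$events, c0$events))
})

test_that("invalid environment configurations are rejected", {
  expect_error(environment_config(bin_width = 7), "divide 360")
  expect_error(environment_config(min_rotation = 0), "rotation bounds")
  expect_error(environment_config(max_rotation = 180), "rotation bounds")
  expect_error(environment_config(n_segments = 10), "per direction bin")
  expect_error(environment_config(segment_length_range = c(200, 300)),
               "usable room extent")
})

test_that("coverage of a stationary position equals a brute-force disc", {
  cfg <- environment_config()
  ev <- data.frame(onset = 0, duration = 620, trial_type = "rest",
                   direction = NA_real_, x_start = 80, y_start = 80,
                   x_end = 80, y_end = 80)
  traj <- structure(list(events = ev, config = cfg, seed = 0),
                    class = "trajectory")
  got <- compute_coverage(traj)
  # oracle: every 1x1 vm bin centre within 3 vm of (80, 80)
  centers <- expand.grid(x = seq_len(160) - 0.5, y = seq_len(160) - 0.5)
  oracle <- sum((centers$x - 80)^2 + (centers$y - 80)^2 <= 9) / 160^2
  expect_equal(got, oracle)
})

test_that("coverage saturates, is monotone, and respects room symmetry", {
  cfg <- environment_config()
  # rows of horizontal sweeps 2 vm apart: the 3 vm disc covers everything
  rows <- seq(1, 159, by = 2)
  ev_full <- data.frame(onset = seq_along(rows) - 1, duration = 1,
                        trial_type = "translation", direction = 0,
                        x_start = 0, y_start = rows, x_end = 160, y_end = rows)
  traj_full <- structure(list(events = ev_full, config = cfg), class = "trajectory")
  expect_equal(compute_coverage(traj_full), 1.0)

  traj <- default_traj()
  sub <- traj
  sub$events <- traj$events[1:20, ]
  expect_lte(compute_coverage(sub), compute_coverage(traj))

  # single central segment rotated by 90 degrees covers the same area
  seg <- function(dir, x0, y0, x1, y1)
    structure(list(events = data.frame(
      onset = 0, duration = 2, trial_type = "translation", direction = dir,
      x_start = x0, y_start = y0, x_end = x1, y_end = y1),
      config = cfg), class = "trajectory")
  expect_equal(compute_coverage(seg(0, 65, 80, 95, 80)),
               compute_coverage(seg(90, 80, 65, 80, 95)))

  empty <- structure(list(events = ev_full[0, ], config = cfg),
                     class = "trajectory")
  expect_warning(cov0 <- compute_coverage(empty), "empty")
  expect_equal(cov0, 0)
})

test_that("realised coverage of the default design is in a plausible range", {
  # the printed task layout exposes roughly three quarters of the room
  cov <- compute_coverage(default_traj())
  expect_gt(cov, 0.6)
  expect_lt(cov, 0.95)
})
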