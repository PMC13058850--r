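#' Configuration of the virtual environment and trajectory design
#'
#' Describes the passive-navigation task geometry: a square room in virtual
#' meters (vm), alternating translation and rotation segments, movement
#' directions balanced across angular bins, and the coverage geometry used to
#' summarise how much of the room a path exposes.
#'
#' @param room_side side of the square room, vm.
#' @param translation_speed translation speed, vm/s.
#' @param rotation_speed rotation speed, deg/s.
#' @param run_length total scheduled run duration, s.
#' @param n_segments number of translation segments per run.
#' @param bin_width width of the direction bins, degrees; must divide 360.
#' @param coverage_radius radius of the visibility disc around the current
#'   position, vm.
#' @param coverage_cone_length length of the forward visibility cone, vm.
#' @param coverage_cone_width full angular width of the cone, degrees
#'   (i.e. +/- half this value about the heading).
#' @param min_rotation,max_rotation bounds on the magnitude of the turn
#'   between consecutive translations, degrees; exact reversals (180 deg)
#'   are excluded by `max_rotation < 180`.
#' @param segment_length_range `c(min, max)` translation length, vm; the
#'   default gives a realised mean segment length close to 50 vm (wall
#'   clamping pulls the realised mean below the interval midpoint).
#' @param margin buffer kept between the path and the walls, vm.
#' @return an object of class `environment_config` (a validated list).
#' @export
environment_config <- function(room_side = 160,
                               translation_speed = 15,
                               rotation_speed = 50,
                               run_length = 620,
                               n_segments = 112,
                               bin_width = 10,
                               coverage_radius = 3,
                               coverage_cone_length = 8,
                               coverage_cone_width = 65,
                               min_rotation = 10,
                               max_rotation = 170,
                               segment_length_range = c(32, 76),
                               margin = 2) {
  cfg <- list(room_side = room_side, translation_speed = translation_speed,
              rotation_speed = rotation_speed, run_length = run_length,
              n_segments = n_segments, bin_width = bin_width,
              coverage_radius = coverage_radius,
              coverage_cone_length = coverage_cone_length,
              coverage_cone_width = coverage_cone_width,
              min_rotation = min_rotation, max_rotation = max_rotation,
              segment_length_range = segment_length_range, margin = margin)
  if (room_side <= 0) stop("room_side must be positive")
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  if (!(min_rotation > 0 && min_rotation <= max_rotation && max_rotation < 180))
    stop("rotation bounds must satisfy 0 < min_rotation <= max_rotation < 180")
  if (length(segment_length_range) != 2 ||
      segment_length_range[1] <= 0 ||
      diff(segment_length_range) < 0)
    stop("segment_length_range must be an increasing positive pair")
  n_bins <- 360 / bin_width
  if (n_segments < n_bins)
    stop("n_segments must allow at least one segment per direction bin")
  if (segment_length_range[2] > room_side - 2 * margin)
    stop("segment_length_range exceeds the usable room extent")
  structure(cfg, class = "environment_config")
}

#' @export
print.environment_config <- function(x, ...) {
  cat(sprintf(
    "<environment_config> %g x %g vm room, %d segments over %d direction bins\n",
    x$room_side, x$room_side, x$n_segments, 360 %/% x$bin_width))
  cat(sprintf("  speeds: %g vm/s translation, %g deg/s rotation; run %g s\n",
              x$translation_speed, x$rotation_speed, x$run_length))
  invisible(x)
}

# Allocate n_segments over the direction bins so every bin receives
# floor(n/bins) or floor(n/bins)+1 segments; the bins carrying the extra
# segment are chosen at random.
.allocate_bins <- function(n_segments, n_bins) {
  base <- n_segments %/% n_bins
  extra <- n_segments %% n_bins
  counts <- rep(base, n_bins)
  if (extra > 0) counts[sample.int(n_bins, extra)] <- base + 1L
  counts
}

# Order the sampled directions and walk them through the room in one greedy
# pass: each next direction is drawn among the remaining ones whose
# shortest-arc turn from the current heading lies in
# [min_rotation, max_rotation] and which leave room for at least the minimum
# segment length. Dead ends abort the pass (the caller restarts).
.walk_directions <- function(dirs, config) {
  n <- length(dirs)
  side <- config$room_side; margin <- config$margin
  rng <- config$segment_length_range
  x <- stats::runif(1, side * 0.25, side * 0.75)
  y <- stats::runif(1, side * 0.25, side * 0.75)
  ord <- numeric(n); len <- numeric(n)
  xs <- numeric(n); ys <- numeric(n); xe <- numeric(n); ye <- numeric(n)
  remaining <- dirs
  heading <- NULL
  for (i in seq_len(n)) {
    ok_turn <- if (is.null(heading)) rep(TRUE, length(remaining)) else {
      turns <- abs(circ_dist_fold(remaining, heading, k = 1))
      turns >= config$min_rotation & turns <= config$max_rotation
    }
    cand <- which(ok_turn)
    if (length(cand) > 1L) cand <- sample(cand)   # random tie-break
    pick <- 0L
    for (j in cand) {
      lmax <- min(rng[2], .max_in_room_length(x, y, remaining[j], side, margin))
      if (lmax >= rng[1]) { pick <- j; break }
    }
    if (pick == 0L) return(NULL)                  # cornered: restart pass
    d <- remaining[pick]
    ord[i] <- d
    len[i] <- stats::runif(1, rng[1], lmax)
    xs[i] <- x; ys[i] <- y
    x <- x + len[i] * cos(deg2rad(d))
    y <- y + len[i] * sin(deg2rad(d))
    xe[i] <- x; ye[i] <- y
    heading <- d
    remaining <- remaining[-pick]
  }
  list(dirs = ord, xs = xs, ys = ys, xe = xe, ye = ye, len = len)
}

# Longest translation from (x, y) along heading `dir` (degrees) that keeps
# the endpoint inside [margin, side - margin]^2.
.max_in_room_length <- function(x, y, dir, side, margin) {
  dx <- cos(deg2rad(dir)); dy <- sin(deg2rad(dir))
  lo <- margin; hi <- side - margin
  lim <- function(pos, d) {
    if (abs(d) < 1e-12) return(Inf)
    if (d > 0) (hi - pos) / d else (lo - pos) / d
  }
  max(0, min(lim(x, dx), lim(y, dy)))
}

#' Generate a direction-balanced passive-navigation trajectory
#'
#' Produces the fixed trajectory of one run: `n_segments` translation
#' segments whose allocentric directions are balanced over the direction
#' bins (each bin receives `floor(n/bins)` or one more segment, directions
#' drawn uniformly inside their bin), separated by shortest-arc rotations
#' whose magnitude lies in `[min_rotation, max_rotation]`, all inside the
#' room, with a trailing stationary rest event padding the schedule to
#' exactly `run_length` seconds.
#'
#' @param config an [environment_config()].
#' @param seed integer seed; the trajectory is a deterministic function of
#'   `(config, seed)`.
#' @return an object of class `trajectory`: a list with `events` (data frame
#'   with columns `onset`, `duration`, `trial_type`, `direction`, `x_start`,
#'   `y_start`, `x_end`, `y_end`), `config` and `seed`. For translation rows
#'   `direction` is the allocentric heading in `[0, 360)`; for rotation rows
#'   it is the signed turn in degrees; for the rest row it is `NA`.
#' @export
#' @examples
#' traj <- generate_trajectory(environment_config(), seed = 1)
#' table(cut(subset(traj$events, trial_type == "translation")$direction,
#'           seq(0, 360, 10)))
generate_trajectory <- function(config = environment_config(), seed = 1L) {
  stopifnot(inherits(config, "environment_config"))
  with_seed(seed, .generate_trajectory_impl(config, seed))
}

.generate_trajectory_impl <- function(config, seed, max_restarts = 50L) {
  n_bins <- 360 %/% config$bin_width
  for (attempt in seq_len(max_restarts)) {
    counts <- .allocate_bins(config$n_segments, n_bins)
    bin_lo <- rep((seq_len(n_bins) - 1L) * config$bin_width, counts)
    dirs <- bin_lo + stats::runif(config$n_segments, 0, config$bin_width)
    path <- .walk_directions(dirs, config)
    if (is.null(path)) next
    ev <- .schedule_events(path$dirs, path, config)
    if (is.null(ev)) next
    return(structure(list(events = ev, config = config, seed = seed),
                     class = "trajectory"))
  }
  stop("trajectory generation infeasible after ", max_restarts,
       " restarts: could not satisfy segment_length_range inside the room ",
       "with the rotation-magnitude constraint")
}

.schedule_events <- function(dirs, path, config) {
  n <- length(dirs)
  turn <- circ_dist_fold(dirs[-1], dirs[-n], k = 1)   # signed shortest arc
  t_trans <- path$len / config$translation_speed
  t_rot <- abs(turn) / config$rotation_speed
  total <- sum(t_trans) + sum(t_rot)
  if (total > config$run_length) return(NULL)         # over-long: restart
  n_events <- 2L * n                                   # n trans + (n-1) rot + rest
  onset <- numeric(n_events); duration <- numeric(n_events)
  trial_type <- character(n_events); direction <- numeric(n_events)
  x0 <- numeric(n_events); y0 <- numeric(n_events)
  x1 <- numeric(n_events); y1 <- numeric(n_events)
  tcur <- 0; j <- 1L
  for (i in seq_len(n)) {
    onset[j] <- tcur; duration[j] <- t_trans[i]
    trial_type[j] <- "translation"; direction[j] <- dirs[i]
    x0[j] <- path$xs[i]; y0[j] <- path$ys[i]
    x1[j] <- path$xe[i]; y1[j] <- path$ye[i]
    tcur <- tcur + t_trans[i]; j <- j + 1L
    if (i < n) {
      onset[j] <- tcur; duration[j] <- t_rot[i]
      trial_type[j] <- "rotation"; direction[j] <- turn[i]
      x0[j] <- path$xe[i]; y0[j] <- path$ye[i]
      x1[j] <- path$xe[i]; y1[j] <- path$ye[i]
      tcur <- tcur + t_rot[i]; j <- j + 1L
    }
  }
  onset[j] <- tcur; duration[j] <- config$run_length - tcur
  trial_type[j] <- "rest"; direction[j] <- NA_real_
  x0[j] <- path$xe[n]; y0[j] <- path$ye[n]
  x1[j] <- path$xe[n]; y1[j] <- path$ye[n]
  data.frame(onset = onset, duration = duration, trial_type = trial_type,
             direction = direction, x_start = x0, y_start = y0,
             x_end = x1, y_end = y1)
}

#' @export
print.trajectory <- function(x, ...) {
  tr <- x$events$trial_type
  cat(sprintf(
    "<trajectory> %d translations, %d rotations, %.1f s scheduled (seed %s)\n",
    sum(tr == "translation"), sum(tr == "rotation"),
    sum(x$events$duration), format(x$seed)))
  invisible(x)
}

#' Fraction of the room exposed by a trajectory
#'
#' Discretises the room into 1 x 1 vm bins and marks a bin covered when, at
#' any point sampled along the path (0.5 vm steps along translations; the
#' position of rest events), its centre lies within `coverage_radius` of the
#' position, or — during translations — inside the forward cone of length
#' `coverage_cone_length` and full width `coverage_cone_width` aimed along
#' the heading.
#'
#' @param trajectory a [generate_trajectory()] result.
#' @param config geometry; defaults to the trajectory's own config.
#' @return covered fraction in `[0, 1]`.
#' @export
compute_coverage <- function(trajectory, config = trajectory$config) {
  ev <- trajectory$events
  trans <- ev[ev$trial_type == "translation", , drop = FALSE]
  rest <- ev[ev$trial_type == "rest", , drop = FALSE]
  if (nrow(trans) + nrow(rest) == 0L) {
    warning("empty trajectory: coverage is 0")
    return(0)
  }
  side <- as.integer(round(config$room_side))
  covered <- matrix(FALSE, side, side)
  step <- 0.5
  mark <- function(covered, x, y, heading) {
    reach <- max(config$coverage_radius, config$coverage_cone_length)
    ix <- seq(max(1L, floor(x - reach)), min(side, ceiling(x + reach) + 1L))
    iy <- seq(max(1L, floor(y - reach)), min(side, ceiling(y + reach) + 1L))
    cx <- ix - 0.5; cy <- iy - 0.5
    dx <- outer(cx - x, rep(1, length(iy)))
    dy <- outer(rep(1, length(ix)), cy - y)
    d2 <- dx^2 + dy^2
    hit <- d2 <= config$coverage_radius^2
    if (!is.na(heading)) {
      ang <- rad2deg(atan2(dy, dx))
      dang <- abs(circ_dist_fold(ang, heading, k = 1))
      hit <- hit | (d2 <= config$coverage_cone_length^2 &
                      dang <= config$coverage_cone_width / 2)
    }
    covered[ix, iy] <- covered[ix, iy] | hit
    covered
  }
  for (i in seq_len(nrow(trans))) {
    len <- sqrt((trans$x_end[i] - trans$x_start[i])^2 +
                  (trans$y_end[i] - trans$y_start[i])^2)
    n_samp <- max(2L, ceiling(len / step) + 1L)
    tt <- seq(0, 1, length.out = n_samp)
    px <- trans$x_start[i] + tt * (trans$x_end[i] - trans$x_start[i])
    py <- trans$y_start[i] + tt * (trans$y_end[i] - trans$y_start[i])
    for (s in seq_len(n_samp))
      covered <- mark(covered, px[s], py[s], trans$direction[i])
  }
  for (i in seq_len(nrow(rest)))
    covered <- mark(covered, rest$x_start[i], rest$y_start[i], NA_real_)
  sum(covered) / length(covered)
}
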