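#' Per-voxel grid orientation and amplitude from quadrature betas
#'
#' Orientation is the phase of the k-fold modulation,
#' `theta_v = atan2(beta_sin, beta_cos) / k` mapped into `[0, 360/k)`
#' (the two-argument arctangent keeps the full fundamental domain);
#' amplitude is `sqrt(beta_sin^2 + beta_cos^2)`. Voxels with both betas
#' exactly zero have no defined orientation and are flagged invalid.
#'
#' @param beta_sin,beta_cos per-voxel coefficients of the `sin(k*phi)` and
#'   `cos(k*phi)` modulators (or a `glm_fit`, from which the `sin`/`cos`
#'   columns are taken).
#' @param k fold symmetry.
#' @return object of class `grid_estimate`: data frame with `theta`
#'   (degrees in `[0, 360/k)`), `amplitude`, `valid`; attribute `k`.
#' @export
#' @examples
#' estimate_orientations(c(0, 1), c(1, 0), k = 6)  # 0 and 15 degrees
estimate_orientations <- function(beta_sin, beta_cos = NULL, k = 6) {
  if (inherits(beta_sin, "glm_fit")) {
    fit <- beta_sin
    beta_sin <- fit$betas[, "sin"]
    beta_cos <- fit$betas[, "cos"]
  }
  stopifnot(length(beta_sin) == length(beta_cos),
            all(is.finite(beta_sin)), all(is.finite(beta_cos)))
  valid <- !(beta_sin == 0 & beta_cos == 0)
  theta <- wrap_fold(rad2deg(atan2(beta_sin, beta_cos)) / k, k)
  theta[!valid] <- NA_real_
  out <- data.frame(theta = theta,
                    amplitude = sqrt(beta_sin^2 + beta_cos^2),
                    valid = valid)
  structure(out, class = c("grid_estimate", "data.frame"), k = k)
}

#' Amplitude-weighted mean grid orientation
#'
#' Weighted circular mean in k-fold angle space:
#' `phi_bar = atan2(sum(w sin(k theta)), sum(w cos(k theta))) / k`,
#' mapped into `[0, 360/k)`. The resultant length (weighted mean of the unit
#' vectors) is returned as a dispersion diagnostic; a resultant below
#' `min_resultant` means the orientations cancel and no mean is defined.
#'
#' @param theta per-voxel orientations, degrees (a vector or a
#'   `grid_estimate`, whose amplitudes then serve as default weights).
#' @param weights non-negative weights (amplitudes); zero-weight and
#'   invalid voxels drop out of the average.
#' @param k fold symmetry.
#' @param min_resultant tolerance below which the mean is declared undefined.
#' @return list with `phi_bar` (degrees in `[0, 360/k)`), `resultant`,
#'   `n_voxels` used.
#' @export
mean_orientation <- function(theta, weights = NULL, k = 6,
                             min_resultant = 1e-10) {
  if (inherits(theta, "grid_estimate")) {
    k <- attr(theta, "k")
    if (is.null(weights)) weights <- theta$amplitude
    theta <- theta$theta
  }
  if (is.null(weights)) weights <- rep(1, length(theta))
  stopifnot(length(weights) == length(theta), all(weights >= 0, na.rm = TRUE))
  keep <- is.finite(theta) & is.finite(weights) & weights > 0
  if (!any(keep)) stop("no valid voxels to average")
  theta <- theta[keep]; w <- weights[keep]
  ang <- deg2rad(theta * k)
  s <- sum(w * sin(ang)); c0 <- sum(w * cos(ang))
  resultant <- sqrt(s^2 + c0^2) / sum(w)
  if (resultant < min_resultant)
    stop("mean orientation undefined: orientations are fully dispersed ",
         "(resultant length ", format(resultant), ")")
  list(phi_bar = wrap_fold(rad2deg(atan2(s, c0)) / k, k),
       resultant = resultant, n_voxels = sum(keep))
}

#' Split a run and its events into estimation and test halves
#'
#' Scans split at `floor(n_scans / 2)`; events belong to the half containing
#' their onset, and an event straddling the boundary is truncated at the
#' boundary and kept in the first half. Second-half onsets are re-expressed
#' relative to the start of that half. The split direction is fixed (first
#' half estimates, second half tests); no reverse fold.
#'
#' @param run a `bold_run`.
#' @param events events data frame aligned to the run's clock.
#' @param warn_sparse warn when a half leaves some direction bin without any
#'   translation event (`bin_width` degrees, default 10).
#' @param bin_width direction-bin width used for the sparseness check.
#' @return list with `estimation` and `test`, each a list of `run`
#'   (a `bold_run` restricted to that half) and `events`; the test half
#'   additionally carries `carryover`: the estimation-half events (original
#'   durations) on the test clock (negative onsets), so test designs can
#'   model the hemodynamic tails bleeding across the boundary. Also
#'   `boundary_time` (s) and `empty_bins` counts per half.
#' @export
split_run <- function(run, events, warn_sparse = TRUE, bin_width = 10) {
  stopifnot(inherits(run, "bold_run"), run$n_scans > 2)
  n1 <- floor(run$n_scans / 2)
  boundary <- n1 * run$TR
  first <- events$onset < boundary
  ev1 <- events[first, , drop = FALSE]
  ev1$duration <- pmin(ev1$duration, boundary - ev1$onset)
  carry <- events[first, , drop = FALSE]
  carry$onset <- carry$onset - boundary
  ev2 <- events[!first, , drop = FALSE]
  ev2$onset <- ev2$onset - boundary
  half_run <- function(idx) {
    structure(list(data = run$data[, idx, drop = FALSE], TR = run$TR,
                   n_scans = length(idx), mask_labels = run$mask_labels,
                   ground_truth = run$ground_truth),
              class = "bold_run")
  }
  empty_bins <- vapply(list(ev1, ev2), function(ev) {
    d <- ev$direction[ev$trial_type == "translation"]
    sum(tabulate(floor(d %% 360 / bin_width) + 1L, 360 %/% bin_width) == 0L)
  }, integer(1))
  if (warn_sparse && any(empty_bins > 0))
    warning(sprintf(
      "sparse direction sampling after split: %d (estimation) / %d (test) empty %g-degree bins",
      empty_bins[1], empty_bins[2], bin_width))
  list(estimation = list(run = half_run(seq_len(n1)), events = ev1),
       test = list(run = half_run((n1 + 1L):run$n_scans), events = ev2,
                   carryover = carry),
       boundary_time = boundary, empty_bins = empty_bins)
}

#' Cross-validated grid-like signal magnitude (GLM2)
#'
#' Fits the test model with modulator `cos(k*(phi - phi_bar))` to every
#' voxel of the test half and averages the modulator coefficient over the
#' ROI (unweighted voxel mean). Positive magnitude means the held-out data
#' align with the estimated orientation.
#'
#' @param test_run `bold_run` for the test half.
#' @param test_events events of the test half (onsets relative to the half).
#' @param phi_bar reference orientation, degrees in `[0, 360/k)`.
#' @param k fold symmetry.
#' @param roi optional logical/integer voxel selector; default all voxels.
#' @param carryover_events optional pre-window events (see [split_run()]).
#' @param design optional precomputed design: either a test
#'   `design_matrix`, or a quadrature `design_matrix` on the same events
#'   from which the test design is derived via
#'   [test_design_from_quadrature()].
#' @return list with `magnitude`, `n_voxels`, `per_voxel` coefficients and
#'   `phi_bar`.
#' @export
gls_magnitude <- function(test_run, test_events = NULL, phi_bar, k = 6,
                          roi = NULL, carryover_events = NULL,
                          design = NULL) {
  if (is.null(design)) {
    design <- build_test_design(test_events, k, phi_bar,
                                test_run$n_scans, test_run$TR,
                                carryover_events = carryover_events)
  } else if ("sin" %in% design$names) {
    design <- test_design_from_quadrature(design, phi_bar)
  }
  Y <- test_run$data
  if (!is.null(roi)) Y <- Y[roi, , drop = FALSE]
  if (nrow(Y) == 0L) stop("empty ROI")
  fit <- fit_glm(Y, design)
  per_voxel <- fit$betas[, "aligned"]
  list(magnitude = mean(per_voxel), n_voxels = nrow(Y),
       per_voxel = per_voxel, phi_bar = phi_bar)
}

#' Full two-stage grid-code analysis for one participant
#'
#' For every hemisphere mask, run and fold symmetry: split the run in
#' halves, fit GLM1 on the estimation half, derive voxel orientations and
#' the amplitude-weighted mean orientation, then score the test half with
#' GLM2. Per-run magnitudes are averaged across runs within participant.
#' Failures in individual cells (e.g. an undefined mean orientation) are
#' recorded as `NA`, not raised.
#'
#' @param runs list of `bold_run`s (the participant's fMRI runs).
#' @param events_list list of events data frames, one per run (runs may
#'   share a trajectory).
#' @param masks named list of voxel selectors (logical or integer), e.g.
#'   `list(left = 1:25, right = 26:50)`.
#' @param folds integer vector of fold symmetries to analyse.
#' @param participant identifier carried into the output tables.
#' @return object of class `gls_result`: `cells` (one row per hemisphere x
#'   run x fold: `magnitude`, `phi_bar`, `resultant`, `n_voxels`) and
#'   `participant_level` (run-averaged magnitude per hemisphere x fold,
#'   with `n_runs` actually contributing), plus `intermediates` (per-cell
#'   voxel orientations and amplitudes) and `flags` (logged warnings).
#' @export
run_participant <- function(runs, events_list, masks,
                            folds = c(1, 5, 6, 7),
                            participant = "p01") {
  stopifnot(length(runs) >= 1, length(runs) == length(events_list),
            length(masks) >= 1, !is.null(names(masks)))
  cells <- list(); inter <- list(); flags <- character(0)
  for (r in seq_along(runs)) {
    halves <- split_run(runs[[r]], events_list[[r]], warn_sparse = FALSE)
    if (any(halves$empty_bins > 0))
      flags <- c(flags, sprintf("run %d: %d/%d empty direction bins after split",
                                r, halves$empty_bins[1], halves$empty_bins[2]))
    for (k in folds) {
      est_design <- build_design(halves$estimation$events, k,
                                 halves$estimation$run$n_scans,
                                 halves$estimation$run$TR)
      test_quad <- build_design(halves$test$events, k,
                                halves$test$run$n_scans,
                                halves$test$run$TR,
                                carryover_events = halves$test$carryover)
      for (h in names(masks)) {
        roi <- masks[[h]]
        cell <- tryCatch({
          Yest <- halves$estimation$run$data[roi, , drop = FALSE]
          fit1 <- fit_glm(Yest, est_design)
          est <- estimate_orientations(fit1, k = k)
          mo <- mean_orientation(est, k = k)
          gls <- gls_magnitude(
            structure(list(data = halves$test$run$data[roi, , drop = FALSE],
                           TR = runs[[r]]$TR,
                           n_scans = halves$test$run$n_scans),
                      class = "bold_run"),
            phi_bar = mo$phi_bar, k = k, design = test_quad)
          list(magnitude = gls$magnitude, phi_bar = mo$phi_bar,
               resultant = mo$resultant, n_voxels = gls$n_voxels, est = est)
        }, error = function(e) {
          flags <<- c(flags, sprintf("run %d fold %d %s: %s",
                                     r, k, h, conditionMessage(e)))
          list(magnitude = NA_real_, phi_bar = NA_real_,
               resultant = NA_real_, n_voxels = NA_integer_, est = NULL)
        })
        cells[[length(cells) + 1L]] <- data.frame(
          participant = participant, hemisphere = h, run = r, fold = k,
          magnitude = cell$magnitude, phi_bar = cell$phi_bar,
          resultant = cell$resultant, n_voxels = cell$n_voxels)
        inter[[sprintf("%s_run%d_fold%d", h, r, k)]] <- cell$est
      }
    }
  }
  cells <- do.call(rbind, cells)
  agg <- stats::aggregate(magnitude ~ participant + hemisphere + fold,
                          data = cells, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  agg$n_runs <- stats::aggregate(magnitude ~ participant + hemisphere + fold,
                                 data = cells,
                                 FUN = function(x) sum(is.finite(x)),
                                 na.action = stats::na.pass)$magnitude
  agg$magnitude[agg$n_runs == 0] <- NA_real_
  if (any(agg$n_runs < length(runs) & agg$n_runs > 0))
    flags <- c(flags, "participant average uses fewer runs in some cells")
  structure(list(cells = cells, participant_level = agg,
                 intermediates = inter, flags = flags),
            class = "gls_result")
}

#' @export
print.gls_result <- function(x, ...) {
  cat(sprintf("<gls_result> %s: %d cells (%d hemisphere x fold averages)\n",
              x$cells$participant[1], nrow(x$cells),
              nrow(x$participant_level)))
  if (length(x$flags)) cat("  flags:", length(x$flags), "\n")
  invisible(x)
}
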