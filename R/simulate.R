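#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style parameterisation: response gamma with shape 6, undershoot gamma
#' with shape 16 (both rate 1), undershoot ratio 1/6, 32 s support, scaled to
#' unit peak. No temporal or dispersion derivatives.
#'
#' @param t times in seconds at which to evaluate.
#' @param peak_delay,undershoot_delay gamma shape parameters, s.
#' @param ratio peak:undershoot ratio denominator.
#' @param duration support length, s; the response is 0 outside `[0, duration]`.
#' @return HRF values, unit peak.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 6, duration = 32) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    stats::dgamma(t, shape = undershoot_delay, rate = 1) / ratio
  h[t < 0 | t > duration] <- 0
  peak <- stats::dgamma(peak_delay - 1, shape = peak_delay, rate = 1) -
    stats::dgamma(peak_delay - 1, shape = undershoot_delay, rate = 1) / ratio
  h / peak
}

#' Configuration of the synthetic BOLD generator
#'
#' The generative counterpart of the quadrature measurement model: each voxel
#' carries a k-fold directional modulation `amplitude * cos(k*(phi - theta_v))`
#' of translational movement events, with per-voxel preferred orientations
#' `theta_v` drawn around a common group orientation in k-fold angle space.
#'
#' @param k fold symmetry of the planted modulation (6 = grid signature).
#' @param group_orientation common orientation theta*, degrees in
#'   `[0, 360/k)`; `NULL` draws it uniformly at simulation time.
#' @param orientation_concentration von Mises concentration kappa of voxel
#'   orientations around the group orientation, measured in k-fold angle
#'   space (0 = uniform voxels, `Inf` = all voxels identical).
#' @param modulation_amplitude signal units; scalar (shared) or one value per
#'   voxel.
#' @param n_voxels voxels per simulated run.
#' @param TR repetition time, s.
#' @param baseline additive constant, signal units.
#' @param drift_slope linear drift, signal units per scan.
#' @param noise_sd stationary marginal SD of the AR(1) noise, signal units.
#' @param ar1_coefficient lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param orientation_drift degrees added to every voxel orientation at the
#'   run midpoint (0 = temporally stable orientations).
#' @param mask_labels optional character vector of per-voxel ROI/hemisphere
#'   tags (recycled to `n_voxels`).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(k = 6,
                              group_orientation = NULL,
                              orientation_concentration = 8,
                              modulation_amplitude = 0.5,
                              n_voxels = 30,
                              TR = 1,
                              baseline = 100,
                              drift_slope = 0.01,
                              noise_sd = 1,
                              ar1_coefficient = 0.3,
                              orientation_drift = 0,
                              mask_labels = NULL) {
  stopifnot(k >= 1, orientation_concentration >= 0, noise_sd >= 0,
            abs(ar1_coefficient) < 1, n_voxels >= 1, TR > 0)
  if (!is.null(group_orientation))
    stopifnot(group_orientation >= 0, group_orientation < 360 / k)
  structure(list(k = k, group_orientation = group_orientation,
                 orientation_concentration = orientation_concentration,
                 modulation_amplitude = modulation_amplitude,
                 n_voxels = n_voxels, TR = TR, baseline = baseline,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 ar1_coefficient = ar1_coefficient,
                 orientation_drift = orientation_drift,
                 mask_labels = mask_labels),
            class = "simulation_config")
}

# Stationary AR(1) noise, marginal SD = sd, voxels x scans.
.ar1_noise <- function(n_voxels, n_scans, sd, rho) {
  if (sd == 0) return(matrix(0, n_voxels, n_scans))
  eps <- matrix(0, n_voxels, n_scans)
  eps[, 1] <- stats::rnorm(n_voxels, 0, sd)
  if (n_scans > 1) {
    innov_sd <- sd * sqrt(1 - rho^2)
    for (t in 2:n_scans)
      eps[, t] <- rho * eps[, t - 1] + stats::rnorm(n_voxels, 0, innov_sd)
  }
  eps
}

#' Simulate a BOLD run with planted k-fold directional modulation
#'
#' During each translation event the neural signal of voxel v is
#' `a_v * cos(k * (phi - theta_v))` as a boxcar over the event, zero
#' elsewhere; this is convolved with the canonical double-gamma HRF at a
#' 0.1 s microtime resolution, sampled at scan times, and summed with
#' `baseline + drift_slope * scan + AR(1) noise`. If `orientation_drift` is
#' non-zero, all voxel orientations shift by that amount for events starting
#' at or after the run midpoint.
#'
#' @param trajectory a [generate_trajectory()] result (or a list with an
#'   `events` data frame and a `config` holding `run_length`).
#' @param sim a [simulation_config()].
#' @param seed integer seed; output is deterministic given
#'   `(trajectory, sim, seed)`.
#' @return object of class `bold_run`: `data` (voxels x scans matrix), `TR`,
#'   `n_scans`, `mask_labels`, and `ground_truth` with per-voxel `theta`
#'   (degrees in `[0, 360/k)`), `amplitude`, the realised `group_orientation`
#'   and `k`.
#' @export
simulate_bold <- function(trajectory, sim = simulation_config(), seed = 1L) {
  stopifnot(inherits(sim, "simulation_config"))
  with_seed(seed, .simulate_bold_impl(trajectory, sim))
}

.simulate_bold_impl <- function(trajectory, sim) {
  run_length <- trajectory$config$run_length
  n_scans <- as.integer(ceiling(run_length / sim$TR))
  ev <- trajectory$events
  if (max(ev$onset + ev$duration) > n_scans * sim$TR + 1e-9)
    stop("trajectory schedule exceeds the scan window")
  k <- sim$k
  theta_star <- if (is.null(sim$group_orientation))
    stats::runif(1, 0, 360 / k) else sim$group_orientation
  psi <- rvonmises(sim$n_voxels, deg2rad(theta_star * k),
                   sim$orientation_concentration)
  theta_v <- wrap_fold(rad2deg(psi) / k, k)
  amp <- rep_len(sim$modulation_amplitude, sim$n_voxels)

  scans <- seq_len(n_scans) - 1L
  signal <- matrix(0, sim$n_voxels, n_scans)
  if (any(amp != 0)) {
    trans <- ev[ev$trial_type == "translation", , drop = FALSE]
    halves <- if (sim$orientation_drift != 0)
      split(trans, trans$onset >= run_length / 2) else list(trans)
    shift <- 0
    for (h in seq_along(halves)) {
      th <- halves[[h]]
      if (nrow(th) > 0) {
        phi_k <- deg2rad(th$direction * k)
        creg <- .convolved_regressor(th$onset, th$duration, cos(phi_k),
                                     n_scans, sim$TR)
        sreg <- .convolved_regressor(th$onset, th$duration, sin(phi_k),
                                     n_scans, sim$TR)
        tk <- deg2rad((theta_v + shift) * k)
        signal <- signal + amp * (cos(tk) %o% creg + sin(tk) %o% sreg)
      }
      shift <- shift + sim$orientation_drift
    }
  }
  data <- signal + sim$baseline + rep(1, sim$n_voxels) %o%
    (sim$drift_slope * scans) +
    .ar1_noise(sim$n_voxels, n_scans, sim$noise_sd, sim$ar1_coefficient)
  labels <- if (is.null(sim$mask_labels)) NULL
  else rep_len(sim$mask_labels, sim$n_voxels)
  structure(list(data = data, TR = sim$TR, n_scans = n_scans,
                 mask_labels = labels,
                 ground_truth = list(theta = theta_v, amplitude = amp,
                                     group_orientation = theta_star, k = k)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d voxels x %d scans, TR %g s%s\n",
              nrow(x$data), x$n_scans, x$TR,
              if (!is.null(x$ground_truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Write / read a BOLD run
#'
#' `write_bold()` stores the voxels x scans matrix. A `.nii`/`.nii.gz` path
#' uses NIfTI-1 (via the RNifti package, scans as the 4th dimension, TR in
#' the header); any other path writes a plain-text matrix (`<path>`, scans in
#' columns) plus a JSON sidecar `<path>.json` holding `TR`, `n_voxels`,
#' `n_scans`, `mask_labels` and any ground truth. `read_bold()` inverts
#' either layout.
#'
#' @param run a `bold_run`.
#' @param path destination.
#' @return `write_bold()` returns `path` invisibly; `read_bold()` a
#'   `bold_run`.
#' @export
write_bold <- function(run, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("writing NIfTI requires the RNifti package")
    arr <- array(run$data, dim = c(nrow(run$data), 1L, 1L, run$n_scans))
    img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, run$TR))
    RNifti::writeNifti(img, path)
    side <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  } else {
    utils::write.table(format(run$data, digits = 17), path, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    side <- paste0(path, ".json")
  }
  meta <- list(TR = run$TR, n_voxels = nrow(run$data), n_scans = run$n_scans,
               mask_labels = run$mask_labels, ground_truth = run$ground_truth)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  nifti <- grepl("\\.nii(\\.gz)?$", path)
  side <- if (nifti) paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  else paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else NULL
  if (nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI requires the RNifti package")
    img <- RNifti::readNifti(path)
    d <- dim(img)
    data <- matrix(as.vector(img), prod(d[1:3]), d[4])
    TR <- if (!is.null(meta$TR)) meta$TR else RNifti::pixdim(img)[4]
  } else {
    data <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(data) <- NULL
    TR <- meta$TR
  }
  gt <- meta$ground_truth
  structure(list(data = data, TR = TR, n_scans = ncol(data),
                 mask_labels = meta$mask_labels,
                 ground_truth = if (length(gt)) gt else NULL),
            class = "bold_run")
}
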