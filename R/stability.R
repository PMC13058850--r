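#' Temporal stability of voxel orientations across data halves
#'
#' A voxel is temporally stable when its orientations estimated from the two
#' run halves differ by at most `tolerance` degrees in the k-fold periodic
#' space. With independent uniform orientations the expected stable fraction
#' is the chance level `2 * tolerance / (360/k)` (50% for the canonical
#' +/-15 degrees in 60-degree space). Voxels with an undefined orientation
#' in either half drop out of the denominator (counts reported).
#'
#' @param theta_half1,theta_half2 per-voxel orientations, degrees.
#' @param k fold symmetry.
#' @param tolerance stability criterion, degrees (default +/-15).
#' @return object of class `stability_result`: `temporal_fraction`,
#'   `chance_level`, `n_voxels` (valid pairs), `n_dropped`, `k`, `tolerance`.
#' @export
temporal_stability <- function(theta_half1, theta_half2, k = 6,
                               tolerance = 15) {
  stopifnot(length(theta_half1) == length(theta_half2))
  if (length(theta_half1) == 0L) stop("empty orientation vectors")
  stopifnot(tolerance > 0, tolerance <= 180 / k)
  keep <- is.finite(theta_half1) & is.finite(theta_half2)
  if (!any(keep)) stop("no voxel with a defined orientation in both halves")
  d <- abs(circ_dist_fold(theta_half1[keep], theta_half2[keep], k))
  structure(list(temporal_fraction = mean(d <= tolerance),
                 chance_level = 2 * tolerance / (360 / k),
                 n_voxels = sum(keep), n_dropped = sum(!keep),
                 k = k, tolerance = tolerance),
            class = "stability_result")
}

#' Rayleigh test for non-uniformity of circular data
#'
#' Mean resultant length of unit vectors, `Z = n * Rbar^2`, with the
#' standard small-sample series approximation of the p-value
#' `p = exp(-Z) * [1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288 n^2)]`,
#' clipped to `(0, 1]`.
#'
#' @param angles angles in radians on the full circle.
#' @return list with `Rbar`, `Z`, `p`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2L) stop("Rayleigh test needs at least 2 angles")
  Rbar <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  Z <- n * Rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(Rbar = Rbar, Z = Z, p = min(max(p, .Machine$double.xmin), 1), n = n)
}

#' Spatial stability of voxel orientations (Rayleigh test in fold space)
#'
#' Maps orientations to `k * theta` and tests the resulting circular sample
#' for non-uniformity: a high Rayleigh Z means the voxels share a common
#' grid orientation. Unweighted (amplitudes are not used).
#'
#' @param theta per-voxel orientations, degrees.
#' @param k fold symmetry.
#' @return object of class `stability_result`: `rayleigh_Z`, `rayleigh_p`,
#'   `resultant`, `n_voxels`, `k`.
#' @export
spatial_stability <- function(theta, k = 6) {
  theta <- theta[is.finite(theta)]
  if (length(theta) < 2L) stop("need at least 2 valid orientations")
  rt <- rayleigh_test(deg2rad(theta * k))
  structure(list(rayleigh_Z = rt$Z, rayleigh_p = rt$p, resultant = rt$Rbar,
                 n_voxels = rt$n, k = k),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  if (!is.null(x$temporal_fraction))
    cat(sprintf("<stability_result> temporal fraction %.3f (chance %.3f, n = %d)\n",
                x$temporal_fraction, x$chance_level, x$n_voxels))
  if (!is.null(x$rayleigh_Z))
    cat(sprintf("<stability_result> Rayleigh Z = %.2f, p = %.3g (n = %d)\n",
                x$rayleigh_Z, x$rayleigh_p, x$n_voxels))
  invisible(x)
}

#' tSNR-based voxel exclusion
#'
#' Temporal signal-to-noise ratio per voxel (temporal mean over temporal
#' standard deviation). Voxels are excluded when their tSNR falls more than
#' 1.5 interquartile ranges below the first quartile (quartiles by linear
#' interpolation, type 7), or when tSNR is undefined (constant series).
#'
#' @param run a `bold_run` or voxels x scans matrix with >= 2 scans.
#' @param iqr_factor multiple of the IQR defining the lower fence.
#' @return object of class `qc_result`: `tsnr` per voxel, `q1`, `iqr`,
#'   `threshold`, logical `excluded`, `excluded_indices`.
#' @export
tsnr_filter <- function(run, iqr_factor = 1.5) {
  Y <- if (inherits(run, "bold_run")) run$data else run
  if (ncol(Y) < 2L) stop("tSNR needs at least 2 scans")
  m <- rowMeans(Y)
  s <- sqrt(rowSums((Y - m)^2) / (ncol(Y) - 1L))
  tsnr <- unname(ifelse(s > 0, m / s, NA_real_))
  q <- stats::quantile(tsnr, c(0.25, 0.75), na.rm = TRUE, type = 7,
                       names = FALSE)
  iqr <- q[2] - q[1]
  threshold <- q[1] - iqr_factor * iqr
  excluded <- !is.finite(tsnr) | tsnr < threshold
  structure(list(tsnr = tsnr, q1 = q[1], iqr = iqr, threshold = threshold,
                 excluded = excluded, excluded_indices = which(excluded)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d/%d voxels excluded (tSNR < %.2f)\n",
              sum(x$excluded), length(x$tsnr), x$threshold))
  invisible(x)
}
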