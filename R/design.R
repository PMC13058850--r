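#' @name design-matrices
#' @title Quadrature GLM design matrices
#'
#' @description
#' The measurement model is a pair of general linear models. GLM1 (the
#' estimation model, [build_design()]) carries two parametric modulators of
#' the translational movement events, `sin(k*phi)` and `cos(k*phi)` with
#' `phi` the allocentric movement direction; its fitted coefficients define
#' each voxel's preferred orientation. GLM2 (the test model,
#' [build_test_design()]) carries the single modulator `cos(k*(phi - phi_bar))`
#' against a supplied reference orientation; its coefficient is the
#' cross-validated grid-like signal magnitude. Both share an intercept, an
#' unmodulated translation boxcar, an unmodulated rotation boxcar as
#' nuisance, and a drift set (linear trend plus discrete-cosine basis up to
#' the high-pass cutoff). Event regressors are built as boxcars at 0.1 s
#' microtime resolution, convolved with the canonical double-gamma HRF, then
#' sampled at scan onsets.
NULL

# Boxcar of per-event weights at microtime resolution, HRF-convolved and
# sampled at scan onsets. Negative onsets are allowed (events preceding the
# window whose hemodynamic tail reaches into it): the microtime grid is
# padded backwards before convolution.
.convolved_regressor <- function(onsets, durations, weights, n_scans, TR,
                                 dt = 0.1) {
  pad <- max(0L, as.integer(ceiling(-min(c(onsets, 0)) / dt)))
  n_micro <- as.integer(ceiling(n_scans * TR / dt)) + 1L
  x <- numeric(pad + n_micro)
  for (i in seq_along(onsets)) {
    i0 <- pad + as.integer(floor(onsets[i] / dt)) + 1L
    i1 <- pad + as.integer(ceiling((onsets[i] + durations[i]) / dt))
    if (i1 >= max(i0, 1L)) {
      idx <- max(i0, 1L):min(i1, pad + n_micro)
      x[idx] <- x[idx] + weights[i]
    }
  }
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(x, rev(h), type = "open")[pad + seq_len(n_micro)] * dt
  scan_idx <- as.integer(round((seq_len(n_scans) - 1L) * TR / dt)) + 1L
  conv[scan_idx]
}

# Carry-over nuisance columns: the hemodynamic tails of events that precede
# the modelled window (onsets on the window clock, hence negative), split
# into an unmodulated translation tail, its k-fold quadrature tails, and a
# rotation tail. Columns that are effectively zero inside the window are
# dropped.
.carryover_columns <- function(carry_events, k, n_scans, TR) {
  if (is.null(carry_events) || nrow(carry_events) == 0L) return(NULL)
  cols <- list()
  trans <- carry_events[carry_events$trial_type == "translation", , drop = FALSE]
  if (nrow(trans) > 0L) {
    phi <- deg2rad(trans$direction * k)
    cols$carry_translation <- .convolved_regressor(
      trans$onset, trans$duration, rep(1, nrow(trans)), n_scans, TR)
    cols$carry_sin <- .convolved_regressor(
      trans$onset, trans$duration, sin(phi), n_scans, TR)
    cols$carry_cos <- .convolved_regressor(
      trans$onset, trans$duration, cos(phi), n_scans, TR)
  }
  rot <- carry_events[carry_events$trial_type == "rotation", , drop = FALSE]
  if (nrow(rot) > 0L)
    cols$carry_rotation <- .convolved_regressor(
      rot$onset, rot$duration, rep(1, nrow(rot)), n_scans, TR)
  cols[vapply(cols, function(x) max(abs(x)) > 1e-12, logical(1))]
}

# Discrete-cosine high-pass basis (constant term excluded): one column per
# frequency below 1/cutoff Hz.
.dct_basis <- function(n_scans, TR, cutoff = 128) {
  n_basis <- floor(2 * n_scans * TR / cutoff)
  if (n_basis < 1) return(NULL)
  t <- seq_len(n_scans) - 1L
  out <- sapply(seq_len(n_basis), function(r)
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * r / (2 * n_scans)))
  colnames(out) <- paste0("dct_", seq_len(n_basis))
  out
}

.check_events_window <- function(events, n_scans, TR) {
  over <- which(events$onset + events$duration > n_scans * TR + 1e-9)
  if (length(over))
    stop("event(s) extend beyond the scan window; first offending onset: ",
         events$onset[over[1]], " s")
  if (any(events$onset < 0))
    stop("negative event onset")
}

.assemble_design <- function(columns, names, TR, k, hrf_id, cutoff) {
  X <- do.call(cbind, columns)
  colnames(X) <- names
  if (any(!is.finite(X))) stop("non-finite values in design matrix")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(matrix = X, names = colnames(X), TR = TR, k = k,
                 hrf_id = hrf_id, highpass_cutoff = cutoff),
            class = "design_matrix")
}

#' Build the estimation (GLM1) design matrix
#'
#' @param events events data frame (see [read_events()]); translation rows
#'   must carry a finite `direction`.
#' @param k fold symmetry of the quadrature modulators.
#' @param n_scans number of scans the design covers.
#' @param TR repetition time, s.
#' @param phase_offset reference direction subtracted from every event
#'   direction before the modulators are formed, degrees.
#' @param highpass_cutoff high-pass period, s; drift columns model the
#'   linear trend and cosines slower than this cutoff.
#' @param carryover_events optional events preceding the modelled window
#'   (onsets on the window clock, hence negative), whose hemodynamic tails
#'   reach into it; modelled as nuisance columns `carry_*`. [split_run()]
#'   supplies these for the test half.
#' @return object of class `design_matrix` with columns `intercept`,
#'   `translation`, `sin`, `cos`, (`rotation` when rotation events are
#'   present), optional `carry_*` nuisance tails, `linear`, `dct_*`.
#' @export
build_design <- function(events, k, n_scans, TR, phase_offset = 0,
                         highpass_cutoff = 128, carryover_events = NULL) {
  stopifnot(k >= 1)
  .check_events_window(events, n_scans, TR)
  trans <- events[events$trial_type == "translation", , drop = FALSE]
  if (nrow(trans) == 0L) stop("no translation events in the design window")
  phi <- deg2rad((trans$direction - phase_offset) * k)
  cols <- list(intercept = rep(1, n_scans),
               translation = .convolved_regressor(
                 trans$onset, trans$duration, rep(1, nrow(trans)), n_scans, TR),
               sin = .convolved_regressor(
                 trans$onset, trans$duration, sin(phi), n_scans, TR),
               cos = .convolved_regressor(
                 trans$onset, trans$duration, cos(phi), n_scans, TR))
  nm <- c("intercept", "translation", "sin", "cos")
  rot <- events[events$trial_type == "rotation", , drop = FALSE]
  if (nrow(rot) > 0L) {
    cols$rotation <- .convolved_regressor(
      rot$onset, rot$duration, rep(1, nrow(rot)), n_scans, TR)
    nm <- c(nm, "rotation")
  }
  carry <- .carryover_columns(carryover_events, k, n_scans, TR)
  if (length(carry)) {
    cols <- c(cols, carry)
    nm <- c(nm, names(carry))
  }
  cols$linear <- seq_len(n_scans) - 1L
  nm <- c(nm, "linear")
  dct <- .dct_basis(n_scans, TR, highpass_cutoff)
  if (!is.null(dct)) {
    cols$dct <- dct
    nm <- c(nm, colnames(dct))
  }
  .assemble_design(cols, nm, TR, k, "double-gamma", highpass_cutoff)
}

#' Build the test (GLM2) design matrix
#'
#' As [build_design()] but with the single parametric modulator
#' `cos(k*(phi - phi_bar))`, whose fitted coefficient is the grid-like
#' signal magnitude.
#'
#' @inheritParams build_design
#' @param phi_bar reference (mean grid) orientation, degrees in `[0, 360/k)`.
#' @return `design_matrix` with the modulator column named `aligned`.
#' @export
build_test_design <- function(events, k, phi_bar, n_scans, TR,
                              highpass_cutoff = 128,
                              carryover_events = NULL) {
  stopifnot(k >= 1, phi_bar >= 0, phi_bar < 360 / k)
  .check_events_window(events, n_scans, TR)
  trans <- events[events$trial_type == "translation", , drop = FALSE]
  if (nrow(trans) == 0L) stop("no translation events in the design window")
  mod <- cos(deg2rad((trans$direction - phi_bar) * k))
  cols <- list(intercept = rep(1, n_scans),
               translation = .convolved_regressor(
                 trans$onset, trans$duration, rep(1, nrow(trans)), n_scans, TR),
               aligned = .convolved_regressor(
                 trans$onset, trans$duration, mod, n_scans, TR))
  nm <- c("intercept", "translation", "aligned")
  rot <- events[events$trial_type == "rotation", , drop = FALSE]
  if (nrow(rot) > 0L) {
    cols$rotation <- .convolved_regressor(
      rot$onset, rot$duration, rep(1, nrow(rot)), n_scans, TR)
    nm <- c(nm, "rotation")
  }
  carry <- .carryover_columns(carryover_events, k, n_scans, TR)
  if (length(carry)) {
    cols <- c(cols, carry)
    nm <- c(nm, names(carry))
  }
  cols$linear <- seq_len(n_scans) - 1L
  nm <- c(nm, "linear")
  dct <- .dct_basis(n_scans, TR, highpass_cutoff)
  if (!is.null(dct)) {
    cols$dct <- dct
    nm <- c(nm, colnames(dct))
  }
  .assemble_design(cols, nm, TR, k, "double-gamma", highpass_cutoff)
}

#' Derive a test design from a quadrature design
#'
#' Because `cos(k*(phi - phi_bar)) = cos(k*phi_bar) cos(k*phi) +
#' sin(k*phi_bar) sin(k*phi)` and HRF convolution is linear, the GLM2
#' modulator column is an exact linear combination of a quadrature design's
#' `sin`/`cos` columns. This avoids re-convolving events when scoring many
#' reference orientations against the same test data.
#'
#' @param design a quadrature `design_matrix` from [build_design()] (built
#'   with `phase_offset = 0`).
#' @param phi_bar reference orientation, degrees in `[0, 360/k)`.
#' @return `design_matrix` equivalent to [build_test_design()] on the same
#'   events.
#' @export
test_design_from_quadrature <- function(design, phi_bar) {
  stopifnot(inherits(design, "design_matrix"),
            all(c("sin", "cos") %in% design$names))
  k <- design$k
  stopifnot(phi_bar >= 0, phi_bar < 360 / k)
  a <- deg2rad(phi_bar * k)
  X <- design$matrix
  aligned <- cos(a) * X[, "cos"] + sin(a) * X[, "sin"]
  keep <- setdiff(design$names, c("sin", "cos"))
  Xout <- cbind(X[, keep, drop = FALSE], aligned = aligned)
  ord <- c("intercept", "translation", "aligned",
           setdiff(colnames(Xout), c("intercept", "translation", "aligned")))
  Xout <- Xout[, ord, drop = FALSE]
  structure(list(matrix = Xout, names = colnames(Xout), TR = design$TR,
                 k = k, hrf_id = design$hrf_id,
                 highpass_cutoff = design$highpass_cutoff),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d regressors (k = %d): %s\n",
              nrow(x$matrix), ncol(x$matrix), x$k,
              paste(utils::head(x$names, 6), collapse = ", ")))
  invisible(x)
}

#' Write a design matrix to TSV
#'
#' @param design a `design_matrix`.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design$matrix), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fit a GLM to every voxel of a run
#'
#' Ordinary least squares per voxel (no prewhitening); the simulator's AR(1)
#' noise only inflates coefficient variance, which the calibration checks
#' absorb.
#'
#' @param run a `bold_run` (or a voxels x scans matrix).
#' @param design a `design_matrix` with as many rows as the run has scans.
#' @return object of class `glm_fit`: `betas` (voxels x regressors, design
#'   order), `residual_variance` per voxel, and residual `df`.
#' @export
fit_glm <- function(run, design) {
  Y <- if (inherits(run, "bold_run")) run$data else run
  X <- design$matrix
  if (ncol(Y) != nrow(X))
    stop("run has ", ncol(Y), " scans but design has ", nrow(X), " rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- nrow(X) - qrX$rank
  if (df <= 0) stop("no residual degrees of freedom")
  B <- qr.coef(qrX, t(Y))                  # regressors x voxels
  res <- t(Y) - X %*% B
  structure(list(betas = t(B), residual_variance = colSums(res^2) / df,
                 df = df, names = design$names),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d voxels x %d regressors, df = %d\n",
              nrow(x$betas), ncol(x$betas), x$df))
  invisible(x)
}
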