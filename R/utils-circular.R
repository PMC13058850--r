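#' Circular helpers for k-fold orientation spaces
#'
#' Grid orientations live on a periodic domain of width `360/k` degrees
#' (60 degrees for the canonical 6-fold grid signature). These helpers wrap
#' angles into that fundamental domain and measure distances inside it.
#'
#' @name circular-helpers
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into the fundamental domain of a k-fold symmetry
#'
#' @param theta angle(s) in degrees.
#' @param k fold symmetry (k = 6 gives the 60-degree grid domain).
#' @return angle(s) in `[0, 360/k)` degrees.
#' @export
#' @examples
#' wrap_fold(-15, 6)  # 45
wrap_fold <- function(theta, k = 6) {
  period <- 360 / k
  out <- theta %% period
  # guard against period itself arising from floating-point mod
  out[out >= period] <- 0
  out
}

#' Signed circular distance in a k-fold periodic space
#'
#' @param a,b angles in degrees (any representative).
#' @param k fold symmetry.
#' @return signed distance `a - b` wrapped to `[-180/k, 180/k)` degrees.
#' @export
circ_dist_fold <- function(a, b, k = 6) {
  period <- 360 / k
  d <- (a - b) %% period
  d - period * (d >= period / 2)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler on the full circle. `kappa = 0` reduces to
#' the uniform distribution; `kappa = Inf` returns `mu` exactly.
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0).
#' @return draws in `[0, 2*pi)`, radians.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (is.infinite(kappa)) return(rep((mu %% (2 * pi)), n))
  if (kappa == 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  (out + mu) %% (2 * pi)
}

# Run an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
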