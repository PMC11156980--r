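## Internal angle helpers. Orientations (axes) live in [0, 180) degrees,
## directions in [0, 360). All angles are measured CCW from +x (temporal).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normalize an axis angle into [0, 180)
#'
#' Orientation axes are 180-degree periodic; every I/O boundary of the
#' package stores them in `[0, 180)`.
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles folded into `[0, 180)`.
#' @export
norm_axis_deg <- function(deg) {
  out <- deg %% 180
  ## guard against 180 - eps rounding back to exactly 180
  out[out >= 180] <- 0
  out
}

#' Normalize a direction angle into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return angles folded into `[0, 360)`.
#' @export
norm_dir_deg <- function(deg) deg %% 360

#' Circular mean of orientation axes (double-angle space)
#'
#' Axial data are averaged by doubling the angles, taking the circular mean
#' on the full circle, and halving the result. The resultant length of the
#' doubled-angle vectors measures coherence (1 = all axes identical,
#' 0 = uniform/cancelling).
#'
#' @param axis_deg axis angles in degrees, `[0, 180)`.
#' @param resultant_min if the resultant length falls below this, the mean
#'   axis is reported as `NA` (direction undefined by cancellation).
#' @return list with `mean_axis_deg` and `resultant`.
#' @export
circular_mean_axis <- function(axis_deg, resultant_min = 0) {
  stopifnot(length(axis_deg) >= 1)
  z <- exp(2i * deg2rad(axis_deg))
  m <- mean(z)
  r <- Mod(m)
  ang <- if (r < resultant_min || r == 0) NA_real_ else norm_axis_deg(rad2deg(Arg(m)) / 2)
  list(mean_axis_deg = ang, resultant = r)
}

## Smallest absolute difference between two axes (degrees, in [0, 90]).
axis_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

## von Mises sampler (Best & Fisher 1979). Returns angles in radians in
## (-pi, pi] around mu. kappa = Inf returns mu exactly; kappa = 0 is uniform.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
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
  out + mu
}
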