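#' Angle helpers on the 0--360 degree circle
#'
#' Small circular-arithmetic utilities used throughout the package. The
#' package-wide angular convention is the two-argument arctangent of (x, y)
#' measured clockwise from the positive y axis, so that (0, 1) maps to 0
#' degrees and (1, 0) to 90 degrees.
#'
#' @param x,y Cartesian coordinates.
#' @return `angle_from_xy()` returns degrees in `[0, 360)`.
#' @keywords internal
#' @noRd
angle_from_xy <- function(x, y) {
  wrap_deg(atan2(x, y) * 180 / pi)
}

#' @noRd
wrap_deg <- function(theta) theta %% 360

#' Signed circular difference a - b mapped to (-180, 180]
#' @noRd
wrap_signed_deg <- function(delta) {
  d <- atan2(sin(delta * pi / 180), cos(delta * pi / 180)) * 180 / pi
  # atan2 returns (-180, 180]; -180 can appear from rounding, fold it up
  d[d <= -180] <- 180
  d
}

#' @noRd
deg2rad <- function(x) x * pi / 180

#' @noRd
rad2deg <- function(x) x * 180 / pi

#' Circular mean of angles in degrees
#' @noRd
circ_mean_deg <- function(theta) {
  r <- deg2rad(theta)
  wrap_deg(rad2deg(atan2(mean(sin(r)), mean(cos(r)))))
}

#' Circular-circular correlation (pairwise Fisher-Lee statistic)
#'
#' The rotation-invariant T-linear association
#' `sum_{i<j} sin(a_i - a_j) sin(b_i - b_j)` normalized by its maximum,
#' computed in O(n) through trigonometric moment identities. Stable for
#' uniform marginals (unlike mean-deviation variants). Used to compare an
#' inferred angular ordering with a known truth; direction reversal flips
#' the sign, so callers take `abs()` when orientation is a gauge.
#'
#' @param a,b Angles in degrees.
#' @return Correlation in `[-1, 1]`.
#' @export
circular_cor <- function(a, b) {
  a <- deg2rad(a); b <- deg2rad(b)
  n <- length(a)
  mod2 <- function(x) Re(x)^2 + Im(x)^2
  e <- function(x) sum(complex(argument = x))
  num <- mod2(e(a - b)) - mod2(e(a + b))
  den <- sqrt((n^2 - mod2(e(2 * a))) * (n^2 - mod2(e(2 * b))))
  num / den
}
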