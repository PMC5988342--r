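#' Canonicalize angles to [0, 360)
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Angles wrapped into `[0, 360)`.
#' @examples
#' wrap_angle(c(-45, 370, 360))
#' @export
wrap_angle <- function(theta) {
  out <- theta %% 360
  out[out == 360] <- 0
  out
}

#' Absolute angular distance on the circle
#'
#' Shortest arc between two polar angles, in degrees; always in `[0, 180]`.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Absolute angular separation in degrees.
#' @examples
#' angular_distance(350, 10) # 20, not 340
#' @export
angular_distance <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 360 - d)
}

deg2rad <- function(x) x * pi / 180

# signed shortest rotation from `from` to `to`, in (-180, 180]
signed_angle_diff <- function(from, to) {
  d <- wrap_angle(to - from)
  ifelse(d > 180, d - 360, d)
}
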