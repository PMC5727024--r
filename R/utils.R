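#' @keywords internal
"_PACKAGE"

# gravitational acceleration used throughout (m/s^2), +Z up global frame
GRAVITY <- 9.81

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric length-3
#' @return 3x3 matrix S with S %*% w == v x w
#' @keywords internal
skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Normalize a vector to unit length
#' @keywords internal
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Round half away from zero at a fixed number of decimals
#'
#' Report-time rounding used for table output; R's round() rounds half to
#' even, which does not match how measurement tables are conventionally
#' printed.
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# rotation about a unit axis by angle (radians), Rodrigues form
rot_axis_angle <- function(axis, angle) {
  a <- unitize(axis)
  K <- skew(a)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
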