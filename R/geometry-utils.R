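# Small 3D vector/rotation helpers shared across modules.

.vnorm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix for a rotation about an arbitrary axis
#'
#' Right-handed rotation by `angle_deg` degrees about `axis` (Rodrigues
#' formula).  Applied to column vectors: `R %*% v`.
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# signed angle (degrees, in [-180, 180)) from a to b about axis n
.signed_angle <- function(a, b, n) {
  n <- .unit(n)
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  if (.vnorm(a) < 1e-12 || .vnorm(b) < 1e-12) return(NA_real_)
  ang <- atan2(sum(.cross(a, b) * n), sum(a * b)) * 180 / pi
  if (ang >= 180) ang <- ang - 360
  if (ang < -180) ang <- ang + 360
  ang
}

# apply 3x3 rotation R to an n x 3 coordinate matrix about a center point
.rotate_coords <- function(xyz, R, center = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
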