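# Internal geometry helpers shared across modules. All coordinates are in
# Angstrom; rotations are proper (det +1) unless a reflection is explicitly
# requested by the caller.

#' @importFrom rlang .data abort warn `%||%`
#' @importFrom dplyr filter mutate arrange select group_by ungroup summarise
#'   left_join bind_rows distinct across n row_number first
#' @importFrom tibble tibble as_tibble
NULL

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) abort("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector; normalized internally.
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues form).
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

vec_angle <- function(a, b, c) {
  # interior angle at b, degrees
  u <- a - b
  v <- c - b
  cc <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cc))) * 180 / pi
}

vec_dihedral <- function(a, b, c, d) {
  # signed dihedral (IUPAC convention), degrees in (-180, 180]
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum || R x_i + t - y_i ||^2` over corresponding rows of `x` and `y`.
#'
#' @param x,y n x 3 coordinate matrices (mobile, target).
#' @return list with `R` (3x3), `t` (length 3), and `rmsd` after fitting.
#' @keywords internal
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) < 3) abort("superposition needs at least 3 correspondence points")
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  fit <- sweep(x0 %*% t(R), 2, cy, `+`)
  rmsd <- sqrt(mean(rowSums((fit - y)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

apply_rigid <- function(x, R, t) {
  sweep(x %*% t(R), 2, t, `+`)
}

rmsd_xyz <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer no matter what base seed the caller supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}
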