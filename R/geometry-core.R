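# Low-level 3D vector machinery shared by the builders and torsion code.
# All angles cross the package boundary in degrees; radians never leave a
# function body.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Wrap angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Angle between three points
#'
#' @param a,b,c numeric length-3 coordinates; the angle is measured at `b`.
#' @return angle a-b-c in degrees.
#' @export
bond_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Torsion angle of four points
#'
#' Returns the signed dihedral a-b-c-d in degrees, wrapped to (-180, 180].
#' Degenerate (collinear) configurations yield NA rather than an error so
#' that per-residue torsion tables can carry holes.
#'
#' @param a,b,c,d numeric length-3 coordinates.
#' @return dihedral angle in degrees, or NA if undefined.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) return(NA_real_)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) / DEG)
}

# cross product (no external dependency)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# NeRF atom placement: position of atom D given chain A-B-C, the C-D bond
# length, the B-C-D angle (deg) and the A-B-C-D dihedral (deg).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * DEG
  ph <- -dihedral * DEG
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix about an arbitrary unit axis (Rodrigues), theta in degrees.
rotation_matrix <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Kabsch superposition: proper rotation R and translation t minimizing
# || (P %*% t(R) + t) - Q ||. P, Q are n x 3 with matched rows.
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.vector(R %*% cp)
  list(R = R, t = t)
}

apply_rigid <- function(X, R, t) {
  sweep(X %*% t(R), 2, t, "+")
}

# The two unit directions completing an approximately tetrahedral centre
# whose known substituent unit directions are u1, u2. Returned as a 2 x 3
# matrix; row 1 is on the +(u1 x u2) side.
tetra_pair <- function(u1, u2, target = 109.47) {
  b <- unitv(u1 + u2)
  p <- unitv(pracma_cross(u1, u2))
  cb <- -cos(target * DEG) / sum(u1 * b)
  cb <- max(-1, min(1, cb))
  sb <- sqrt(max(0, 1 - cb^2))
  rbind(-b * cb + p * sb, -b * cb - p * sb)
}

# Unique fourth tetrahedral direction given three substituent directions.
tetra_fourth <- function(u1, u2, u3) {
  -unitv(unitv(u1) + unitv(u2) + unitv(u3))
}
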