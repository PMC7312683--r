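# Small 3D geometry toolkit shared by the helix model, the synthetic
# generator and the interaction detectors.  All angles are in degrees,
# all lengths in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b formed by points a-b-c, in degrees.
#' @noRd
angle3 <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed torsion angle p1-p2-p3-p4 in degrees, range (-180, 180].
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- -rad2deg(atan2(y, x))          # IUPAC sign convention
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix about an arbitrary unit axis (Rodrigues).
rotation_about_axis <- function(axis, theta_deg) {
  u <- unitv(axis)
  th <- deg2rad(theta_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (u %o% u)
}

rot_z <- function(theta_deg) rotation_about_axis(c(0, 0, 1), theta_deg)

# Rotation taking unit vector a onto unit vector b (minimal rotation).
rotation_between <- function(a, b) {
  a <- unitv(a); b <- unitv(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite vectors: rotate 180 deg about any perpendicular axis
    perp <- cross3(a, c(1, 0, 0))
    if (vnorm(perp) < 1e-6) perp <- cross3(a, c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  rotation_about_axis(v, rad2deg(atan2(s, c_)))
}

#' Place a new atom from three reference atoms (NeRF construction).
#'
#' Returns the position d with |d - c| = bond, angle(b, c, d) = angle_deg
#' and torsion(a, b, c, d) = torsion_deg.
#' @noRd
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  ang <- deg2rad(180 - angle_deg)
  tor <- deg2rad(torsion_deg)
  d2 <- c(bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Deterministic quasi-uniform directions on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Full cross distance matrix between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(A, B) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * (A %*% t(B))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Minimum distance between two atom coordinate sets.
min_dist <- function(A, B) min(cross_dist(A, B))
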