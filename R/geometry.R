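## Low-level vector geometry shared by the generator and the analyses.
## All coordinates are in nm, all angles in degrees wrapped to (-180, 180].

#' Wrap angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles in degrees, wrapped to `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("points must have 3 columns")
    p
  } else {
    if (length(p) != 3L) stop("a point must have 3 coordinates")
    matrix(p, nrow = 1L)
  }
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_dot <- function(a, b) rowSums(a * b)

row_norm <- function(a) sqrt(rowSums(a * a))

#' Signed torsion angle of four points
#'
#' Computes the torsion (dihedral) angle about the `p2 -> p3` axis by the
#' right-hand rule: looking down `p2 -> p3`, a positive angle rotates the
#' `p1` side clockwise onto the `p4` side.  Inputs may be single points
#' (length-3 vectors) or `n x 3` matrices for a whole series at once.
#'
#' @param p1,p2,p3,p4 points (length-3 vectors) or `n x 3` matrices.
#' @return torsion angle(s) in degrees in `(-180, 180]`.
#' @examples
#' compute_dihedral(c(1, 1, 0), c(0, 0, 0), c(0, 0, 1), c(-1, 1, 1)) # 180
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  p1 <- as_point_matrix(p1); p2 <- as_point_matrix(p2)
  p3 <- as_point_matrix(p3); p4 <- as_point_matrix(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- row_norm(b2)
  if (any(nb2 < 1e-12)) stop("p2 and p3 coincide: torsion undefined")
  if (any(row_norm(n1) < 1e-12) || any(row_norm(n2) < 1e-12))
    stop("collinear points: torsion undefined")
  m <- row_cross(n1, b2 / nb2)
  ang <- -atan2(row_dot(m, n2), row_dot(n1, n2))
  wrap_angle(rad2deg(ang))
}

## NeRF atom placement: given positions A, B, C (each n x 3), place D bonded
## to C with bond length r, bond angle theta at C (B-C-D) and torsion tau
## (A-B-C-D).  Vectorised over frames; r/theta fixed scalars, tau may be a
## vector of per-frame torsions.
nerf_place <- function(A, B, C, r, theta_deg, tau_deg) {
  th <- deg2rad(180 - theta_deg)   # supplement: direction continues the chain
  ta <- deg2rad(tau_deg)
  bc <- C - B
  bc <- bc / row_norm(bc)
  ab <- B - A
  n <- row_cross(ab, bc)
  nn <- row_norm(n)
  if (any(nn < 1e-12)) stop("degenerate NeRF frame: collinear reference atoms")
  n <- n / nn
  m <- row_cross(n, bc)
  d <- r * cbind(cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  C + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

## Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    ax <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  ax <- ax / s
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

## Kabsch: rotation matrix that best superposes moving onto fixed
## (both n x 3, uncentered).  Returns list(R, t) so that
## moving %*% R + t approximates fixed.
kabsch_transform <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M <- sweep(moving, 2, cm); F <- sweep(fixed, 2, cf)
  H <- crossprod(M, F)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, t = cf - as.vector(cm %*% R))
}

apply_transform <- function(coords, tr) {
  sweep(coords %*% tr$R, 2, tr$t, `+`)
}
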