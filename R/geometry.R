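# Internal vector geometry used by SSE assignment, the motif matcher and the
# fixture builders. All coordinates are Angstrom, all angles degrees unless
# stated otherwise.

.norm <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# signed torsion angle a-b-c-d in degrees, (-180, 180]
.dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  m1 <- .cross(n1, .unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# angle between two direction vectors in [0, 180]
.vec_angle <- function(u, v) {
  ct <- sum(.unit(u) * .unit(v))
  acos(max(-1, min(1, ct))) * 180 / pi
}

# place atom D given A, B, C with |C-D| = r, angle(B,C,D) = theta (deg) and
# torsion(A,B,C,D) = chi (deg): the standard internal-coordinate (NeRF) step
.place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- -chi * pi / 180
  d2 <- c(r * cos(pi - th),
          r * sin(pi - th) * cos(ch),
          r * sin(pi - th) * sin(ch))
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- cbind(bc, .cross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# rotation matrix for angle deg about unit axis
.rot_axis <- function(axis, deg) {
  u <- .unit(axis)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# least-squares line through points (n x 3): centroid + principal direction,
# oriented from first to last point; returns list(center, dir, start, end)
.fit_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  sv <- svd(x, nu = 0, nv = 1)
  d <- sv$v[, 1]
  if (sum(d * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) d <- -d
  t <- x %*% d
  list(center = ctr, dir = as.numeric(d),
       start = ctr + min(t) * d, end = ctr + max(t) * d)
}

# least-squares plane through points: returns list(center, normal)
.fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  sv <- svd(x, nu = 0, nv = 3)
  list(center = ctr, normal = as.numeric(sv$v[, 3]))
}

# Kabsch: optimal proper rotation R and translation t minimizing
# ||P R^T + t - Q||; P, Q are n x 3 with corresponding rows.
.kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)             # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

# minimum pairwise distance between two coordinate sets (n x 3, m x 3)
.min_dist <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(Inf)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}
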