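# Small 3-D geometry kernel shared by the trajectory modules.

#' Signed torsion angle for four points
#'
#' Standard IUPAC convention: looking from atom 2 towards atom 3, the angle
#' from the plane (1,2,3) to the plane (2,3,4); cis = 0 degrees, trans = 180
#' degrees; result in (-180, 180]. Computed with the atan2 formulation, which
#' is well conditioned near 0 and 180.
#'
#' @param p1,p2,p3,p4 numeric matrices (n x 3) or length-3 vectors.
#' @return numeric vector of angles in degrees, in (-180, 180].
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 3L)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n2 <- sqrt(rowSums(b2 * b2))
  if (any(n2 < 1e-12) ||
      any(rowSums(row_cross(b1, b2)^2) < 1e-20) ||
      any(rowSums(row_cross(b2, b3)^2) < 1e-20)) {
    stop("torsion_angle: degenerate (collinear) atom triplet", call. = FALSE)
  }
  c12 <- row_cross(b1, b2)
  c23 <- row_cross(b2, b3)
  y <- rowSums(b1 * c23) * n2
  x <- rowSums(c12 * c23)
  ang <- atan2(y, x) * 180 / pi
  # map -180 -> +180 so the range is (-180, 180]
  ang[ang <= -180 + 1e-12] <- 180
  ang
}

# Row-wise cross product of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Rotation matrix taking unit vector u onto unit vector v (Rodrigues).
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any axis orthogonal to u
    ortho <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ortho - sum(ortho * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- skew(axis)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

skew <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

# Rotation about z by angle (radians).
rotation_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

# Place a new atom D given positions A, B, C, a bond length |C-D|, a bond
# angle B-C-D (degrees) and a torsion A-B-C-D (degrees). The usual internal
# coordinate ("natural extension of reference frame") construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Supporting-plane representation of the convex hull of a small 3-D point
# set. Every plane through a triplet of points with all points on one side
# (within tol) is a supporting plane; the hull is the intersection of the
# corresponding halfspaces. O(n^3) in the point count, which is fine for the
# 10 anchor atoms it is used on. Coplanar facets (e.g. the pentagonal faces
# of an ideal bundle) are handled by the tolerance.
hull_halfspaces <- function(pts, tol = 1e-7) {
  n <- nrow(pts)
  if (n < 4) stop("hull_halfspaces: need at least 4 points", call. = FALSE)
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 3)
    stop("hull_halfspaces: degenerate (coplanar) anchor points", call. = FALSE)
  normals <- NULL
  offsets <- NULL
  idx <- utils::combn(n, 3)
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]; l <- idx[3, k]
    v1 <- pts[j, ] - pts[i, ]
    v2 <- pts[l, ] - pts[i, ]
    nv <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-10) next
    nv <- nv / nn
    d <- as.numeric(pts %*% nv) - sum(nv * pts[i, ])
    if (all(d <= tol)) {
      normals <- rbind(normals, nv)
      offsets <- c(offsets, sum(nv * pts[i, ]))
    } else if (all(d >= -tol)) {
      normals <- rbind(normals, -nv)
      offsets <- c(offsets, -sum(nv * pts[i, ]))
    }
  }
  if (is.null(normals))
    stop("hull_halfspaces: no supporting planes found", call. = FALSE)
  list(normals = normals, offsets = offsets)
}

# Closed-hull membership test: TRUE when the point is inside or on the hull.
in_hull <- function(hs, pts, tol = 1e-7) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3L)
  d <- pts %*% t(hs$normals)
  apply(d <= rep(hs$offsets + tol, each = nrow(pts)), 1L, all)
}
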