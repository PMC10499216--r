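# Small 3D geometry toolkit shared by the graph builder, featurizer and
# synthetic backbone generator. All coordinates are in Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) return(c(0, 0, 0))
  a / n
}

#' Planar angle at b formed by points a-b-c, in radians
#' @noRd
planar_angle <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v))))
}

#' Signed dihedral angle of points a-b-c-d, in radians, range (-pi, pi]
#' @noRd
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  atan2(sum(vcross(n1, n2) * unitv(b2)), sum(n1 * n2))
}

#' Place a new atom d at distance `bond` from c, with angle a(b,c,d) = `angle`
#' and dihedral (a,b,c,d) = `torsion` (NeRF construction; angles in radians)
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal tetrahedral C-beta position from backbone N, CA, C
#'
#' Standard construction used to impute the side-chain beta carbon for
#' glycine (and for any residue whose CB record is absent): an orthogonal
#' frame is built from the N-CA and C-CA bonds and the CB is placed at the
#' ideal tetrahedral position 1.53 Angstrom from CA.
#'
#' @param n,ca,c numeric length-3 backbone coordinates (Angstrom).
#' @return numeric length-3 CB coordinate.
#' @export
impute_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  ca + (-0.58273431 * a + 0.56802827 * b - 0.54067466 * cc)
}

#' Random rigid-body motion (optionally improper) for invariance testing
#'
#' @param reflect if `TRUE` the linear part has determinant -1.
#' @return list with 3x3 matrix `R` and length-3 translation `t`.
#' @export
random_rigid_motion <- function(reflect = FALSE) {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if ((det(R) < 0) != reflect) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 20))
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#' @param x n x 3 matrix.
#' @param motion list with `R` and `t` from [random_rigid_motion()].
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(x, motion) {
  sweep(x %*% t(motion$R), 2, motion$t, "+")
}

#' Surface area of the 3D convex hull of a point set
#'
#' Brute-force facet enumeration: every plane through three points that has
#' all remaining points on one side is a supporting plane; points on each
#' unique supporting plane are projected into 2D and their planar hull area
#' accumulated, so faces with more than three coplanar vertices are counted
#' once. Intended for small point sets (residue atom groups).
#'
#' @param pts n x 3 numeric matrix.
#' @param tol coplanarity tolerance (Angstrom).
#' @return total facet area; 0 if the hull is degenerate (fewer than 4
#'   points or all points coplanar).
#' @export
convex_hull_area <- function(pts, tol = 1e-7) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4) return(0)
  # degenerate (coplanar/collinear) point sets have no 3D hull
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < tol * max(sv[1], 1)) return(0)
  seen <- character(0)
  total <- 0
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        nrm <- vcross(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
        ln <- vnorm(nrm)
        if (ln < tol) next
        nrm <- nrm / ln
        s <- as.vector(pts %*% nrm) - sum(nrm * pts[i, ])
        if (all(s <= tol)) {
          # canonical orientation: outward normal
        } else if (all(s >= -tol)) {
          nrm <- -nrm
          s <- -s
        } else next
        key <- paste(round(c(nrm, sum(nrm * pts[i, ])), 6), collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        face <- which(abs(s) <= tol)
        total <- total + planar_face_area(pts[face, , drop = FALSE], nrm)
      }
    }
  }
  total
}

# area of the 2D convex hull of coplanar 3D points with plane normal nrm
planar_face_area <- function(pts, nrm) {
  if (nrow(pts) < 3) return(0)
  # orthonormal basis in the plane
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitv(vcross(nrm, ref))
  v <- vcross(nrm, u)
  p2 <- cbind(pts %*% u, pts %*% v)
  h <- grDevices::chull(p2[, 1], p2[, 2])
  hp <- p2[h, , drop = FALSE]
  m <- nrow(hp)
  if (m < 3) return(0)
  nx <- c(2:m, 1)
  abs(sum(hp[, 1] * hp[nx, 2] - hp[nx, 1] * hp[, 2])) / 2
}
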