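## Exact geometric primitives. All coordinates Angstrom, all angles degrees.

#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors, Angstrom.
#' @return distance in Angstrom.
#' @export
#' @examples
#' vecDistance(c(0, 0, 0), c(0, 0, 4)) # 4
vecDistance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    .err("non-finite coordinates in distance", "value_error")
  d <- a - b
  sqrt(sum(d * d))
}

#' Angle at vertex b between ba and bc
#'
#' @param a,b,c numeric 3-vectors; `b` is the vertex.
#' @return angle in degrees, in [0, 180].
#' @export
vecAngle <- function(a, b, c) {
  u <- .unitv(a - b)
  v <- .unitv(c - b)
  d <- sum(u * v)
  .rad2deg(acos(max(-1, min(1, d))))
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: cis (eclipsed) is 0 degrees, trans is 180 degrees;
#' the value lies in (-180, 180] with the trans branch mapped to +180.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors, Angstrom.
#' @return angle in degrees in (-180, 180].
#' @export
#' @examples
#' # trans-planar zig-zag
#' dihedralAngle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)) # 180
dihedralAngle <- function(p1, p2, p3, p4) {
  for (p in list(p1, p2, p3, p4))
    if (!all(is.finite(p))) .err("non-finite coordinates in dihedral",
                                 "value_error")
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 ||
      sqrt(sum(b3^2)) < 1e-9)
    .err("coincident consecutive points: dihedral undefined",
         "undefined_dihedral_error")
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  if (sqrt(sum(c1^2)) < 1e-9 || sqrt(sum(c2^2)) < 1e-9)
    .err("collinear points: dihedral undefined", "undefined_dihedral_error")
  ang <- .rad2deg(atan2(sum(.cross3(c1, c2) * b2) / sqrt(sum(b2^2)),
                        sum(c1 * c2)))
  # branch: (-180, 180], trans -> +180
  if (ang <= -180 + 1e-12) ang <- ang + 360
  ang
}

#' Kabsch superposition of two matched point clouds
#'
#' Finds the proper rotation (det = +1; mirror fits are rejected so chirality
#' is preserved) and translation minimising the least-squares deviation of
#' `mobile` from `reference` under positional correspondence, together with
#' the residual RMSD.
#'
#' @param mobile,reference N x 3 matrices, N >= 3, Angstrom.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   transformed = mobile %*% t(rotation) + translation (rowwise), and `rmsd`.
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) < 3L || nrow(reference) < 3L)
    .err("kabsch needs at least 3 points", "insufficient_points_error")
  .assert(nrow(mobile) == nrow(reference),
          "mobile and reference must have equal numbers of points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                   # rank-deficient: keep proper rotation
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)          # proper rotation: R %*% p (column vec)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum((moved - Q)^2) / nrow(P))
  translation <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform returned by kabsch() to a coordinate matrix
#'
#' @param xyz N x 3 matrix.
#' @param transform list with `rotation` and `translation`.
#' @return transformed N x 3 matrix.
#' @export
applyTransform <- function(xyz, transform) {
  m <- as.matrix(xyz) %*% t(transform$rotation)
  m + matrix(transform$translation, nrow(m), 3L, byrow = TRUE)
}

#' RMSD of an evaluation subset after fitting on a different subset
#'
#' The two-stage primitive behind the indole-core RMSD criterion: superpose
#' the fit subset (receptor frame alignment), then measure the RMSD of the
#' evaluation subset (ligand core) under that same transform, without
#' refitting.
#'
#' @param mobileFit,refFit M x 3 matrices (M >= 3) defining the superposition.
#' @param mobileEval,refEval K x 3 matrices (K >= 1) measured after the fit.
#' @return RMSD in Angstrom.
#' @export
rmsdAfterFitOnSubset <- function(mobileFit, refFit, mobileEval, refEval) {
  mobileEval <- rbind(as.matrix(mobileEval))
  refEval <- rbind(as.matrix(refEval))
  .assert(nrow(mobileEval) >= 1L && nrow(mobileEval) == nrow(refEval),
          "evaluation subsets must be non-empty and matched")
  tr <- kabsch(mobileFit, refFit)
  moved <- applyTransform(mobileEval, tr)
  sqrt(sum((moved - refEval)^2) / nrow(moved))
}
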