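## Low-level vector geometry: dihedral angles, internal-coordinate atom
## placement (natural extension reference frame), and Kabsch superposition.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Signed dihedral angle of four points
#'
#' IUPAC convention: looking from b to c, the angle from the a-b-c plane to
#' the b-c-d plane, positive clockwise, in degrees in (-180, 180].
#'
#' @param a,b,c,d Length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Place atom D bonded to C given chain A-B-C, bond length |CD|, angle
## B-C-D (deg) and dihedral A-B-C-D (deg). Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  bc <- c - b; bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc); n <- n / vnorm(n)
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d_local)
}

#' Kabsch superposition of one frame onto a reference
#'
#' Least-squares optimal proper rotation (determinant +1) and translation of
#' `mobile` onto `reference`, computed over `selection` and applied to all
#' atoms of `mobile`.
#'
#' @param mobile,reference atoms x 3 coordinate matrices (Angstrom).
#' @param selection Optional row indices used for the fit (default all);
#'   at least 3 non-collinear atoms.
#' @return List with `coords` (superposed mobile, all atoms) and `rmsd`
#'   (Angstrom, over the selection).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  stopifnot(length(selection) >= 3L, max(selection) <= nrow(mobile),
            max(selection) <= nrow(reference))
  x <- mobile[selection, , drop = FALSE]
  y <- reference[selection, , drop = FALSE]
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  if (max(svd(xc)$d) < 1e-12) stop("degenerate (zero-extent) selection")
  s <- svd(crossprod(xc, yc))           # X' Y
  if (s$d[2] < 1e-10 * s$d[1]) {
    stop("collinear or degenerate atom selection: rotation is not unique")
  }
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- xc %*% rot
  rmsd <- sqrt(mean(rowSums((fitted_sel - yc)^2)))
  all_fit <- sweep(sweep(mobile, 2L, cx) %*% rot, 2L, cy, "+")
  list(coords = all_fit, rmsd = rmsd)
}

#' Pairwise RMSD after optimal superposition
#'
#' @param mobile,reference atoms x 3 matrices.
#' @param selection Optional fit selection.
#' @return RMSD in Angstrom.
#' @export
superposed_rmsd <- function(mobile, reference, selection = NULL) {
  kabsch_superpose(mobile, reference, selection)$rmsd
}

## random rigid motion (rotation via QR of a Gaussian matrix + translation)
random_rigid_motion <- function(coords, rng_max_shift = 50) {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- stats::runif(3, -rng_max_shift, rng_max_shift)
  sweep(as.matrix(coords) %*% q, 2L, shift, "+")
}
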