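#' Signed dihedral angle between four points
#'
#' Computes the torsion angle defined by four points using the IUPAC sign
#' convention: looking from `p2` towards `p3`, a clockwise rotation of the
#' `p3`-`p4` bond relative to the `p1`-`p2` bond is positive. Angles are
#' reported in degrees on `(-180, 180]`; degrees are the unit for every
#' angle in this package.
#'
#' @param p1,p2,p3,p4 Numeric length-3 vectors (x, y, z in Angstrom), or
#'   matrices with 3 columns to compute many dihedrals at once (row-wise).
#' @return A numeric vector of angles in degrees in `(-180, 180]`.
#' @examples
#' dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)) # cis, 0
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- rbind3(p1); p2 <- rbind3(p2); p3 <- rbind3(p3); p4 <- rbind3(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (any(row_norm(b1) < 1e-9) || any(row_norm(b2) < 1e-9) ||
      any(row_norm(b3) < 1e-9)) {
    stop("dihedral_angle(): two consecutive points coincide", call. = FALSE)
  }
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  if (any(row_norm(n1) < 1e-9) || any(row_norm(n2) < 1e-9)) {
    stop("dihedral_angle(): three consecutive points are collinear",
         call. = FALSE)
  }
  x <- rowSums(n1 * n2)
  y <- rowSums(row_cross(n1, n2) * (b2 / row_norm(b2)))
  wrap_angle(atan2(y, x) * 180 / pi)
}

# wrap degrees into (-180, 180]
wrap_angle <- function(deg) {
  out <- deg - 360 * floor((deg + 180) / 360)
  out[out <= -180 + 1e-12] <- out[out <= -180 + 1e-12] + 360
  out[out > 180] <- out[out > 180] - 360
  out
}

rbind3 <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3)
    p
  } else {
    matrix(as.numeric(p), ncol = 3)
  }
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a^2))

#' Best-fit plane through a point set
#'
#' The plane through the centroid whose normal is the eigenvector of the
#' smallest eigenvalue of the covariance of the centered points (total
#' least squares).
#'
#' @param points Numeric matrix with 3 columns and at least 3 rows.
#' @return An object of class `qg_plane`: a list with `centroid` (length-3),
#'   `normal` (unit length-3) and `rms` (root-mean-square out-of-plane
#'   distance of the input points, Angstrom).
#' @export
best_fit_plane <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 3) stop("best_fit_plane(): need at least 3 points",
                             call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  e <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)
  if (e$values[2] < 1e-12) {
    stop("best_fit_plane(): points are collinear", call. = FALSE)
  }
  n <- e$vectors[, 3]
  n <- n / sqrt(sum(n^2))
  d <- as.numeric(x %*% n)
  structure(list(centroid = ctr, normal = n, rms = sqrt(mean(d^2))),
            class = "qg_plane")
}

#' @export
print.qg_plane <- function(x, ...) {
  cat("<qg_plane> centroid (", paste(sprintf("%.3f", x$centroid),
                                     collapse = ", "),
      ") normal (", paste(sprintf("%.4f", x$normal), collapse = ", "),
      ") rms ", sprintf("%.4f", x$rms), " A\n", sep = "")
  invisible(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets. Reflections are never returned: the determinant
#' of the rotation is forced to +1 (DNA is chiral), using the standard
#' sign correction on the smallest singular vector.
#'
#' @param mobile,reference Numeric matrices with 3 columns and equal row
#'   counts (paired points, Angstrom).
#' @return An object of class `qg_superposition`: list with `rotation`
#'   (3x3, det +1), `translation` (length-3) and `rmsd` (Angstrom). The
#'   fitted coordinates are
#'   `sweep(mobile, 2, cm) %*% rotation + translation` where `cm` is the
#'   mobile centroid; use [apply_superposition()].
#' @export
superpose <- function(mobile, reference) {
  mobile <- rbind3(mobile); reference <- rbind3(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("superpose(): coordinate sets must pair row-for-row", call. = FALSE)
  }
  if (nrow(mobile) < 3) stop("superpose(): need at least 3 paired points",
                             call. = FALSE)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  pm <- sweep(mobile, 2, cm)
  pr <- sweep(reference, 2, cr)
  s <- svd(crossprod(pm, pr))            # H = t(pm) %*% pr = U D V'
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- pm %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - pr)^2)))
  structure(list(rotation = rot, translation = cr, mobile_centroid = cm,
                 rmsd = rmsd),
            class = "qg_superposition")
}

#' Apply a fitted superposition to coordinates
#'
#' @param xyz Numeric matrix with 3 columns.
#' @param sp A `qg_superposition` from [superpose()].
#' @return Transformed coordinates, same shape as `xyz`.
#' @export
apply_superposition <- function(xyz, sp) {
  stopifnot(inherits(sp, "qg_superposition"))
  sweep(sweep(rbind3(xyz), 2, sp$mobile_centroid) %*% sp$rotation,
        2, sp$translation, `+`)
}

#' @export
print.qg_superposition <- function(x, ...) {
  cat("<qg_superposition> rmsd", sprintf("%.4f", x$rmsd), "A\n")
  invisible(x)
}

#' Root-mean-square deviation between paired coordinate sets
#'
#' @param a,b Numeric matrices with 3 columns, equal row counts.
#' @param fit If `TRUE`, superpose `a` onto `b` first ([superpose()]);
#'   if `FALSE`, compute the deviation in place.
#' @return RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b, fit = FALSE) {
  a <- rbind3(a); b <- rbind3(b)
  if (nrow(a) != nrow(b)) {
    stop("rmsd_coords(): coordinate sets must pair row-for-row",
         call. = FALSE)
  }
  if (fit) {
    superpose(a, b)$rmsd
  } else {
    sqrt(mean(rowSums((a - b)^2)))
  }
}

# random proper rotation (uniform via QR of gaussian matrix), internal
random_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
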