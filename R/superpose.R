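#' Optimal rigid-body superposition of two coordinate sets (Kabsch)
#'
#' Finds the proper rotation and translation that superpose coordinate set
#' `coords_b` onto `coords_a` in the least-squares sense, and the minimized
#' root-mean-square deviation (RMSD). The rotation is obtained from the
#' singular value decomposition of the cross-covariance matrix of the
#' mean-centred coordinates; a reflection (improper rotation) is corrected by
#' flipping the sign of the singular vector associated with the smallest
#' singular value, so `det(rotation)` is always +1.
#'
#' @param coords_a,coords_b Numeric matrices of dimension N x 3 (Angstrom),
#'   row i of `coords_a` paired with row i of `coords_b`. N must be >= 3.
#' @return An object of class `kabsch_superposition`: a list with elements
#'   `rotation` (3 x 3 proper rotation matrix), `translation` (length-3
#'   vector), `rmsd` (Angstrom) and `n_atoms`. The transform maps b onto a:
#'   `a_hat = b %*% t(rotation) + translation`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' th <- 0.3
#' rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' b <- a %*% rot + 5
#' kabsch_superpose(a, b)$rmsd  # ~0
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as_coord_matrix(coords_a)
  coords_b <- as_coord_matrix(coords_b)
  if (nrow(coords_a) != nrow(coords_b)) {
    stop("coordinate sets differ in length (", nrow(coords_a), " vs ",
         nrow(coords_b), ")", call. = FALSE)
  }
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 paired atoms, got ", n, call. = FALSE)

  cen_a <- colMeans(coords_a)
  cen_b <- colMeans(coords_b)
  a <- sweep(coords_a, 2, cen_a)
  b <- sweep(coords_b, 2, cen_b)

  # rank deficiency (collinear/coplanar points) makes the rotation about the
  # degenerate axis arbitrary; the RMSD is still well defined
  sv_a <- svd(a, nu = 0, nv = 0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1e-12)) {
    warning("degenerate (collinear) coordinates; rotation not unique",
            call. = FALSE)
  }

  h <- crossprod(b, a)  # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  corr <- diag(c(1, 1, d))
  rot <- s$v %*% corr %*% t(s$u)

  b_rot <- b %*% t(rot)
  rmsd <- sqrt(mean(rowSums((a - b_rot)^2)))
  translation <- as.numeric(cen_a - rot %*% cen_b)

  structure(
    list(rotation = rot, translation = translation,
         rmsd = rmsd, n_atoms = n),
    class = "kabsch_superposition"
  )
}

#' Apply a superposition transform to coordinates
#'
#' @param superposition A `kabsch_superposition` object.
#' @param coords N x 3 matrix of coordinates in the frame of the second
#'   (moving) structure.
#' @return N x 3 matrix in the frame of the first (fixed) structure.
#' @export
apply_superposition <- function(superposition, coords) {
  stopifnot(inherits(superposition, "kabsch_superposition"))
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(superposition$rotation), 2,
        superposition$translation, `+`)
}

#' @export
print.kabsch_superposition <- function(x, ...) {
  cat("Kabsch superposition over", x$n_atoms, "atoms\n")
  cat(sprintf("  RMSD: %.4f Angstrom\n", x$rmsd))
  invisible(x)
}

#' @export
glance.kabsch_superposition <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_atoms = x$n_atoms,
                 det_rotation = det(x$rotation))
}

# coerce tibbles / data frames with x,y,z columns or plain matrices to Nx3
as_coord_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("x", "y", "z") %in% names(x))) {
      stop("data frame input must have columns x, y, z", call. = FALSE)
    }
    x <- cbind(x$x, x$y, x$z)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) stop("coordinates must be N x 3", call. = FALSE)
  if (!all(is.finite(x))) stop("coordinates must be finite", call. = FALSE)
  x
}

# plain RMSD between already-aligned coordinate sets
rmsd_inframe <- function(a, b) {
  a <- as_coord_matrix(a); b <- as_coord_matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# uniform random rotation matrix (quaternion method), used by the synthetic
# generators and the mock docking engine
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}
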