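#' Rigid transform (proper rotation + translation)
#'
#' A rigid-body transform in the convention used throughout the package:
#' it maps *target* coordinates into the *query* frame, `x -> R x + t`.
#' The rotation must be orthonormal with determinant +1 (no reflection).
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation vector, in Angstrom.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' rigid_transform(diag(3), c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err >= 1e-8)
    stop("rotation is not orthonormal (max |R'R - I| = ", format(err), ")")
  if (abs(det(rotation) - 1) >= 1e-8)
    stop("rotation has determinant ", format(det(rotation)),
         "; reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.3f, %.3f, %.3f) A\n",
              ang * 180 / pi, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Identity transform
#' @return A `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to coordinates
#'
#' @param t A [rigid_transform()].
#' @param coords Numeric n x 3 matrix of coordinates (rows are points).
#' @return The transformed n x 3 matrix `coords %*% t(R) + t`.
#' @export
apply_transform <- function(t, coords) {
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(t$rotation), 2, t$translation, "+")
}

#' Invert a rigid transform
#' @param t A [rigid_transform()].
#' @return The inverse transform `x -> R' (x - t)`.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation))
}

#' Compose two rigid transforms
#' @param a,b [rigid_transform()]s; the result applies `b` first, then `a`.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Rotation angle of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Rotation angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Optimal superposition of two point sets (Kabsch)
#'
#' Finds the rigid transform (proper rotation + translation) minimizing the
#' root-mean-square deviation between `q_coords` and the transformed
#' `t_coords`, by singular value decomposition of the cross-covariance
#' matrix with the standard sign correction that excludes reflections.
#'
#' @param q_coords,t_coords n x 3 coordinate matrices with equal n >= 3.
#' @return A list with `transform` (a [rigid_transform()] mapping
#'   `t_coords` onto `q_coords`) and `rmsd` (the minimized RMSD, Angstrom).
#' @examples
#' q <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(q, q)$rmsd  # 0
#' @export
kabsch_superpose <- function(q_coords, t_coords) {
  q_coords <- as_coord_matrix(q_coords)
  t_coords <- as_coord_matrix(t_coords)
  if (nrow(q_coords) != nrow(t_coords))
    stop("coordinate sets differ in length (", nrow(q_coords), " vs ",
         nrow(t_coords), ")")
  if (nrow(q_coords) < 3L)
    stop("superposition needs at least 3 points")
  if (coord_rank(q_coords) < 2L || coord_rank(t_coords) < 2L)
    stop("degenerate geometry: points are collinear or coincident")
  res <- .kabsch_cpp(q_coords, t_coords)
  list(transform = rigid_transform(res$rotation, as.numeric(res$translation)),
       rmsd = res$rmsd)
}

as_coord_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x))
    x <- do.call(rbind, x)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("coordinates must be n x 3")
  x
}

coord_rank <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  qr(xc)$rank
}
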