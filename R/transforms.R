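#' Rigid-body transform
#'
#' A proper rigid transform acting on row vectors of coordinates as
#' `x %*% t(rotation) + translation` (i.e. `y = R x + t` for column vectors).
#'
#' @param rotation 3x3 proper orthonormal matrix (det = +1).
#' @param translation length-3 numeric vector, Angstrom.
#' @return An object of class `rigid_transform` with elements `rotation` and
#'   `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal (R^T R != I within 1e-9)")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not proper (det != +1); reflections are not allowed")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  sd <- screw_decompose(x)
  cat("rigid_transform: rotation", sprintf("%.2f", sd$angle_deg),
      "deg, slide", sprintf("%.2f", sd$slide), "A",
      if (sd$degenerate) "(degenerate axis)" else "", "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param coords n x 3 numeric matrix (rows are points).
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- rbind(coords) # tolerate a single point as a vector
  coords %*% t(transform$rotation) +
    matrix(transform$translation, nrow(coords), 3, byrow = TRUE)
}

#' Compose two rigid transforms
#'
#' `compose_transform(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimising the RMSD between `mobile` and
#' `target` point sets (rows paired by index).
#'
#' @param mobile,target equal-size n x 3 matrices, n >= 3, not collinear.
#' @return List with `transform` (maps mobile onto target) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("mobile and target must be equal-size n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  # collinearity: rank of centred mobile set < 2
  if (svd(A)$d[2] < 1e-8 * max(1, svd(A)$d[1]))
    stop("points are collinear; superposition is underdetermined")
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- rigid_transform(R, ct - as.numeric(R %*% cm))
  moved <- apply_transform(tr, mobile)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - target)^2))))
}

#' Screw (Chasles) decomposition of a rigid transform
#'
#' Any proper rigid motion is a rotation about an axis plus a translation
#' (slide) along that axis. The angle is reported in \[0, 180\] degrees and the
#' axis is oriented so the slide is non-negative whenever the angle is
#' non-degenerate.
#'
#' @param transform A [rigid_transform()].
#' @return List with `axis_point`, `axis_dir`, `angle_deg`, `slide` (Angstrom)
#'   and logical `degenerate` (TRUE when the rotation angle is below 0.1 degrees
#'   and the axis is undefined; the slide is then the full translation norm).
#' @export
screw_decompose <- function(transform) {
  R <- transform$rotation; tv <- transform$translation
  cs <- (sum(diag(R)) - 1) / 2
  angle <- acos(min(1, max(-1, cs)))
  if (angle * 180 / pi < 0.1) {
    nrm <- sqrt(sum(tv^2))
    dir <- if (nrm > 0) tv / nrm else c(0, 0, 1)
    return(list(axis_point = c(0, 0, 0), axis_dir = dir,
                angle_deg = angle * 180 / pi, slide = nrm, degenerate = TRUE))
  }
  if (pi - angle > 1e-6) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    # angle ~ 180 deg: axis from the symmetric part eigenvector
    ev <- eigen((R + diag(3)) / 2, symmetric = TRUE)
    axis <- ev$vectors[, 1]
  }
  axis <- axis / sqrt(sum(axis^2))
  # the axis point must be computed with the orientation consistent with R
  # (R = rotation by +angle about `axis` as extracted above); the reported
  # direction may then be flipped to make the slide non-negative
  slide <- sum(tv * axis)
  t_perp <- tv - slide * axis
  # point on the axis: solve (I - R) q = t_perp with q orthogonal to the axis
  q <- 0.5 * (t_perp + pracma::cross(axis, t_perp) / tan(angle / 2))
  if (slide < 0) { axis <- -axis; slide <- -slide }
  list(axis_point = as.numeric(q), axis_dir = as.numeric(axis),
       angle_deg = angle * 180 / pi, slide = slide, degenerate = FALSE)
}
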