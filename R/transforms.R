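#' Rigid transform
#'
#' A proper rigid transform: a 3x3 rotation matrix (orthonormal, determinant
#' +1) plus a translation vector in mm. Applied to row-vector points as
#' `p' = p R^T + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector (mm).
#' @param tol orthonormality tolerance.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-9) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > tol)
    stop("rotation is not orthonormal (tolerance ", tol, ")")
  if (abs(det(rotation) - 1) > tol)
    stop("rotation determinant is not +1; reflections are not rigid transforms")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 6), collapse = " "), "mm\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric matrix with 3 columns (or a length-3 vector).
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, ncol = 3L) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (vec) as.numeric(out) else out
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform that applies `b` first,
#' then `a` (matrix convention `a %*% b`).
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Elementary rotation about a world axis
#'
#' Returns the standard right-handed rotation matrix about the world X, Y or
#' Z axis as a [rigid_transform()] with zero translation. About X this is the
#' flexion-extension generator, about Y abduction-adduction, about Z
#' internal-external rotation (world axes: X mediolateral to the patient's
#' right, Y anterior, Z superior).
#'
#' @param axis `"X"`, `"Y"` or `"Z"`.
#' @param angle_deg rotation angle in degrees.
#' @return a `rigid_transform`.
#' @export
#' @examples
#' apply_transform(rotation_about_world_axis("X", 90), c(0, 1, 0)) # -> (0, 0, 1)
rotation_about_world_axis <- function(axis, angle_deg) {
  stopifnot(is.finite(angle_deg))
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  rot <- switch(toupper(axis),
    X = rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca)),
    Y = rbind(c(ca, 0, sa), c(0, 1, 0), c(-sa, 0, ca)),
    Z = rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1)),
    stop("axis must be one of 'X', 'Y', 'Z'")
  )
  rigid_transform(rot, c(0, 0, 0))
}

#' Rotation aligning one unit vector with another
#'
#' Minimal rotation taking direction `from` to direction `to`; for
#' antiparallel inputs a 180 degree rotation about a perpendicular axis is
#' returned.
#'
#' @param from,to length-3 direction vectors (need not be unit length).
#' @return a `rigid_transform` with zero translation.
#' @export
rotation_between <- function(from, to) {
  f <- from / sqrt(sum(from^2))
  t_ <- to / sqrt(sum(to^2))
  v <- c(f[2] * t_[3] - f[3] * t_[2],
         f[3] * t_[1] - f[1] * t_[3],
         f[1] * t_[2] - f[2] * t_[1])
  c_ <- sum(f * t_)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(rigid_transform(diag(3), c(0, 0, 0)))
    # antiparallel: rotate 180 degrees about any axis perpendicular to f
    perp <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * f) * f
    axis <- axis / sqrt(sum(axis^2))
    rot <- 2 * tcrossprod(axis) - diag(3)
    return(rigid_transform(rot, c(0, 0, 0)))
  }
  vx <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  rot <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  rigid_transform(rot, c(0, 0, 0))
}
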