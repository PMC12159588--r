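#' Anatomical landmark set
#'
#' Named 3D points in mm. The pelvic frame needs `ASIS_right`, `ASIS_left`,
#' `PTUB_right`, `PTUB_left` (anterior superior iliac spines and pubic
#' tubercles) plus the hip joint centre `HJC`; the femoral frame needs
#' `EPI_lateral`, `EPI_medial`, `knee_center` and `HJC`.
#'
#' @param ... named length-3 numeric vectors.
#' @return an object of class `landmark_set` (a named list of points).
#' @export
#' @examples
#' lm <- landmark_set(HJC = c(0, 0, 0), knee_center = c(0, 0, -400),
#'                    EPI_lateral = c(40, 0, -400), EPI_medial = c(-40, 0, -400))
landmark_set <- function(...) {
  pts <- list(...)
  if (is.null(names(pts)) || any(names(pts) == ""))
    stop("all landmarks must be named")
  pts <- lapply(pts, as.numeric)
  ok <- vapply(pts, function(p) length(p) == 3L && all(is.finite(p)), TRUE)
  if (!all(ok))
    stop("non-finite or wrongly sized landmarks: ",
         paste(names(pts)[!ok], collapse = ", "))
  structure(pts, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in names(x))
    cat(sprintf("  %-12s %8.2f %8.2f %8.2f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

PELVIC_LANDMARKS <- c("ASIS_right", "ASIS_left", "PTUB_right", "PTUB_left", "HJC")
FEMORAL_LANDMARKS <- c("EPI_lateral", "EPI_medial", "knee_center", "HJC")

require_landmarks <- function(landmarks, names_needed) {
  missing <- setdiff(names_needed, names(landmarks))
  if (length(missing) > 0L)
    stop("missing landmarks: ", paste(missing, collapse = ", "))
  invisible(landmarks)
}

#' Coordinate frame
#'
#' An origin plus a right-handed orthonormal basis. `axes` holds the X, Y
#' and Z unit vectors as columns, so `axes` is the rotation that maps frame
#' coordinates to world coordinates.
#'
#' @param origin length-3 numeric (mm).
#' @param axes 3x3 matrix with unit basis vectors in columns.
#' @param tol orthonormality tolerance.
#' @return an object of class `frame`.
#' @export
frame <- function(origin = c(0, 0, 0), axes = diag(3), tol = 1e-9) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  stopifnot(length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (max(abs(crossprod(axes) - diag(3))) > tol)
    stop("frame axes are not orthonormal")
  if (det(axes) < 0)
    stop("frame axes are not right-handed")
  structure(list(origin = origin, axes = axes), class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame> origin:", paste(round(x$origin, 3), collapse = " "), "mm\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' World-from-frame rigid transform
#'
#' @param f a [frame()].
#' @return the [rigid_transform()] mapping frame coordinates to world.
#' @export
frame_to_world <- function(f) rigid_transform(f$axes, f$origin)

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction (zero length)")
  v / n
}

#' Pelvic coordinate system from landmarks
#'
#' Builds the pelvic frame from the two anterior superior iliac spines
#' (ASIS), the two pubic tubercles (PTUB), and the hip joint centre (HJC),
#' following the anterior pelvic plane (APP) convention: the mediolateral X
#' axis runs from the left to the right ASIS; the anteroposterior Y axis is
#' the APP normal (plane through both ASIS and the pubic-tubercle midpoint),
#' pointing anteriorly; Z completes the right-handed frame (superior). The
#' origin is the HJC.
#'
#' @param landmarks a [landmark_set()] with the pelvic names present.
#' @return a [frame()].
#' @export
build_pelvic_frame <- function(landmarks) {
  require_landmarks(landmarks, PELVIC_LANDMARKS)
  ar <- landmarks$ASIS_right
  al <- landmarks$ASIS_left
  if (sqrt(sum((ar - al)^2)) < 1e-9) stop("left and right ASIS coincide")
  x <- unit(ar - al)
  m_asis <- (ar + al) / 2
  m_ptub <- (landmarks$PTUB_right + landmarks$PTUB_left) / 2
  v <- m_ptub - m_asis
  y_raw <- c(x[2] * v[3] - x[3] * v[2],
             x[3] * v[1] - x[1] * v[3],
             x[1] * v[2] - x[2] * v[1])
  if (sqrt(sum(y_raw^2)) < 1e-9 * sqrt(sum(v^2)) || sqrt(sum(v^2)) < 1e-9)
    stop("pelvic landmarks are collinear; APP is degenerate")
  y <- unit(y_raw)
  z <- c(x[2] * y[3] - x[3] * y[2],
         x[3] * y[1] - x[1] * y[3],
         x[1] * y[2] - x[2] * y[1])
  frame(origin = landmarks$HJC, axes = cbind(x, y, z))
}

#' Femoral coordinate system from landmarks
#'
#' Longitudinal Z axis from the knee centre to the HJC; mediolateral X axis
#' from the medial to the lateral epicondyle, orthogonalised against Z;
#' anteroposterior Y completes the right-handed frame. Origin at the HJC.
#'
#' @param landmarks a [landmark_set()] with the femoral names present.
#' @return a [frame()].
#' @export
build_femoral_frame <- function(landmarks) {
  require_landmarks(landmarks, FEMORAL_LANDMARKS)
  hjc <- landmarks$HJC
  kc <- landmarks$knee_center
  if (sqrt(sum((hjc - kc)^2)) < 1e-9) stop("HJC coincides with knee centre")
  z <- unit(hjc - kc)
  epi <- landmarks$EPI_lateral - landmarks$EPI_medial
  x_raw <- epi - sum(epi * z) * z
  if (sqrt(sum(x_raw^2)) < 1e-9 * sqrt(sum(epi^2)) || sqrt(sum(epi^2)) < 1e-9)
    stop("epicondylar line is parallel to the longitudinal axis")
  x <- unit(x_raw)
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  frame(origin = hjc, axes = cbind(x, y, z))
}

#' Rigid least-squares fit between corresponding point sets
#'
#' Closed-form (SVD) solution of the orthogonal Procrustes problem without
#' scaling: finds rotation `R` and translation `t` minimising
#' `sum || R source_i + t - target_i ||^2`.
#'
#' @param source,target numeric matrices with matching rows (n >= 3) and 3
#'   columns.
#' @return a [rigid_transform()]; attribute `"rms"` holds the root mean
#'   squared residual (mm).
#' @export
rigid_best_fit <- function(source, target) {
  source <- as.matrix(source)
  target <- as.matrix(target)
  if (nrow(source) != nrow(target)) stop("point sets must have equal length")
  if (nrow(source) < 3L) stop("at least 3 correspondences are required")
  cs <- colMeans(source)
  ct <- colMeans(target)
  a <- sweep(source, 2, cs)
  b <- sweep(target, 2, ct)
  if (svd(crossprod(a))$d[2] < 1e-9 * max(1, sum(a^2)))
    stop("source points are collinear; rotation is underdetermined")
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- ct - as.numeric(rot %*% cs)
  fit <- rigid_transform(rot, tr, tol = 1e-6)
  resid <- apply_transform(fit, source) - target
  attr(fit, "rms") <- sqrt(mean(rowSums(resid^2)))
  fit
}
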