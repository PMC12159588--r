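#' Triangle mesh
#'
#' Constructs a validated triangle mesh. Meshes are stored with an `n x 3`
#' numeric vertex matrix (millimetres), an `m x 3` integer face matrix of
#' 1-based vertex indices, and a component label naming the part of the hip
#' model the mesh represents.
#'
#' @param vertices numeric matrix with 3 columns, one row per vertex (mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param label component name: one of `"pelvis"`, `"femur"`, `"cup"`,
#'   `"liner"`, `"head"`, `"stem"`, or any other identifier for fixtures.
#' @return an object of class `trimesh`.
#' @export
#' @examples
#' tet <- trimesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
#'   label = "femur"
#' )
#' n_faces(tet)
trimesh <- function(vertices, faces, label = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  mesh <- structure(
    list(vertices = vertices, faces = faces, label = as.character(label)[1]),
    class = "trimesh"
  )
  validate_trimesh(mesh)
  mesh
}

#' Validate a triangle mesh
#'
#' Checks the `trimesh` invariants: finite coordinates, face indices in
#' range, and no degenerate (zero-area) triangles.
#'
#' @param mesh a `trimesh`.
#' @param degenerate_tol triangles with area below this value (mm^2) are
#'   reported as degenerate.
#' @return `mesh`, invisibly; errors describe all offending faces.
#' @export
validate_trimesh <- function(mesh, degenerate_tol = 1e-12) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 3L) stop("mesh '", mesh$label, "' has fewer than 3 vertices")
  if (nrow(f) < 1L) stop("mesh '", mesh$label, "' has no faces")
  if (!all(is.finite(v))) stop("mesh '", mesh$label, "' has non-finite coordinates")
  if (any(f < 1L) || any(f > nrow(v)))
    stop("mesh '", mesh$label, "' has face indices out of range")
  areas <- triangle_areas(mesh)
  bad <- which(areas <= degenerate_tol)
  if (length(bad) > 0L)
    stop("mesh '", mesh$label, "' has degenerate (zero-area) faces: ",
         paste(bad, collapse = ", "))
  invisible(mesh)
}

#' Triangle areas of a mesh
#'
#' @param mesh a `trimesh`.
#' @return numeric vector of face areas (mm^2).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Number of faces / vertices
#'
#' @param mesh a `trimesh`.
#' @return integer count.
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

#' @rdname n_faces
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s': %d vertices, %d faces>\n",
              x$label, n_vertices(x), n_faces(x)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] mm\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a `trimesh`.
#' @param transform a [rigid_transform()].
#' @return the transformed `trimesh` (label preserved).
#' @export
transform_mesh <- function(mesh, transform) {
  mesh$vertices <- apply_transform(transform, mesh$vertices)
  mesh
}

#' Reflect a mesh across the plane x = 0
#'
#' Face winding is flipped so outward normals remain outward.
#' @param mesh a `trimesh`.
#' @return the mirrored `trimesh`.
#' @export
reflect_mesh_x <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}

#' Merge duplicate vertices
#'
#' Vertices closer than `tol` (snapped to a grid of spacing `tol`) are
#' merged; used by the STL reader, where each facet repeats its corners.
#'
#' @param vertices numeric matrix of vertex coordinates.
#' @param faces integer face matrix indexing `vertices`.
#' @param tol merge tolerance in mm.
#' @return list with merged `vertices` and re-indexed `faces`.
#' @export
merge_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3L))
}
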