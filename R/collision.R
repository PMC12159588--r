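#' Build an axis-aligned bounding-box hierarchy over a mesh
#'
#' Deterministic median-split AABB tree: at each node the triangles are
#' split at the median centroid along the longest axis of the centroid
#' bounds (ties broken by triangle index). Leaves hold at most `leaf_size`
#' triangles; every triangle's box is contained in all its ancestors' boxes
#' and the leaf triangle sets partition the face set.
#'
#' @param mesh a [trimesh()].
#' @param leaf_size maximum triangles per leaf (default 4).
#' @return an object of class `bvh` (flat-array tree; node 1 is the root,
#'   `left`/`right` are `NA` at leaves, `order` is the triangle permutation).
#' @export
build_bvh <- function(mesh, leaf_size = 4L) {
  validate_trimesh(mesh)
  out <- .cpp_build_bvh(mesh$vertices, mesh$faces, as.integer(leaf_size))
  out$label <- mesh$label
  class(out) <- "bvh"
  out
}

#' @export
print.bvh <- function(x, ...) {
  cat(sprintf("<bvh over '%s': %d faces, %d nodes, leaf size %d>\n",
              x$label, x$n_faces, length(x$left), x$leaf_size))
  invisible(x)
}

#' Do two triangles intersect?
#'
#' Closed-triangle convention: sharing a single point (a touching vertex or
#' edge) counts as intersecting. Ties within the floating-point tolerance
#' (1e-10 on scaled coordinates) resolve toward intersecting.
#'
#' @param t1,t2 3x3 matrices, one vertex per row (mm).
#' @return logical.
#' @export
triangles_intersect <- function(t1, t2) {
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  stopifnot(all(dim(t1) == c(3L, 3L)), all(dim(t2) == c(3L, 3L)))
  for (tr in list(t1, t2)) {
    e1 <- tr[2, ] - tr[1, ]
    e2 <- tr[3, ] - tr[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(n^2)) <= 1e-12 * max(1, sum(tr^2)))
      stop("degenerate triangle passed to triangles_intersect")
  }
  .cpp_tri_tri(t1, t2)
}

contact_report <- function(colliding, label_a, label_b, tri_a, tri_b) {
  structure(list(colliding = colliding,
                 witness = if (colliding)
                   list(a = list(label = label_a, triangle = tri_a),
                        b = list(label = label_b, triangle = tri_b))
                 else NULL),
            class = "contact_report")
}

#' @export
print.contact_report <- function(x, ...) {
  if (x$colliding)
    cat(sprintf("<contact: %s[%d] x %s[%d]>\n", x$witness$a$label,
                x$witness$a$triangle, x$witness$b$label, x$witness$b$triangle))
  else cat("<no contact>\n")
  invisible(x)
}

#' BVH-accelerated mesh-mesh collision test
#'
#' Tests whether two posed triangle meshes share at least one point
#' (surface intersection; touching counts). The colliding flag is
#' independent of argument order and agrees with [brute_force_collide()].
#'
#' @param a,b [trimesh()] objects in their posed positions.
#' @param bvh_a,bvh_b optional prebuilt [build_bvh()] trees for `a`/`b`;
#'   built on the fly when omitted. Must have been built from the posed
#'   meshes as passed.
#' @return a `contact_report`: `colliding` flag plus, when colliding, a
#'   witness pair of (mesh label, triangle index).
#' @export
meshes_collide <- function(a, b, bvh_a = NULL, bvh_b = NULL) {
  if (is.null(bvh_a)) bvh_a <- build_bvh(a)
  if (is.null(bvh_b)) bvh_b <- build_bvh(b)
  res <- .cpp_bvh_collide(a$vertices, a$faces, unclass(bvh_a),
                          b$vertices, b$faces, unclass(bvh_b))
  contact_report(res$colliding, a$label, b$label, res$tri1, res$tri2)
}

#' Brute-force mesh-mesh collision test
#'
#' All-pairs triangle-triangle reference path; the independent oracle for
#' [meshes_collide()].
#'
#' @param a,b [trimesh()] objects in their posed positions.
#' @return a `contact_report`.
#' @export
brute_force_collide <- function(a, b) {
  res <- .cpp_brute_collide(a$vertices, a$faces, b$vertices, b$faces)
  contact_report(res$colliding, a$label, b$label, res$tri1, res$tri2)
}
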