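# Shared fixtures and independent oracles for the test suite.

# unit tetrahedron (4 vertices, 4 faces)
unit_tetrahedron <- function(label = "femur") {
  trimesh(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
    label = label
  )
}

# write a mesh as binary STL (little-endian), to exercise the binary reader
write_binary_stl <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(n_faces(mesh)), con, size = 4, endian = "little")
  for (i in seq_len(n_faces(mesh))) {
    tri <- mesh$vertices[mesh$faces[i, ], , drop = FALSE]
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    n <- n / max(sqrt(sum(n^2)), 1e-30)
    writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

# independent separating-axis oracle for closed-triangle intersection:
# triangles are disjoint iff some candidate axis strictly separates their
# projections (face normals, edge cross products, in-plane edge normals)
sat_triangles_intersect <- function(t1, t2) {
  e1 <- list(t1[2, ] - t1[1, ], t1[3, ] - t1[2, ], t1[1, ] - t1[3, ])
  e2 <- list(t2[2, ] - t2[1, ], t2[3, ] - t2[2, ], t2[1, ] - t2[3, ])
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(e1[[1]], e1[[2]])
  n2 <- cr(e2[[1]], e2[[2]])
  axes <- c(list(n1, n2),
            unlist(lapply(e1, function(a) lapply(e2, function(b) cr(a, b))),
                   recursive = FALSE),
            lapply(e1, function(a) cr(n1, a)),
            lapply(e2, function(b) cr(n2, b)))
  scale <- max(abs(rbind(t1, t2)), 1)
  for (ax in axes) {
    len <- sqrt(sum(ax^2))
    if (len < 1e-12 * scale^2) next
    ax <- ax / len
    p1 <- t1 %*% ax
    p2 <- t2 %*% ax
    if (max(p1) < min(p2) - 1e-9 * scale || max(p2) < min(p1) - 1e-9 * scale)
      return(FALSE)
  }
  TRUE
}

# random well-conditioned triangle (rejects slivers)
random_triangle <- function(center = c(0, 0, 0), size = 1) {
  repeat {
    tri <- matrix(stats::runif(9, -size, size), 3, 3, byrow = TRUE)
    tri <- sweep(tri, 2, center, "+")
    e1 <- tri[2, ] - tri[1, ]
    e2 <- tri[3, ] - tri[1, ]
    n <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(n^2)) / 2 > 0.05 * size^2) return(tri)
  }
}

# random lumpy closed mesh with roughly n_target faces
random_blob_mesh <- function(n_target = 300, label = "blob") {
  n_rings <- max(4L, as.integer(round(sqrt(n_target / 2))))
  n_seg <- 2L * n_rings
  base <- uv_sphere_mesh(1, n_seg = n_seg, n_rings = n_rings, label = label)
  dir <- matrix(stats::rnorm(9), 3, 3)
  bump <- function(v) {
    r <- sqrt(rowSums(v^2))
    u <- v / r
    f <- 1 + 0.3 * sin(3 * (u %*% dir[, 1])) * cos(2 * (u %*% dir[, 2]))
    v * as.numeric(f)
  }
  base$vertices <- bump(base$vertices)
  base
}

random_rigid_transform <- function(max_translation = 1) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
  rigid_transform(rot, stats::runif(3, -max_translation, max_translation),
                  tol = 1e-6)
}

# small parametric model for fast ROM tests
fast_hip <- function(...) {
  make_parametric_hip(synthetic_hip_params(resolution = 300L, ...))
}
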