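# Parametric watertight mesh primitives used by the synthetic-data module.
# All primitives index shared vertices explicitly (wrapped seams, single pole
# vertices), so the resulting surfaces are watertight by construction.

# faces between two vertex rings of equal length (wrapped)
ring_band_faces <- function(ring_a, ring_b) {
  n <- length(ring_a)
  j2 <- c(2:n, 1L)
  rbind(cbind(ring_a, ring_a[j2], ring_b[j2]),
        cbind(ring_a, ring_b[j2], ring_b))
}

# triangle fan from a pole vertex to a ring; `flip` reverses the winding
pole_fan_faces <- function(pole, ring, flip = FALSE) {
  n <- length(ring)
  j2 <- c(2:n, 1L)
  if (flip) cbind(pole, ring[j2], ring) else cbind(pole, ring, ring[j2])
}

circle_ring <- function(radius, z, n_seg, phase = 0) {
  phi <- phase + 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  cbind(radius * cos(phi), radius * sin(phi), z)
}

#' UV-sphere mesh
#'
#' @param radius sphere radius (mm).
#' @param center length-3 centre (mm).
#' @param n_seg azimuthal segments.
#' @param n_rings polar subdivisions (>= 2).
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
uv_sphere_mesh <- function(radius, center = c(0, 0, 0), n_seg = 24L,
                           n_rings = 12L, label = "sphere") {
  stopifnot(radius > 0, n_seg >= 3L, n_rings >= 2L)
  theta <- pi * seq_len(n_rings - 1L) / n_rings
  verts <- rbind(c(0, 0, radius))
  rings <- vector("list", n_rings - 1L)
  for (i in seq_along(theta)) {
    ring <- circle_ring(radius * sin(theta[i]), radius * cos(theta[i]), n_seg)
    rings[[i]] <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, ring)
  }
  south <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, -radius))
  faces <- pole_fan_faces(1L, rings[[1]], flip = TRUE)
  if (n_rings > 2L)
    for (i in seq_len(n_rings - 2L))
      faces <- rbind(faces, ring_band_faces(rings[[i]], rings[[i + 1L]]))
  faces <- rbind(faces, pole_fan_faces(south, rings[[n_rings - 1L]]))
  trimesh(sweep(verts, 2, center, "+"), faces, label)
}

#' Capped cylinder mesh
#'
#' Cylinder of radius `radius` from `p0` to `p1` with flat end caps.
#'
#' @param radius cylinder radius (mm).
#' @param p0,p1 axis end points (mm).
#' @param n_seg azimuthal segments.
#' @param n_rings axial subdivisions.
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
cylinder_mesh <- function(radius, p0, p1, n_seg = 24L, n_rings = 2L,
                          label = "cylinder") {
  stopifnot(radius > 0, n_seg >= 3L)
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  stopifnot(len > 1e-9)
  rot <- rotation_between(c(0, 0, 1), axis)$rotation
  verts <- rbind(c(0, 0, 0))
  rings <- vector("list", n_rings + 1L)
  for (i in 0:n_rings) {
    ring <- circle_ring(radius, len * i / n_rings, n_seg)
    rings[[i + 1L]] <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, ring)
  }
  top <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, len))
  faces <- pole_fan_faces(1L, rings[[1L]])
  for (i in seq_len(n_rings))
    faces <- rbind(faces, ring_band_faces(rings[[i]], rings[[i + 1L]]))
  faces <- rbind(faces, pole_fan_faces(top, rings[[n_rings + 1L]], flip = TRUE))
  trimesh(sweep(verts %*% t(rot), 2, p0, "+"), faces, label)
}

#' Capped cone-frustum mesh
#'
#' Frustum from radius `r0` at `p0` to radius `r1` at `p1`, with flat caps;
#' `r1 = 0` produces a cone with its apex at `p1`.
#'
#' @param r0,r1 end radii (mm); `r0 > 0`, `r1 >= 0`.
#' @param p0,p1 axis end points (mm).
#' @param n_seg azimuthal segments.
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
frustum_mesh <- function(r0, r1, p0, p1, n_seg = 24L, label = "frustum") {
  stopifnot(r0 > 0, r1 >= 0, n_seg >= 3L)
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  stopifnot(len > 1e-9)
  rot <- rotation_between(c(0, 0, 1), axis)$rotation
  verts <- rbind(c(0, 0, 0), circle_ring(r0, 0, n_seg))
  ring0 <- 1L + seq_len(n_seg)
  faces <- pole_fan_faces(1L, ring0)
  if (r1 > 0) {
    ring1 <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, circle_ring(r1, len, n_seg))
    top <- nrow(verts) + 1L
    verts <- rbind(verts, c(0, 0, len))
    faces <- rbind(faces, ring_band_faces(ring0, ring1),
                   pole_fan_faces(top, ring1, flip = TRUE))
  } else {
    apex <- nrow(verts) + 1L
    verts <- rbind(verts, c(0, 0, len))
    faces <- rbind(faces, pole_fan_faces(apex, ring0, flip = TRUE))
  }
  trimesh(sweep(verts %*% t(rot), 2, p0, "+"), faces, label)
}

#' Spherical cup-shell mesh
#'
#' Closed shell between two concentric sphere surfaces, spanning polar
#' angles from the dome pole down to the rim. In the canonical pose the
#' opening axis is +Z (the dome pole sits at -Z on the inner/outer radius)
#' and the sphere centre is the origin. `coverage_deg` extends the shell
#' beyond the hemisphere (positive values wrap the rim past the equator
#' toward the opening; negative values recess it).
#'
#' @param r_in,r_out inner and outer sphere radii (mm), `r_out > r_in`.
#' @param coverage_deg rim extension beyond the hemisphere (degrees).
#' @param n_seg azimuthal segments.
#' @param n_rings polar subdivisions per surface.
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
cup_shell_mesh <- function(r_in, r_out, coverage_deg = 0, n_seg = 48L,
                           n_rings = 8L, label = "cup") {
  stopifnot(r_out > r_in, r_in > 0, abs(coverage_deg) < 89)
  span <- (90 + coverage_deg) * pi / 180  # polar span from the dome pole
  surface <- function(r) {
    # returns list(verts, rings, pole_index_offset); pole at theta = 0 (dome, -Z)
    verts <- rbind(c(0, 0, -r))
    rings <- vector("list", n_rings)
    for (i in seq_len(n_rings)) {
      th <- span * i / n_rings
      ring <- circle_ring(r * sin(th), -r * cos(th), n_seg)
      rings[[i]] <- nrow(verts) + seq_len(n_seg)
      verts <- rbind(verts, ring)
    }
    list(verts = verts, rings = rings)
  }
  inner <- surface(r_in)
  outer <- surface(r_out)
  n_in <- nrow(inner$verts)
  verts <- rbind(inner$verts, outer$verts)
  out_rings <- lapply(outer$rings, function(r) r + n_in)
  faces <- pole_fan_faces(1L, inner$rings[[1L]])  # inner surface faces inward
  for (i in seq_len(n_rings - 1L))
    faces <- rbind(faces, ring_band_faces(inner$rings[[i + 1L]], inner$rings[[i]]))
  faces <- rbind(faces, pole_fan_faces(n_in + 1L, out_rings[[1L]], flip = TRUE))
  for (i in seq_len(n_rings - 1L))
    faces <- rbind(faces, ring_band_faces(out_rings[[i]], out_rings[[i + 1L]]))
  # rim band joining the two boundary circles
  faces <- rbind(faces, ring_band_faces(inner$rings[[n_rings]], out_rings[[n_rings]]))
  trimesh(verts, faces, label)
}

#' Generalised surface-of-revolution bone mesh
#'
#' Closed surface built from rings along the Z axis with an
#' azimuth-dependent radius function, capped by cones at both ends; used for
#' the parametric femur (shaft plus trochanter bumps).
#'
#' @param z_vals increasing vector of ring heights (mm).
#' @param radius_fun function `(z, phi)` -> radius (mm, vectorised over phi).
#' @param n_seg azimuthal segments.
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
lathe_mesh <- function(z_vals, radius_fun, n_seg = 32L, label = "bone") {
  stopifnot(length(z_vals) >= 2L, all(diff(z_vals) > 0))
  phi <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  verts <- rbind(c(0, 0, z_vals[1] - 1e-9))
  rings <- vector("list", length(z_vals))
  for (i in seq_along(z_vals)) {
    r <- radius_fun(z_vals[i], phi)
    stopifnot(all(r > 0))
    ring <- cbind(r * cos(phi), r * sin(phi), z_vals[i])
    rings[[i]] <- nrow(verts) + seq_len(n_seg)
    verts <- rbind(verts, ring)
  }
  top <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, z_vals[length(z_vals)] + 1e-9))
  faces <- pole_fan_faces(1L, rings[[1L]])
  for (i in seq_len(length(z_vals) - 1L))
    faces <- rbind(faces, ring_band_faces(rings[[i]], rings[[i + 1L]]))
  faces <- rbind(faces, pole_fan_faces(top, rings[[length(z_vals)]], flip = TRUE))
  trimesh(verts, faces, label)
}

#' Acetabular-region bone shell with azimuth-dependent rim extent
#'
#' Closed shell between radii `r_in` and `r_out` around a dome axis (-Z dome
#' pole, +Z opening, like [cup_shell_mesh()]), whose polar extent varies
#' with azimuth via `extent_fun(phi)` (radians from the dome pole). Models
#' the bony acetabular margin: rim prominences are extra angular wrap at
#' specific azimuths.
#'
#' @param r_in,r_out inner and outer radii (mm).
#' @param extent_fun function phi -> polar extent (radians), vectorised.
#' @param n_seg azimuthal segments.
#' @param n_rings polar subdivisions.
#' @param label component label.
#' @return a watertight [trimesh()].
#' @export
bone_shell_mesh <- function(r_in, r_out, extent_fun, n_seg = 48L, n_rings = 8L,
                            label = "pelvis") {
  stopifnot(r_out > r_in, r_in > 0)
  phi <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ext <- extent_fun(phi)
  stopifnot(all(ext > 0), all(ext < pi))
  surface <- function(r) {
    verts <- rbind(c(0, 0, -r))
    rings <- vector("list", n_rings)
    for (i in seq_len(n_rings)) {
      th <- ext * i / n_rings  # per-azimuth polar angle
      ring <- cbind(r * sin(th) * cos(phi), r * sin(th) * sin(phi), -r * cos(th))
      rings[[i]] <- nrow(verts) + seq_len(n_seg)
      verts <- rbind(verts, ring)
    }
    list(verts = verts, rings = rings)
  }
  inner <- surface(r_in)
  outer <- surface(r_out)
  n_in <- nrow(inner$verts)
  verts <- rbind(inner$verts, outer$verts)
  out_rings <- lapply(outer$rings, function(r) r + n_in)
  faces <- pole_fan_faces(1L, inner$rings[[1L]])
  for (i in seq_len(n_rings - 1L))
    faces <- rbind(faces, ring_band_faces(inner$rings[[i + 1L]], inner$rings[[i]]))
  faces <- rbind(faces, pole_fan_faces(n_in + 1L, out_rings[[1L]], flip = TRUE))
  for (i in seq_len(n_rings - 1L))
    faces <- rbind(faces, ring_band_faces(out_rings[[i]], out_rings[[i + 1L]]))
  faces <- rbind(faces, ring_band_faces(inner$rings[[n_rings]], out_rings[[n_rings]]))
  trimesh(verts, faces, label)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  all(table(key) == 2L)
}
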