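test_that("mesh readers handle STL (ascii + binary), OBJ and PLY consistently", {
  tet <- unit_tetrahedron()
  stl <- withr::local_tempfile(fileext = ".stl")
  obj <- withr::local_tempfile(fileext = ".obj")
  bin <- withr::local_tempfile(fileext = ".stl")
  ply <- withr::local_tempfile(fileext = ".ply")

  write_mesh(tet, stl)
  m_stl <- read_mesh(stl, "femur")
  expect_equal(n_vertices(m_stl), 4L)
  expect_equal(n_faces(m_stl), 4L)

  write_mesh(tet, obj)
  m_obj <- read_mesh(obj, "femur")
  expect_equal(m_obj$vertices, tet$vertices)
  expect_equal(m_obj$faces, tet$faces)

  write_binary_stl(tet, bin)
  m_bin <- read_mesh(bin, "femur")
  expect_equal(n_faces(m_bin), 4L)
  expect_equal(sort(round(as.numeric(m_bin$vertices), 6)),
               sort(round(as.numeric(tet$vertices), 6)))

  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "0 0 1",
               "3 0 2 1", "3 0 1 3", "3 0 3 2", "3 1 2 3"), ply)
  m_ply <- read_mesh(ply, "femur")
  expect_equal(m_ply$vertices, tet$vertices)
  expect_equal(m_ply$faces, tet$faces)

  expect_error(read_mesh(file.path(tempdir(), "nope.stl")), "cannot read")
})

test_that("degenerate triangles are rejected with the offending face named", {
  stl <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t",
               "  facet normal 0 0 1", "    outer loop",
               "      vertex 0 0 0", "      vertex 1 0 0", "      vertex 0 1 0",
               "    endloop", "  endfacet",
               "  facet normal 0 0 1", "    outer loop",
               "      vertex 2 2 0", "      vertex 3 3 0", "      vertex 2 2 0",
               "    endloop", "  endfacet",
               "endsolid t"), stl)
  expect_error(read_mesh(stl), "degenerate.*2")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                       rbind(c(1, 2, 3))), "degenerate")
  expect_error(trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 4))), "out of range")
})

test_that("landmark files round-trip through CSV and JSON", {
  lm <- landmark_set(HJC = c(1, 2, 3), ASIS_right = c(4, 5, 6))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, csv)
  back <- read_landmarks(csv)
  expect_equal(back$HJC, c(1, 2, 3))
  expect_equal(back$ASIS_right, c(4, 5, 6))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lapply(lm, identity), js, auto_unbox = FALSE)
  back2 <- read_landmarks(js)
  expect_equal(back2$ASIS_right, c(4, 5, 6))
})

test_that("pelvic frame follows the anterior pelvic plane convention", {
  lm <- landmark_set(ASIS_right = c(120, 0, 0), ASIS_left = c(-120, 0, 0),
                     PTUB_right = c(25, 0, -80), PTUB_left = c(-25, 0, -80),
                     HJC = c(40, -10, -40))
  f <- build_pelvic_frame(lm)
  expect_equal(f$origin, c(40, -10, -40))
  expect_equal(f$axes[, 1], c(1, 0, 0), tolerance = 1e-12)  # mediolateral
  expect_equal(f$axes[, 2], c(0, 1, 0), tolerance = 1e-12)  # APP normal, anterior
  expect_equal(f$axes[, 3], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(det(f$axes), 1, tolerance = 1e-12)

  # collinear landmarks degenerate the plane
  bad <- landmark_set(ASIS_right = c(120, 0, 0), ASIS_left = c(-120, 0, 0),
                      PTUB_right = c(25, 0, 0), PTUB_left = c(-25, 0, 0),
                      HJC = c(0, 0, 0))
  expect_error(build_pelvic_frame(bad), "collinear")
  expect_error(build_pelvic_frame(landmark_set(HJC = c(0, 0, 0))), "missing")
})

test_that("femoral frame axes and degeneracies behave as specified", {
  lm <- landmark_set(HJC = c(0, 0, 0), knee_center = c(0, 0, -400),
                     EPI_medial = c(-40, 0, -400), EPI_lateral = c(40, 0, -400))
  f <- build_femoral_frame(lm)
  expect_equal(f$axes[, 3], c(0, 0, 1), tolerance = 1e-12)  # longitudinal
  expect_equal(f$axes[, 1], c(1, 0, 0), tolerance = 1e-12)  # mediolateral

  # equivariance: rigidly moved landmarks give a rigidly moved frame
  set.seed(11)
  tf <- random_rigid_transform(50)
  lm2 <- do.call(landmark_set, lapply(lm, function(p) apply_transform(tf, p)))
  f2 <- build_femoral_frame(lm2)
  expect_equal(f2$axes, tf$rotation %*% f$axes, tolerance = 1e-9)
  expect_equal(f2$origin, apply_transform(tf, f$origin), tolerance = 1e-9)

  expect_error(build_femoral_frame(
    landmark_set(HJC = c(0, 0, 0), knee_center = c(0, 0, 0),
                 EPI_medial = c(-40, 0, -400), EPI_lateral = c(40, 0, -400))),
    "coincides")
  expect_error(build_femoral_frame(
    landmark_set(HJC = c(0, 0, 0), knee_center = c(0, 0, -400),
                 EPI_medial = c(0, 0, -100), EPI_lateral = c(0, 0, -300))),
    "parallel")
})

test_that("align_to_neutral is idempotent, rigid, and undoes a known pose", {
  set.seed(21)
  model <- fast_hip()
  neutral <- align_to_neutral(model)
  expect_equal(neutral$meshes$femur$vertices, model$meshes$femur$vertices,
               tolerance = 1e-9)

  tf <- random_rigid_transform(30)
  moved <- model
  for (nm in names(moved$meshes))
    moved$meshes[[nm]] <- transform_mesh(moved$meshes[[nm]], tf)
  moved$landmarks <- do.call(landmark_set,
                             lapply(moved$landmarks, function(p)
                               apply_transform(tf, p)))
  moved$pcs <- build_pelvic_frame(moved$landmarks)
  moved$fcs <- build_femoral_frame(moved$landmarks)
  realigned <- align_to_neutral(moved)
  expect_equal(realigned$meshes$pelvis$vertices, model$meshes$pelvis$vertices,
               tolerance = 1e-6)
  expect_equal(realigned$meshes$stem$vertices, model$meshes$stem$vertices,
               tolerance = 1e-6)

  # rigidity: pairwise distances within a mesh unchanged
  v0 <- model$meshes$cup$vertices[1:10, ]
  v1 <- realigned$meshes$cup$vertices[1:10, ]
  expect_equal(as.numeric(dist(v0)), as.numeric(dist(v1)), tolerance = 1e-9)

  twice <- align_to_neutral(realigned)
  expect_equal(twice$meshes$head$vertices, realigned$meshes$head$vertices,
               tolerance = 1e-9)
})

test_that("mirroring is an involution that swaps sides and landmark names", {
  model <- fast_hip()
  m1 <- mirror_model(model)
  expect_equal(m1$side, "L")
  expect_equal(m1$landmarks$ASIS_right, model$landmarks$ASIS_left * c(-1, 1, 1))
  m2 <- mirror_model(m1)
  expect_equal(m2$side, "R")
  for (nm in names(model$meshes))
    expect_equal(m2$meshes[[nm]]$vertices, model$meshes[[nm]]$vertices,
                 tolerance = 1e-9)
})

test_that("rigid_best_fit recovers exact and noisy transforms", {
  set.seed(31)
  src <- matrix(stats::runif(30, -50, 50), ncol = 3)
  expect_equal(rigid_best_fit(src, src)$rotation, diag(3), tolerance = 1e-9)

  rot <- rotation_about_world_axis("Z", 30)
  tf <- rigid_transform(rot$rotation, c(1, 2, 3))
  tgt <- apply_transform(tf, src)
  fit <- rigid_best_fit(src, tgt)
  expect_equal(fit$rotation, tf$rotation, tolerance = 1e-9)
  expect_equal(fit$translation, tf$translation, tolerance = 1e-9)
  expect_equal(attr(fit, "rms"), 0, tolerance = 1e-9)

  # Monte-Carlo noise: RMS residual bounded by 3 sigma
  sigma <- 0.1
  for (i in 1:20) {
    noisy <- tgt + matrix(stats::rnorm(length(tgt), 0, sigma), ncol = 3)
    expect_lt(attr(rigid_best_fit(src, noisy), "rms"), 3 * sigma)
  }

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_best_fit(line, line + 1), "collinear")
  expect_error(rigid_best_fit(src[1:2, ], src[1:2, ]), "at least 3")
})

test_that("world-axis rotations match the standard elementary matrices", {
  expect_equal(rotation_about_world_axis("X", 0)$rotation, diag(3))
  expect_equal(apply_transform(rotation_about_world_axis("X", 90), c(0, 1, 0)),
               c(0, 0, 1), tolerance = 1e-12)
  a <- rotation_about_world_axis("Z", 23.5)
  b <- rotation_about_world_axis("Z", 41.25)
  expect_equal(compose_transforms(a, b)$rotation,
               rotation_about_world_axis("Z", 64.75)$rotation,
               tolerance = 1e-12)
  tf <- compose_transforms(a, rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(compose_transforms(invert_transform(tf), tf)$rotation, diag(3),
               tolerance = 1e-12)
})

test_that("bundled synthetic sample files load through the readers", {
  lm_path <- system.file("extdata", "sample_landmarks.csv", package = "hipsweep")
  lm <- read_landmarks(lm_path)
  expect_s3_class(build_pelvic_frame(lm), "frame")
  expect_s3_class(build_femoral_frame(lm), "frame")

  ip_path <- system.file("extdata", "sample_implant_params.csv",
                         package = "hipsweep")
  ip <- read_implant_params(ip_path)
  expect_equal(nrow(ip), 3L)
  expect_true(all(ip$side %in% c("L", "R")))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ip[, -3], bad, row.names = FALSE)
  expect_error(read_implant_params(bad), "missing implant parameter")
})
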