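test_that("cup axis from radiographic angles matches the closed form and inverts", {
  expect_equal(cup_axis_from_angles(cup_orientation(0, 0), "R"), c(0, 0, -1),
               tolerance = 1e-12)
  ax <- cup_axis_from_angles(cup_orientation(45, 20), "R")
  expect_equal(ax, c(sin(pi / 4) * cos(pi / 9), sin(pi / 9),
                     -cos(pi / 4) * cos(pi / 9)), tolerance = 1e-12)
  expect_equal(ax, c(0.6645, 0.3420, -0.6645), tolerance = 1e-4)

  # left side mirrors the lateral component
  axl <- cup_axis_from_angles(cup_orientation(45, 20), "L")
  expect_equal(axl, ax * c(-1, 1, 1), tolerance = 1e-12)

  # round trip to 1e-9 degrees over a grid
  for (inc in c(5, 30, 45, 70)) {
    for (av in c(-20, 0, 15, 40)) {
      for (side in c("R", "L")) {
        back <- cup_angles_from_axis(
          cup_axis_from_angles(cup_orientation(inc, av), side), side)
        expect_equal(back$inclination_deg, inc, tolerance = 1e-9)
        expect_equal(back$anteversion_deg, av, tolerance = 1e-9)
      }
    }
  }

  expect_error(cup_orientation(95, 10), "inclination")
  expect_error(cup_orientation(40, -60), "anteversion")
})

test_that("cup/liner placement is rigid, shared, and centred on the HJC", {
  cup <- cup_shell_mesh(20, 24, 5, n_seg = 24, n_rings = 4, label = "cup")
  liner <- cup_shell_mesh(16, 20, 5, n_seg = 24, n_rings = 4, label = "liner")
  hjc <- c(3, -7, 11)
  placed <- place_cup_liner(cup, liner, cup_orientation(40, 20), hjc, "R")

  # same transform for both: relative pose preserved exactly
  rel0 <- cup$vertices[1:5, ] - liner$vertices[1:5, ]
  rel1 <- placed$cup$vertices[1:5, ] - placed$liner$vertices[1:5, ]
  expect_equal(apply_transform(rigid_transform(placed$transform$rotation),
                               rel0), rel1, tolerance = 1e-9)

  # centre lands on the HJC; rigidity
  expect_equal(placed$transform$translation, hjc, tolerance = 1e-12)
  expect_equal(as.numeric(dist(cup$vertices[1:8, ])),
               as.numeric(dist(placed$cup$vertices[1:8, ])), tolerance = 1e-9)

  # identity orientation flips the canonical +Z opening to -Z (180 about X)
  p0 <- place_cup_liner(cup, liner, cup_orientation(0, 0), c(0, 0, 0), "R")
  expect_equal(p0$transform$rotation,
               rotation_about_world_axis("X", 180)$rotation, tolerance = 1e-9)

  shifted <- transform_mesh(cup, rigid_transform(diag(3), c(0.5, 0, 0)))
  expect_error(place_cup_liner(shifted, liner, cup_orientation(40, 20)),
               "canonical")
})

test_that("taper seat depth matches a mesh-collision bisection oracle", {
  tip_r <- 5
  half <- 3
  bore_r <- 5.5
  depth <- taper_seat_depth(tip_r, half, bore_r)
  expect_equal(depth, 0.5 / tan(3 * pi / 180), tolerance = 1e-12)

  # independent oracle: narrow conical shells for taper and bore; bisect the
  # tip position where the surfaces first touch
  tanh_ <- tan(half * pi / 180)
  taper_surface <- function(tip_z) {
    # taper from its tip (at tip_z, going deeper in -z): radius grows with z
    frustum_mesh(tip_r + 14 * tanh_, tip_r, c(0, 0, tip_z - 14),
                 c(0, 0, tip_z), n_seg = 96, label = "taper")
  }
  # bore surface: cone with radius bore_r at z = 0 (head-centre plane),
  # narrowing upward toward its apex
  bore <- frustum_mesh(bore_r + 14 * tanh_, bore_r - 10 * tanh_,
                       c(0, 0, -14), c(0, 0, 10), n_seg = 96, label = "bore")
  collides <- function(tip_z) meshes_collide(taper_surface(tip_z), bore)$colliding
  clear_z <- depth - 2      # backed out of the seat: no interference
  deep_z <- depth + 2       # past the seat: cones cross
  expect_false(collides(clear_z))
  expect_true(collides(deep_z))
  for (i in 1:24) {
    mid <- (clear_z + deep_z) / 2
    if (collides(mid)) deep_z <- mid else clear_z <- mid
  }
  expect_equal((clear_z + deep_z) / 2, depth, tolerance = 1e-3)

  expect_error(taper_seat_depth(5, 3, 4.9), "infeasible")
})

test_that("head and stem placement seats the head at the HJC", {
  head <- uv_sphere_mesh(16, n_seg = 20, n_rings = 10, label = "head")
  stem <- frustum_mesh(6, 5, c(0, 0, -12), c(0, 0, 0), n_seg = 20,
                       label = "stem")
  cfg <- stem_config(c(0.7, -0.1, -0.707) / sqrt(0.7^2 + 0.01 + 0.5))
  placed <- place_head_stem(head, stem, cfg, hjc = c(2, 4, -1))
  expect_equal(colMeans(placed$head$vertices), c(2, 4, -1), tolerance = 1e-9)
  expect_equal(placed$insertion_depth_mm,
               taper_seat_depth(5, 3, 5.5), tolerance = 1e-12)
  # rigidity of the stem
  expect_equal(as.numeric(dist(stem$vertices[1:8, ])),
               as.numeric(dist(placed$stem$vertices[1:8, ])), tolerance = 1e-9)

  off_head <- uv_sphere_mesh(16, center = c(1, 0, 0), n_seg = 20, n_rings = 10)
  expect_error(place_head_stem(off_head, stem, cfg), "canonical")
})

test_that("assembled synthetic model passes clearance; interference is caught", {
  model <- fast_hip()
  expect_s3_class(model, "hip_model")
  expect_true(check_initial_clearance(model)$pass)
  # head centre coincides with the pelvic-frame HJC
  expect_equal(colMeans(model$meshes$head$vertices), model$landmarks$HJC,
               tolerance = 1e-6)

  # constructed interference: femoral side shifted superiorly drives the
  # head into the bony acetabular shell
  shifted <- model
  up <- rigid_transform(diag(3), c(0, 0, 12))
  for (nm in c("femur", "head", "stem"))
    shifted$meshes[[nm]] <- transform_mesh(shifted$meshes[[nm]], up)
  cc <- check_initial_clearance(shifted)
  expect_false(cc$pass)
  labels <- unlist(lapply(cc$collisions, function(r)
    c(r$witness$a$label, r$witness$b$label)))
  expect_true("pelvis" %in% labels || "liner" %in% labels)
  # the articulating pair is never reported
  for (r in cc$collisions)
    expect_false(setequal(c(r$witness$a$label, r$witness$b$label),
                          c("head", "liner")))
})
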