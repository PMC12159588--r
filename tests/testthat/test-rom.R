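test_that("pelvic posing is exact, invertible and monotone in functional anteversion", {
  model <- fast_hip()
  expect_identical(pose_pelvis(model, pt_condition("noPT"))$meshes$pelvis$vertices,
                   model$meshes$pelvis$vertices)

  tilted <- pose_pelvis(model, pt_condition("StPT", 10))
  back <- hipsweep:::transform_body(tilted, rotation_about_world_axis("X", 10),
                                    "pelvis")
  expect_equal(back$meshes$pelvis$vertices, model$meshes$pelvis$vertices,
               tolerance = 1e-9)
  # femoral side untouched
  expect_identical(tilted$meshes$stem$vertices, model$meshes$stem$vertices)

  # functional anteversion of the cup axis decreases monotonically with
  # anterior tilt
  axis0 <- cup_axis_from_angles(cup_orientation(40, 20), "R")
  av <- vapply(c(-10, 0, 10, 20), function(tilt) {
    ax <- apply_transform(rotation_about_world_axis("X", -tilt), axis0)
    cup_angles_from_axis(ax, "R")$anteversion_deg
  }, 0)
  expect_true(all(diff(av) < 0))

  expect_error(pt_condition("StPT", 65), "outside the validated range")
  expect_error(pt_condition("noPT", 5), "zero tilt")
})

test_that("femoral posing composes pre-rotation and sweep about world axes", {
  model <- fast_hip()
  flex <- standard_motions()$Flex
  ir90 <- standard_motions()$`IR@90Flex`
  ext <- standard_motions()$Ext

  expect_equal(pose_femur(model, flex, 0)$meshes$femur$vertices,
               model$meshes$femur$vertices, tolerance = 1e-12)

  # IR@90Flex at zero sweep is a pure 90 degree flexion
  expect_equal(pose_femur(model, ir90, 0)$meshes$stem$vertices,
               pose_femur(model, flex, 90)$meshes$stem$vertices,
               tolerance = 1e-12)

  # flexion at a equals extension at -a
  expect_equal(pose_femur(model, flex, 35)$meshes$head$vertices,
               pose_femur(model, ext, -35)$meshes$head$vertices,
               tolerance = 1e-12)
})

test_that("impingement classification maps pair categories with fixed priority", {
  expect_equal(classify_impingement(c("liner", "stem")), "ITII")
  expect_equal(classify_impingement(c("cup", "stem")), "ITII")
  expect_equal(classify_impingement(c("pelvis", "stem")), "ITBI")
  expect_equal(classify_impingement(c("pelvis", "head")), "ITBI")
  expect_equal(classify_impingement(c("pelvis", "femur")), "BTBI")
  # priority when several categories collide at the same step
  expect_equal(classify_impingement(list(c("pelvis", "femur"),
                                         c("liner", "stem"))), "ITII")
  expect_equal(classify_impingement(list(c("pelvis", "femur"),
                                         c("pelvis", "stem"))), "ITBI")
  expect_error(classify_impingement(c("head", "liner")), "excluded")
  expect_error(classify_impingement(list()), "no contact")
  expect_error(classify_impingement(c("pelvis", "hat")), "unknown")
})

test_that("sweep recovers the analytic ball-in-cup limit and tilt shifts it", {
  fx <- make_analytic_ball_cup(8, 16, 0)
  flex <- standard_motions()$Flex
  res <- find_limiting_rom(fx$model, flex, pt_condition("noPT"))
  expect_lte(abs(res$limit_deg - 60), 0.5)
  expect_equal(res$impingement_type, "ITII")
  expect_equal(sort(res$witness), c("liner", "stem"))

  res10 <- find_limiting_rom(fx$model, flex, pt_condition("StPT", 10))
  expect_lte(abs(res10$limit_deg - 50), 0.5)
  # tilt on the sweep axis shifts the limit by exactly the grid-aligned tilt
  expect_equal(res$limit_deg - res10$limit_deg, 10)

  # a capped sweep that never collides reports NONE at the cap
  capped <- motion_spec("Flex", "X", +1, cap_deg = 10)
  res_cap <- find_limiting_rom(fx$model, capped, pt_condition("noPT"))
  expect_equal(res_cap$limit_deg, 10)
  expect_equal(res_cap$impingement_type, "NONE")
  expect_null(res_cap$witness)

  # extreme anterior tilt puts the start pose into collision
  expect_error(find_limiting_rom(fx$model, flex, pt_condition("StPT", 60)),
               "initial pose already colliding")
})

test_that("limits sit on the step grid and refine consistently", {
  fx <- make_analytic_ball_cup(8, 16, 5, n_seg = 48)
  flex <- standard_motions()$Flex
  coarse <- find_limiting_rom(fx$model, flex, step = 1)
  fine <- find_limiting_rom(fx$model, flex, step = 0.5)
  expect_equal(coarse$limit_deg %% 1, 0)
  expect_equal(fine$limit_deg %% 0.5, 0)
  expect_lte(abs(fine$limit_deg - coarse$limit_deg), 1)
  expect_error(find_limiting_rom(fx$model, motion_spec("Flex", "X", 1,
                                                       cap_deg = 10.3)),
               "multiple of the step")
})

test_that("tilt-flexion coupling is exact on the grid for the parametric hip", {
  model <- fast_hip()
  flex <- standard_motions()$Flex
  ext <- standard_motions()$Ext
  f0 <- find_limiting_rom(model, flex, pt_condition("noPT"))$limit_deg
  f10 <- find_limiting_rom(model, flex, pt_condition("StPT", 10))$limit_deg
  e0 <- find_limiting_rom(model, ext, pt_condition("noPT"))$limit_deg
  e10 <- find_limiting_rom(model, ext, pt_condition("StPT", 10))$limit_deg
  expect_equal(f0 - f10, 10)
  expect_equal(e10 - e0, 10)
})

test_that("mirrored models reproduce right-hip limits exactly on the grid", {
  model <- fast_hip()
  left <- mirror_model(model)
  for (m in standard_motions()[c("Flex", "Abd", "ER")]) {
    r_r <- find_limiting_rom(model, m, pt_condition("StPT", 5))
    r_l <- find_limiting_rom(left, m, pt_condition("StPT", 5))
    expect_equal(r_l$limit_deg, r_r$limit_deg)
    expect_equal(r_l$impingement_type, r_r$impingement_type)
  }
})

test_that("simulate_patient yields the full motion-by-condition grid, deterministically", {
  model <- fast_hip()
  pts <- list(pt_condition("noPT"), pt_condition("StPT_6", 14))
  res <- simulate_patient(model, pts)
  expect_equal(nrow(res), 6L * 2L)
  expect_setequal(unique(res$motion), names(standard_motions()))
  expect_true(all(res$limit_deg %% 0.5 == 0))
  expect_true(all((res$impingement_type == "NONE") == (res$limit_deg %in% c(150, 180))))

  res2 <- simulate_patient(model, pts)
  expect_identical(res, res2)

  # anterior tilt reduces flexion monotonically across conditions
  flex <- res[res$motion == "Flex", ]
  expect_lt(flex$limit_deg[flex$pt_label == "StPT_6"],
            flex$limit_deg[flex$pt_label == "noPT"])
})
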