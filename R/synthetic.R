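# Synthetic hip geometry and pelvic-tilt cohort generators. The parametric
# anatomy is deliberately simplified (smooth prominences instead of a
# statistical shape model): the simulation pipeline tests mechanism --
# collision, tilt-ROM coupling, impingement classification -- not
# anatomical realism.

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# landmark set whose pelvic/femoral frames are the identity (APP parallel
# to the x-z plane, mechanical axis along z), HJC at the origin
neutral_landmarks <- function() {
  landmark_set(
    ASIS_right = c(120, 5, 85), ASIS_left = c(-120, 5, 85),
    PTUB_right = c(25, 5, 5), PTUB_left = c(-25, 5, 5),
    EPI_lateral = c(40, 0, -400), EPI_medial = c(-40, 0, -400),
    knee_center = c(0, 0, -400), HJC = c(0, 0, 0)
  )
}

ang_wrap <- function(a) atan2(sin(a), cos(a))

#' Analytic ball-in-cup fixture
#'
#' A hip model with exactly known limiting angles: a spherical head of
#' radius `head_radius` centred at the HJC articulating in a spherical cup
#' shell whose rim sits `cup_coverage` degrees beyond the hemisphere, with
#' a cylindrical neck of radius `neck_radius` along the cup axis at
#' neutral, cup axis pointing straight inferior. For every planar sweep
#' that tilts the neck toward the rim the closed-form limiting angle is
#'
#'   `90 - asin(neck_radius / head_radius) - cup_coverage`  (degrees),
#'
#' since the neck axis contacts the rim circle (radius `head_radius`) when
#' its angular distance from the rim drops to `asin(neck_radius /
#' head_radius)`. The fixture is the independent oracle for the sweep
#' simulation.
#'
#' @param neck_radius neck cylinder radius (mm), `< head_radius`.
#' @param head_radius head sphere radius (mm).
#' @param cup_coverage degrees of cup beyond the hemisphere (`|x| < 30`).
#' @param n_seg azimuthal resolution of the generated meshes.
#' @return list with `model` (a [hip_model()]) and `closed_form_limit_deg`.
#' @export
make_analytic_ball_cup <- function(neck_radius = 8, head_radius = 16,
                                   cup_coverage = 0, n_seg = 64L) {
  if (neck_radius >= head_radius)
    stop("infeasible fixture: neck radius must be smaller than the head radius")
  if (abs(cup_coverage) >= 30)
    stop("infeasible fixture: |cup_coverage| must be below 30 degrees")
  limit <- 90 - asin(neck_radius / head_radius) * 180 / pi - cup_coverage

  # liner inner surface exactly at head_radius => rim circle radius is exact;
  # the head mesh articulates with 0.05 mm clearance (head-liner is excluded
  # from collision checks anyway)
  liner_c <- cup_shell_mesh(head_radius, head_radius + 3, cup_coverage,
                            n_seg = n_seg, n_rings = 6L, label = "liner")
  cup_c <- cup_shell_mesh(head_radius + 3, head_radius + 6, cup_coverage,
                          n_seg = n_seg, n_rings = 6L, label = "cup")
  # canonical opening axis +Z -> world axis (0,0,-1): cup opens inferiorly
  flip <- rotation_between(c(0, 0, 1), c(0, 0, -1))
  liner <- transform_mesh(liner_c, flip)
  cup <- transform_mesh(cup_c, flip)
  head <- uv_sphere_mesh(head_radius - 0.05, n_seg = n_seg %/% 2,
                         n_rings = n_seg %/% 4, label = "head")
  stem <- cylinder_mesh(neck_radius, c(0, 0, 0), c(0, 0, -2.5 * head_radius),
                        n_seg = n_seg, n_rings = 2L, label = "stem")
  # inert distant bones: the fixture isolates the implant-implant mechanism
  femur <- uv_sphere_mesh(5, center = c(0, 0, -120), n_seg = 8L, n_rings = 4L,
                          label = "femur")
  pelvis <- uv_sphere_mesh(5, center = c(0, 0, 150), n_seg = 8L, n_rings = 4L,
                           label = "pelvis")
  model <- hip_model(list(pelvis = pelvis, femur = femur, cup = cup,
                          liner = liner, head = head, stem = stem),
                     neutral_landmarks(), side = "R")
  list(model = model, closed_form_limit_deg = limit)
}

#' Parameters of the synthetic parametric hip
#'
#' Dimensions driving [make_parametric_hip()]. Defaults describe a typical
#' right THA hip: 32 mm head (cohort standard), 6 mm prosthetic neck
#' radius, 130 degree neck-shaft angle, 10 degrees stem anteversion,
#' hemispherical cup, a 14 mm anterior-inferior iliac rim prominence and a
#' 14 mm ischial prominence on the bony acetabular margin.
#'
#' @param head_diameter_mm prosthetic head diameter.
#' @param neck_radius_mm prosthetic neck radius (`2 * neck_radius <
#'   head_diameter`).
#' @param neck_shaft_angle_deg angle between neck axis and shaft axis.
#' @param stem_anteversion_deg anteversion of the neck about the shaft.
#' @param cup_coverage_deg cup/liner rim extension beyond the hemisphere.
#' @param anterior_rim_prominence_mm height of the anterior-inferior bony
#'   rim prominence.
#' @param ischial_prominence_mm height of the posterior-inferior bony
#'   prominence.
#' @param head_offset_mm femoral offset (HJC to shaft axis).
#' @param resolution approximate triangles per component (>= 100).
#' @param seed generator seed (the geometry is deterministic in the
#'   parameters; the seed is carried for provenance).
#' @return an object of class `synthetic_hip_params`.
#' @export
synthetic_hip_params <- function(head_diameter_mm = 32, neck_radius_mm = 6,
                                 neck_shaft_angle_deg = 130,
                                 stem_anteversion_deg = 10,
                                 cup_coverage_deg = 0,
                                 anterior_rim_prominence_mm = 14,
                                 ischial_prominence_mm = 14,
                                 head_offset_mm = 47,
                                 resolution = 700L, seed = 1L) {
  if (2 * neck_radius_mm >= head_diameter_mm)
    stop("neck diameter must be smaller than the head diameter")
  if (resolution < 100L) stop("resolution must be at least 100 triangles per component")
  structure(list(head_diameter_mm = head_diameter_mm,
                 neck_radius_mm = neck_radius_mm,
                 neck_shaft_angle_deg = neck_shaft_angle_deg,
                 stem_anteversion_deg = stem_anteversion_deg,
                 cup_coverage_deg = cup_coverage_deg,
                 anterior_rim_prominence_mm = anterior_rim_prominence_mm,
                 ischial_prominence_mm = ischial_prominence_mm,
                 head_offset_mm = head_offset_mm,
                 resolution = as.integer(resolution), seed = as.integer(seed)),
            class = "synthetic_hip_params")
}

# world neck axis (head centre -> shaft) for a right hip
neck_axis_from_params <- function(params) {
  tilt <- (180 - params$neck_shaft_angle_deg) * pi / 180
  d0 <- c(sin(tilt), 0, -cos(tilt))
  apply_transform(rotation_about_world_axis("Z", -params$stem_anteversion_deg), d0)
}

#' Parametric synthetic hip model
#'
#' Builds a watertight right-hip geometry set (pelvis with acetabular
#' socket shell, anterior-inferior and ischial rim prominences; resected
#' proximal femur with greater/lesser trochanter bumps; cup, liner, head,
#' neck/taper stem) and assembles it at neutral via [assemble_hip_model()].
#' Deterministic for fixed parameters; errors if the parameters produce a
#' model that fails initial clearance.
#'
#' @param params a [synthetic_hip_params()].
#' @param orientation a [cup_orientation()] (default 40 degrees
#'   inclination, 20 anteversion).
#' @return a neutral [hip_model()] passing [check_initial_clearance()].
#' @export
make_parametric_hip <- function(params = synthetic_hip_params(),
                                orientation = cup_orientation(40, 20)) {
  head_r <- params$head_diameter_mm / 2
  neck_r <- params$neck_radius_mm
  res <- params$resolution
  n_seg <- max(12L, as.integer(round(sqrt(1.2 * res))))
  n_rings <- max(4L, n_seg %/% 5L)

  liner_in <- head_r + 0.05          # articulating clearance
  liner_out <- liner_in + 4
  cup_out <- liner_out + 4
  cover <- params$cup_coverage_deg

  liner <- cup_shell_mesh(liner_in, liner_out, cover, n_seg, n_rings, "liner")
  cup <- cup_shell_mesh(liner_out, cup_out, cover, n_seg, n_rings, "cup")
  head <- uv_sphere_mesh(head_r, n_seg = n_seg, n_rings = max(6L, n_seg %/% 2L),
                         label = "head")

  # canonical stem: taper tip at the origin (+z extreme), frustum widening
  # down -z into the neck cylinder
  taper_len <- 12
  tip_r <- 5
  half_angle <- 3
  neck_len <- 50
  stem <- local({
    taper <- frustum_mesh(tip_r + taper_len * tan(half_angle * pi / 180), tip_r,
                          c(0, 0, -taper_len), c(0, 0, 0), n_seg, "stem")
    neck <- cylinder_mesh(neck_r, c(0, 0, -neck_len), c(0, 0, -taper_len + 1),
                          n_seg, 3L, "stem")
    trimesh(rbind(taper$vertices, neck$vertices),
            rbind(taper$faces, neck$faces + n_vertices(taper)), "stem")
  })

  neck_axis <- neck_axis_from_params(params)
  config <- stem_config(neck_axis, head_offset_mm = params$head_offset_mm,
                        head_diameter_mm = params$head_diameter_mm,
                        taper_tip_radius_mm = tip_r,
                        taper_half_angle_deg = half_angle,
                        bore_radius_mm = tip_r + 0.5)

  axis <- cup_axis_from_angles(orientation, "R")
  rot <- rotation_between(c(0, 0, 1), axis)$rotation

  # bony acetabular margin: shell concentric with the cup, rim wrapped
  # further at the anterior-inferior (AIIS-like) and ischial azimuths
  pelvis <- local({
    r_in <- cup_out + 1
    r_out <- r_in + 6
    r_mid <- (r_in + r_out) / 2
    base_ext <- 75 * pi / 180
    # canonical azimuths of the bump directions: the anterior (AIIS-like)
    # prominence sits where the neck path crosses the margin in deep
    # flexion, the ischial prominence where it crosses in extension
    to_canonical <- function(dir) {
      v <- as.numeric(t(rot) %*% (dir / sqrt(sum(dir^2))))
      atan2(v[2], v[1])
    }
    phi_ant <- to_canonical(apply_transform(rotation_about_world_axis("X", 115),
                                            neck_axis))
    phi_isch <- to_canonical(apply_transform(rotation_about_world_axis("X", -60),
                                             neck_axis))
    extent_fun <- function(phi) {
      pmin(pi * 0.95, base_ext +
        (params$anterior_rim_prominence_mm / r_mid) *
          exp(-(ang_wrap(phi - phi_ant) / 0.55)^2) +
        (params$ischial_prominence_mm / r_mid) *
          exp(-(ang_wrap(phi - phi_isch) / 0.55)^2))
    }
    shell <- bone_shell_mesh(r_in, r_out, extent_fun, n_seg, n_rings, "pelvis")
    transform_mesh(shell, rigid_transform(rot, c(0, 0, 0)))
  })

  # resected proximal femur: vertical shaft at the offset with metaphyseal
  # flare and trochanter bumps, built as a lathe surface
  femur <- local({
    t_sh <- params$head_offset_mm / neck_axis[1]
    shaft_xy <- c(params$head_offset_mm, t_sh * neck_axis[2])
    z_top <- -30
    z_bot <- -170
    phi_gt <- -0.35        # lateral, slightly posterior
    phi_lt <- pi * 1.25    # posteromedial
    radius_fun <- function(z, phi) {
      13 + 8 * exp(-((z - (z_top - 8)) / 16)^2) +
        10 * exp(-((z - (z_top + 2)) / 14)^2 - (ang_wrap(phi - phi_gt) / 0.7)^2) +
        6 * exp(-((z - (z_top - 22)) / 10)^2 - (ang_wrap(phi - phi_lt) / 0.6)^2)
    }
    z_vals <- seq(z_bot, z_top, length.out = max(8L, n_rings * 2L))
    mesh <- lathe_mesh(z_vals, radius_fun, n_seg, "femur")
    transform_mesh(mesh, rigid_transform(diag(3), c(shaft_xy, 0)))
  })

  assemble_hip_model(list(pelvis = pelvis, femur = femur, cup = cup,
                          liner = liner, head = head, stem = stem),
                     neutral_landmarks(), orientation, config, side = "R")
}

#' Pelvic-tilt cohort generator configuration
#'
#' Defaults reproduce the study cohort's first and second moments:
#' preoperative standing tilt 18.9 +/- 8.8 degrees, a posterior change of
#' 4.8 +/- 6.0 degrees by 6 months, and an anterior change of 0.6 +/- 6.9
#' degrees from 6 to 12 months, for 56 patients. Implant-orientation
#' jitters default to inclination 40 +/- 6 and anteversion 20 +/- 6
#' degrees.
#'
#' @param n number of patients (>= 2).
#' @param pt0_mean,pt0_sd preoperative standing tilt distribution (deg).
#' @param delta6_mean,delta6_sd change from baseline to 6 months (deg).
#' @param delta12_mean,delta12_sd change from 6 to 12 months (deg).
#' @param incl_mean,incl_sd cup inclination distribution (deg).
#' @param av_mean,av_sd cup anteversion distribution (deg).
#' @param offset_mean,offset_sd femoral offset distribution (mm).
#' @param geometry_jitter multiplier on the anatomical jitter SDs (0
#'   disables geometry variation).
#' @param resolution triangles per component for generated models.
#' @param seed RNG seed.
#' @return an object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(n = 56L, pt0_mean = 18.9, pt0_sd = 8.8,
                              delta6_mean = -4.8, delta6_sd = 6.0,
                              delta12_mean = 0.6, delta12_sd = 6.9,
                              incl_mean = 40, incl_sd = 6,
                              av_mean = 20, av_sd = 6,
                              offset_mean = 47, offset_sd = 4,
                              geometry_jitter = 1, resolution = 700L,
                              seed = 1L) {
  stopifnot(n >= 2L, pt0_sd >= 0, delta6_sd >= 0, delta12_sd >= 0,
            incl_sd >= 0, av_sd >= 0, offset_sd >= 0, geometry_jitter >= 0)
  structure(list(n = as.integer(n), pt0_mean = pt0_mean, pt0_sd = pt0_sd,
                 delta6_mean = delta6_mean, delta6_sd = delta6_sd,
                 delta12_mean = delta12_mean, delta12_sd = delta12_sd,
                 incl_mean = incl_mean, incl_sd = incl_sd,
                 av_mean = av_mean, av_sd = av_sd,
                 offset_mean = offset_mean, offset_sd = offset_sd,
                 geometry_jitter = geometry_jitter,
                 resolution = as.integer(resolution), seed = as.integer(seed)),
            class = "cohort_gen_config")
}

#' Generate a synthetic standing pelvic-tilt cohort
#'
#' Draws `StPT_0 ~ N(pt0_mean, pt0_sd)`, chains `StPT_6 = StPT_0 +
#' N(delta6_mean, delta6_sd)` and `StPT_12 = StPT_6 + N(delta12_mean,
#' delta12_sd)` (changes at the two follow-ups modelled as independent
#' normal increments), and clips all columns to the simulator's validated
#' range [-30, 50] degrees.
#'
#' @param config a [cohort_gen_config()].
#' @return data frame with `patient_id`, `StPT_0`, `StPT_6`, `StPT_12`.
#' @export
generate_cohort_pt <- function(config = cohort_gen_config()) {
  with_seed(config$seed, {
    n <- config$n
    pt0 <- stats::rnorm(n, config$pt0_mean, config$pt0_sd)
    pt6 <- pt0 + stats::rnorm(n, config$delta6_mean, config$delta6_sd)
    pt12 <- pt6 + stats::rnorm(n, config$delta12_mean, config$delta12_sd)
    clip <- function(x) pmin(50, pmax(-30, x))
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               StPT_0 = clip(pt0), StPT_6 = clip(pt6), StPT_12 = clip(pt12),
               stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort
#'
#' For each patient: anatomical and implant parameters are jittered around
#' the defaults ([synthetic_hip_params()]), cup angles drawn from the
#' configured distributions, a parametric model built and verified
#' clearance-free (an infeasible draw is regenerated from the next RNG
#' substream, up to 10 attempts), and a standing-tilt triple attached from
#' [generate_cohort_pt()]. Geometry and tilt are drawn independently.
#'
#' @param config a [cohort_gen_config()].
#' @return list with `patients` (list of `patient_id`, `model`, `pt`,
#'   `implant`) and `pt_table` (the [generate_cohort_pt()] frame).
#' @export
generate_synthetic_cohort <- function(config = cohort_gen_config()) {
  pt_table <- generate_cohort_pt(config)
  g <- config$geometry_jitter
  patients <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    built <- NULL
    for (attempt in 0:9) {
      draw <- with_seed(config$seed + 131L * i + 7919L * attempt, {
        list(incl = stats::rnorm(1, config$incl_mean, config$incl_sd),
             av = stats::rnorm(1, config$av_mean, config$av_sd),
             offset = stats::rnorm(1, config$offset_mean, config$offset_sd),
             neck_r = stats::rnorm(1, 6, 0.3 * g),
             nsa = stats::rnorm(1, 130, 4 * g),
             sav = stats::rnorm(1, 10, 5 * g),
             rim = max(0, stats::rnorm(1, 14, 1.5 * g)),
             cover = pmin(10, pmax(-5, stats::rnorm(1, 0, 2 * g))))
      })
      draw$incl <- pmin(60, pmax(25, draw$incl))
      draw$av <- pmin(40, pmax(0, draw$av))
      params <- synthetic_hip_params(
        neck_radius_mm = draw$neck_r, neck_shaft_angle_deg = draw$nsa,
        stem_anteversion_deg = draw$sav, cup_coverage_deg = draw$cover,
        anterior_rim_prominence_mm = draw$rim,
        head_offset_mm = draw$offset, resolution = config$resolution,
        seed = config$seed + i)
      built <- tryCatch(
        list(model = make_parametric_hip(params,
                                         cup_orientation(draw$incl, draw$av)),
             draw = draw, params = params),
        error = function(e) NULL)
      if (!is.null(built)) break
    }
    if (is.null(built))
      stop("could not generate a clearance-free model for patient ", i,
           " after 10 attempts")
    patients[[i]] <- list(patient_id = pt_table$patient_id[i],
                          model = built$model,
                          pt = as.numeric(pt_table[i, c("StPT_0", "StPT_6", "StPT_12")]),
                          implant = built$draw)
  }
  list(patients = patients, pt_table = pt_table)
}
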