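#' Acetabular cup orientation
#'
#' Radiographic inclination and anteversion relative to the anterior pelvic
#' plane (Murray's radiographic definition): anteversion is the angle
#' between the cup axis and the coronal (APP) plane; inclination is the
#' angle between the longitudinal axis and the cup axis projected onto the
#' coronal plane.
#'
#' @param inclination_deg degrees, `0 <= inclination < 90`.
#' @param anteversion_deg degrees, `-45 < anteversion < 90`.
#' @return an object of class `cup_orientation`.
#' @export
cup_orientation <- function(inclination_deg, anteversion_deg) {
  if (!is.finite(inclination_deg) || inclination_deg < 0 || inclination_deg >= 90)
    stop("inclination must be in [0, 90) degrees")
  if (!is.finite(anteversion_deg) || anteversion_deg <= -45 || anteversion_deg >= 90)
    stop("anteversion must be in (-45, 90) degrees")
  structure(list(inclination_deg = inclination_deg,
                 anteversion_deg = anteversion_deg),
            class = "cup_orientation")
}

#' Cup opening axis from radiographic angles
#'
#' Unit axis of the cup opening in the neutral world frame (X mediolateral
#' to the patient's right, Y anterior, Z superior). For a right hip the
#' lateral component is `sin(inc) cos(av)`, the anterior component
#' `sin(av)`, and the inferior component `-cos(inc) cos(av)`; for a left hip
#' the lateral (x) component is negated.
#'
#' @param orientation a [cup_orientation()].
#' @param side `"R"` or `"L"`.
#' @return unit length-3 vector.
#' @export
#' @examples
#' cup_axis_from_angles(cup_orientation(45, 20), "R")
cup_axis_from_angles <- function(orientation, side = "R") {
  side <- match.arg(side, c("R", "L"))
  inc <- orientation$inclination_deg * pi / 180
  av <- orientation$anteversion_deg * pi / 180
  s <- if (side == "R") 1 else -1
  c(s * sin(inc) * cos(av), sin(av), -cos(inc) * cos(av))
}

#' Recover radiographic angles from a cup axis
#'
#' Inverse of [cup_axis_from_angles()]; exact round trip.
#'
#' @param axis unit length-3 vector.
#' @param side `"R"` or `"L"`.
#' @return a [cup_orientation()].
#' @export
cup_angles_from_axis <- function(axis, side = "R") {
  side <- match.arg(side, c("R", "L"))
  axis <- axis / sqrt(sum(axis^2))
  s <- if (side == "R") 1 else -1
  av <- asin(pmin(1, pmax(-1, axis[2])))
  inc <- atan2(s * axis[1], -axis[3])
  cup_orientation(inc * 180 / pi, av * 180 / pi)
}

# canonical-pose check: component must be centred on the z-axis
# (vertex centroid, which is exactly on the axis for uniform ring sampling)
check_canonical_xy <- function(mesh, what, tol = 1e-6) {
  off <- max(abs(colMeans(mesh$vertices[, 1:2, drop = FALSE])))
  if (off > tol)
    stop(what, " is not in canonical pose (centre offset ", signif(off, 3),
         " mm from the z-axis)")
  invisible(mesh)
}

#' Place cup and liner at the hip joint centre
#'
#' Both components must be supplied in the canonical pose (sphere centre at
#' the origin, opening axis along +Z). They receive one identical rigid
#' transform: the axis is rotated onto [cup_axis_from_angles()] and the
#' centre translated to the HJC, so their relative pose is preserved
#' exactly.
#'
#' @param cup,liner canonical [trimesh()] components.
#' @param orientation a [cup_orientation()].
#' @param hjc hip joint centre (mm).
#' @param side `"R"` or `"L"`.
#' @return list with transformed `cup`, `liner`, the applied `transform`
#'   and the world-frame `axis`.
#' @export
place_cup_liner <- function(cup, liner, orientation, hjc = c(0, 0, 0),
                            side = "R") {
  check_canonical_xy(cup, "cup")
  check_canonical_xy(liner, "liner")
  axis <- cup_axis_from_angles(orientation, side)
  rot <- rotation_between(c(0, 0, 1), axis)
  transform <- rigid_transform(rot$rotation, as.numeric(hjc))
  list(cup = transform_mesh(cup, transform),
       liner = transform_mesh(liner, transform),
       transform = transform, axis = axis)
}

#' Femoral stem configuration
#'
#' Geometry needed to seat the head on the stem taper: the neck axis (unit
#' vector from the head centre toward the shaft, world frame at neutral),
#' the head offset and diameter, and the matching cone pair (taper and head
#' bore share the cone half-angle; the bore is referenced by its radius at
#' the head-centre plane).
#'
#' @param neck_axis length-3 direction, head centre -> shaft.
#' @param head_offset_mm femoral offset (mm), carried as patient data.
#' @param head_diameter_mm prosthetic head diameter (mm, cohort default 32).
#' @param taper_tip_radius_mm radius of the taper at its tip (mm).
#' @param taper_half_angle_deg cone half-angle (degrees).
#' @param bore_radius_mm bore radius at the head-centre reference plane (mm).
#' @param seat_clearance_mm axial back-off from exact tangency so that the
#'   articulating surfaces do not register as intersecting (mm).
#' @return an object of class `stem_config`.
#' @export
stem_config <- function(neck_axis, head_offset_mm = 45,
                        head_diameter_mm = 32, taper_tip_radius_mm = 5,
                        taper_half_angle_deg = 3, bore_radius_mm = 5.5,
                        seat_clearance_mm = 1e-3) {
  stopifnot(head_diameter_mm > 0, head_offset_mm >= 0,
            taper_tip_radius_mm > 0, taper_half_angle_deg > 0,
            bore_radius_mm > 0, seat_clearance_mm >= 0)
  structure(list(neck_axis = as.numeric(neck_axis) /
                   sqrt(sum(as.numeric(neck_axis)^2)),
                 head_offset_mm = head_offset_mm,
                 head_diameter_mm = head_diameter_mm,
                 taper_tip_radius_mm = taper_tip_radius_mm,
                 taper_half_angle_deg = taper_half_angle_deg,
                 bore_radius_mm = bore_radius_mm,
                 seat_clearance_mm = seat_clearance_mm),
            class = "stem_config")
}

#' Analytic taper seat depth
#'
#' For a stem taper and head bore sharing cone half-angle `half_angle_deg`,
#' returns the axial distance from the head-centre reference plane to the
#' taper tip at exact surface tangency: `(bore_radius - tip_radius) /
#' tan(half_angle)`. Errors when the bore is smaller than the taper tip (no
#' interference-free seat exists).
#'
#' @param tip_radius_mm taper tip radius (mm).
#' @param half_angle_deg shared cone half-angle (degrees).
#' @param bore_radius_mm bore radius at the head-centre plane (mm).
#' @return seat depth in mm (>= 0).
#' @export
taper_seat_depth <- function(tip_radius_mm, half_angle_deg, bore_radius_mm) {
  if (bore_radius_mm < tip_radius_mm)
    stop("placement infeasible: bore radius (", bore_radius_mm,
         " mm) is smaller than the taper tip (", tip_radius_mm, " mm)")
  (bore_radius_mm - tip_radius_mm) / tan(half_angle_deg * pi / 180)
}

#' Place the head and stem
#'
#' The head (canonical: sphere centre at the origin) is translated so its
#' centre is the HJC. The stem (canonical: taper tip at the origin, taper
#' axis +Z pointing from tip toward the neck) is rotated so its insertion
#' direction opposes the neck axis and translated along the neck axis by the
#' analytic seat depth minus the configured seat clearance, so the taper
#' seats in the bore with no interpenetration.
#'
#' @param head,stem canonical [trimesh()] components.
#' @param config a [stem_config()].
#' @param hjc hip joint centre (mm).
#' @return list with transformed `head`, `stem`, the `insertion_depth_mm`
#'   (analytic seat depth from the head-centre plane) and the stem transform.
#' @export
place_head_stem <- function(head, stem, config, hjc = c(0, 0, 0)) {
  if (max(abs(colMeans(head$vertices))) > 1e-6)
    stop("head is not in canonical pose (sphere centre off the origin)")
  check_canonical_xy(stem, "stem")
  if (max(stem$vertices[, 3]) > 1e-6)
    stop("stem is not in canonical pose (taper tip must be the +z extreme at the origin)")
  depth <- taper_seat_depth(config$taper_tip_radius_mm,
                            config$taper_half_angle_deg,
                            config$bore_radius_mm)
  hjc <- as.numeric(hjc)
  head_t <- transform_mesh(head, rigid_transform(diag(3), hjc))
  # deep direction in the bore is -neck_axis; tip sits `depth` past the
  # head centre, backed off axially by the seat clearance
  tip <- hjc - (depth - config$seat_clearance_mm) * config$neck_axis
  rot <- rotation_between(c(0, 0, 1), -config$neck_axis)
  stem_t <- transform_mesh(stem, rigid_transform(rot$rotation, tip))
  list(head = head_t, stem = stem_t, insertion_depth_mm = depth,
       transform = rigid_transform(rot$rotation, tip))
}

#' Monitored impingement contact pairs
#'
#' The pairs evaluated by [check_initial_clearance()] and the ROM sweep:
#' liner/cup vs stem and femur (implant and bone impingement at the
#' acetabular rim), pelvis vs stem/head (implant-to-bone) and pelvis vs
#' femur (bone-to-bone). The articulating pairs (head-liner, head-cup) and
#' same-side fixation pairs (cup-pelvis, stem-femur, head-stem) are
#' intentionally in contact or interpenetrating and are excluded.
#'
#' @return list of character pairs `(pelvis-side label, femur-side label)`.
#' @export
monitored_pairs <- function() {
  list(c("liner", "stem"), c("cup", "stem"),
       c("liner", "femur"), c("cup", "femur"),
       c("pelvis", "stem"), c("pelvis", "head"),
       c("pelvis", "femur"))
}

#' Check that a hip model is collision-free at its current pose
#'
#' Evaluates every monitored contact pair; passes iff none collide.
#'
#' @param model a [hip_model()].
#' @return an object of class `clearance_check`: `pass` flag and the list
#'   of colliding pairs (with witness triangle indices) when failing.
#' @export
check_initial_clearance <- function(model) {
  bvhs <- lapply(model$meshes, build_bvh)
  colliding <- list()
  for (pair in monitored_pairs()) {
    rep <- meshes_collide(model$meshes[[pair[1]]], model$meshes[[pair[2]]],
                          bvhs[[pair[1]]], bvhs[[pair[2]]])
    if (rep$colliding) colliding[[length(colliding) + 1L]] <- rep
  }
  structure(list(pass = length(colliding) == 0L, collisions = colliding),
            class = "clearance_check")
}

#' @export
print.clearance_check <- function(x, ...) {
  if (x$pass) cat("<clearance: pass>\n")
  else {
    cat("<clearance: FAIL>\n")
    for (rep in x$collisions)
      cat(sprintf("  %s x %s\n", rep$witness$a$label, rep$witness$b$label))
  }
  invisible(x)
}

#' Assemble a complete hip model
#'
#' Aligns the bones to the neutral pose from their landmarks, places the cup
#' and liner at the hip joint centre from the radiographic angles, seats the
#' head and stem on the neck axis, and verifies initial clearance.
#'
#' @param parts named list of [trimesh()] objects: `pelvis` and `femur` in
#'   the landmark coordinate system; `cup`, `liner`, `head`, `stem` in their
#'   canonical poses.
#' @param landmarks a [landmark_set()].
#' @param orientation a [cup_orientation()].
#' @param config a [stem_config()].
#' @param side `"R"` or `"L"`.
#' @param check when `TRUE` (default) an initial-clearance failure is an
#'   error reporting the witness pairs.
#' @return a neutral-aligned [hip_model()].
#' @export
assemble_hip_model <- function(parts, landmarks, orientation, config,
                               side = "R", check = TRUE) {
  needed <- c("pelvis", "femur", "cup", "liner", "head", "stem")
  missing <- setdiff(needed, names(parts))
  if (length(missing) > 0L)
    stop("missing parts: ", paste(missing, collapse = ", "))
  pcs <- build_pelvic_frame(landmarks)
  fcs <- build_femoral_frame(landmarks)
  t_p <- invert_transform(frame_to_world(pcs))
  t_f <- invert_transform(frame_to_world(fcs))
  pelvis <- transform_mesh(parts$pelvis, t_p)
  femur <- transform_mesh(parts$femur, t_f)
  lms <- landmarks
  for (nm in setdiff(PELVIC_LANDMARKS, "HJC"))
    lms[[nm]] <- apply_transform(t_p, lms[[nm]])
  for (nm in setdiff(FEMORAL_LANDMARKS, "HJC"))
    lms[[nm]] <- apply_transform(t_f, lms[[nm]])
  lms$HJC <- apply_transform(t_p, lms$HJC)  # = origin by construction
  hjc <- lms$HJC
  acetab <- place_cup_liner(parts$cup, parts$liner, orientation, hjc, side)
  femoral <- place_head_stem(parts$head, parts$stem, config, hjc)
  model <- hip_model(list(pelvis = pelvis, femur = femur,
                          cup = acetab$cup, liner = acetab$liner,
                          head = femoral$head, stem = femoral$stem),
                     lms, side = side)
  if (check) {
    clearance <- check_initial_clearance(model)
    if (!clearance$pass) {
      pairs <- vapply(clearance$collisions, function(r)
        paste(r$witness$a$label, r$witness$b$label, sep = "-"), "")
      stop("assembled model fails initial clearance at neutral: ",
           paste(pairs, collapse = ", "))
    }
  }
  model
}
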