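#' Hip motion specification
#'
#' The six motions are realised as single-axis sweeps about world-fixed
#' axes (Rx flexion-extension, Ry abduction-adduction, Rz internal-external
#' rotation), with directions given for the canonical right hip: flexion
#' +X, extension -X, abduction -Y, adduction +Y, internal rotation +Z,
#' external rotation -Z. Internal rotation at 90 degrees flexion applies a
#' 90 degree flexion pre-rotation before sweeping about world Z.
#'
#' @param name motion name.
#' @param sweep_axis `"X"`, `"Y"` or `"Z"`.
#' @param direction `+1` or `-1`.
#' @param pre_rotation_deg flexion applied before the sweep (0 or 90).
#' @param cap_deg sweep cap in degrees; results at the cap are reported as
#'   no impingement.
#' @return an object of class `motion_spec`.
#' @export
motion_spec <- function(name, sweep_axis, direction, pre_rotation_deg = 0,
                        cap_deg = 180) {
  sweep_axis <- match.arg(sweep_axis, c("X", "Y", "Z"))
  stopifnot(direction %in% c(-1, 1), pre_rotation_deg %in% c(0, 90),
            cap_deg > 0)
  structure(list(name = name, sweep_axis = sweep_axis,
                 direction = direction, pre_rotation_deg = pre_rotation_deg,
                 cap_deg = cap_deg),
            class = "motion_spec")
}

#' The six standard hip motions
#'
#' Flexion (Flex), extension (Ext), abduction (Abd), adduction (Add),
#' external rotation at neutral (ER) and internal rotation at 90 degrees
#' flexion (IR@90Flex). Flexion/extension/abduction/adduction are capped at
#' 180 degrees, the axial rotations at 150.
#'
#' @return named list of [motion_spec()] objects.
#' @export
standard_motions <- function() {
  list(
    Flex = motion_spec("Flex", "X", +1),
    Ext = motion_spec("Ext", "X", -1),
    Abd = motion_spec("Abd", "Y", -1),
    Add = motion_spec("Add", "Y", +1),
    ER = motion_spec("ER", "Z", -1, cap_deg = 150),
    `IR@90Flex` = motion_spec("IR@90Flex", "Z", +1, pre_rotation_deg = 90,
                              cap_deg = 150)
  )
}

#' Pelvic tilt condition
#'
#' Sagittal pelvic rotation about the world X axis, anterior-positive,
#' measured relative to the anterior pelvic plane. The validated range is
#' -60 to 60 degrees.
#'
#' @param label condition label, conventionally one of `"noPT"`,
#'   `"StPT_0"`, `"StPT_6"`, `"StPT_12"`.
#' @param tilt_deg anterior-positive tilt in degrees (`"noPT"` forces 0).
#' @return an object of class `pt_condition`.
#' @export
pt_condition <- function(label, tilt_deg = 0) {
  if (label == "noPT" && tilt_deg != 0)
    stop("the noPT condition must have zero tilt")
  if (!is.finite(tilt_deg) || abs(tilt_deg) > 60)
    stop("pelvic tilt ", tilt_deg, " degrees is outside the validated range (-60, 60)")
  structure(list(label = label, tilt_deg = tilt_deg), class = "pt_condition")
}

#' Pose the pelvis by pelvic tilt
#'
#' Rotates the pelvis-side rigid body (pelvis, cup, liner) about the world
#' X axis through the origin. With world axes X right / Y anterior / Z
#' superior, anterior tilt positive corresponds to the rotation Rx(-tilt):
#' the superior pelvis tips anteriorly and the acetabular opening rotates
#' to cover the femoral neck anteriorly, reducing flexion. The femoral side
#' is untouched.
#'
#' @param model a neutral [hip_model()].
#' @param pt a [pt_condition()] (or a number of degrees).
#' @return the posed `hip_model`.
#' @export
pose_pelvis <- function(model, pt) {
  tilt <- if (inherits(pt, "pt_condition")) pt$tilt_deg else pt
  if (tilt == 0) return(model)
  transform_body(model, rotation_about_world_axis("X", -tilt), "pelvis")
}

#' Pose the femur along a motion sweep
#'
#' Applies `R_sweep(direction * angle) o R_x(pre_rotation)` to the femoral
#' side (femur, head, stem) about the world origin: pre-rotation first,
#' then the sweep about the fixed world axis.
#'
#' @param model a [hip_model()] (pelvis may already be posed).
#' @param motion a [motion_spec()].
#' @param angle_deg sweep angle in degrees.
#' @return the posed `hip_model`.
#' @export
pose_femur <- function(model, motion, angle_deg) {
  transform_body(model, femur_pose_transform(motion, angle_deg), "femur")
}

femur_pose_transform <- function(motion, angle_deg) {
  sweep_rot <- rotation_about_world_axis(motion$sweep_axis,
                                         motion$direction * angle_deg)
  if (motion$pre_rotation_deg == 0) return(sweep_rot)
  compose_transforms(sweep_rot,
                     rotation_about_world_axis("X", motion$pre_rotation_deg))
}

#' Classify an impingement event
#'
#' Maps colliding contact pairs to the impingement type: implant-implant
#' pairs give ITII, implant-bone ITBI and bone-bone BTBI (bones are pelvis
#' and femur; implants cup, liner, head, stem). When several categories
#' first collide at the same sweep step the fixed priority ITII > ITBI >
#' BTBI applies. The articulating head-liner pair must never reach
#' classification.
#'
#' @param pairs list of character 2-vectors of component labels (or a
#'   single 2-vector).
#' @return `"ITII"`, `"ITBI"` or `"BTBI"`.
#' @export
#' @examples
#' classify_impingement(c("liner", "stem"))   # ITII
#' classify_impingement(c("pelvis", "stem"))  # ITBI
#' classify_impingement(c("pelvis", "femur")) # BTBI
classify_impingement <- function(pairs) {
  if (is.character(pairs)) pairs <- list(pairs)
  if (length(pairs) == 0L) stop("no contact pairs to classify")
  bone <- c("pelvis", "femur")
  implant <- c("cup", "liner", "head", "stem")
  types <- vapply(pairs, function(p) {
    stopifnot(length(p) == 2L)
    if (setequal(p, c("head", "liner")))
      stop("the articulating head-liner pair is excluded from impingement")
    is_bone <- p %in% bone
    is_implant <- p %in% implant
    if (!all(is_bone | is_implant)) stop("unknown component labels: ",
                                         paste(p, collapse = ", "))
    n_bone <- sum(is_bone)
    if (n_bone == 0L) "ITII" else if (n_bone == 1L) "ITBI" else "BTBI"
  }, "")
  priority <- c("ITII", "ITBI", "BTBI")
  priority[min(match(types, priority))]
}

#' Find the limiting range of motion for one motion and tilt condition
#'
#' Poses the pelvis by the tilt condition, then sweeps the femoral side in
#' `step` degree increments from zero until a monitored contact pair
#' collides. The limiting ROM is the last collision-free angle (one step
#' below the first colliding angle); the impingement type is classified
#' from all pairs colliding at that first angle. If the sweep reaches the
#' cap without collision the limit is the cap and the type `"NONE"`.
#'
#' @param model a neutral [hip_model()]; left hips are mirrored to the
#'   canonical right-hip frame internally.
#' @param motion a [motion_spec()].
#' @param pt a [pt_condition()].
#' @param step sweep increment in degrees (default 0.5); the cap must be a
#'   multiple of the step.
#' @return an object of class `rom_result`: `limit_deg`,
#'   `impingement_type`, witness pair and the motion/tilt descriptors.
#' @export
find_limiting_rom <- function(model, motion, pt = pt_condition("noPT"),
                              step = 0.5) {
  stopifnot(inherits(motion, "motion_spec"), step > 0)
  n_steps <- motion$cap_deg / step
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("cap (", motion$cap_deg, ") must be a multiple of the step (", step, ")")
  n_steps <- round(n_steps)
  if (model$side == "L") model <- mirror_model(model)
  model <- pose_pelvis(model, pt)

  pairs <- monitored_pairs()
  pelvis_meshes <- model$meshes[PELVIS_SIDE]
  pelvis_bvh <- lapply(pelvis_meshes, build_bvh)
  femur_base <- model$meshes[FEMUR_SIDE]

  step_contacts <- function(angle) {
    tf <- femur_pose_transform(motion, angle)
    posed <- lapply(femur_base, transform_mesh, transform = tf)
    bvhs <- lapply(posed, build_bvh)
    hits <- list()
    for (p in pairs) {
      rep <- meshes_collide(pelvis_meshes[[p[1]]], posed[[p[2]]],
                            pelvis_bvh[[p[1]]], bvhs[[p[2]]])
      if (rep$colliding) hits[[length(hits) + 1L]] <- p
    }
    hits
  }

  initial <- step_contacts(0)
  if (length(initial) > 0L)
    stop("initial pose already colliding (", motion$name, ", tilt ",
         pt$tilt_deg, " deg): ",
         paste(vapply(initial, paste, "", collapse = "-"), collapse = ", "),
         "; invalid assembly or extreme pelvic tilt")

  for (k in seq_len(n_steps)) {
    hits <- step_contacts(k * step)
    if (length(hits) > 0L) {
      type <- classify_impingement(hits)
      # witness: the highest-priority colliding pair (ITII > ITBI > BTBI)
      prio <- vapply(hits, function(p)
        match(classify_impingement(list(p)), c("ITII", "ITBI", "BTBI")), 0L)
      witness <- hits[[which.min(prio)]]
      return(rom_result(motion, pt, (k - 1L) * step, type, witness))
    }
  }
  rom_result(motion, pt, motion$cap_deg, "NONE", NULL)
}

rom_result <- function(motion, pt, limit, type, witness) {
  structure(list(motion = motion$name, pt_label = pt$label,
                 pt_deg = pt$tilt_deg, limit_deg = limit,
                 impingement_type = type, witness = witness),
            class = "rom_result")
}

#' @export
print.rom_result <- function(x, ...) {
  cat(sprintf("<rom_result %s @ %s (%g deg): limit %.1f deg, %s%s>\n",
              x$motion, x$pt_label, x$pt_deg, x$limit_deg, x$impingement_type,
              if (!is.null(x$witness))
                paste0(" (", paste(x$witness, collapse = "-"), ")") else ""))
  invisible(x)
}

#' Simulate all motions for one patient
#'
#' Runs [find_limiting_rom()] for every motion and every tilt condition;
#' deterministic for fixed inputs.
#'
#' @param model a neutral [hip_model()].
#' @param pt_values list of [pt_condition()] objects (non-empty).
#' @param motions named list of [motion_spec()]s (default the six standard
#'   motions).
#' @param step sweep increment (degrees).
#' @return data frame with one row per motion x condition: `motion`,
#'   `pt_label`, `pt_deg`, `limit_deg`, `impingement_type`, `witness_a`,
#'   `witness_b`.
#' @export
simulate_patient <- function(model, pt_values, motions = standard_motions(),
                             step = 0.5) {
  if (length(pt_values) == 0L) stop("pt_values must be non-empty")
  if (inherits(pt_values, "pt_condition")) pt_values <- list(pt_values)
  rows <- list()
  for (m in motions) {
    for (pt in pt_values) {
      res <- find_limiting_rom(model, m, pt, step)
      rows[[length(rows) + 1L]] <- data.frame(
        motion = res$motion, pt_label = res$pt_label, pt_deg = res$pt_deg,
        limit_deg = res$limit_deg, impingement_type = res$impingement_type,
        witness_a = if (is.null(res$witness)) NA_character_ else res$witness[1],
        witness_b = if (is.null(res$witness)) NA_character_ else res$witness[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
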