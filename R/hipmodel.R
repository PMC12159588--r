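#' Posable hip model
#'
#' Container for one hip: bone and implant meshes, anatomical landmarks,
#' treatment side and the pelvic/femoral coordinate frames. The pelvis-side
#' rigid body is `pelvis + cup + liner`; the femoral-side rigid body is
#' `femur + head + stem`.
#'
#' @param meshes named list of [trimesh()] objects with names `pelvis`,
#'   `femur`, `cup`, `liner`, `head`, `stem`.
#' @param landmarks a [landmark_set()] with pelvic and femoral names.
#' @param side `"R"` or `"L"`.
#' @param pcs,fcs pelvic and femoral [frame()]s; recomputed from the
#'   landmarks when omitted.
#' @return an object of class `hip_model`.
#' @export
hip_model <- function(meshes, landmarks, side = "R", pcs = NULL, fcs = NULL) {
  needed <- c("pelvis", "femur", "cup", "liner", "head", "stem")
  missing <- setdiff(needed, names(meshes))
  if (length(missing) > 0L)
    stop("missing component meshes: ", paste(missing, collapse = ", "))
  side <- match.arg(side, c("R", "L"))
  for (nm in needed) {
    if (!inherits(meshes[[nm]], "trimesh")) stop("component '", nm, "' is not a trimesh")
    meshes[[nm]]$label <- nm
  }
  require_landmarks(landmarks, union(PELVIC_LANDMARKS, FEMORAL_LANDMARKS))
  if (is.null(pcs)) pcs <- build_pelvic_frame(landmarks)
  if (is.null(fcs)) fcs <- build_femoral_frame(landmarks)
  structure(list(meshes = meshes[needed], landmarks = landmarks, side = side,
                 pcs = pcs, fcs = fcs),
            class = "hip_model")
}

#' @export
print.hip_model <- function(x, ...) {
  cat(sprintf("<hip_model: side %s>\n", x$side))
  for (nm in names(x$meshes))
    cat(sprintf("  %-7s %6d faces\n", nm, n_faces(x$meshes[[nm]])))
  cat("  PCS origin:", paste(round(x$pcs$origin, 2), collapse = " "), "mm\n")
  invisible(x)
}

PELVIS_SIDE <- c("pelvis", "cup", "liner")
FEMUR_SIDE <- c("femur", "head", "stem")

# apply a rigid transform to one rigid body (its meshes + owned landmarks)
transform_body <- function(model, transform, body = c("pelvis", "femur")) {
  body <- match.arg(body)
  mesh_names <- if (body == "pelvis") PELVIS_SIDE else FEMUR_SIDE
  lm_names <- if (body == "pelvis") PELVIC_LANDMARKS else FEMORAL_LANDMARKS
  for (nm in mesh_names)
    model$meshes[[nm]] <- transform_mesh(model$meshes[[nm]], transform)
  for (nm in setdiff(lm_names, "HJC"))
    model$landmarks[[nm]] <- apply_transform(transform, model$landmarks[[nm]])
  if (body == "pelvis")  # the HJC is carried by the pelvis (it is the cup centre)
    model$landmarks$HJC <- apply_transform(transform, model$landmarks$HJC)
  model
}

#' Align a hip model to the neutral pose
#'
#' Rigidly moves the pelvis-side body by the inverse of the pelvic frame and
#' the femoral-side body by the inverse of the femoral frame, so that both
#' frame origins sit at the world origin and all six axes coincide with the
#' world axes. Idempotent; all meshes move rigidly with their frames.
#'
#' @param model a [hip_model()].
#' @return the aligned `hip_model` with identity PCS/FCS.
#' @export
align_to_neutral <- function(model) {
  t_p <- invert_transform(frame_to_world(model$pcs))
  t_f <- invert_transform(frame_to_world(model$fcs))
  model <- transform_body(model, t_p, "pelvis")
  model <- transform_body(model, t_f, "femur")
  model$pcs <- build_pelvic_frame(model$landmarks)
  model$fcs <- build_femoral_frame(model$landmarks)
  model
}

#' Mirror a hip model across the sagittal plane
#'
#' Reflects all meshes and landmarks across the plane x = 0 (the
#' mediolateral-normal plane through the world origin), flips face windings
#' to preserve outward normals, swaps left/right landmark names, and toggles
#' the side flag. Applying it twice returns the original model. Simulated
#' limiting angles are invariant under mirroring.
#'
#' @param model a [hip_model()].
#' @return the mirrored `hip_model`.
#' @export
mirror_model <- function(model) {
  for (nm in names(model$meshes))
    model$meshes[[nm]] <- reflect_mesh_x(model$meshes[[nm]])
  lms <- model$landmarks
  swap <- function(nm) {
    if (grepl("_right$", nm)) sub("_right$", "_left", nm)
    else if (grepl("_left$", nm)) sub("_left$", "_right", nm)
    else nm
  }
  new <- lapply(lms, function(p) p * c(-1, 1, 1))
  names(new) <- vapply(names(lms), swap, "")
  model$landmarks <- do.call(landmark_set, new)
  model$side <- if (model$side == "R") "L" else "R"
  model$pcs <- build_pelvic_frame(model$landmarks)
  model$fcs <- build_femoral_frame(model$landmarks)
  model
}
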