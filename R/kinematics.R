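# Quasi-static single-limb kinematics.
#
# Global frame: x anterior, y mediolateral (medial/left positive for the
# right limb), z vertical.  The pelvis is fixed; the limb hangs from the
# hip through a 3-DOF hip (extension about the mediolateral axis, then
# abduction about the anteroposterior axis, then long-axis rotation),
# a hinge knee (optionally with a skewed axis), a hinge ankle and a hinge
# metatarsophalangeal joint: six actuated rotational degrees of freedom
# (plus the six bookkeeping DOFs of the fixed pelvis).

DOF_NAMES <- c("hip_extension", "hip_abduction", "hip_lar",
               "knee_flexion", "ankle_flexion", "mtp_angle")

DOF_BOUNDS_DEFAULT <- list(
  hip_extension = c(0, 90),
  hip_abduction = c(-45, 135),
  hip_lar       = c(-45, 135),
  knee_flexion  = c(-45, 135),
  ankle_flexion = c(-45, 135),
  mtp_angle     = c(-45, 135)
)

#' Construct a posture
#'
#' Joint-angle sign conventions: hip extension is measured from the
#' horizontal (0 = femur horizontal pointing anteriorly, 90 = vertical,
#' columnar); positive hip abduction swings the knee laterally; positive
#' hip long-axis rotation is external (lateral) rotation; knee flexion is
#' measured relative to the femur (positive deflects the crus
#' posteriorly); ankle flexion relative to the tibiotarsus (positive
#' deflects the tarsometatarsus anteriorly); the metatarsophalangeal
#' angle is relative to the neutral (foot-flat) configuration, positive
#' pitching the toes down.
#'
#' @param hip_extension,hip_abduction,hip_lar,knee_flexion,ankle_flexion,mtp_angle
#'   angles in degrees
#' @param bounds named list of `c(lo, hi)` per DOF
#' @return a named numeric vector of class `posture`
#' @export
posture <- function(hip_extension = 90, hip_abduction = 0, hip_lar = 0,
                    knee_flexion = 0, ankle_flexion = 0, mtp_angle = 0,
                    bounds = DOF_BOUNDS_DEFAULT) {
  p <- c(hip_extension = hip_extension, hip_abduction = hip_abduction,
         hip_lar = hip_lar, knee_flexion = knee_flexion,
         ankle_flexion = ankle_flexion, mtp_angle = mtp_angle)
  for (d in DOF_NAMES) {
    b <- bounds[[d]]
    if (p[[d]] < b[1] - 1e-9 || p[[d]] > b[2] + 1e-9)
      stop("posture angle ", d, " = ", p[[d]],
           " outside bounds [", b[1], ", ", b[2], "]")
  }
  structure(p, class = "posture")
}

as_posture <- function(x) {
  if (inherits(x, "posture")) return(x)
  do.call(posture, as.list(x[DOF_NAMES]))
}

#' Assemble a complete limb model
#'
#' @param template a [build_species_template()] result (or compatible list)
#' @param g gravitational acceleration (m/s^2)
#' @param knee_axis_skew obliquity of the knee flexion-extension axis in
#'   the coronal plane, degrees (default 0)
#' @param hip_medial_offset medial translation of the femur (and all
#'   distal structures) within the acetabulum, metres; see
#'   [apply_hip_variant()]
#' @param com_fraction position of each limb-segment COM as a fraction of
#'   segment length from the proximal joint
#' @return a `model_spec`
#' @export
model_spec <- function(template, g = 9.81, knee_axis_skew = 0,
                       hip_medial_offset = 0, com_fraction = 0.45) {
  stopifnot(g > 0)
  structure(list(
    template = template,
    g = g,
    knee_axis_skew = knee_axis_skew,
    hip_medial_offset = hip_medial_offset,
    extra_abduction = 0,
    extra_lar = 0,
    com_fraction = com_fraction,
    muscles = template$muscle_roster,
    mtp_reserve_max = template$mtp_reserve_max,
    fmax = 2 * template$total_body_mass * g
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> template:", x$template$name,
      "| g =", x$g, "m/s^2 | Fmax =", signif(x$fmax, 6), "N\n")
  invisible(x)
}

#' Forward kinematics of the limb chain
#'
#' Computes segment frames (rotation + proximal-joint origin), joint
#' centres, hip height above the ground plane and the whole-body centre of
#' mass.  The ground plane is set under the lowest foot point (the limb is
#' placed so the foot touches z = 0); a posture that puts the hip, knee or
#' ankle below that plane is flagged infeasible.
#'
#' @param model a [model_spec()]
#' @param pose a [posture()]
#' @return list with `frames` (per segment: rotation `R` local->global and
#'   global `origin`), `joints` (hip, knee, ankle, mtp, toe), `h` (hip
#'   height, m), `com` (whole-body COM, global), `limb_com`, `feasible`
#' @export
forward_kinematics <- function(model, pose) {
  pose <- as_posture(pose)
  tpl <- model$template
  Ls <- tpl$segment_lengths
  th <- deg2rad(pose[["hip_extension"]])
  ab <- deg2rad(pose[["hip_abduction"]] + model$extra_abduction)
  la <- deg2rad(pose[["hip_lar"]] + model$extra_lar)
  kf <- deg2rad(pose[["knee_flexion"]])
  af <- deg2rad(pose[["ankle_flexion"]])
  mt <- deg2rad(pose[["mtp_angle"]])
  skew <- deg2rad(model$knee_axis_skew)

  # femur: extension (about global y), then abduction (about global x;
  # positive swings the knee laterally, i.e. -y), then external LAR about
  # the femoral long axis
  R_f0 <- rot_x(-ab) %*% rot_y(th)
  d_f <- R_f0 %*% c(1, 0, 0)
  R_f <- rot_axis(d_f, la) %*% R_f0
  R_t <- R_f %*% (rot_z(skew) %*% rot_y(kf) %*% rot_z(-skew))
  R_m <- R_t %*% rot_y(-af)
  R_p <- R_m %*% rot_y(mt - pi / 2)

  hip <- c(0, model$hip_medial_offset, 0)
  knee  <- hip + Ls[["femur"]] * as.vector(R_f %*% c(1, 0, 0))
  ankle <- knee + Ls[["tibiotarsus"]] * as.vector(R_t %*% c(1, 0, 0))
  mtpj  <- ankle + Ls[["tarsometatarsus"]] * as.vector(R_m %*% c(1, 0, 0))
  toe   <- mtpj + Ls[["pes"]] * as.vector(R_p %*% c(1, 0, 0))

  ground <- min(mtpj[3], toe[3])
  shift <- c(0, 0, -ground)
  hip <- hip + shift; knee <- knee + shift; ankle <- ankle + shift
  mtpj <- mtpj + shift; toe <- toe + shift

  feasible <- !(hip[3] < -1e-9 || knee[3] < -1e-9 || ankle[3] < -1e-9)

  frames <- list(
    pelvis = list(R = diag(3), origin = hip - c(0, model$hip_medial_offset, 0)),
    femur = list(R = R_f, origin = hip),
    tibiotarsus = list(R = R_t, origin = knee),
    tarsometatarsus = list(R = R_m, origin = ankle),
    pes = list(R = R_p, origin = mtpj)
  )

  cf <- model$com_fraction
  seg_com <- rbind(
    femur = hip + cf * (knee - hip),
    tibiotarsus = knee + cf * (ankle - knee),
    tarsometatarsus = ankle + cf * (mtpj - ankle),
    pes = mtpj + cf * (toe - mtpj)
  )
  m_seg <- tpl$segment_masses[rownames(seg_com)]
  limb_com <- colSums(seg_com * m_seg) / sum(m_seg)
  pelvis_com <- frames$pelvis$origin + c(tpl$pelvis_com_offset_anterior, 0, 0)
  com <- (limb_com * sum(m_seg) + pelvis_com * tpl$pelvis_segment_mass) /
    tpl$total_body_mass

  list(frames = frames,
       joints = list(hip = hip, knee = knee, ankle = ankle,
                     mtp = mtpj, toe = toe),
       seg_com = seg_com, h = hip[3], com = com, limb_com = limb_com,
       feasible = feasible)
}

#' Map a segment-local point to the global frame
#' @keywords internal
local_to_global <- function(fk, segment, p) {
  fr <- fk$frames[[segment]]
  as.vector(fr$origin + fr$R %*% p)
}

#' Global coordinates of a muscle path at a posture
#' @param model a `model_spec`
#' @param fk result of [forward_kinematics()]
#' @param muscle one entry of `model$muscles`
#' @return n x 3 matrix of global points, proximal to distal
#' @keywords internal
muscle_path_global <- function(model, fk, muscle) {
  pts <- vapply(muscle$path, function(pt)
    local_to_global(fk, pt$segment, pt$p), numeric(3))
  t(pts)
}

#' Single-limb quasi-static load case
#'
#' @param model a `model_spec`
#' @param grf_magnitude vertical ground-reaction-force magnitude in
#'   newtons; defaults to one body weight
#' @param cop_frac centre-of-pressure position along the pes, as a
#'   fraction of pes length from the metatarsophalangeal joint
#' @return a `load_case`
#' @export
load_case <- function(model, grf_magnitude = NULL, cop_frac = 0.4) {
  if (is.null(grf_magnitude))
    grf_magnitude <- model$template$total_body_mass * model$g
  stopifnot(grf_magnitude >= 0, cop_frac >= 0, cop_frac <= 1)
  structure(list(grf_magnitude = grf_magnitude, cop_frac = cop_frac),
            class = "load_case")
}

#' Centre of pressure in global coordinates
#' @keywords internal
cop_position <- function(model, fk, loadcase) {
  mtpj <- fk$joints$mtp
  toe <- fk$joints$toe
  mtpj + loadcase$cop_frac * (toe - mtpj)
}

#' Reference (initial) posture for a species template
#'
#' A mid-stance-like starting posture per body-size scale: largely
#' upright with a subvertical femur at tyrannosaurid scale, progressively
#' more crouched toward chicken scale.  These serve as search starting
#' points and as the generating postures of the synthetic test world.
#'
#' @param name template name (see [build_species_template()])
#' @return a [posture()]
#' @export
reference_posture <- function(name) {
  switch(name,
    "large-tyrannosaurid-scale" = posture(80, 0, 5, 25, 20, 5),
    "troodontid-scale" = posture(70, 0, 5, 35, 25, 10),
    "chicken-scale" = posture(60, 5, 0, 45, 30, 10),
    stop("unknown template '", name, "'"))
}
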