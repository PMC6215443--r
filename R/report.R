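# Cross-species parameter extraction: normalized muscle moments,
# postural and bone-loading metrics, and monotone-trend checks across a
# basal -> derived -> extant species ordering.

#' Normalized (dimensionless) muscle moment
#'
#' M* = a Fmax r / (m g h): the moment a muscle exerts about a joint
#' axis, normalized by body weight times hip height, a size-independent
#' measure of stabilizing effort.
#'
#' @param a activation in [0, 1]
#' @param Fmax maximum muscle force (N)
#' @param r moment arm about the joint axis (m, signed)
#' @param m body mass (kg)
#' @param g gravitational acceleration (m/s^2)
#' @param h hip height (m)
#' @return dimensionless moment (signed as `r`)
#' @export
normalized_moment <- function(a, Fmax, r, m, g, h) {
  if (h <= 0) stop("hip height must be positive")
  if (m <= 0 || g <= 0) stop("mass and g must be positive")
  if (any(a < 0 | a > 1)) stop("activation must lie in [0, 1]")
  a * Fmax * r / (m * g * h)
}

#' Group-summed normalized moments
#'
#' Sums M* over the muscles carrying a functional group tag, about the
#' stated hip DOF: abductors about hip abduction, medial rotators about
#' hip long-axis rotation (medial = negative of the external-positive
#' convention, so the magnitude is reported).
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @param sol an `activation_solution`
#' @param group `"hip_abductor"` or `"hip_medial_rotator"`
#' @return dimensionless group moment magnitude
#' @export
group_normalized_moment <- function(model, pose, sol,
                                    group = c("hip_abductor",
                                              "hip_medial_rotator")) {
  group <- match.arg(group)
  dof <- if (group == "hip_abductor") "hip_abduction" else "hip_lar"
  fk <- forward_kinematics(model, pose)
  tot <- 0
  for (mu in model$muscles) {
    if (!identical(mu$group, group)) next
    a <- sol$activations[[mu$name]]
    r <- sol$moment_arms[mu$name, dof]
    tot <- tot + normalized_moment(a, model$fmax, r,
                                   model$template$total_body_mass,
                                   model$g, fk$h)
  }
  abs(tot)
}

#' Degree of crouch
#'
#' 1 - (hip height / fully extended functional limb length): 0 for a
#' columnar limb, approaching 1 as the limb collapses.  The fully
#' extended length is the sum of femur, tibiotarsus and tarsometatarsus
#' interarticular lengths (foot flat).
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @return dimensionless crouch index in [0, 1]
#' @export
crouch_index <- function(model, pose) {
  fk <- forward_kinematics(model, pose)
  if (!fk$feasible) stop("infeasible posture")
  Ls <- model$template$segment_lengths
  Lmax <- Ls[["femur"]] + Ls[["tibiotarsus"]] + Ls[["tarsometatarsus"]]
  max(0, min(1, 1 - fk$h / Lmax))
}

#' Strict monotone trend check
#'
#' @param values numeric vector ordered basal -> derived -> extant
#'   (length >= 3)
#' @return list: `monotone` (logical), `direction` ("increasing",
#'   "decreasing" or NA)
#' @export
check_monotonic_trend <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  d <- diff(values)
  if (all(d > 0)) list(monotone = TRUE, direction = "increasing")
  else if (all(d < 0)) list(monotone = TRUE, direction = "decreasing")
  else list(monotone = FALSE, direction = NA_character_)
}

#' Cross-species biomechanical record for one solution posture
#'
#' Extracts the postural, bone-loading and muscular-support parameters
#' from a solved posture: whole-body COM offset normalized by total leg
#' length, joint angles, degree of crouch, femoral mid-shaft
#' principal-stress inclination, shear/bending ratio and neutral-axis
#' angle, and the normalized hip abductor and medial rotator moments.
#'
#' @param model a `model_spec`
#' @param pose the solution [posture()]
#' @param sol optional `activation_solution` (solved if missing)
#' @param loadcase a [load_case()]
#' @return one-row data.frame (a `cross_species_record`)
#' @export
cross_species_record <- function(model, pose, sol = NULL,
                                 loadcase = load_case(model)) {
  pose <- as_posture(pose)
  if (is.null(sol)) {
    M <- inverse_static_moments(model, pose, loadcase)
    sol <- static_optimization(model, M, pose)
  }
  fk <- forward_kinematics(model, pose)
  Ls <- model$template$segment_lengths
  leg_len <- sum(Ls)

  loads <- internal_loads(model, pose, sol, "femur", n_stations = 21,
                          loadcase = loadcase)
  mid <- loads[which.min(abs(loads$station - Ls[["femur"]] / 2)), ]
  st <- section_stresses(list(N = mid$N, M_y = mid$M_y, M_z = mid$M_z,
                              T = mid$T),
                         model$template$cross_sections$femur)
  sbr <- suppressWarnings(shear_bending_ratio(st))

  com_anterior <- fk$com[1] - fk$frames$pelvis$origin[1]
  data.frame(
    species = model$template$name,
    com_fraction = com_anterior / leg_len,
    hip_extension = pose[["hip_extension"]],
    hip_abduction = pose[["hip_abduction"]],
    hip_lar = pose[["hip_lar"]],
    knee_flexion = pose[["knee_flexion"]],
    crouch_index = crouch_index(model, pose),
    theta_principal = st$theta_principal,
    shear_bending_ratio = sbr,
    neutral_axis_angle = st$neutral_axis_angle,
    M_abductor = group_normalized_moment(model, pose, sol, "hip_abductor"),
    M_medial_rotator = group_normalized_moment(model, pose, sol,
                                               "hip_medial_rotator")
  )
}
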