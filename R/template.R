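# Limb-model templates at three body-size scales.
#
# Each template is a self-contained description of a single right hindlimb:
# segment lengths and masses, pelvis-segment bookkeeping, idealized
# hollow-ellipse bone cross-sections, and a 33-muscle roster with activity
# flags and functional group tags.  Printed reference masses, femur lengths
# and centre-of-mass offsets are used where available; everything else is a
# documented default chosen to be anatomically plausible at that scale.
#
# Segment-local frames: origin at the proximal joint centre, local x along
# the bone long axis pointing distally, local y mediolateral (medial
# positive for the right limb), local z completing a right-handed triad
# (the "anterior" face of a vertically oriented bone).  The pelvis frame
# sits at the hip joint centre with axes parallel to the global frame
# (x anterior, y medial, z up); the pelvis is fixed in all simulations.

SPECIES_NAMES <- c("large-tyrannosaurid-scale", "troodontid-scale",
                   "chicken-scale")

# Mass split of the limb across segments (fractions of right-hindlimb mass).
# Per-segment fossil masses are not tabulated, so fixed fractions are used:
# thigh 60%, shank 30%, foot 10% (tarsometatarsus 7%, pes 3%).
LIMB_MASS_FRACTIONS <- c(femur = 0.60, tibiotarsus = 0.30,
                         tarsometatarsus = 0.07, pes = 0.03)

#' Build a species-scale limb template
#'
#' Constructs the complete parameter set for one of the three built-in
#' body-size scales.  The two fossil-scale templates carry the printed
#' total body masses, right-hindlimb masses, femur lengths and
#' pelvis-segment centre-of-mass offsets; the chicken-scale template's
#' total mass defaults to 1.56 kg, back-derived from the stated
#' metatarsophalangeal reserve-actuator proportionality (1,000 N m at
#' chicken scale vs 1,767,308 N m at 2,757 kg).
#'
#' @param name one of `"large-tyrannosaurid-scale"`, `"troodontid-scale"`,
#'   `"chicken-scale"`.
#' @return an object of class `species_template`: a list with fields
#'   `name`, `total_body_mass` (kg), `right_hindlimb_mass` (kg),
#'   `pelvis_segment_mass` (kg), `femur_length` (m), `segment_lengths`
#'   (named, m), `segment_masses` (named, kg), `pelvis_com_offset_anterior`
#'   (m), `cross_sections` (per-bone hollow-ellipse parameters),
#'   `muscle_roster` (list of muscle specs), and `mtp_reserve_max` (N m).
#' @export
#' @examples
#' tpl <- build_species_template("troodontid-scale")
#' tpl$pelvis_segment_mass  # 42.85
build_species_template <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% SPECIES_NAMES))
    stop("unknown template '", paste(name, collapse = ","),
         "'; valid templates: ", paste(SPECIES_NAMES, collapse = ", "))

  chicken_mass <- 1.56  # kg, implied by reserve-actuator scaling; a default

  pars <- switch(name,
    "large-tyrannosaurid-scale" = list(
      total_body_mass = 2757, right_hindlimb_mass = 342.7,
      femur_length = 0.984,
      # tibiotarsus:femur ~ 1.0, tmt ~ 0.55, pes ~ 0.40 (large tyrannosaurid
      # proportions); defaults, not printed values
      seg_ratio = c(femur = 1.0, tibiotarsus = 1.00,
                    tarsometatarsus = 0.55, pes = 0.40),
      pelvis_com_offset_anterior = 0.423,
      femur_radius_frac = 0.080, wall_fraction = 0.35),
    "troodontid-scale" = list(
      total_body_mass = 48.5, right_hindlimb_mass = 5.65,
      femur_length = 0.304,
      seg_ratio = c(femur = 1.0, tibiotarsus = 1.30,
                    tarsometatarsus = 0.75, pes = 0.45),
      pelvis_com_offset_anterior = 0.168,
      femur_radius_frac = 0.055, wall_fraction = 0.30),
    "chicken-scale" = list(
      total_body_mass = chicken_mass,
      right_hindlimb_mass = 0.10 * chicken_mass,  # ~10% of body mass
      femur_length = 0.075,
      seg_ratio = c(femur = 1.0, tibiotarsus = 1.40,
                    tarsometatarsus = 0.80, pes = 0.60),
      # isometric rescale of the dromaeosaur reference offset (0.090 m at
      # 0.163 m femur) to a 0.075 m femur
      pelvis_com_offset_anterior = 0.090 * 0.075 / 0.163,
      femur_radius_frac = 0.050, wall_fraction = 0.25)
  )

  seg_len <- pars$seg_ratio * pars$femur_length
  seg_mass <- LIMB_MASS_FRACTIONS * pars$right_hindlimb_mass

  rf <- pars$femur_radius_frac * pars$femur_length
  cross_sections <- list(
    femur = cross_section(a_y = rf, a_z = 0.9 * rf,
                          wall_fraction = pars$wall_fraction),
    tibiotarsus = cross_section(a_y = 0.85 * rf, a_z = 0.80 * rf,
                                wall_fraction = pars$wall_fraction),
    tarsometatarsus = cross_section(a_y = 0.70 * rf, a_z = 0.60 * rf,
                                    wall_fraction = pars$wall_fraction),
    pes = cross_section(a_y = 0.80 * rf, a_z = 0.45 * rf,
                        wall_fraction = pars$wall_fraction)
  )

  tpl <- structure(list(
    name = name,
    total_body_mass = pars$total_body_mass,
    right_hindlimb_mass = pars$right_hindlimb_mass,
    pelvis_segment_mass = pars$total_body_mass - pars$right_hindlimb_mass,
    femur_length = pars$femur_length,
    segment_lengths = seg_len,
    segment_masses = seg_mass,
    pelvis_com_offset_anterior = pars$pelvis_com_offset_anterior,
    cross_sections = cross_sections,
    mtp_reserve_max = scale_reserve_actuator(1000, chicken_mass,
                                             pars$total_body_mass),
    muscle_roster = NULL
  ), class = "species_template")
  tpl$muscle_roster <- default_muscle_roster(tpl)
  tpl
}

#' @export
print.species_template <- function(x, ...) {
  cat("<species_template> ", x$name, "\n",
      "  total body mass:      ", x$total_body_mass, " kg\n",
      "  right hindlimb mass:  ", x$right_hindlimb_mass, " kg\n",
      "  pelvis segment mass:  ", x$pelvis_segment_mass, " kg\n",
      "  femur length:         ", x$femur_length, " m\n",
      "  muscles:              ", length(x$muscle_roster), " (",
      sum(vapply(x$muscle_roster, `[[`, TRUE, "active")), " active)\n",
      sep = "")
  invisible(x)
}

#' Isometric centre-of-mass scaling
#'
#' Rescales a reference anterior COM offset from a reference skeleton to a
#' target skeleton in proportion to femur length.
#'
#' @param ref_offset reference COM offset (m)
#' @param ref_femur reference femur length (m)
#' @param target_femur target femur length (m)
#' @return scaled offset in metres: `ref_offset * target_femur / ref_femur`
#' @export
#' @examples
#' scale_com_isometric(0.544, 1.265, 0.984)  # 0.423
scale_com_isometric <- function(ref_offset, ref_femur, target_femur) {
  if (ref_femur <= 0 || target_femur <= 0 || ref_offset <= 0)
    stop("lengths must be strictly positive")
  ref_offset * target_femur / ref_femur
}

#' Mass-proportional reserve-actuator scaling
#'
#' The metatarsophalangeal reserve actuator's ceiling scales linearly with
#' total body mass from a base model.
#'
#' @param base_moment base ceiling (N m)
#' @param base_mass base model body mass (kg)
#' @param target_mass target model body mass (kg)
#' @return scaled ceiling (N m)
#' @export
#' @examples
#' scale_reserve_actuator(1767308, 2757, 48.5)  # ~31090
scale_reserve_actuator <- function(base_moment, base_mass, target_mass) {
  if (base_mass <= 0 || target_mass <= 0)
    stop("masses must be strictly positive")
  base_moment * target_mass / base_mass
}

#' Maximum isometric muscle force
#'
#' Every active muscle gets the same force ceiling of two body weights.
#'
#' @param model a `model_spec` (or `species_template` plus `g`)
#' @param g gravitational acceleration, m/s^2
#' @return force in newtons
#' @export
max_muscle_force <- function(model, g = 9.81) {
  m <- if (inherits(model, "model_spec")) model$template$total_body_mass
       else model$total_body_mass
  if (inherits(model, "model_spec")) g <- model$g
  if (m <= 0) stop("total body mass must be positive")
  2 * m * g
}

# ---------------------------------------------------------------------------
# Muscle roster
# ---------------------------------------------------------------------------

# Activity mask for the fossil-scale templates (X = active, O = inactive).
MUSCLE_ACTIVITY <- c(
  IT1 = TRUE, IT2 = TRUE, IT3 = TRUE, AMB = TRUE, FMTE = TRUE, FMTI = TRUE,
  ILFB = TRUE, IFE = TRUE, ITC = TRUE, PIFI1 = TRUE, PIFI2 = TRUE,
  FTI1 = TRUE, FTI3 = TRUE, FTE = TRUE, ADD1 = TRUE, ADD2 = TRUE,
  PIFE1 = FALSE, PIFE2 = FALSE, PIFE3 = FALSE, ISTR = TRUE,
  CFL = TRUE, CFB = TRUE, GL = TRUE, GM = TRUE, FDL = TRUE, FDB = TRUE,
  FHL = TRUE, EDL = FALSE, EDB = FALSE, EHL = FALSE, TA = FALSE,
  FL = FALSE, FB = FALSE
)

#' Default muscle roster for a template
#'
#' Thirty-three musculotendon actuators with procedurally generated 3-D
#' paths (origin, optional via points, insertion) in segment-local frames,
#' scaled to the template.  Functional group tags: the iliofemoralis
#' externus is the hip abductor; the iliotrochantericus caudalis and
#' puboischiofemorales interni 1-2 are the hip medial (internal) long-axis
#' rotators at fossil scale, while at chicken scale the iliotrochanteric
#' group alone carries that role and the iliofemoralis externus is inactive.
#'
#' @param template a `species_template`
#' @return list of muscle specs (name, active, group, path)
#' @export
default_muscle_roster <- function(template) {
  Lf <- template$femur_length
  Ls <- template$segment_lengths
  rf <- template$cross_sections$femur$a_y
  rt <- template$cross_sections$tibiotarsus$a_y
  rm_ <- template$cross_sections$tarsometatarsus$a_y
  rp <- 0.5 * rm_  # pes half-depth

  chicken <- identical(template$name, "chicken-scale")

  # helper to build a path point: segment + local xyz in metres
  P <- function(seg, x, y, z) list(segment = seg, p = c(x, y, z))
  pel <- function(x, y, z) P("pelvis", x * Lf, y * Lf, z * Lf)
  fem <- function(f, y, z) P("femur", f * Ls[["femur"]], y, z)
  tib <- function(f, y, z) P("tibiotarsus", f * Ls[["tibiotarsus"]], y, z)
  tmt <- function(f, y, z) P("tarsometatarsus",
                             f * Ls[["tarsometatarsus"]], y, z)
  pes <- function(f, y, z) P("pes", f * Ls[["pes"]], y, z)

  # shared via points
  knee_ant  <- fem(0.98, 0, 2.4 * rf)     # over the patellar region
  knee_post <- fem(0.95, 0, -1.8 * rf)
  ankle_post <- tib(1.00, 0, -2.8 * rt)   # hypotarsus / tuber calcanei
  ankle_ant  <- tib(0.98, 0, 1.6 * rt)
  mtp_post <- tmt(0.98, 0, -1.8 * rm_)
  mtp_ant  <- tmt(0.98, 0, 1.8 * rm_)

  M <- function(name, group, ...) {
    list(name = name, active = unname(MUSCLE_ACTIVITY[[name]]),
         group = group, path = list(...))
  }

  roster <- list(
    M("IT1", "other", pel(0.35, 0.05, 0.30), knee_ant, tib(0.07, 0, 1.2 * rt)),
    M("IT2", "other", pel(0.00, 0.05, 0.40), knee_ant, tib(0.07, 0, 1.2 * rt)),
    M("IT3", "other", pel(-0.35, 0.05, 0.30), knee_ant, tib(0.07, 0, 1.2 * rt)),
    M("AMB", "other", pel(0.30, 0.02, -0.15), knee_ant, tib(0.07, 0, 1.2 * rt)),
    M("FMTE", "other", fem(0.35, -rf, 0.2 * rf), knee_ant,
      tib(0.07, 0, 1.2 * rt)),
    M("FMTI", "other", fem(0.35, 0.7 * rf, 0.7 * rf), knee_ant,
      tib(0.07, 0, 1.2 * rt)),
    M("ILFB", "other", pel(-0.40, 0.04, 0.25), fem(0.95, -0.5 * rf, -1.2 * rf),
      tib(0.12, -rt, -0.3 * rt)),
    M("IFE", "hip_abductor", pel(0.02, -0.22, 0.28),
      fem(0.25, -1.5 * rf, 0)),
    M("ITC", "hip_medial_rotator", pel(0.08, -0.15, 0.20),
      fem(0.08, -1.1 * rf, 1.2 * rf)),
    M("PIFI1", if (chicken) "other" else "hip_medial_rotator",
      pel(0.20, 0.02, 0.10), fem(0.12, 0.6 * rf, 0.8 * rf)),
    M("PIFI2", if (chicken) "other" else "hip_medial_rotator",
      pel(0.22, -0.06, 0.15), fem(0.16, -0.6 * rf, 1.2 * rf)),
    M("FTI1", "other", pel(-0.30, 0.02, -0.35),
      fem(0.95, 0.5 * rf, -1.1 * rf), tib(0.06, rt, -0.3 * rt)),
    M("FTI3", "other", pel(-0.25, 0.02, -0.25),
      fem(0.95, 0.5 * rf, -1.1 * rf), tib(0.06, rt, -0.3 * rt)),
    M("FTE", "other", pel(-0.40, 0.04, 0.22),
      fem(0.95, 0.3 * rf, -1.1 * rf), tib(0.06, rt, -0.3 * rt)),
    M("ADD1", "other", pel(-0.15, 0.02, -0.30),
      fem(0.70, 0.6 * rf, -0.8 * rf)),
    M("ADD2", "other", pel(-0.30, 0.02, -0.20),
      fem(0.70, -0.3 * rf, -1.0 * rf)),
    M("PIFE1", "other", pel(0.30, 0.02, -0.35), fem(0.06, -0.9 * rf, 0.3 * rf)),
    M("PIFE2", "other", pel(0.25, 0.02, -0.40), fem(0.06, -0.9 * rf, 0.3 * rf)),
    M("PIFE3", "other", pel(-0.20, 0.02, -0.35),
      fem(0.06, -0.9 * rf, 0.3 * rf)),
    M("ISTR", "other", pel(-0.25, 0.04, -0.10), fem(0.08, -1.0 * rf,
                                                    -0.5 * rf)),
    M("CFL", "other", pel(-0.65, 0.03, -0.05), fem(0.35, 0.8 * rf,
                                                   -0.8 * rf)),
    M("CFB", "other", pel(-0.50, 0.03, 0.10), fem(0.35, -0.3 * rf, -rf)),
    M("GL", "other", fem(0.92, -0.6 * rf, -1.0 * rf), ankle_post,
      tmt(0.15, 0, -1.1 * rm_)),
    M("GM", "other", tib(0.06, rt, -0.5 * rt), ankle_post,
      tmt(0.15, 0, -1.1 * rm_)),
    M("FDL", "other", fem(0.92, 0, -1.1 * rf), ankle_post, mtp_post,
      pes(0.40, 0, -0.8 * rp)),
    M("FDB", "other", tmt(0.10, 0, -1.0 * rm_), mtp_post,
      pes(0.40, 0, -0.8 * rp)),
    M("FHL", "other", fem(0.85, 0, -1.05 * rf), ankle_post, mtp_post,
      pes(0.25, 0.3 * rp, -0.8 * rp)),
    M("EDL", "other", fem(0.95, -0.3 * rf, 1.1 * rf), ankle_ant, mtp_ant,
      pes(0.40, 0, 0.8 * rp)),
    M("EDB", "other", tmt(0.10, 0, 1.0 * rm_), mtp_ant,
      pes(0.40, 0, 0.8 * rp)),
    M("EHL", "other", tib(0.85, -rt, 0.2 * rt), mtp_ant,
      pes(0.30, 0.5 * rp, 0.6 * rp)),
    M("TA", "other", tib(0.10, 0, 1.1 * rt), ankle_ant,
      tmt(0.10, 0, 1.1 * rm_)),
    M("FL", "other", tib(0.30, -rt, 0.5 * rt), tib(0.97, -rt, -0.5 * rt),
      tmt(0.10, -0.8 * rm_, -0.8 * rm_)),
    M("FB", "other", tib(0.60, -rt, 0.2 * rt), tib(0.97, -rt, -0.5 * rt),
      tmt(0.10, -0.8 * rm_, 0.6 * rm_))
  )

  if (chicken) {
    for (i in seq_along(roster))
      if (roster[[i]]$name == "IFE") roster[[i]]$active <- FALSE
  }
  names(roster) <- vapply(roster, `[[`, "", "name")
  roster
}
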