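# Shared lazily-built fixtures.  Everything is generated in code; the
# heavier objects (templates, zero-noise fabric fields) are cached per
# test run.

.fix <- new.env(parent = emptyenv())

fx_template <- function(name = "troodontid-scale") {
  key <- paste0("tpl_", name)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_species_template(name)
  .fix[[key]]
}

fx_model <- function(name = "troodontid-scale") {
  key <- paste0("mod_", name)
  if (is.null(.fix[[key]])) .fix[[key]] <- model_spec(fx_template(name))
  .fix[[key]]
}

# zero-noise fabric generated at the template's reference posture
fx_fabric_exact <- function(name = "troodontid-scale") {
  key <- paste0("fab_", name)
  if (is.null(.fix[[key]])) {
    sc <- fabric_scenario(reference_posture(name),
                          axial_concentration = Inf, rng_seed = 42)
    .fix[[key]] <- generate_fabric_field(fx_template(name), sc,
                                         fx_model(name))
  }
  .fix[[key]]
}

fx_solution <- function(name = "troodontid-scale",
                        pose = reference_posture(name)) {
  m <- fx_model(name)
  static_optimization(m, inverse_static_moments(m, pose), pose)
}

# an activation_solution with every muscle silent (for pure-GRF loading)
fx_zero_solution <- function(model) {
  a <- stats::setNames(rep(0, length(model$muscles)), names(model$muscles))
  structure(list(activations = a, reserve_moment = 0,
                 residuals = stats::setNames(rep(0, 6), trabpose:::DOF_NAMES),
                 moment_arms = NULL),
            class = "activation_solution")
}

# model variant with massless limb segments
fx_massless <- function(name = "troodontid-scale") {
  m <- fx_model(name)
  m$template$segment_masses[] <- 0
  m
}

# uniformly scaled copy of a template: lengths x s, masses x s^3
fx_scaled_template <- function(tpl, s) {
  sc <- tpl
  sc$total_body_mass <- tpl$total_body_mass * s^3
  sc$right_hindlimb_mass <- tpl$right_hindlimb_mass * s^3
  sc$pelvis_segment_mass <- sc$total_body_mass - sc$right_hindlimb_mass
  sc$femur_length <- tpl$femur_length * s
  sc$segment_lengths <- tpl$segment_lengths * s
  sc$segment_masses <- tpl$segment_masses * s^3
  sc$pelvis_com_offset_anterior <- tpl$pelvis_com_offset_anterior * s
  sc$cross_sections <- lapply(tpl$cross_sections, function(cs)
    cross_section(cs$a_y * s, cs$a_z * s, cs$wall_fraction))
  sc$mtp_reserve_max <- tpl$mtp_reserve_max * s^4
  sc$muscle_roster <- default_muscle_roster(sc)
  sc
}
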