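# Synthetic cancellous-bone fabric fields with known ground truth.
#
# Idealized bone volumes are capsules (a cylinder along the bone long
# axis with hemispherical epiphyseal caps).  A regular lattice fills each
# capsule; at every lattice point a unit fabric axis is drawn from a
# Watson (bipolar axial) distribution whose modal axis is the principal
# stress axis of the forward model at a hidden "true" posture: the
# compressive (sigma_3) axis in compressive regions, the tensile
# (sigma_1) axis within tensile-mode regions of interest.  kappa = Inf is
# the zero-dispersion sentinel.  All coordinates and axes are bone-local
# (material frame), so the field is a property of the bone, not of any
# one posture.

#' Spherical region of interest
#'
#' @param label anatomical name (unique within a model)
#' @param bone bone carrying the ROI
#' @param centre bone-local centre, length-3 (m)
#' @param radius sphere radius (m)
#' @param mode `"compressive"` (compare the sigma_3 axis) or `"tensile"`
#'   (compare sigma_1)
#' @return a `spherical_roi`
#' @export
spherical_roi <- function(label, bone, centre, radius,
                          mode = c("compressive", "tensile")) {
  mode <- match.arg(mode)
  stopifnot(radius > 0, length(centre) == 3)
  structure(list(label = label, bone = bone, centre = as.numeric(centre),
                 radius = radius, mode = mode), class = "spherical_roi")
}

#' Default anatomical ROI set for a template
#'
#' Spheres at the femoral head, lesser trochanter (tensile), medial
#' femoral condyle, femoral mid-shaft, and the proximal/distal ends of
#' the tibiotarsus and tarsometatarsus.  Radii default to 20% of the
#' epiphysis width (anatomical scaling).
#'
#' @param template a `species_template`
#' @return list of [spherical_roi()]
#' @export
default_rois <- function(template) {
  Ls <- template$segment_lengths
  ep <- function(b) epiphysis_radius(template, b)
  # 20% of epiphysis width; the slender tarsometatarsus gets a relatively
  # larger sphere so enough lattice points fall inside at default spacing
  rr <- function(b) (if (b == "tarsometatarsus") 0.55 else 0.4) * ep(b)
  ef <- ep("femur"); et <- ep("tibiotarsus"); em <- ep("tarsometatarsus")
  list(
    spherical_roi("femoral_head", "femur",
                  c(-0.2 * ef, 0.5 * ef, 0), rr("femur"), "compressive"),
    spherical_roi("lesser_trochanter", "femur",
                  c(0.45 * ef, -0.5 * ef, 0.4 * ef), rr("femur"), "tensile"),
    spherical_roi("medial_femoral_condyle", "femur",
                  c(Ls[["femur"]] - 0.3 * ef, 0.5 * ef, -0.3 * ef),
                  rr("femur"), "compressive"),
    spherical_roi("femoral_midshaft", "femur",
                  c(0.5 * Ls[["femur"]], 0.4 * ef, 0), rr("femur"),
                  "compressive"),
    spherical_roi("proximal_tibia", "tibiotarsus",
                  c(-0.2 * et, 0.4 * et, 0), rr("tibiotarsus"),
                  "compressive"),
    spherical_roi("distal_tibiotarsus", "tibiotarsus",
                  c(Ls[["tibiotarsus"]] + 0.2 * et, 0, 0),
                  rr("tibiotarsus"), "compressive"),
    spherical_roi("proximal_tarsometatarsus", "tarsometatarsus",
                  c(-0.1 * em, 0, 0), rr("tarsometatarsus"), "compressive"),
    spherical_roi("distal_tarsometatarsus", "tarsometatarsus",
                  c(Ls[["tarsometatarsus"]] + 0.1 * em, 0, 0),
                  rr("tarsometatarsus"), "compressive"),
    spherical_roi("proximal_pes", "pes",
                  c(-0.1 * epiphysis_radius(template, "pes"), 0, 0),
                  0.55 * epiphysis_radius(template, "pes"), "compressive")
  )
}

#' Fabric-generation scenario
#'
#' @param true_posture the hidden generating [posture()]
#' @param lattice_spacing lattice step (m); default 1/40 of femur length
#'   (resolved at generation time when `NULL`)
#' @param axial_concentration Watson concentration kappa (>= 0);
#'   `Inf` means zero dispersion
#' @param rois list of [spherical_roi()]; default anatomical set
#' @param rng_seed integer seed controlling all randomness
#' @return a `fabric_scenario`
#' @export
fabric_scenario <- function(true_posture, lattice_spacing = NULL,
                            axial_concentration = 50, rois = NULL,
                            rng_seed = 1L) {
  if (is.na(axial_concentration) || axial_concentration < 0)
    stop("axial concentration kappa must be >= 0 (Inf = no dispersion)")
  structure(list(true_posture = as_posture(true_posture),
                 lattice_spacing = lattice_spacing,
                 axial_concentration = axial_concentration,
                 rois = rois, rng_seed = as.integer(rng_seed)),
            class = "fabric_scenario")
}

#' Regular lattice filling the capsule volume of each bone
#'
#' @param template a `species_template`
#' @param spacing lattice step (m)
#' @param bones bones to cover
#' @return data.frame `bone`, `x`, `y`, `z` (bone-local, m)
#' @export
bone_lattice <- function(template, spacing,
                         bones = c("femur", "tibiotarsus",
                                   "tarsometatarsus", "pes")) {
  stopifnot(spacing > 0)
  out <- list()
  for (bone in bones) {
    L <- template$segment_lengths[[bone]]
    ep <- epiphysis_radius(template, bone)
    xs <- seq(-ep, L + ep, by = spacing)
    ys <- seq(-ep, ep, by = spacing)
    g <- expand.grid(x = xs, y = ys, z = ys)
    xc <- pmin(pmax(g$x, 0), L)
    keep <- (g$x - xc)^2 + g$y^2 + g$z^2 <= ep^2
    g <- g[keep, , drop = FALSE]
    out[[bone]] <- data.frame(bone = bone, g)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample unit axes from a Watson (bipolar) axial distribution
#'
#' Density proportional to exp(kappa (mu . x)^2) on the unit sphere,
#' sampled by rejection from the uniform sphere.  `kappa = Inf` returns
#' the modal axes exactly.
#'
#' @param mu n x 3 matrix of modal unit axes (or a single axis)
#' @param kappa concentration (>= 0)
#' @return n x 3 matrix of unit axes
#' @export
rwatson_axes <- function(mu, kappa) {
  if (is.null(dim(mu))) mu <- matrix(mu, 1)
  n <- nrow(mu)
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.infinite(kappa)) return(mu)
  out <- matrix(NA_real_, n, 3)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    m <- length(todo)
    z <- matrix(stats::rnorm(3 * m), m, 3)
    z <- z / sqrt(rowSums(z^2))
    c2 <- rowSums(z * mu[todo, , drop = FALSE])^2
    acc <- stats::runif(m) < exp(kappa * (c2 - 1))
    out[todo[acc], ] <- z[acc, , drop = FALSE]
    todo <- todo[!acc]
  }
  out
}

#' Generate a synthetic fabric field
#'
#' Runs the forward model (inverse statics, static optimization, stress
#' trajectories) at the scenario's true posture and draws Watson axes
#' about the resulting stress axes at every lattice point: the sigma_3
#' axis everywhere except inside tensile-mode ROIs, where the sigma_1
#' axis is the modal axis.  Deterministic given `rng_seed`.
#'
#' @param template a `species_template`
#' @param scenario a [fabric_scenario()]
#' @param model optional prebuilt `model_spec` (defaults to
#'   `model_spec(template)`)
#' @return a `fabric_field`: data.frame `bone, x, y, z, ux, uy, uz, roi`
#'   with attributes `scenario` and `n_skipped`
#' @export
generate_fabric_field <- function(template, scenario, model = NULL) {
  if (is.null(model)) model <- model_spec(template)
  spacing <- scenario$lattice_spacing %||% (template$femur_length / 40)
  rois <- scenario$rois %||% default_rois(template)
  lat <- bone_lattice(template, spacing)

  # every ROI sphere must be inside some bone capsule the lattice covers
  for (roi in rois) {
    L <- template$segment_lengths[[roi$bone]]
    ep <- epiphysis_radius(template, roi$bone)
    ctr <- roi$centre
    xc <- pmin(pmax(ctr[1], 0), L)
    d_ctr <- sqrt((ctr[1] - xc)^2 + ctr[2]^2 + ctr[3]^2)
    if (d_ctr + roi$radius > ep + spacing)
      stop("lattice/ROI mismatch: ROI '", roi$label,
           "' is not contained in the ", roi$bone, " capsule")
  }

  pose <- scenario$true_posture
  M <- inverse_static_moments(model, pose)
  sol <- static_optimization(model, M, pose)
  fld <- stress_trajectory_field(model, pose, sol, lat)

  fld$roi <- ""
  tensile <- rep(FALSE, nrow(fld))
  for (roi in rois) {
    sel <- fld$bone == roi$bone &
      (fld$x - roi$centre[1])^2 + (fld$y - roi$centre[2])^2 +
      (fld$z - roi$centre[3])^2 <= roi$radius^2
    fld$roi[sel] <- roi$label
    if (roi$mode == "tensile") tensile <- tensile | sel
  }
  modal <- as.matrix(fld[, c("s3x", "s3y", "s3z")])
  modal[tensile, ] <- as.matrix(fld[tensile, c("s1x", "s1y", "s1z")])

  seed_keep <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  set.seed(scenario$rng_seed)
  axes <- rwatson_axes(modal, scenario$axial_concentration)
  if (!is.null(seed_keep)) assign(".Random.seed", seed_keep, globalenv())

  out <- data.frame(bone = fld$bone, x = fld$x, y = fld$y, z = fld$z,
                    ux = axes[, 1], uy = axes[, 2], uz = axes[, 3],
                    roi = fld$roi)
  attr(out, "scenario") <- scenario
  attr(out, "n_skipped") <- attr(fld, "n_skipped")
  class(out) <- c("fabric_field", "data.frame")
  out
}
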