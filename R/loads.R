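# Internal bone loads and principal-stress trajectory fields.
#
# The continuum finite-element stage is replaced by a beam surrogate:
# internal force/moment resultants along each long bone come from
# free-body equilibrium of everything distal to the cut (ground reaction
# force, segment weights, and musculotendon forces applied where tendon
# path edges enter the free body), and cross-section stresses follow from
# hollow-ellipse beam theory.  Within the epiphyses, the compressive
# principal axis is taken as the direction of the joint resultant force
# transmitted through that epiphysis (a documented surrogate for the
# arching continuum trajectories), with the tensile axis orthogonal in
# the plane spanned by the resultant and the bone long axis.

BONE_CHAIN <- c("femur", "tibiotarsus", "tarsometatarsus", "pes")

#' Epiphysis (capsule) radius of a bone volume
#' @keywords internal
epiphysis_radius <- function(template, bone) {
  2.2 * template$cross_sections[[bone]]$a_y
}

# Build the external-load "items" for free-body analysis along `bone`.
# Each item is a point force with a station-activity window [t_lo, t_hi):
# it acts on the free body distal of station s iff t_lo <= s < t_hi.
# Membership coordinate t: +Inf for points on segments distal to the
# bone, -Inf for proximal segments/pelvis, and the local axial coordinate
# for points on the bone itself.
build_load_items <- function(model, fk, sol, loadcase, bone) {
  idx <- match(bone, BONE_CHAIN)
  if (is.na(idx)) stop("unknown bone '", bone, "'")
  tpl <- model$template
  memb <- function(segment, p_local) {
    j <- match(segment, BONE_CHAIN)
    if (is.na(j)) return(-Inf)           # pelvis
    if (j > idx) return(Inf)
    if (j < idx) return(-Inf)
    p_local[1]
  }
  pos <- list(); frc <- list(); tlo <- c(); thi <- c()
  add <- function(p, F, lo, hi) {
    if (hi <= lo) return()
    pos[[length(pos) + 1]] <<- p; frc[[length(frc) + 1]] <<- F
    tlo <<- c(tlo, lo); thi <<- c(thi, hi)
  }

  # gravity on chain segments at/below the bone
  for (seg in BONE_CHAIN) {
    j <- match(seg, BONE_CHAIN)
    if (j < idx) next
    t_com <- if (j == idx) model$com_fraction * tpl$segment_lengths[[seg]]
             else Inf
    add(fk$seg_com[seg, ], c(0, 0, -tpl$segment_masses[[seg]] * model$g),
        -Inf, t_com)
  }
  # ground reaction force at the centre of pressure (on the pes)
  add(cop_position(model, fk, loadcase), c(0, 0, loadcase$grf_magnitude),
      -Inf, Inf)

  # musculotendon forces: for every path edge with exactly one endpoint in
  # the free body, tension pulls the inside endpoint toward the outside one
  for (mu in model$muscles) {
    f <- sol$activations[[mu$name]] * model$fmax
    if (f <= 1e-9) next
    P <- muscle_path_global(model, fk, mu)
    tv <- vapply(seq_along(mu$path), function(k)
      memb(mu$path[[k]]$segment, mu$path[[k]]$p), 0)
    for (k in seq_len(nrow(P) - 1)) {
      u <- P[k + 1, ] - P[k, ]
      nu <- sqrt(sum(u^2)); if (nu < 1e-12) next
      u <- u / nu
      # endpoint k inside (t_k > s), endpoint k+1 outside (t_{k+1} <= s)
      add(P[k, ], f * u, tv[k + 1], tv[k])
      # endpoint k+1 inside, endpoint k outside
      add(P[k + 1, ], -f * u, tv[k], tv[k + 1])
    }
  }
  list(pos = do.call(rbind, pos), frc = do.call(rbind, frc),
       t_lo = tlo, t_hi = thi)
}

# Free-body resultants at stations s (vector) along `bone`.
# Returns the force and moment the proximal part exerts on the distal
# part, in global coordinates.
free_body_resultants <- function(items, origin, xhat, s) {
  act <- outer(s, items$t_lo, ">=") & outer(s, items$t_hi, "<")
  Fsum <- act %*% items$frc                       # n_s x 3
  C <- cbind(items$pos[, 2] * items$frc[, 3] - items$pos[, 3] * items$frc[, 2],
             items$pos[, 3] * items$frc[, 1] - items$pos[, 1] * items$frc[, 3],
             items$pos[, 1] * items$frc[, 2] - items$pos[, 2] * items$frc[, 1])
  Msum <- act %*% C                               # sum p_k x F_k
  ps <- outer(s, xhat) + matrix(origin, length(s), 3, byrow = TRUE)
  ps_x_F <- cbind(ps[, 2] * Fsum[, 3] - ps[, 3] * Fsum[, 2],
                  ps[, 3] * Fsum[, 1] - ps[, 1] * Fsum[, 3],
                  ps[, 1] * Fsum[, 2] - ps[, 2] * Fsum[, 1])
  list(R_force = -Fsum,                 # proximal-on-distal force
       M_int = -Msum + ps_x_F)          # proximal-on-distal moment about p_s
}

#' Internal loads along a bone
#'
#' Section resultants at evenly spaced stations: axial force `N` (tension
#' positive), bending moments `M_y`, `M_z` and torque `T` in the bone's
#' local frame (signs chosen so the values feed [section_stresses()]
#' directly), and transverse shear forces.
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @param sol an `activation_solution` for this posture
#' @param bone one of `"femur"`, `"tibiotarsus"`, `"tarsometatarsus"`
#' @param n_stations number of stations (>= 20)
#' @param loadcase a [load_case()]
#' @return data.frame with columns `station`, `N`, `M_y`, `M_z`, `T`,
#'   `V_y`, `V_z`
#' @export
internal_loads <- function(model, pose, sol, bone, n_stations = 21,
                           loadcase = load_case(model)) {
  if (!inherits(sol, "activation_solution"))
    stop("need a solved activation_solution")
  fk <- forward_kinematics(model, pose)
  items <- build_load_items(model, fk, sol, loadcase, bone)
  fr <- fk$frames[[bone]]
  L <- model$template$segment_lengths[[bone]]
  s <- seq(0, L, length.out = max(n_stations, 2))
  res <- free_body_resultants(items, fr$origin, as.vector(fr$R[, 1]), s)
  F_loc <- res$R_force %*% fr$R   # rows: global -> local components
  M_loc <- res$M_int %*% fr$R
  data.frame(station = s,
             N = -F_loc[, 1],
             M_y = -M_loc[, 2],
             M_z = -M_loc[, 3],
             T = M_loc[, 1],
             V_y = F_loc[, 2],
             V_z = F_loc[, 3])
}

#' Joint resultant forces
#'
#' Force transmitted across each joint (global frame), from free-body
#' closure of everything distal to the joint.
#'
#' @inheritParams internal_loads
#' @return list of 3-vectors: `hip`, `knee`, `ankle`, `mtp`
#' @export
joint_resultants <- function(model, pose, sol, loadcase = load_case(model)) {
  fk <- forward_kinematics(model, pose)
  out <- list()
  jn <- c(femur = "hip", tibiotarsus = "knee", tarsometatarsus = "ankle",
          pes = "mtp")
  for (bone in BONE_CHAIN) {
    items <- build_load_items(model, fk, sol, loadcase, bone)
    fr <- fk$frames[[bone]]
    res <- free_body_resultants(items, fr$origin, as.vector(fr$R[, 1]), 0)
    out[[jn[[bone]]]] <- as.vector(res$R_force)
  }
  out
}

#' Principal stress axes at bone-local lattice points
#'
#' At shaft points the beam stress tensor (axial normal stress plus
#' torsional shear at that radius; transverse shear neglected) is
#' diagonalized in closed form; within an epiphysis (inside the capsule
#' cap at either bone end) the compressive axis is the joint-resultant
#' direction and the tensile axis is orthogonal to it in the plane it
#' spans with the bone long axis.  All coordinates and axes are in the
#' bone's local (material) frame, so the result is directly comparable
#' with a fabric field.
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @param sol an `activation_solution`
#' @param points data.frame with columns `bone`, `x`, `y`, `z`
#'   (bone-local metres)
#' @param loadcase a [load_case()]
#' @return `points` with added unit-axis columns `s3x,s3y,s3z` and
#'   `s1x,s1y,s1z`; points outside the bone volume are dropped (count
#'   reported via attribute `n_skipped`)
#' @export
stress_trajectory_field <- function(model, pose, sol, points,
                                    loadcase = load_case(model)) {
  fk <- forward_kinematics(model, pose)
  tpl <- model$template
  jres <- joint_resultants(model, pose, sol, loadcase)
  prox_joint <- c(femur = "hip", tibiotarsus = "knee",
                  tarsometatarsus = "ankle", pes = "mtp")
  dist_joint <- c(femur = "knee", tibiotarsus = "ankle",
                  tarsometatarsus = "mtp", pes = "grf")
  out <- list(); skipped <- 0L
  for (bone in intersect(unique(points$bone), names(prox_joint))) {
    pb <- points[points$bone == bone, , drop = FALSE]
    L <- tpl$segment_lengths[[bone]]
    ep <- epiphysis_radius(tpl, bone)
    # inside capsule? (cylinder radius ep over [0, L] + hemispherical caps)
    r2 <- pb$y^2 + pb$z^2
    xc <- pmin(pmax(pb$x, 0), L)
    inside <- (pb$x - xc)^2 + r2 <= ep^2 + 1e-12
    skipped <- skipped + sum(!inside)
    pb <- pb[inside, , drop = FALSE]
    if (nrow(pb) == 0) next
    fr <- fk$frames[[bone]]
    sec <- tpl$cross_sections[[bone]]
    is_ep <- pb$x < ep | pb$x > L - ep

    u3 <- matrix(NA_real_, nrow(pb), 3)
    u1 <- matrix(NA_real_, nrow(pb), 3)

    if (any(!is_ep)) {
      sh <- pb[!is_ep, , drop = FALSE]
      items <- build_load_items(model, fk, sol, loadcase, bone)
      res <- free_body_resultants(items, fr$origin, as.vector(fr$R[, 1]),
                                  sh$x)
      F_loc <- res$R_force %*% fr$R
      M_loc <- res$M_int %*% fr$R
      N <- -F_loc[, 1]
      sig <- N / sec$A - M_loc[, 2] * sh$z / sec$I_y +
        M_loc[, 3] * sh$y / sec$I_z
      r <- sqrt(sh$y^2 + sh$z^2)
      tau_mag <- abs(M_loc[, 1]) * r / sec$J
      # shear vector on the +x face: q = -(T/J) (xhat x r)
      qy <- (M_loc[, 1] / sec$J) * sh$z
      qz <- -(M_loc[, 1] / sec$J) * sh$y
      qn <- sqrt(qy^2 + qz^2)
      e2y <- ifelse(qn > 1e-12, qy / qn, 1)  # fallback direction, tau = 0
      e2z <- ifelse(qn > 1e-12, qz / qn, 0)
      thp <- 0.5 * atan2(2 * qn, sig)
      # v1 in the (long axis, shear) plane; v3 orthogonal in that plane
      u1[!is_ep, ] <- cbind(cos(thp), sin(thp) * e2y, sin(thp) * e2z)
      u3[!is_ep, ] <- cbind(-sin(thp), cos(thp) * e2y, cos(thp) * e2z)
    }
    if (any(is_ep)) {
      epp <- pb[is_ep, , drop = FALSE]
      prox <- epp$x < ep
      Rg <- fr$R
      for (side in c(TRUE, FALSE)) {
        sel <- if (side) prox else !prox
        if (!any(sel)) next
        jname <- if (side) prox_joint[[bone]] else dist_joint[[bone]]
        jr <- if (jname == "grf") c(0, 0, loadcase$grf_magnitude)
              else jres[[jname]]
        a3 <- as.vector(unit3(t(Rg) %*% jr))  # local frame, axial
        xh <- c(1, 0, 0)
        perp <- xh - sum(xh * a3) * a3
        a1 <- if (sqrt(sum(perp^2)) < 1e-8) {
          p2 <- c(0, 1, 0) - a3[2] * a3
          unit3(p2)
        } else unit3(perp)
        idxs <- which(is_ep)[sel]
        u3[idxs, ] <- matrix(a3, sum(sel), 3, byrow = TRUE)
        u1[idxs, ] <- matrix(a1, sum(sel), 3, byrow = TRUE)
      }
    }
    pb$s3x <- u3[, 1]; pb$s3y <- u3[, 2]; pb$s3z <- u3[, 3]
    pb$s1x <- u1[, 1]; pb$s1y <- u1[, 2]; pb$s1z <- u1[, 3]
    out[[bone]] <- pb
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}
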