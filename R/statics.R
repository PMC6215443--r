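# Inverse statics and static optimization.
#
# Generalized-coordinate formulation: the six actuated DOF angles are the
# generalized coordinates (radians internally).  Moment arms come from
# tendon excursion (r = -dL/dtheta) and required joint moments from
# virtual work of gravity and the ground reaction force, which guarantees
# sign consistency between the two sides of the equilibrium equations.

FD_STEP_RAD <- 1e-4  # central-difference step for kinematic derivatives

perturbed_posture <- function(pose, dof, delta_rad) {
  p <- unclass(as_posture(pose))
  p[[dof]] <- p[[dof]] + rad2deg(delta_rad)
  structure(p, class = "posture")
}

fk_noclip <- function(model, pose) forward_kinematics(model, pose)

#' Tendon-excursion moment arm
#'
#' Signed moment arm of a muscle about one DOF: r = -dL/dtheta by central
#' finite difference on musculotendon path length, theta in radians.
#' Positive r means the muscle produces a positive moment about the DOF's
#' positive rotation sense.
#'
#' @param model a `model_spec`
#' @param muscle muscle name (in `model$muscles`) or a muscle spec
#' @param dof one of the six DOF names
#' @param pose a [posture()]
#' @return moment arm in metres
#' @export
moment_arm <- function(model, muscle, dof, pose) {
  if (is.character(muscle)) muscle <- model$muscles[[muscle]]
  if (is.null(muscle)) stop("unknown muscle")
  if (!dof %in% DOF_NAMES) stop("unknown DOF '", dof, "'")
  if (length(muscle$path) < 2) stop("degenerate muscle path")
  h <- FD_STEP_RAD
  lp <- polyline_length(muscle_path_global(
    model, fk_noclip(model, perturbed_posture(pose, dof, h)), muscle))
  lm <- polyline_length(muscle_path_global(
    model, fk_noclip(model, perturbed_posture(pose, dof, -h)), muscle))
  if (lp == 0 && lm == 0) stop("degenerate (zero-length) muscle path")
  -(lp - lm) / (2 * h)
}

#' Moment-arm matrix for all muscles and DOFs
#' @return muscles x DOFs matrix (metres)
#' @keywords internal
moment_arm_matrix <- function(model, pose) {
  h <- FD_STEP_RAD
  lens <- function(p) {
    fk <- fk_noclip(model, p)
    vapply(model$muscles, function(mu)
      polyline_length(muscle_path_global(model, fk, mu)), 0)
  }
  R <- matrix(0, length(model$muscles), length(DOF_NAMES),
              dimnames = list(names(model$muscles), DOF_NAMES))
  for (d in DOF_NAMES) {
    lp <- lens(perturbed_posture(pose, d, h))
    lm <- lens(perturbed_posture(pose, d, -h))
    R[, d] <- -(lp - lm) / (2 * h)
  }
  R
}

#' Required joint moments for quasi-static stance
#'
#' Net moments (N m) that muscles plus the metatarsophalangeal reserve
#' must supply at each actuated DOF so that the limb is in static
#' equilibrium under the ground reaction force at the centre of pressure
#' and the segment weights.  Computed as minus the generalized force of
#' the external loads, by central finite differences of the virtual work.
#'
#' @param model a `model_spec`
#' @param pose a [posture()]
#' @param loadcase a [load_case()]; defaults to one body weight
#' @return named numeric vector over the six DOFs
#' @export
inverse_static_moments <- function(model, pose, loadcase = load_case(model)) {
  fk0 <- forward_kinematics(model, pose)
  if (!fk0$feasible) stop("infeasible posture: joint below ground plane")
  h <- FD_STEP_RAD
  grf <- c(0, 0, loadcase$grf_magnitude)
  m_seg <- model$template$segment_masses
  gvec <- c(0, 0, -model$g)

  work <- function(p) {
    fk <- fk_noclip(model, p)
    # virtual work potential: gravity on limb segments + GRF at the COP.
    # The pelvis is fixed so its weight does no work.  Positions are taken
    # in the hip-fixed frame (subtract the ground shift, which is itself
    # posture-dependent and must not enter the virtual displacement).
    ref <- fk$joints$hip  # hip is fixed in the hip frame
    w <- 0
    for (s in rownames(fk$seg_com))
      w <- w + m_seg[[s]] * sum(gvec * (fk$seg_com[s, ] - ref))
    w + sum(grf * (cop_position(model, fk, loadcase) - ref))
  }
  M <- vapply(DOF_NAMES, function(d) {
    wp <- work(perturbed_posture(pose, d, h))
    wm <- work(perturbed_posture(pose, d, -h))
    -(wp - wm) / (2 * h)
  }, 0)
  names(M) <- DOF_NAMES
  M
}

#' Static optimization of muscle activations
#'
#' Solves min sum(a_i^2) (+ a vanishing regularizer on the normalized
#' reserve moment) subject to moment balance at every actuated DOF,
#' 0 <= a_i <= 1 for active muscles, a_i = 0 for inactive muscles, and
#' |reserve| <= the model's metatarsophalangeal reserve ceiling.
#'
#' @param model a `model_spec`
#' @param required_moments named vector over DOFs (N m), e.g. from
#'   [inverse_static_moments()]
#' @param pose posture at which moment arms are evaluated (needed unless
#'   `arm_matrix` is supplied)
#' @param arm_matrix optional precomputed [moment_arm_matrix()]
#' @param tol equilibrium tolerance (N m)
#' @return an `activation_solution`: `activations` (named, in [0,1]),
#'   `reserve_moment` (N m), `residuals` (N m per DOF), `moment_arms`
#' @export
static_optimization <- function(model, required_moments, pose = NULL,
                                arm_matrix = NULL, tol = NULL) {
  if (is.null(arm_matrix)) {
    if (is.null(pose)) stop("need pose or arm_matrix")
    arm_matrix <- moment_arm_matrix(model, pose)
  }
  if (any(!is.finite(required_moments))) stop("non-finite required moments")
  act <- vapply(model$muscles, `[[`, TRUE, "active")
  fmax <- model$fmax
  rmax <- model$mtp_reserve_max

  # The reserve actuator carries no effective cost and enters only the
  # metatarsophalangeal row, so that row never constrains the muscles:
  # solve the activation QP over the remaining DOFs and let the reserve
  # absorb whatever metatarsophalangeal moment is left.
  E_full <- t(arm_matrix[act, , drop = FALSE]) * fmax  # DOFs x muscles
  mtp_row <- which(DOF_NAMES == "mtp_angle")
  E <- E_full[-mtp_row, , drop = FALSE]
  d_full <- required_moments[DOF_NAMES]
  d <- d_full[-mtp_row]
  n <- ncol(E)

  sol <- qp_min_weighted_norm(E, d, rep(0, n), rep(1, n), rep(1, n))
  if (is.null(tol)) tol <- 1e-6 * max(1, sum(abs(d_full)))
  if (!sol$converged && max(abs(sol$residuals)) > tol) {
    bad <- DOF_NAMES[-mtp_row][which.max(abs(sol$residuals))]
    stop("static optimization infeasible; worst DOF: ", bad,
         " (residual ", signif(max(abs(sol$residuals)), 4), " N m)")
  }
  a <- stats::setNames(rep(0, length(model$muscles)), names(model$muscles))
  a[names(which(act))] <- sol$x
  reserve <- d_full[[mtp_row]] - sum(E_full[mtp_row, ] * sol$x)
  if (abs(reserve) > rmax)
    stop("static optimization infeasible; worst DOF: mtp_angle ",
         "(reserve demand ", signif(reserve, 4), " N m exceeds ceiling ",
         signif(rmax, 4), " N m)")
  res <- stats::setNames(rep(0, length(DOF_NAMES)), DOF_NAMES)
  res[DOF_NAMES[-mtp_row]] <- as.vector(E %*% sol$x) - d
  structure(list(activations = a, reserve_moment = reserve,
                 residuals = res,
                 moment_arms = arm_matrix, objective = sum(sol$x^2),
                 required_moments = d_full),
            class = "activation_solution")
}

#' @export
print.activation_solution <- function(x, ...) {
  nz <- x$activations[x$activations > 1e-6]
  cat("<activation_solution> ", length(nz), " muscles recruited; reserve ",
      signif(x$reserve_moment, 4), " N m; max |residual| ",
      signif(max(abs(x$residuals)), 3), " N m\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Weighted min-norm QP with equality constraints and box bounds:
#   min sum(w_i x_i^2)  s.t.  E x = d,  l <= x <= u
# Active-set projection: bound-clamped variables are fixed, free variables
# take the weighted least-norm solution of the remaining equality system;
# KKT multipliers decide releases.  Small dense problems only.
# ---------------------------------------------------------------------------
qp_min_weighted_norm <- function(E, d, lower, upper, w,
                                 max_iter = 400, tol = 1e-9) {
  n <- ncol(E); m <- nrow(E)
  scale_d <- max(1, max(abs(d)))
  x <- rep(0, n)
  at_lo <- rep(FALSE, n); at_hi <- rep(FALSE, n)

  solve_free <- function(free, xb) {
    rhs <- d - if (any(!free)) E[, !free, drop = FALSE] %*% xb[!free] else 0
    Ef <- E[, free, drop = FALSE]
    Wi <- 1 / w[free]
    # min sum w x^2 s.t. Ef x = rhs  ->  x = Wi Ef' lam, (Ef Wi Ef') lam = rhs
    G <- Ef %*% (Wi * t(Ef))
    sv <- svd(G)
    pos <- sv$d > max(sv$d[1], 1e-300) * 1e-12
    lam <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    list(x = as.vector(Wi * (t(Ef) %*% lam)), lam = as.vector(lam))
  }

  for (it in seq_len(max_iter)) {
    free <- !(at_lo | at_hi)
    xb <- ifelse(at_lo, lower, ifelse(at_hi, upper, 0))
    if (!any(free)) {
      x <- xb
    } else {
      sf <- solve_free(free, xb)
      x <- xb
      x[free] <- sf$x
    }
    resid <- as.vector(E %*% x) - d

    viol_lo <- free & (x < lower - 1e-12)
    viol_hi <- free & (x > upper + 1e-12)
    if (any(viol_lo) || any(viol_hi)) {
      # clamp the single worst violator and re-solve
      excess <- pmax(lower - x, 0) + pmax(x - upper, 0)
      i <- which.max(excess)
      if (x[i] < lower[i]) at_lo[i] <- TRUE else at_hi[i] <- TRUE
      next
    }
    # KKT release check for bound variables: stationarity 2 w x = E' lambda
    # holds on the free set; estimate lambda by least squares and inspect
    # the reduced gradient at the bounds
    if (any(at_lo | at_hi)) {
      lam <- rep(0, m)
      if (any(free)) {
        Ef <- E[, free, drop = FALSE]
        co <- tryCatch(stats::lm.fit(t(Ef), 2 * w[free] * x[free])$coefficients,
                       error = function(e) rep(0, m))
        co[is.na(co)] <- 0
        lam <- co
      }
      g <- 2 * w * x - as.vector(t(E) %*% lam)
      rel_lo <- at_lo & (g < -1e-9)   # wants to increase from lower bound
      rel_hi <- at_hi & (g > 1e-9)    # wants to decrease from upper bound
      if (any(rel_lo) || any(rel_hi)) {
        i <- which.max(pmax(ifelse(rel_lo, -g, -Inf),
                            ifelse(rel_hi, g, -Inf)))
        at_lo[i] <- FALSE; at_hi[i] <- FALSE
        next
      }
    }
    converged <- max(abs(resid)) <= max(tol * scale_d, 1e-9)
    return(list(x = x, residuals = resid, converged = converged,
                iterations = it))
  }
  x <- pmin(pmax(x, lower), upper)  # never return a bound-violating point
  list(x = x, residuals = as.vector(E %*% x) - d, converged = FALSE,
       iterations = max_iter)
}
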