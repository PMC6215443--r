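# Idealized hollow-ellipse cross-sections and section-level stress
# calculations.  These stand in for the continuum finite-element stage:
# what downstream comparisons consume are principal stress *directions*
# and mid-shaft loading metrics, which beam theory provides directly.

#' Hollow-ellipse cross-section
#'
#' Section local axes: y mediolateral (semi-axis `a_y`), z anteroposterior
#' (semi-axis `a_z`); the bone long axis is x.  The inner void is a
#' concentric ellipse with both semi-axes reduced by `wall_fraction`
#' (cortical thickness as a fraction of the outer semi-axis).
#'
#' @param a_y,a_z outer semi-axes (m)
#' @param wall_fraction cortical wall thickness / outer semi-axis, in (0, 1]
#' @return a `cross_section` with derived area `A` (m^2), second moments
#'   `I_y`, `I_z` (m^4), polar moment `J` (m^4) and outer-fibre distance
#'   `c` (m)
#' @export
cross_section <- function(a_y, a_z, wall_fraction = 0.3) {
  stopifnot(a_y > 0, a_z > 0, wall_fraction > 0, wall_fraction <= 1)
  bi_y <- a_y * (1 - wall_fraction)
  bi_z <- a_z * (1 - wall_fraction)
  A <- pi * (a_y * a_z - bi_y * bi_z)
  # I_y: bending about the y (mediolateral) axis, stress varies with z
  I_y <- pi / 4 * (a_y * a_z^3 - bi_y * bi_z^3)
  I_z <- pi / 4 * (a_y^3 * a_z - bi_y^3 * bi_z)
  structure(list(a_y = a_y, a_z = a_z, wall_fraction = wall_fraction,
                 inner_y = bi_y, inner_z = bi_z,
                 A = A, I_y = I_y, I_z = I_z, J = I_y + I_z,
                 c = max(a_y, a_z)),
            class = "cross_section")
}

#' Stresses at a cross-section station
#'
#' Evaluates normal stress sigma = N/A + M_y z / I_y - M_z y / I_z on a
#' dense grid of outer-fibre points, torsional shear tau = T r / J at the
#' same points, and summarizes: maximum (tensile) and minimum (compressive)
#' normal stress, maximum shear, the bending-stress amplitude
#' (|sigma_max| + |sigma_min|) / 2 evaluated on the bending component alone
#' (zero under pure axial load), the folded principal-stress inclination
#' from the long axis, and the neutral-axis angle from the mediolateral
#' axis.  A planar (beam) stress state is assumed throughout.
#'
#' @param load list with `N` (axial force, tension positive, N), `M_y`,
#'   `M_z` (bending moments, N m), `T` (torque, N m); missing entries
#'   default to zero
#' @param section a [cross_section()]
#' @param n_theta number of outer-fibre sample points
#' @return a `stress_state` list: `sigma_max`, `sigma_min`, `tau_max`,
#'   `sigma_bending` (Pa), `theta_principal` (degrees, in [0, 45]),
#'   `neutral_axis_angle` (degrees from the mediolateral axis, NA when
#'   bending is absent), plus a `pure_axial` flag
#' @export
section_stresses <- function(load, section, n_theta = 72) {
  if (!inherits(section, "cross_section")) stop("need a cross_section")
  if (section$A <= 0) stop("zero-area section")
  N <- load$N %||% 0; M_y <- load$M_y %||% 0
  M_z <- load$M_z %||% 0; Tq <- load$T %||% 0

  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  y <- section$a_y * cos(th)
  z <- section$a_z * sin(th)
  sig_ax  <- N / section$A
  sig_bnd <- M_y * z / section$I_y - M_z * y / section$I_z
  sig <- sig_ax + sig_bnd
  tau <- abs(Tq) * sqrt(y^2 + z^2) / section$J

  smax <- max(sig); smin <- min(sig)
  bmax <- max(sig_bnd); bmin <- min(sig_bnd)
  pure_axial <- (abs(M_y) + abs(M_z)) == 0
  # bending amplitude: equals (|smax| + |smin|)/2 whenever the extreme
  # fibre stresses straddle zero (the planar-bending regime the formula
  # assumes); under axial-dominated load it reduces to the half-range of
  # the bending component, i.e. zero for pure axial load
  sigma_bending <- (bmax - bmin) / 2
  tau_max <- max(tau)

  i_max <- which.max(sig)
  theta_p <- principal_orientation(sig[i_max], tau[i_max])

  neutral_axis_angle <- NA_real_
  if (!pure_axial) {
    # neutral axis of the bending component: M_y z / I_y = M_z y / I_z
    # direction (y, z) with z/y = (M_z / I_z) / (M_y / I_y)
    ang <- atan2(M_z / section$I_z, M_y / section$I_y)
    # fold into [-90, 90] measured from the mediolateral (y) axis
    ang <- rad2deg(ang)
    if (ang > 90) ang <- ang - 180
    if (ang < -90) ang <- ang + 180
    neutral_axis_angle <- ang
  }

  structure(list(sigma_max = smax, sigma_min = smin, tau_max = tau_max,
                 sigma_bending = sigma_bending,
                 theta_principal = theta_p,
                 neutral_axis_angle = neutral_axis_angle,
                 pure_axial = pure_axial),
            class = "stress_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal-stress inclination from the bone long axis
#'
#' For a beam stress state (axial normal stress `sigma_axial` plus shear
#' `tau` on the transverse plane) the two principal axes lie at
#' theta = atan2(2 tau, sigma_axial) / 2 and theta + 90 degrees from the
#' long axis.  Each is folded into [0, 45] degrees and the mean of the two
#' folded inclinations is returned: 0 under pure bending (principal axes
#' parallel/perpendicular to the long axis), 45 under pure torsion.
#'
#' @param sigma_axial axial normal stress (Pa)
#' @param tau shear stress (Pa)
#' @return inclination in degrees, in [0, 45]; NA (with a warning) when
#'   both inputs are zero
#' @export
#' @examples
#' principal_orientation(1e6, 0)    # 0
#' principal_orientation(0, 1e6)    # 45
#' principal_orientation(10e6, 5e6) # 22.5
principal_orientation <- function(sigma_axial, tau) {
  if (sigma_axial == 0 && tau == 0) {
    warning("undefined principal orientation: sigma = tau = 0")
    return(NA_real_)
  }
  th1 <- rad2deg(0.5 * atan2(2 * tau, sigma_axial))
  fold <- function(th) {
    m <- abs(th) %% 90
    min(m, 90 - m)
  }
  mean(c(fold(th1), fold(th1 + 90)))
}

#' Shear-to-bending stress ratio at a section
#'
#' @param state a `stress_state` from [section_stresses()]
#' @return `tau_max / sigma_bending`; NA (with a warning) when the bending
#'   stress is zero (pure-torsion or pure-axial sentinel)
#' @export
shear_bending_ratio <- function(state) {
  if (state$sigma_bending <= 0) {
    warning("sigma_bending is zero; shear/bending ratio undefined")
    return(NA_real_)
  }
  state$tau_max / state$sigma_bending
}

#' Least-squares cylinder fit for a local long axis
#'
#' Fits a circular cylinder to a 3-D point cloud around the mid-shaft:
#' the cylinder axis defines the local long axis and the plane normal to
#' it the mid-shaft section plane.  Initialization is by principal
#' components; the axis direction, a point on the axis and the radius are
#' then refined by Gauss-Newton-style minimization of squared radial
#' residuals.
#'
#' @param points n x 3 matrix (n >= 6, non-collinear)
#' @return list with unit `axis`, `centre` (point on the axis), `radius`,
#'   and `plane_normal` (= axis)
#' @export
fit_local_long_axis <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stop("need at least 6 points for a cylinder fit")
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-12 * sv$d[1]) stop("degenerate (collinear) point set")
  axis0 <- sv$v[, 1]

  resid_vec <- function(par) {
    # par: theta, phi (axis direction), c1, c2 (axis offset in the plane
    # orthogonal to the axis), r
    a <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    e1 <- unit3(if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0))
                else cross3(a, c(0, 1, 0)))
    e2 <- cross3(a, e1)
    p0 <- ctr + par[3] * e1 + par[4] * e2
    Y <- sweep(points, 2, p0)
    along <- Y %*% a
    radial <- sqrt(pmax(rowSums(Y^2) - along^2, 0))
    radial - par[5]
  }
  th0 <- acos(min(max(axis0[3], -1), 1))
  ph0 <- atan2(axis0[2], axis0[1])
  r0 <- {
    e1 <- unit3(if (abs(axis0[1]) < 0.9) cross3(axis0, c(1, 0, 0))
                else cross3(axis0, c(0, 1, 0)))
    Y <- X
    along <- Y %*% axis0
    mean(sqrt(pmax(rowSums(Y^2) - along^2, 0)))
  }
  # damped Gauss-Newton on the radial residual vector (the scalar-objective
  # quasi-Newton route stalls well short of machine precision on exact data)
  par <- c(th0, ph0, 0, 0, r0)
  scale <- c(1, 1, r0, r0, r0)
  val <- sum(resid_vec(par)^2)
  lambda <- 1e-8
  for (it in 1:60) {
    r_cur <- resid_vec(par)
    J <- matrix(0, length(r_cur), 5)
    for (k in 1:5) {
      hstep <- 1e-6 * max(abs(par[k]), scale[k])
      pp <- par; pp[k] <- pp[k] + hstep
      pm <- par; pm[k] <- pm[k] - hstep
      J[, k] <- (resid_vec(pp) - resid_vec(pm)) / (2 * hstep)
    }
    G <- crossprod(J) + lambda * diag(5)
    step <- tryCatch(solve(G, crossprod(J, r_cur)), error = function(e) NULL)
    if (is.null(step)) break
    cand <- par - as.vector(step)
    v_new <- sum(resid_vec(cand)^2)
    if (v_new < val) {
      par <- cand
      if (val - v_new < 1e-18 * (1 + val)) { val <- v_new; break }
      val <- v_new
      lambda <- max(lambda / 10, 1e-12)
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  a <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
  if (sum(a * axis0) < 0) a <- -a
  e1 <- unit3(if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0))
              else cross3(a, c(0, 1, 0)))
  e2 <- cross3(a, e1)
  list(axis = unit3(a), centre = ctr + par[3] * e1 + par[4] * e2,
       radius = par[5], plane_normal = unit3(a))
}
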