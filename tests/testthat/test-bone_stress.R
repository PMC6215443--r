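test_that("hollow-ellipse section properties match numerical integration", {
  cs <- cross_section(a_y = 0.02, a_z = 0.015, wall_fraction = 0.3)
  # midpoint-rule integration over the annulus
  hgrid <- 4e-4
  ys <- seq(-0.02, 0.02, by = hgrid)
  zs <- seq(-0.015, 0.015, by = hgrid)
  g <- expand.grid(y = ys, z = zs)
  inside <- (g$y / cs$a_y)^2 + (g$z / cs$a_z)^2 <= 1 &
    (g$y / cs$inner_y)^2 + (g$z / cs$inner_z)^2 > 1
  dA <- hgrid^2
  expect_equal(cs$A, sum(inside) * dA, tolerance = 1e-3)
  expect_equal(cs$I_y, sum(g$z[inside]^2) * dA, tolerance = 1e-3)
  expect_equal(cs$I_z, sum(g$y[inside]^2) * dA, tolerance = 1e-3)
  expect_equal(cs$J, cs$I_y + cs$I_z)
  expect_equal(cs$c, 0.02)
  expect_error(cross_section(-1, 1), "a_y")
})

test_that("section stresses follow the bending-stress formula", {
  cs <- cross_section(0.02, 0.02, 0.3)
  # pure symmetric bending: sigma_bending equals the fibre stress S
  Mb <- 10
  S <- Mb * cs$c / cs$I_y
  st <- section_stresses(list(M_y = Mb), cs)
  expect_equal(st$sigma_max, S, tolerance = 1e-9)
  expect_equal(st$sigma_min, -S, tolerance = 1e-9)
  expect_equal(st$sigma_bending, S, tolerance = 1e-9)
  expect_equal(st$theta_principal, 0)
  expect_equal(st$neutral_axis_angle, 0, tolerance = 1e-9)

  # mixed extremes (|30| + |-50|)/2 = 40: bending amplitude with an axial
  # offset; construct N and M_y giving exactly those extreme stresses
  sig_ax <- (30e6 + (-50e6)) / 2
  sig_b <- (30e6 - (-50e6)) / 2
  st2 <- section_stresses(list(N = sig_ax * cs$A,
                               M_y = sig_b * cs$I_y / cs$c), cs)
  expect_equal(st2$sigma_max, 30e6, tolerance = 1e-6 * 50e6)
  expect_equal(st2$sigma_min, -50e6, tolerance = 1e-6 * 50e6)
  expect_equal((abs(st2$sigma_max) + abs(st2$sigma_min)) / 2, 40e6,
               tolerance = 1)
  expect_equal(st2$sigma_bending, 40e6, tolerance = 1)

  # pure axial load: no bending stress, neutral axis undefined
  st3 <- section_stresses(list(N = -1000), cs)
  expect_equal(st3$sigma_bending, 0)
  expect_true(st3$pure_axial)
  expect_true(is.na(st3$neutral_axis_angle))
})

test_that("principal orientation reproduces the Mohr-circle closed form", {
  expect_equal(principal_orientation(1e6, 0), 0)
  expect_equal(principal_orientation(0, 1e6), 45)
  expect_equal(principal_orientation(10e6, 5e6), 22.5)
  expect_warning(th <- principal_orientation(0, 0), "undefined")
  expect_true(is.na(th))
  set.seed(3)
  for (i in 1:50) {
    sig <- rnorm(1, sd = 1e7); tau <- abs(rnorm(1, sd = 1e7))
    th <- principal_orientation(sig, tau)
    expect_gte(th, 0); expect_lte(th, 45)
    # fold the analytic Mohr angle the same way
    th_m <- atan2(2 * tau, sig) / 2 * 180 / pi
    fold <- function(t) { mm <- abs(t) %% 90; min(mm, 90 - mm) }
    expect_equal(th, mean(c(fold(th_m), fold(th_m + 90))),
                 tolerance = 1e-9)
  }
})

test_that("shear-to-bending ratio behaves across regimes", {
  cs <- cross_section(0.02, 0.02, 0.3)
  st_b <- section_stresses(list(M_y = 10), cs)
  expect_equal(shear_bending_ratio(st_b), 0)
  st_m <- section_stresses(list(M_y = 10, T = 10), cs)
  # equal moment and torque on a circular section: tau_max/sigma_bending =
  # (T c / J) / (M c / I) = I / J = 1/2
  expect_equal(shear_bending_ratio(st_m), 0.5, tolerance = 1e-9)
  st_t <- section_stresses(list(T = 10), cs)
  expect_warning(r <- shear_bending_ratio(st_t), "undefined")
  expect_true(is.na(r))
})

test_that("cylinder fitting recovers the shaft axis", {
  set.seed(11)
  axis <- trabpose:::unit3(c(0.2, 0.1, 1))
  e1 <- trabpose:::unit3(trabpose:::cross3(axis, c(1, 0, 0)))
  e2 <- trabpose:::cross3(axis, e1)
  t <- runif(200, -0.05, 0.05); th <- runif(200, 0, 2 * pi)
  r0 <- 0.012
  pts <- t(vapply(seq_along(t), function(i)
    t[i] * axis + r0 * cos(th[i]) * e1 + r0 * sin(th[i]) * e2,
    numeric(3)))
  fit <- fit_local_long_axis(pts)
  expect_lt(acos(min(abs(sum(fit$axis * axis)), 1)), 1e-6)
  expect_equal(fit$radius, r0, tolerance = 1e-6)

  # 1% isotropic noise: axis within 1 degree
  ptsn <- pts + matrix(rnorm(600, sd = 0.01 * r0), ncol = 3)
  fitn <- fit_local_long_axis(ptsn)
  expect_lt(acos(min(abs(sum(fitn$axis * axis)), 1)) * 180 / pi, 1)

  # equivariance under rigid rotation
  R <- trabpose:::rot_axis(c(1, 2, 3), 0.7)
  fit_r <- fit_local_long_axis(pts %*% t(R))
  expect_lt(acos(min(abs(sum(fit_r$axis * as.vector(R %*% axis))), 1)),
            1e-5)

  expect_error(fit_local_long_axis(pts[1:4, ]), "at least 6")
})

test_that("internal loads reproduce column and cantilever closed forms", {
  m <- fx_massless("troodontid-scale")
  sol0 <- fx_zero_solution(m)
  P <- 500
  # column: columnar limb, COP at the metatarsophalangeal joint, so the
  # GRF line runs up the bone axes: N = -P everywhere, no moments
  lc <- load_case(m, grf_magnitude = P, cop_frac = 0)
  loads <- internal_loads(m, posture(90, 0, 0, 0, 0, 0), sol0, "femur",
                          n_stations = 21, loadcase = lc)
  expect_equal(nrow(loads), 21)
  expect_equal(loads$N, rep(-P, 21), tolerance = 1e-9)
  expect_lt(max(abs(c(loads$M_y, loads$M_z, loads$T))), 1e-8)

  # cantilever analogue: horizontal femur (hip extension 0), vertical limb
  # below the knee; the GRF is transverse to the femur, bending moment at
  # the hip = P x horizontal lever, zero moment at the knee end
  pose <- posture(0, 0, 0, 90, 0, 0)
  fk <- forward_kinematics(m, pose)
  loads2 <- internal_loads(m, pose, sol0, "femur", n_stations = 21,
                           loadcase = lc)
  lever <- trabpose:::cop_position(m, fk, lc)[1] - fk$joints$hip[1]
  bend <- sqrt(loads2$M_y^2 + loads2$M_z^2)
  expect_equal(bend[1], abs(P * lever), tolerance = 1e-6 * abs(P * lever))
  # moment declines linearly toward the load application end
  expect_true(all(diff(bend) < 1e-9))

  # load-state equilibrium: adjacent stations differ only through applied
  # loads; with none between stations the axial force is constant
  expect_lt(max(abs(diff(loads2$N))), 1e-9)
})

test_that("stress trajectory field invariants hold", {
  m <- fx_model()
  pose <- reference_posture(m$template$name)
  sol <- fx_solution()
  fab <- fx_fabric_exact()
  pts <- fab[fab$roi != "", c("bone", "x", "y", "z")]
  st <- stress_trajectory_field(m, pose, sol, pts)
  u1 <- as.matrix(st[, c("s1x", "s1y", "s1z")])
  u3 <- as.matrix(st[, c("s3x", "s3y", "s3z")])
  expect_lt(max(abs(rowSums(u1 * u3))), 1e-9)
  expect_equal(rowSums(u1^2), rep(1, nrow(st)), tolerance = 1e-9)
  expect_equal(rowSums(u3^2), rep(1, nrow(st)), tolerance = 1e-9)

  # epiphyseal compressive axes parallel the joint resultant by
  # construction: femoral head vs the hip resultant in the femur frame
  jr <- joint_resultants(m, pose, sol)
  fkR <- forward_kinematics(m, pose)$frames$femur$R
  hip_loc <- trabpose:::unit3(as.vector(t(fkR) %*% jr$hip))
  fh <- st[fab$roi[fab$roi != ""] == "femoral_head", ]
  dev <- apply(as.matrix(fh[, c("s3x", "s3y", "s3z")]), 1, function(u)
    angular_deviation(u, hip_loc))
  expect_lt(max(dev), 1e-6)

  # axial-only compression: columnar massless limb, GRF up the bone axis:
  # every shaft sigma_3 axis is the long axis
  mm <- fx_massless()
  loads_pose <- posture(90, 0, 0, 0, 0, 0)
  lc <- load_case(mm, grf_magnitude = 300, cop_frac = 0)
  Lf <- mm$template$segment_lengths[["femur"]]
  shaft_pts <- data.frame(bone = "femur", x = seq(0.3, 0.7, 0.1) * Lf,
                          y = 0.01, z = 0.005)
  st2 <- stress_trajectory_field(mm, loads_pose, fx_zero_solution(mm),
                                 shaft_pts, lc)
  expect_lt(max(abs(1 - abs(st2$s3x))), 1e-9)

  # continuity: a 0.1 degree perturbation moves the mid-shaft principal
  # inclination by less than a degree
  rec1 <- cross_species_record(m, pose, sol)
  pose2 <- posture(pose[["hip_extension"]] + 0.1, pose[["hip_abduction"]],
                   pose[["hip_lar"]], pose[["knee_flexion"]],
                   pose[["ankle_flexion"]], pose[["mtp_angle"]])
  rec2 <- cross_species_record(m, pose2)
  expect_lt(abs(rec1$theta_principal - rec2$theta_principal), 1)
})
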