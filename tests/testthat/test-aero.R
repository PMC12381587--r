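test_that("lift/drag coefficient polynomials at reference angles of attack", {
  cd0 <- lift_drag_coeffs(0)
  expect_equal(cd0$CL, 0)
  expect_equal(cd0$CD, 0)
  cd90 <- lift_drag_coeffs(90)
  expect_equal(cd90$CL, 0, tolerance = 1e-12)
  expect_equal(cd90$CD, 3.598, tolerance = 1e-12)
  s <- sin(pi / 4); c <- cos(pi / 4)
  cd45 <- lift_drag_coeffs(45)
  expect_equal(cd45$CL, 1.552 * s * c + 1.725 * s^2 * c, tolerance = 1e-12)
  expect_equal(cd45$CD, 0.0596 * s * c + 3.598 * s^3, tolerance = 1e-12)
  expect_equal(round(cd45$CL, 4), 1.3859)
  expect_equal(round(cd45$CD, 4), 1.3019)
  # scaling factors act linearly
  cdk <- lift_drag_coeffs(45, kL = 2, kD = 0.5)
  expect_equal(cdk$CL, 2 * cd45$CL)
  expect_equal(cdk$CD, 0.5 * cd45$CD)
  expect_error(lift_drag_coeffs(190), "0, 180")
})

test_that("rotational coefficient is pi (3/4 - e)", {
  expect_equal(rotational_coeff(0.75), 0)
  expect_equal(rotational_coeff(0.25), pi / 2)
  expect_equal(rotational_coeff(0), 0.75 * pi)
  expect_error(rotational_coeff(1.2), "0, 1")
})

test_that("frame chain conventions: identity, stroke-plane pitch, mirror symmetry", {
  f <- 12
  const <- function(v) fourier_waveform(a0 = v, f = f)
  wk0 <- wing_kinematics(const(0), const(0), const(0), const(0), beta_r = 0)
  bk0 <- body_kinematics(const(0), const(0), const(0))
  fc <- frame_chain(wk0, bk0, t = 0.01)
  expect_equal(fc$R_stroke, diag(3), tolerance = 1e-12)
  # wing axes: chord forward, span to the right (-y), normal up
  expect_equal(fc$R_wing[, 1], c(1, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fc$R_wing[, 2], c(0, -1, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fc$R_wing[, 3], c(0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fc$omega, c(0, 0, 0), tolerance = 1e-9)

  # beta = 90 deg maps the stroke-plane z-axis onto global -x, and the
  # rotation is orthonormal (self-consistent with its inverse)
  wk90 <- wing_kinematics(const(0), const(0), const(0), const(90), beta_r = 0)
  fc90 <- frame_chain(wk90, bk0, t = 0)
  expect_equal(drop(fc90$R_stroke %*% c(0, 0, 1)), c(-1, 0, 0),
               tolerance = 1e-12)
  expect_equal(t(fc90$R_stroke) %*% fc90$R_stroke, diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # left and right frames mirror through the xz-plane when beta_r != 0
  wkr <- wing_kinematics(const(20), const(5), const(50), const(40),
                         beta_r = 3)
  fcR <- frame_chain(wkr, bk0, t = 0.004, side = "right")
  fcL <- frame_chain(wkr, bk0, t = 0.004, side = "left")
  M <- diag(c(1, -1, 1))
  expect_equal(fcL$R_wing, M %*% fcR$R_wing, tolerance = 1e-12)
})

test_that("angle of attack from the chord/airflow arccos formula", {
  # steady forward flight, flow along -x; feathering sets the chord
  for (alpha in c(0, 90, 180)) {
    cfg <- steady_rect_config(alpha_deg = alpha)
    st <- strip_state(cfg, t = 0.001, i = 100)
    expect_equal(st$alpha_v_deg, alpha, tolerance = 1e-9)
  }
  cfg <- steady_rect_config(alpha_deg = 45)
  st <- strip_state(cfg, t = 0, i = 1)
  expect_true(st$flow_defined)
  expect_equal(st$speed, 2, tolerance = 1e-12)
  expect_equal(st$alpha_h_deg, 45)  # alpha - beta with beta = 0
  # unit vectors
  expect_equal(sum(st$chord_dir^2), 1, tolerance = 1e-12)
  expect_equal(sum(st$normal^2), 1, tolerance = 1e-12)
})

test_that("strip forces reproduce the hand-evaluated blade-element magnitudes", {
  cfg <- steady_rect_config(alpha_deg = 45, V = 2, chord = 0.02, R = 0.1)
  fr <- strip_forces(cfg, t = 0.002, i = 7, frame = "global")
  magn <- sqrt(fr$Fx^2 + fr$Fy^2 + fr$Fz^2)
  names(magn) <- fr$component
  # |dF_L| = 0.5 * 1.225 * CL(45) * 2^2 * 0.02 * 5e-4
  expect_equal(magn[["lift"]], 0.5 * 1.225 * 1.385879 * 4 * 0.02 * 5e-4,
               tolerance = 1e-5)
  # steady translation: no rotational or added-mass force
  expect_equal(magn[["rotational"]], 0, tolerance = 1e-15)
  expect_equal(magn[["added_mass"]], 0, tolerance = 1e-15)
  # lift perpendicular to, drag parallel to, the airflow
  st <- strip_state(cfg, t = 0.002, i = 7)
  lift <- unlist(fr[fr$component == "lift", c("Fx", "Fy", "Fz")])
  drag <- unlist(fr[fr$component == "drag", c("Fx", "Fy", "Fz")])
  expect_equal(sum(lift * st$airflow_dir), 0, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(drag * st$airflow_dir), sqrt(sum(drag^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("total force matches the closed-form steady-translation oracle", {
  cfg <- steady_rect_config(alpha_deg = 45, V = 2)
  ta <- total_aero(cfg, t = 0.01)
  cd <- lift_drag_coeffs(45)
  S <- cfg$morph$area
  q <- 0.5 * cfg$rho * 2^2 * S * 2   # both wings
  # drag along the airflow (-x); lift perpendicular, here downward
  # because the flow meets the upper wing surface
  expect_equal(abs(ta$Fx_N), q * cd$CD, tolerance = 1e-3)
  expect_equal(abs(ta$Fz_N), q * cd$CL, tolerance = 1e-3)
  expect_equal(ta$Fy_N, 0)
})

test_that("forces scale linearly with air density and quadratically with speed", {
  cfg1 <- steady_rect_config(alpha_deg = 30, V = 2)
  cfg2 <- steady_rect_config(alpha_deg = 30, V = 2)
  cfg2$rho <- 2 * cfg1$rho
  ta1 <- total_aero(cfg1, 0.01); ta2 <- total_aero(cfg2, 0.01)
  expect_equal(ta2$Fx_N, 2 * ta1$Fx_N, tolerance = 1e-12)
  expect_equal(ta2$Fz_N, 2 * ta1$Fz_N, tolerance = 1e-12)
  cfg4 <- steady_rect_config(alpha_deg = 30, V = 4)
  ta4 <- total_aero(cfg4, 0.01)
  expect_equal(ta4$Fx_N, 4 * ta1$Fx_N, tolerance = 1e-12)
})

test_that("mirror-symmetric wings cancel lateral force and roll/yaw moments", {
  cfg <- flapping_config(beta_a = 8, beta_r = 2)
  res <- simulate_wingstroke(cfg, n_steps = 300, detail = FALSE)
  scale <- cfg$mt * cfg$g * cfg$morph$r2
  expect_lt(max(abs(res$series$Fy_N)), 1e-12 * cfg$mt * cfg$g)
  expect_lt(max(abs(res$series$Mx_Nm)), 1e-12 * scale)
  expect_lt(max(abs(res$series$Mz_Nm)), 1e-12 * scale)
})

test_that("wing inertial force: zero at constant velocity, zero mean over a period", {
  # no flapping, constant body velocity: wing acceleration is zero
  cfg <- steady_rect_config(alpha_deg = 40, V = 2.5)
  fin <- inertial_force(cfg, t = c(0, 0.01, 0.02))
  expect_lt(max(abs(c(fin$Fx_N, fin$Fz_N))), 1e-12)

  # flapping: instantaneous inertial force is large but averages to zero
  cfg2 <- flapping_config(beta_a = 10)
  tg <- (0:499) / (500 * cfg2$f)
  fin2 <- inertial_force(cfg2, tg)
  peak <- max(sqrt(fin2$Fx_N^2 + fin2$Fz_N^2))
  expect_gt(peak, 0)
  expect_lt(abs(mean(fin2$Fx_N)), 1e-9 * peak)
  expect_lt(abs(mean(fin2$Fz_N)), 1e-9 * peak)
})

test_that("inertial reaction to a sinusoidal body oscillation is +m_w A w^2 sin", {
  # wings rigidly carried by a body oscillating as x(t) = A sin(2 pi f t):
  # u = A w cos(w t), so F = -2 m_w d(u)/dt = +2 m_w A w^2 sin(w t)
  f <- 15; A <- 0.002; w <- 2 * pi * f
  wing <- build_strips(function(r) rep(0.02, length(r)), R = 0.1,
                       wing_mass = 2e-4)
  const <- function(v) fourier_waveform(a0 = v, f = f)
  wk <- wing_kinematics(const(0), const(0), const(45), const(0))
  bk <- body_kinematics(const(0),
                        u = fourier_waveform(0, a = c(A * w), f = f),
                        w = const(0))
  cfg <- moth_config(wing, wk, bk, mt = 0.002)
  tg <- seq(0, 1 / f, length.out = 9)
  fin <- inertial_force(cfg, tg)
  expect_equal(fin$Fx_N, 2 * 2e-4 * A * w^2 * sin(w * tg), tolerance = 1e-7)
})

test_that("aerodynamic power: drag dissipation positive, lift contributes nothing", {
  # steady translation: P = |F_D| v > 0
  cfg <- steady_rect_config(alpha_deg = 45, V = 2)
  P <- aero_power(cfg, 0.01)
  ta <- total_aero(cfg, 0.01)
  expect_equal(P, abs(ta$Fx_N) * 2, tolerance = 1e-9)
  expect_gt(P, 0)

  # zero airflow everywhere -> zero power
  cfg0 <- steady_rect_config(alpha_deg = 45, V = 0)
  expect_equal(aero_power(cfg0, 0.01), 0)

  # numerically assert the lift contribution at every step of a full stroke
  cfg2 <- flapping_config(beta_a = 10)
  res <- simulate_wingstroke(cfg2, n_steps = 400, detail = TRUE)
  expect_lt(max(abs(res$series$P_lift_residual_W)),
            1e-12 * max(abs(res$series$P_W)))
})

test_that("wingstroke averages equal series means and refine with the grid", {
  cfg <- flapping_config()
  res <- simulate_wingstroke(cfg, n_steps = 1000, detail = TRUE)
  expect_equal(res$averages$Fz_N, mean(res$series$Fz_N))
  expect_equal(res$averages$P_W, mean(res$series$P_W))
  expect_equal(nrow(res$series), 1000)

  res500 <- simulate_wingstroke(cfg, n_steps = 500, detail = FALSE)
  expect_equal(res500$averages$Fz_N, res$averages$Fz_N, tolerance = 1e-3)

  cfg100 <- cfg
  cfg100$morph <- reduce_morphology(cfg$morph, 100L)
  res100 <- simulate_wingstroke(cfg100, n_steps = 500, detail = FALSE)
  expect_equal(res100$averages$Fz_N, res500$averages$Fz_N, tolerance = 5e-3)
})
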