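# Quasi-steady blade-element core.
#
# Frame conventions (right-handed, global frame): x forward, y to the
# animal's left, z up. The right wing extends toward -y. The stroke-plane
# frame sits at the wing hinge, pitched by -beta about the global y-axis
# (so at beta = 90 deg the stroke-plane z-axis maps onto global -x) and
# rolled by beta_r about its x-axis (mirrored between sides). Within the
# stroke plane the hinge-to-tip direction is set by sweep phi (azimuth,
# zero when the wing is perpendicular to the body axis, positive toward
# the head) and deviation theta (elevation out of the plane); feathering
# alpha rotates the chord about the spanwise axis, measured from the
# stroke plane so that the wing inclination to the horizontal is
# alpha_h = alpha - beta.
#
# All kinematic evaluation below is written to be complex-safe: the
# inertial force uses complex-step differentiation of the analytic
# velocity field, which is exact to machine precision.

DEG <- pi / 180

rot_y <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# Per-time kinematic series for the RIGHT wing, vectorised over `t`.
# Returns hinge arm and velocity, spanwise direction and its rate, chord
# and normal unit vectors (global frame), and the angular rates the force
# model needs. Complex `t` is supported (used for complex-step
# differentiation); callers needing real output take Re().
kernel_series <- function(config, t) {
  wk <- config$wing_kin; bk <- config$body_kin
  beta  <- eval_waveform(wk$beta,  t) * DEG
  dbeta <- eval_waveform(wk$beta,  t, 1L) * DEG
  phi   <- eval_waveform(wk$phi,   t) * DEG
  dphi  <- eval_waveform(wk$phi,   t, 1L) * DEG
  ddphi <- eval_waveform(wk$phi,   t, 2L) * DEG
  theta <- eval_waveform(wk$theta, t) * DEG
  dtheta<- eval_waveform(wk$theta, t, 1L) * DEG
  alpha <- eval_waveform(wk$alpha, t) * DEG
  dalpha<- eval_waveform(wk$alpha, t, 1L) * DEG
  ddalpha <- eval_waveform(wk$alpha, t, 2L) * DEG
  ddbeta  <- eval_waveform(wk$beta,  t, 2L) * DEG
  chi   <- eval_waveform(bk$chi, t) * DEG
  dchi  <- eval_waveform(bk$chi, t, 1L) * DEG
  u <- eval_waveform(bk$u, t)
  w <- eval_waveform(bk$w, t)
  br <- wk$beta_r * DEG

  cb <- cos(beta); sb <- sin(beta)
  cr <- cos(br);   sr <- sin(br)
  cp <- cos(phi);  sp <- sin(phi)
  ct <- cos(theta); st <- sin(theta)
  ca <- cos(alpha); sa <- sin(alpha)
  cx <- cos(chi);  sx <- sin(chi)

  # stroke rotation R_s = Ry(-beta) %*% Rx(beta_r), written out per element
  R11 <- cb; R12 <- -sb * sr; R13 <- -sb * cr
  R21 <- 0 * cb; R22 <- cr + 0 * cb; R23 <- -sr + 0 * cb
  R31 <- sb; R32 <- cb * sr; R33 <- cb * cr
  # d(R_s)/d(beta)
  D11 <- -sb; D12 <- -cb * sr; D13 <- -cb * cr
  D31 <- cb;  D32 <- -sb * sr; D33 <- -sb * cr

  # span direction in the stroke frame and its time derivative
  s1 <- sp * ct; s2 <- -cp * ct; s3 <- st
  ds1 <- dphi * cp * ct - dtheta * sp * st
  ds2 <- dphi * sp * ct + dtheta * cp * st
  ds3 <- dtheta * ct

  sx_g <- R11 * s1 + R12 * s2 + R13 * s3
  sy_g <- R21 * s1 + R22 * s2 + R23 * s3
  sz_g <- R31 * s1 + R32 * s2 + R33 * s3
  dsx <- dbeta * (D11 * s1 + D12 * s2 + D13 * s3) +
    R11 * ds1 + R12 * ds2 + R13 * ds3
  dsy <- R21 * ds1 + R22 * ds2 + R23 * ds3
  dsz <- dbeta * (D31 * s1 + D32 * s2 + D33 * s3) +
    R31 * ds1 + R32 * ds2 + R33 * ds3

  # chord (trailing -> leading) and wing normal in the stroke frame;
  # feathering rotates against the stroke-plane pitch so that the wing
  # inclination to the horizontal is alpha - beta
  b1 <- ca * cp + sa * sp * st
  b2 <- ca * sp - sa * cp * st
  b3 <- -sa * ct
  n1 <- sa * cp - ca * sp * st
  n2 <- sa * sp + ca * cp * st
  n3 <- ca * ct

  bx <- R11 * b1 + R12 * b2 + R13 * b3
  by <- R21 * b1 + R22 * b2 + R23 * b3
  bz <- R31 * b1 + R32 * b2 + R33 * b3
  nx <- R11 * n1 + R12 * n2 + R13 * n3
  ny <- R21 * n1 + R22 * n2 + R23 * n3
  nz <- R31 * n1 + R32 * n2 + R33 * n3

  # hinge arm (relative to the centre of mass) and hinge velocity
  h <- config$morph$hinge_offset
  armx <- h[1] * cx - h[3] * sx
  army <- h[2] + 0 * cx
  armz <- h[1] * sx + h[3] * cx
  # d(arm)/dt with d/dt Ry(-chi): arm depends on chi only
  darmx <- dchi * (-h[1] * sx - h[3] * cx)
  darmz <- dchi * (h[1] * cx - h[3] * sx)
  vhx <- u + darmx
  vhy <- 0 * u
  vhz <- w + darmz

  list(t = t,
       arm = list(x = armx, y = army, z = armz),
       vh = list(x = vhx, y = vhy, z = vhz),
       s = list(x = sx_g, y = sy_g, z = sz_g),
       ds = list(x = dsx, y = dsy, z = dsz),
       b = list(x = bx, y = by, z = bz),
       n = list(x = nx, y = ny, z = nz),
       alpha = alpha, dalpha = dalpha,
       phi = phi, dphi = dphi, ddphi = ddphi,
       alpha_h = alpha - beta, dalpha_h = dalpha - dbeta,
       ddalpha_h = ddalpha - ddbeta,
       chi = chi, beta = beta)
}

# Second time derivatives of the hinge position and span direction via
# complex-step differentiation of the analytic velocity field.
kernel_accel <- function(config, t) {
  h <- 1e-7 / config$f
  ks <- kernel_series(config, t + 1i * h)
  list(ah = list(x = Im(ks$vh$x) / h, y = Im(ks$vh$y) / h, z = Im(ks$vh$z) / h),
       dds = list(x = Im(ks$ds$x) / h, y = Im(ks$ds$y) / h, z = Im(ks$ds$z) / h))
}

#' Lift and drag coefficients as functions of the angle of attack
#'
#' Empirical flat-plate coefficient polynomials measured on dynamically
#' scaled hawkmoth wings, scaled by the configuration factors `kL`, `kD`:
#' `CL = kL (1.552 sin a cos a + 1.725 sin^2 a cos a)` and
#' `CD = kD (0.0596 sin a cos a + 3.598 sin^3 a)` with `a` the angle of
#' attack.
#'
#' @param alpha_v Angle of attack in degrees, in `[0, 180]`.
#' @param kL,kD Dimensionless scaling factors (default 1).
#' @return A tibble with columns `CL` and `CD`.
#' @export
#' @examples
#' lift_drag_coeffs(45)
lift_drag_coeffs <- function(alpha_v, kL = 1, kD = 1) {
  if (any(alpha_v < 0 | alpha_v > 180)) {
    stop("`alpha_v` must lie in [0, 180] degrees", call. = FALSE)
  }
  a <- alpha_v * DEG
  sa <- sin(a); ca <- cos(a)
  tibble::tibble(
    CL = kL * (1.552 * sa * ca + 1.725 * sa^2 * ca),
    CD = kD * (0.0596 * sa * ca + 3.598 * sa^3))
}

#' Rotational force coefficient for a pitching-axis position
#'
#' Thin-aerofoil value `CR = pi (0.75 - e)` with `e` the pitching-axis
#' position as a fraction of chord behind the leading edge; it vanishes at
#' the three-quarter-chord point.
#'
#' @param e Pitching-axis fraction in `[0, 1]`.
#' @return Numeric vector of `CR` values.
#' @export
rotational_coeff <- function(e) {
  if (any(e < 0 | e > 1)) stop("`e` must lie in [0, 1]", call. = FALSE)
  pi * (0.75 - e)
}

# The vectorised blade-element evaluation over a time grid.
# Returns per-time totals (both wings, global frame) and optional detail
# traces. Exploits left/right mirror symmetry: with identical wing
# waveforms, zero lateral body velocity and no lateral wind, the left-wing
# force is the y-mirror of the right-wing force and the left moment is
# (-Mx, My, -Mz), so lateral force and roll/yaw moments cancel exactly.
blade_element_series <- function(config, t, detail = FALSE) {
  mo <- config$morph
  n_t <- length(t); n_s <- mo$n_strips
  ks <- kernel_series(config, t)

  r <- mo$r; dr <- mo$dr; chord <- mo$chord
  cdr <- chord * dr
  CRc2dr <- rotational_coeff(mo$pitch_axis_frac) * chord^2 * dr
  rc2dr <- r * chord^2 * dr
  c3dr4 <- chord^3 * dr / 4

  m_strip <- function(v) matrix(v, n_t, n_s, byrow = TRUE)
  CDRm <- m_strip(cdr)

  wind <- config$ambient_wind
  Vx <- wind[1] - (ks$vh$x + outer(ks$ds$x, r))
  Vy <- wind[2] - (ks$vh$y + outer(ks$ds$y, r))
  Vz <- wind[3] - (ks$vh$z + outer(ks$ds$z, r))
  v2 <- Vx * Vx + Vy * Vy + Vz * Vz
  v <- sqrt(v2)
  inv_v <- 1 / v
  if (any(v <= 1e-12)) {
    inv_v[v <= 1e-12] <- 0   # v = 0: flow direction undefined,
  }                          # translational force treated as 0
  vhx <- Vx * inv_v
  vhy <- Vy * inv_v
  vhz <- Vz * inv_v

  ca_v <- -(ks$b$x * vhx + ks$b$y * vhy + ks$b$z * vhz)
  ca_v <- pmin(pmax(ca_v, -1), 1)
  sa_v <- sqrt(1 - ca_v * ca_v)
  CL <- config$kL * sa_v * ca_v * (1.552 + 1.725 * sa_v)
  CD <- config$kD * sa_v * (0.0596 * ca_v + 3.598 * sa_v * sa_v)

  q  <- (0.5 * config$rho) * v2 * CDRm
  qL <- q * CL
  qD <- q * CD

  nv <- ks$n$x * vhx + ks$n$y * vhy + ks$n$z * vhz
  wx <- ks$n$x - nv * vhx
  wy <- ks$n$y - nv * vhy
  wz <- ks$n$z - nv * vhz
  wnorm <- sqrt(wx * wx + wy * wy + wz * wz)
  inv_w <- 1 / wnorm
  if (any(wnorm <= 1e-12)) inv_w[wnorm <= 1e-12] <- 0
  sgn <- sign(nv)
  Ldx <- sgn * wx * inv_w
  Ldy <- sgn * wy * inv_w
  Ldz <- sgn * wz * inv_w

  qR <- config$rho * v * ks$dalpha_h * m_strip(CRc2dr)
  qA <- (0.25 * pi * config$rho) *
    (outer(ks$ddphi * sin(ks$alpha) + ks$dphi * ks$dalpha_h * cos(ks$alpha),
           rc2dr) +
       outer(ks$ddalpha_h, c3dr4))
  qN <- qR + qA

  Fmx <- qD * vhx + qL * Ldx + qN * ks$n$x
  Fmy <- qD * vhy + qL * Ldy + qN * ks$n$y
  Fmz <- qD * vhz + qL * Ldz + qN * ks$n$z

  ones <- rep(1, n_s)
  FxR <- drop(Fmx %*% ones); FyR <- drop(Fmy %*% ones); FzR <- drop(Fmz %*% ones)
  FrX <- drop(Fmx %*% r); FrY <- drop(Fmy %*% r); FrZ <- drop(Fmz %*% r)

  # right-wing moment about the centre of mass
  MxR <- ks$arm$y * FzR - ks$arm$z * FyR + ks$s$y * FrZ - ks$s$z * FrY
  MyR <- ks$arm$z * FxR - ks$arm$x * FzR + ks$s$z * FrX - ks$s$x * FrZ
  MzR <- ks$arm$x * FyR - ks$arm$y * FxR + ks$s$x * FrY - ks$s$y * FrX

  # both wings by mirror symmetry
  out <- list(
    t = t,
    Fx = 2 * FxR, Fy = rep(0, n_t), Fz = 2 * FzR,
    Mx = rep(0, n_t), My = 2 * MyR, Mz = rep(0, n_t),
    P = 2 * (drop((qD * v) %*% ones) + drop((qN * nv * v) %*% ones)))

  if (detail) {
    S <- mo$area
    out$P_lift_residual <- 2 * drop((qL * (Ldx * Vx + Ldy * Vy + Ldz * Vz)) %*% ones)
    out$FL_x <- 2 * drop((qL * Ldx) %*% ones)
    out$FL_z <- 2 * drop((qL * Ldz) %*% ones)
    out$FD_x <- 2 * drop((qD * vhx) %*% ones)
    out$FD_z <- 2 * drop((qD * vhz) %*% ones)
    out$Frot_x <- 2 * drop((qR * ks$n$x) %*% ones)
    out$Frot_z <- 2 * drop((qR * ks$n$z) %*% ones)
    out$Fadm_x <- 2 * drop((qA * ks$n$x) %*% ones)
    out$Fadm_z <- 2 * drop((qA * ks$n$z) %*% ones)
    out$alpha_h <- ks$alpha_h / DEG
    out$alpha_v_mean <- drop((acos(ca_v) / DEG * CDRm) %*% ones) / S
    out$v_mean <- drop((v * CDRm) %*% ones) / S
    out$CL_mean <- drop((CL * CDRm) %*% ones) / S
    out$CD_mean <- drop((CD * CDRm) %*% ones) / S
    # inertial reaction force on the body (both wings; lateral cancels)
    acc <- kernel_accel(config, t)
    mw <- mo$wing_mass
    if (is.finite(mw)) {
      S1 <- sum(chord * r * dr)
      out$Fin_x <- -2 * (mw * acc$ah$x + mw * S1 / S * acc$dds$x)
      out$Fin_z <- -2 * (mw * acc$ah$z + mw * S1 / S * acc$dds$z)
    } else {
      out$Fin_x <- rep(NA_real_, n_t)
      out$Fin_z <- rep(NA_real_, n_t)
    }
  }
  out
}
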