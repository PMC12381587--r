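#' Coordinate frames and angular velocity of the kinematic chain
#'
#' Returns the stroke-plane and wing rotation matrices (columns are the
#' frame axes expressed in global coordinates) at time `t`, together with
#' the wing's angular velocity assembled from the stroke-plane, sweep,
#' deviation and feathering rates. The wing frame axes are the chord
#' direction (trailing to leading edge), the spanwise direction, and the
#' wing normal. The left side is the mirror image of the right through the
#' body's sagittal plane.
#'
#' @param wing_kin A [wing_kinematics()].
#' @param body_kin A [body_kinematics()] (used for the body pitch that
#'   carries the hinge).
#' @param t A single time in seconds.
#' @param side `"right"` or `"left"`.
#' @return A list with `R_stroke`, `R_wing` (3x3 matrices, frame axes in
#'   columns) and `omega` (rad/s, global frame).
#' @export
frame_chain <- function(wing_kin, body_kin, t, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(length(t) == 1L)
  cfg <- list(wing_kin = wing_kin, body_kin = body_kin,
              morph = list(hinge_offset = c(0, 0, 0)), f = wing_kin$f)
  axes <- function(tt) {
    ks <- kernel_series(cfg, tt)
    M <- if (side == "left") diag(c(1, -1, 1)) else diag(3)
    b <- M %*% c(ks$b$x, ks$b$y, ks$b$z)
    s <- M %*% c(ks$s$x, ks$s$y, ks$s$z)
    n <- M %*% c(ks$n$x, ks$n$y, ks$n$z)
    if (side == "left") n <- n  # mirror keeps |axes| = 1
    beta <- ks$beta
    br <- wing_kin$beta_r * DEG * (if (side == "left") -1 else 1)
    R_stroke <- rot_y(-beta) %*% rot_x(br)
    list(R_stroke = R_stroke, R_wing = cbind(b, s, n))
  }
  a0 <- axes(t)
  # angular velocity from complex-step differentiation of the wing rotation
  h <- 1e-7 / wing_kin$f
  a1 <- axes(t + 1i * h)
  Rdot <- Im(a1$R_wing) / h
  W <- Rdot %*% t(Re(a1$R_wing))
  omega <- c(W[3, 2], W[1, 3], W[2, 1])
  list(R_stroke = Re(a0$R_stroke), R_wing = Re(a0$R_wing), omega = omega)
}

#' State of one blade-element strip at one instant
#'
#' Gives the strip's global position and velocity, its chord and normal
#' unit vectors, the relative airflow direction and speed, the angle of
#' attack `alpha_v = acos(-b . vhat)` and the wing inclination angle
#' `alpha_h = alpha - beta`.
#'
#' @param config A [moth_config()].
#' @param t A single time (s).
#' @param i Strip index (1-based, within the morphology).
#' @param side `"right"` or `"left"`.
#' @return A list with `position`, `velocity`, `chord_dir`, `normal`,
#'   `airflow_dir`, `speed`, `alpha_v_deg`, `alpha_h_deg`, and
#'   `flow_defined` (FALSE when the relative airflow speed is zero, in
#'   which case translational forces are treated as zero).
#' @export
strip_state <- function(config, t, i, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is_moth_config(config), length(t) == 1L)
  mo <- config$morph
  if (i < 1L || i > mo$n_strips) stop("strip index out of range", call. = FALSE)
  ks <- kernel_series(config, t)
  M <- if (side == "left") diag(c(1, -1, 1)) else diag(3)
  r <- mo$r[i]
  com <- c(0, 0, 0)  # positions are reported relative to the centre of mass
  pos <- M %*% (c(ks$arm$x, ks$arm$y, ks$arm$z) + r * c(ks$s$x, ks$s$y, ks$s$z))
  vel <- M %*% (c(ks$vh$x, ks$vh$y, ks$vh$z) + r * c(ks$ds$x, ks$ds$y, ks$ds$z))
  b <- M %*% c(ks$b$x, ks$b$y, ks$b$z)
  n <- M %*% c(ks$n$x, ks$n$y, ks$n$z)
  vair <- config$ambient_wind - drop(vel)
  speed <- sqrt(sum(vair^2))
  flow_defined <- speed > 1e-12
  vhat <- if (flow_defined) vair / speed else c(NA_real_, NA_real_, NA_real_)
  alpha_v <- if (flow_defined) {
    acos(pmin(pmax(-sum(drop(b) * vhat), -1), 1)) / DEG
  } else NA_real_
  list(position = drop(pos) + com, velocity = drop(vel),
       chord_dir = drop(b), normal = drop(n),
       airflow_dir = vhat, speed = speed,
       alpha_v_deg = alpha_v, alpha_h_deg = ks$alpha_h / DEG,
       flow_defined = flow_defined)
}

#' Quasi-steady force components on one strip at one instant
#'
#' Evaluates the four blade-element force components on strip `i`:
#' translational lift (`0.5 rho CL v^2 c dr`, perpendicular to the airflow,
#' on the suction side), translational drag (`0.5 rho CD v^2 c dr`, along
#' the airflow), the rotational force (`rho CR v c^2 alpha_h_dot dr`, along
#' the wing normal) and the added-mass force
#' (`pi rho / 4 ((phi_dd sin(alpha) + phi_d alpha_h_dot cos(alpha)) r c^2 +
#' alpha_h_dd c^3 / 4) dr`, along the wing normal).
#'
#' @inheritParams strip_state
#' @param frame `"wing"` (components on the chord/span/normal axes) or
#'   `"global"`.
#' @return A tibble with one row per component (`lift`, `drag`,
#'   `rotational`, `added_mass`) and columns `Fx`, `Fy`, `Fz`, `frame`.
#' @export
strip_forces <- function(config, t, i, side = c("right", "left"),
                         frame = c("wing", "global")) {
  side <- match.arg(side); frame <- match.arg(frame)
  st <- strip_state(config, t, i, side)
  ks <- kernel_series(config, t)
  mo <- config$morph
  c_i <- mo$chord[i]; dr <- mo$dr
  rho <- config$rho
  v <- st$speed
  comps <- list(lift = c(0, 0, 0), drag = c(0, 0, 0))
  if (st$flow_defined) {
    cd <- lift_drag_coeffs(st$alpha_v_deg, config$kL, config$kD)
    q <- 0.5 * rho * v^2 * c_i * dr
    vhat <- st$airflow_dir
    nvec <- st$normal
    nv <- sum(nvec * vhat)
    wvec <- nvec - nv * vhat
    wn <- sqrt(sum(wvec^2))
    ldir <- if (wn > 1e-12) sign(nv) * wvec / wn else c(0, 0, 0)
    comps$lift <- q * cd$CL * ldir
    comps$drag <- q * cd$CD * vhat
  }
  CR <- rotational_coeff(mo$pitch_axis_frac[i])
  comps$rotational <- rho * CR * v * c_i^2 * Re(ks$dalpha_h) * dr * st$normal
  adm_mag <- 0.25 * pi * rho *
    ((Re(ks$ddphi) * sin(Re(ks$alpha)) +
        Re(ks$dphi) * Re(ks$dalpha_h) * cos(Re(ks$alpha))) * mo$r[i] * c_i^2 +
       0.25 * Re(ks$ddalpha_h) * c_i^3) * dr
  comps$added_mass <- adm_mag * st$normal
  if (frame == "wing") {
    Rw <- cbind(st$chord_dir, crossprod_axis(st$normal, st$chord_dir), st$normal)
    # columns: chord, span, normal
    Rw[, 2] <- vcross(st$normal, st$chord_dir)
    comps <- lapply(comps, function(fv) drop(t(Rw) %*% fv))
  }
  tibble::tibble(
    component = names(comps),
    Fx = vapply(comps, `[`, numeric(1), 1),
    Fy = vapply(comps, `[`, numeric(1), 2),
    Fz = vapply(comps, `[`, numeric(1), 3),
    frame = frame)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
crossprod_axis <- function(a, b) vcross(a, b)

#' Total aerodynamic force and moment from both wings
#'
#' Strip forces are integrated along each wing and summed over the two
#' wings; the moment is taken about the centre of mass and contains
#' aerodynamic contributions only.
#'
#' @param config A [moth_config()].
#' @param t Numeric vector of times (s).
#' @return A tibble with columns `t_s`, `Fx_N`, `Fy_N`, `Fz_N`, `Mx_Nm`,
#'   `My_Nm`, `Mz_Nm` (global frame).
#' @export
total_aero <- function(config, t) {
  stopifnot(is_moth_config(config))
  bes <- blade_element_series(config, t)
  tibble::tibble(t_s = t, Fx_N = bes$Fx, Fy_N = bes$Fy, Fz_N = bes$Fz,
                 Mx_Nm = bes$Mx, My_Nm = bes$My, Mz_Nm = bes$Mz)
}

#' Inertial reaction force of the flapping wings on the body
#'
#' Each strip of a wing of mass `mw` contributes
#' `dF = -(mw / S) c dr dv/dt` measured in the global frame; the strip
#' acceleration comes from complex-step differentiation of the analytic
#' velocity field (exact to machine precision). Over an exact period the
#' average is zero: wing inertia redistributes force within a wingstroke
#' but cannot generate net force.
#'
#' @param config A [moth_config()] whose morphology has a finite
#'   `wing_mass`.
#' @param t Numeric vector of times (s).
#' @return A tibble with columns `t_s`, `Fx_N`, `Fy_N`, `Fz_N`.
#' @export
inertial_force <- function(config, t) {
  stopifnot(is_moth_config(config))
  mo <- config$morph
  if (!is.finite(mo$wing_mass)) {
    stop("morphology has no `wing_mass`; inertial force undefined", call. = FALSE)
  }
  acc <- kernel_accel(config, t)
  S <- mo$area
  S1 <- sum(mo$chord * mo$r * mo$dr)
  tibble::tibble(
    t_s = t,
    Fx_N = -2 * (mo$wing_mass * acc$ah$x + mo$wing_mass * S1 / S * acc$dds$x),
    Fy_N = 0,
    Fz_N = -2 * (mo$wing_mass * acc$ah$z + mo$wing_mass * S1 / S * acc$dds$z))
}

#' Instantaneous aerodynamic power
#'
#' Work done per unit time by the drag, rotational and added-mass forces
#' against the relative airflow, summed over strips and both wings. Lift
#' is perpendicular to the airflow and contributes exactly zero; negative
#' values (power recovered from the airflow) are preserved.
#'
#' @param config A [moth_config()].
#' @param t Numeric vector of times (s).
#' @return Numeric vector of power values (W).
#' @export
aero_power <- function(config, t) {
  stopifnot(is_moth_config(config))
  blade_element_series(config, t)$P
}

#' Resample a wing morphology to a different strip count
#'
#' Used to run reduced-fidelity evaluations inside the trim search; the
#' chord and pitching-axis profiles are linearly interpolated onto the new
#' strip centres.
#'
#' @param morph A `wing_morphology`.
#' @param n_strips New strip count.
#' @return A `wing_morphology`.
#' @export
reduce_morphology <- function(morph, n_strips) {
  stopifnot(is_wing_morphology(morph))
  if (n_strips == morph$n_strips) return(morph)
  build_strips(
    chord_profile = stats::approxfun(c(0, morph$r, morph$R),
                                     c(morph$chord[1], morph$chord,
                                       morph$chord[morph$n_strips]), rule = 2),
    R = morph$R, n_strips = n_strips,
    pitch_axis_frac = stats::approxfun(c(0, morph$r, morph$R),
                                       c(morph$pitch_axis_frac[1],
                                         morph$pitch_axis_frac,
                                         morph$pitch_axis_frac[morph$n_strips]),
                                       rule = 2),
    wing_mass = morph$wing_mass, hinge_offset = morph$hinge_offset)
}

# tibble-free fast path used inside optimisation loops: wingstroke-mean
# force and pitch moment only
wingstroke_averages <- function(config, n_steps) {
  tg <- (seq_len(n_steps) - 1L) / (n_steps * config$f)
  bes <- blade_element_series(config, tg, detail = FALSE)
  list(Fx_N = mean(bes$Fx), Fz_N = mean(bes$Fz), My_Nm = mean(bes$My),
       P_W = mean(bes$P))
}

#' Simulate one wingstroke of the blade-element model
#'
#' Evaluates the full model on a uniform grid over one wingbeat period
#' `[0, 1/f)`: total aerodynamic force and pitch moment, per-component
#' force breakdown, inertial reaction force, aerodynamic power, the wing
#' inclination angle, the strip-averaged angle of attack and airflow
#' speed, and area-weighted mean lift and drag coefficients. Averages are
#' arithmetic means over the grid, which for periodic series is a
#' spectrally accurate quadrature.
#'
#' @param config A [moth_config()].
#' @param n_steps Number of equal time steps per wingstroke (default 1000).
#' @param detail If `TRUE` (default) include component breakdowns,
#'   inertial force and diagnostic traces; `FALSE` computes only totals
#'   and power (used inside the trim search).
#' @return An object of class `wingstroke_result`: a list with `series`
#'   (a tibble, one row per time step) and `averages` (named list of
#'   wingstroke means and peaks), plus the configuration.
#' @export
simulate_wingstroke <- function(config, n_steps = 1000L, detail = TRUE) {
  stopifnot(is_moth_config(config))
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be at least 2", call. = FALSE)
  tg <- (seq_len(n_steps) - 1L) / (n_steps * config$f)
  bes <- blade_element_series(config, tg, detail = detail)
  series <- tibble::tibble(
    t_s = tg, Fx_N = bes$Fx, Fy_N = bes$Fy, Fz_N = bes$Fz,
    Mx_Nm = bes$Mx, My_Nm = bes$My, Mz_Nm = bes$Mz, P_W = bes$P)
  if (detail) {
    series <- dplyr::bind_cols(series, tibble::tibble(
      FL_x_N = bes$FL_x, FL_z_N = bes$FL_z,
      FD_x_N = bes$FD_x, FD_z_N = bes$FD_z,
      Frot_x_N = bes$Frot_x, Frot_z_N = bes$Frot_z,
      Fadm_x_N = bes$Fadm_x, Fadm_z_N = bes$Fadm_z,
      Fin_x_N = bes$Fin_x, Fin_z_N = bes$Fin_z,
      alpha_h_deg = bes$alpha_h, alpha_v_deg = bes$alpha_v_mean,
      v_ms = bes$v_mean, CL_mean = bes$CL_mean, CD_mean = bes$CD_mean,
      P_lift_residual_W = bes$P_lift_residual))
  }
  Fmag <- sqrt(bes$Fx^2 + bes$Fy^2 + bes$Fz^2)
  averages <- list(
    Fx_N = mean(bes$Fx), Fy_N = mean(bes$Fy), Fz_N = mean(bes$Fz),
    Mx_Nm = mean(bes$Mx), My_Nm = mean(bes$My), Mz_Nm = mean(bes$Mz),
    P_W = mean(bes$P), P_peak_W = max(bes$P),
    F_mean_N = mean(Fmag), F_peak_N = max(Fmag))
  if (detail) {
    averages$Fin_x_N <- mean(bes$Fin_x)
    averages$Fin_z_N <- mean(bes$Fin_z)
    averages$Fin_peak_N <- max(sqrt(bes$Fin_x^2 + bes$Fin_z^2))
    averages$CL_mean <- mean(bes$CL_mean)
    averages$CD_mean <- mean(bes$CD_mean)
  }
  structure(list(series = series, averages = averages, config = config,
                 n_steps = n_steps, n_strips = config$morph$n_strips),
            class = "wingstroke_result")
}

#' @export
print.wingstroke_result <- function(x, ...) {
  av <- x$averages
  mg <- x$config$mt * x$config$g
  cat(sprintf(paste0(
    "<wingstroke_result> %d steps x %d strips\n",
    "  mean force  (N): Fx = %.3e, Fz = %.3e (weight mg = %.3e)\n",
    "  mean moment (Nm): My = %.3e\n",
    "  power (W): mean = %.3e, peak = %.3e\n"),
    x$n_steps, x$n_strips, av$Fx_N, av$Fz_N, mg, av$My_Nm, av$P_W, av$P_peak_W))
  invisible(x)
}

#' @export
tidy.wingstroke_result <- function(x, ...) x$series

#' @export
glance.wingstroke_result <- function(x, ...) {
  tibble::as_tibble(x$averages)
}

#' Write a wingstroke result to CSV with a JSON summary sidecar
#'
#' @param result A [simulate_wingstroke()] result.
#' @param csv,json Output paths.
#' @return The paths, invisibly.
#' @export
write_wingstroke <- function(result, csv, json) {
  stopifnot(inherits(result, "wingstroke_result"))
  utils::write.csv(result$series, csv, row.names = FALSE)
  jsonlite::write_json(result$averages, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}
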