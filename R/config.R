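#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Wing kinematics: sweep, deviation, feathering and stroke-plane waveforms
#'
#' Bundles the four periodic angle waveforms (degrees) and the constant
#' stroke-plane roll angle that together prescribe the wing motion:
#' sweep `phi` (azimuth of the hinge-to-tip vector in the stroke plane),
#' deviation `theta` (elevation out of the stroke plane), feathering
#' `alpha` (rotation of the wing plane about the spanwise axis, measured
#' from the stroke plane), and stroke-plane angle `beta` (inclination of
#' the stroke plane to the horizontal). All waveforms must share the same
#' wingbeat frequency.
#'
#' @param phi,theta,alpha,beta [fourier_waveform()] objects in degrees.
#' @param beta_r Constant stroke-plane roll angle in degrees (the angle the
#'   stroke-plane y-axis makes with the global y-axis; mirrored between
#'   sides).
#' @return An object of class `wing_kinematics`.
#' @export
wing_kinematics <- function(phi, theta, alpha, beta, beta_r = 0) {
  wfs <- list(phi = phi, theta = theta, alpha = alpha, beta = beta)
  stopifnot(all(vapply(wfs, is_fourier_waveform, logical(1))))
  fs <- vapply(wfs, function(w) w$f, numeric(1))
  if (diff(range(fs)) > 1e-12 * fs[1]) {
    stop("all wing waveforms must share the same wingbeat frequency", call. = FALSE)
  }
  structure(c(wfs, list(beta_r = beta_r, f = fs[[1]])),
            class = "wing_kinematics")
}

#' Body kinematics: pitch and centre-of-mass velocity waveforms
#'
#' Body pitch `chi` is the angle of the body long axis above the horizontal
#' (degrees); `u` and `w` are the fore-aft and vertical centre-of-mass
#' velocity components in the global frame (m/s). Lateral velocity is fixed
#' at zero, as appropriate for steady symmetric forward flight.
#'
#' @param chi [fourier_waveform()], degrees.
#' @param u,w [fourier_waveform()] objects, m/s.
#' @return An object of class `body_kinematics`.
#' @export
body_kinematics <- function(chi, u, w) {
  wfs <- list(chi = chi, u = u, w = w)
  stopifnot(all(vapply(wfs, is_fourier_waveform, logical(1))))
  fs <- vapply(wfs, function(x) x$f, numeric(1))
  if (diff(range(fs)) > 1e-12 * fs[1]) {
    stop("all body waveforms must share the same wingbeat frequency", call. = FALSE)
  }
  structure(c(wfs, list(v_lat = 0, f = fs[[1]])), class = "body_kinematics")
}

#' Full configuration of one moth for the blade-element model
#'
#' Gathers everything one aerodynamic simulation needs: morphology, wing
#' and body kinematics, total mass, the lift/drag coefficient scaling
#' factors, and physical constants.
#'
#' @param morph A [build_strips()] / [synthetic_wing()] wing (one side; the
#'   other side is its mirror image).
#' @param wing_kin A [wing_kinematics()].
#' @param body_kin A [body_kinematics()] sharing the same frequency.
#' @param mt Total mass (kg).
#' @param kL,kD Dimensionless scalings applied to the lift and drag
#'   coefficient polynomials (default 1), which absorb interspecific
#'   differences from the reference flat-plate coefficients.
#' @param rho Air density, kg/m^3 (default 1.225).
#' @param g Gravitational acceleration, m/s^2 (default 9.81).
#' @param ambient_wind Global-frame wind vector (m/s, default zero; the
#'   lateral component must be zero to preserve left/right symmetry).
#' @return An object of class `moth_config`.
#' @export
moth_config <- function(morph, wing_kin, body_kin, mt,
                        kL = 1, kD = 1, rho = 1.225, g = 9.81,
                        ambient_wind = c(0, 0, 0)) {
  stopifnot(is_wing_morphology(morph),
            inherits(wing_kin, "wing_kinematics"),
            inherits(body_kin, "body_kinematics"))
  if (abs(wing_kin$f - body_kin$f) > 1e-9 * wing_kin$f) {
    stop("wing and body kinematics must share the same wingbeat frequency",
         call. = FALSE)
  }
  if (!is.numeric(mt) || mt <= 0) stop("`mt` must be positive", call. = FALSE)
  if (kL <= 0 || kD <= 0) stop("`kL` and `kD` must be positive", call. = FALSE)
  if (rho <= 0 || g <= 0) stop("`rho` and `g` must be positive", call. = FALSE)
  stopifnot(length(ambient_wind) == 3L)
  if (ambient_wind[2] != 0) {
    stop("lateral ambient wind breaks the left/right symmetry this model assumes",
         call. = FALSE)
  }
  structure(list(morph = morph, wing_kin = wing_kin, body_kin = body_kin,
                 mt = mt, kL = kL, kD = kD, rho = rho, g = g,
                 ambient_wind = as.numeric(ambient_wind), f = wing_kin$f),
            class = "moth_config")
}

#' @export
print.moth_config <- function(x, ...) {
  sc <- derive_scalars(x$morph, x$mt)
  cat(sprintf(paste0(
    "<moth_config> f = %.3g Hz, mt = %.3g kg, S = %.3g m^2 (one wing), ",
    "Ws = %.3g m^2/kg, kL = %.3g, kD = %.3g\n"),
    x$f, x$mt, sc$S_m2, sc$Ws_m2_kg, x$kL, x$kD))
  invisible(x)
}

is_moth_config <- function(x) inherits(x, "moth_config")

#' Summary statistics of every waveform in a configuration
#'
#' @param config A [moth_config()].
#' @return A tibble with one row per waveform: name, mean, amplitude and
#'   the fundamental phase (degrees).
#' @export
config_waveform_stats <- function(config) {
  stopifnot(is_moth_config(config))
  wfs <- list(phi = config$wing_kin$phi, theta = config$wing_kin$theta,
              alpha = config$wing_kin$alpha, beta = config$wing_kin$beta,
              chi = config$body_kin$chi, u = config$body_kin$u,
              w = config$body_kin$w)
  purrr::map_dfr(names(wfs), function(nm) {
    st <- waveform_stats(wfs[[nm]])
    tibble::tibble(waveform = nm, mean = st$mean, amplitude = st$amplitude,
                   phase_deg = atan2(wfs[[nm]]$b[1], wfs[[nm]]$a[1]) * 180 / pi)
  })
}
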