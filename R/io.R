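# Plain-text serialisation of kinematics (CSV + JSON); all angles in
# degrees, SI units elsewhere.

waveform_to_list <- function(wf) {
  list(a0 = wf$a0, a = wf$a, b = wf$b)
}
waveform_from_list <- function(x, f) {
  fourier_waveform(a0 = x$a0, a = unlist(x$a), b = unlist(x$b), f = f)
}

#' Write / read fitted kinematics as a JSON coefficient file
#'
#' Stores the wingbeat frequency, stroke-plane roll angle, and the Fourier
#' coefficients of every wing and body waveform, plus (optionally) the
#' aerodynamic scalings and total mass, so a configuration can be rebuilt
#' exactly.
#'
#' @param wing_kin A [wing_kinematics()].
#' @param body_kin A [body_kinematics()].
#' @param path JSON path.
#' @param kL,kD,mt Optional scalars recorded alongside.
#' @return `write_kinematics_json()` the path invisibly;
#'   `read_kinematics_json()` a list with `wing_kin`, `body_kin`, `f` and
#'   any recorded scalars.
#' @export
write_kinematics_json <- function(wing_kin, body_kin, path,
                                  kL = NULL, kD = NULL, mt = NULL) {
  stopifnot(inherits(wing_kin, "wing_kinematics"),
            inherits(body_kin, "body_kinematics"))
  obj <- list(
    f_hz = wing_kin$f, beta_r_deg = wing_kin$beta_r,
    waveforms = list(
      phi = waveform_to_list(wing_kin$phi),
      theta = waveform_to_list(wing_kin$theta),
      alpha = waveform_to_list(wing_kin$alpha),
      beta = waveform_to_list(wing_kin$beta),
      chi = waveform_to_list(body_kin$chi),
      u = waveform_to_list(body_kin$u),
      w = waveform_to_list(body_kin$w)))
  if (!is.null(kL)) obj$kL <- kL
  if (!is.null(kD)) obj$kD <- kD
  if (!is.null(mt)) obj$mt_kg <- mt
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinematics_json
#' @export
read_kinematics_json <- function(path) {
  if (!file.exists(path)) {
    stop("kinematics file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("f_hz", "waveforms")) {
    if (is.null(obj[[field]])) {
      stop("kinematics file ", path, " is missing field `", field, "`",
           call. = FALSE)
    }
  }
  f <- obj$f_hz
  wfl <- obj$waveforms
  need <- c("phi", "theta", "alpha", "beta", "chi", "u", "w")
  missing <- setdiff(need, names(wfl))
  if (length(missing) > 0) {
    stop("kinematics file ", path, " is missing waveforms: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  wing <- wing_kinematics(
    phi = waveform_from_list(wfl$phi, f),
    theta = waveform_from_list(wfl$theta, f),
    alpha = waveform_from_list(wfl$alpha, f),
    beta = waveform_from_list(wfl$beta, f),
    beta_r = obj$beta_r_deg %||% 0)
  body <- body_kinematics(
    chi = waveform_from_list(wfl$chi, f),
    u = waveform_from_list(wfl$u, f),
    w = waveform_from_list(wfl$w, f))
  list(wing_kin = wing, body_kin = body, f = f,
       kL = obj$kL %||% 1, kD = obj$kD %||% 1, mt = obj$mt_kg)
}

#' Write an extracted kinematics table to CSV
#'
#' One row per time step with the columns produced by
#' [extract_kinematics()]; the estimated wingbeat frequency rides in a
#' header comment.
#'
#' @param kin An [extract_kinematics()] tibble.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  con <- file(path, "w")
  on.exit(close(con))
  f <- attr(kin, "f_hz")
  if (!is.null(f)) writeLines(sprintf("# f_hz: %.10g", f), con)
  utils::write.csv(as.data.frame(kin), con, row.names = FALSE)
  invisible(path)
}
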