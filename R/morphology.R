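#' Span-discretized wing planform for blade-element analysis
#'
#' The combined fore+hindwing of one side is treated as a single rigid flat
#' plate and divided into `n_strips` chordwise strips of equal spanwise
#' width `dr = R / n_strips`, with the chord sampled at strip centres
#' (midpoint rule). Each strip carries a chord length, a pitching-axis
#' position expressed as a fraction of the chord behind the leading edge,
#' and the wing's share of mass proportional to strip area.
#'
#' @param chord_profile Function mapping span position (m, in `[0, R]`) to
#'   chord length (m); must be non-negative.
#' @param R Wing span (hinge to tip) in metres.
#' @param n_strips Number of spanwise strips (default 200).
#' @param pitch_axis_frac Pitching-axis position as a fraction of chord from
#'   the leading edge (0 = leading edge, 1 = trailing edge); either a single
#'   number or a function of span position. Default 0.25 (quarter chord).
#' @param wing_mass Mass of one wing in kg.
#' @param hinge_offset Numeric 3-vector (m): position of the right wing
#'   hinge relative to the body centre of mass, in the body frame
#'   (x forward, y to the animal's left, z dorsal). The left hinge is its
#'   mirror image through the body's sagittal plane.
#' @return An object of class `wing_morphology` with fields `R`, `n_strips`,
#'   `r` (strip centres), `dr`, `chord`, `pitch_axis_frac`, `wing_mass`,
#'   `hinge_offset`, and derived `area` and `r2` (radius of the second
#'   moment of area).
#' @export
#' @examples
#' wing <- build_strips(function(r) rep(0.02, length(r)), R = 0.1)
#' wing$area     # 0.002 m^2
#' wing$r2       # R / sqrt(3)
build_strips <- function(chord_profile, R, n_strips = 200L,
                         pitch_axis_frac = 0.25,
                         wing_mass = NA_real_,
                         hinge_offset = c(0, 0, 0)) {
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R <= 0) {
    stop("`R` must be a single positive span in metres", call. = FALSE)
  }
  n_strips <- as.integer(n_strips)
  if (is.na(n_strips) || n_strips < 1L) {
    stop("`n_strips` must be a positive integer", call. = FALSE)
  }
  dr <- R / n_strips
  r <- (seq_len(n_strips) - 0.5) * dr
  chord <- chord_profile(r)
  if (length(chord) == 1L) chord <- rep(chord, n_strips)
  if (length(chord) != n_strips || any(!is.finite(chord))) {
    stop("`chord_profile` must return one finite value per strip", call. = FALSE)
  }
  if (any(chord < 0)) {
    stop("invalid profile: negative chord sample", call. = FALSE)
  }
  e <- if (is.function(pitch_axis_frac)) pitch_axis_frac(r) else pitch_axis_frac
  if (length(e) == 1L) e <- rep(e, n_strips)
  if (any(e < 0) || any(e > 1)) {
    stop("`pitch_axis_frac` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.numeric(hinge_offset), length(hinge_offset) == 3L)
  area <- sum(chord * dr)
  r2 <- if (area > 0) sqrt(sum(chord * r^2 * dr) / area) else NA_real_
  structure(list(R = R, n_strips = n_strips, r = r, dr = dr, chord = chord,
                 pitch_axis_frac = e, wing_mass = wing_mass,
                 hinge_offset = as.numeric(hinge_offset),
                 area = area, r2 = r2),
            class = "wing_morphology")
}

#' @export
print.wing_morphology <- function(x, ...) {
  cat(sprintf("<wing_morphology> R = %g m, %d strips, S = %.4g m^2, r2 = %.4g m\n",
              x$R, x$n_strips, x$area, x$r2))
  invisible(x)
}

is_wing_morphology <- function(x) inherits(x, "wing_morphology")

#' Morphological scalars used by the aerodynamic model
#'
#' Computes the single-wing area `S`, the radius of the second moment of
#' area `r2 = sqrt(sum(c r^2 dr) / S)` (the length scale used to normalise
#' the pitch moment in the trim residual), and the wing loading
#' `Ws = 2 S / mt`, defined here as the total wing area of both wings
#' divided by the total mass -- note this is the inverse of the
#' conventional mass-per-area wing loading.
#'
#' @param morph A [build_strips()] wing.
#' @param total_mass Total mass of the animal in kg (body plus wings).
#' @return A tibble with one row: `S_m2`, `r2_m`, `Ws_m2_kg`.
#' @export
derive_scalars <- function(morph, total_mass) {
  stopifnot(is_wing_morphology(morph))
  if (!is.numeric(total_mass) || length(total_mass) != 1L ||
      !is.finite(total_mass) || total_mass <= 0) {
    stop("`total_mass` must be a single positive mass in kg", call. = FALSE)
  }
  tibble::tibble(S_m2 = morph$area, r2_m = morph$r2,
                 Ws_m2_kg = 2 * morph$area / total_mass)
}

#' Synthetic wing planform from a Beta-function chord profile
#'
#' Generates a smooth moth-like planform
#' `c(r) = c0 * g(r / R) / max(g)` with
#' `g(x) = x^(p - 1) * (1 - x)^(q - 1)`, i.e. a Beta-density shape
#' normalised so the maximum chord equals `c0`. `p = q = 1` gives a
#' rectangular wing. The construction is deterministic: `seed` is recorded
#' so generated moths can carry provenance, but no randomness is used in
#' the planform itself.
#'
#' @param shape_params List or named vector with `c0` (maximum chord, m),
#'   `p`, `q` (positive Beta shape exponents).
#' @param R Span in metres.
#' @param n_strips Number of strips (default 200).
#' @param seed Integer recorded on the object for provenance.
#' @param ... Passed to [build_strips()] (e.g. `wing_mass`, `hinge_offset`).
#' @return A `wing_morphology`.
#' @export
synthetic_wing <- function(shape_params = list(c0 = 0.04, p = 1.8, q = 2.2),
                           R = 0.06, n_strips = 200L, seed = 0L, ...) {
  c0 <- shape_params$c0; p <- shape_params$p; q <- shape_params$q
  if (any(c(c0, p, q) <= 0)) stop("`c0`, `p`, `q` must be positive", call. = FALSE)
  gmax <- if (p == 1 && q == 1) 1 else {
    xm <- if (p == 1) 0 else if (q == 1) 1 else (p - 1) / (p + q - 2)
    xm^(p - 1) * (1 - xm)^(q - 1)
  }
  profile <- function(r) {
    x <- pmin(pmax(r / R, 0), 1)
    c0 * x^(p - 1) * (1 - x)^(q - 1) / gmax
  }
  wing <- build_strips(profile, R = R, n_strips = n_strips, ...)
  wing$seed <- as.integer(seed)
  wing$shape_params <- list(c0 = c0, p = p, q = q)
  wing
}

#' Read / write wing morphology as plain-text files
#'
#' The CSV holds one row per strip with columns `r_m`, `chord_m`,
#' `pitch_axis_frac`; the JSON sidecar stores the scalars (`R`, `wing_mass`,
#' `hinge_offset`, and optionally `total_mass`).
#'
#' @param morph A `wing_morphology`.
#' @param csv,json File paths.
#' @param total_mass Optional total mass to record in the sidecar.
#' @return `write_morphology()` returns the paths invisibly;
#'   `read_morphology()` returns a `wing_morphology` (with `total_mass`
#'   attached as an attribute when present).
#' @export
write_morphology <- function(morph, csv, json, total_mass = NULL) {
  stopifnot(is_wing_morphology(morph))
  utils::write.csv(
    data.frame(r_m = morph$r, chord_m = morph$chord,
               pitch_axis_frac = morph$pitch_axis_frac),
    csv, row.names = FALSE)
  side <- list(R = morph$R, n_strips = morph$n_strips,
               wing_mass = morph$wing_mass, hinge_offset = morph$hinge_offset)
  if (!is.null(total_mass)) side$total_mass <- total_mass
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = json))
}

#' @rdname write_morphology
#' @export
read_morphology <- function(csv, json) {
  if (!file.exists(csv)) stop("morphology CSV not found: ", csv, call. = FALSE)
  if (!file.exists(json)) stop("morphology sidecar not found: ", json, call. = FALSE)
  tab <- utils::read.csv(csv)
  for (col in c("r_m", "chord_m", "pitch_axis_frac")) {
    if (!col %in% names(tab)) {
      stop("morphology CSV ", csv, " is missing column `", col, "`", call. = FALSE)
    }
  }
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  n <- nrow(tab)
  # rebuild on the strip grid implied by the table (centres must be uniform)
  morph <- build_strips(
    chord_profile = stats::approxfun(tab$r_m, tab$chord_m, rule = 2),
    R = side$R, n_strips = n,
    pitch_axis_frac = stats::approxfun(tab$r_m, tab$pitch_axis_frac, rule = 2),
    wing_mass = side$wing_mass %||% NA_real_,
    hinge_offset = side$hinge_offset %||% c(0, 0, 0))
  if (!is.null(side$total_mass)) attr(morph, "total_mass") <- side$total_mass
  morph
}
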