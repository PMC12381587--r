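MODEL_TAGS <- c("model1", "model2", "model3", "model1a", "model1b")

#' Body-kinematics model variants
#'
#' Builds the comparative body-kinematics configurations used to isolate
#' the aerodynamic role of body oscillations, always leaving the wing
#' angle waveforms (`phi`, `theta`, `alpha`) untouched:
#'
#' * `model1` - the measured time-varying body kinematics (identity).
#' * `model2` - no body oscillations: body pitch `chi`, stroke-plane angle
#'   `beta`, and body velocities `u`, `w` frozen at their wingstroke
#'   means.
#' * `model3` - antiphase body kinematics: `chi`, `beta`, `u`, `w` shifted
#'   in time by half a period, putting the body 180 degrees out of phase
#'   with the wing motion.
#' * `model1a` - body-speed oscillations only: `chi` (and `beta`, which
#'   oscillates with the body; disable with `flatten_beta = FALSE`)
#'   frozen at their means.
#' * `model1b` - body-pitch oscillations only: `u` and `w` frozen.
#'
#' @param base A [moth_config()] (treated as model 1).
#' @param tag One of `"model1"`, `"model2"`, `"model3"`, `"model1a"`,
#'   `"model1b"`.
#' @param flatten_beta Should `beta` be frozen together with `chi` in
#'   `model2`/`model1a`? Default `TRUE`: the stroke plane rides on the
#'   oscillating body.
#' @return A [moth_config()].
#' @export
make_variant <- function(base, tag, flatten_beta = TRUE) {
  stopifnot(is_moth_config(base))
  if (!tag %in% MODEL_TAGS) {
    stop("unknown model tag `", tag, "`; use one of ",
         paste(MODEL_TAGS, collapse = ", "), call. = FALSE)
  }
  wk <- base$wing_kin; bk <- base$body_kin
  flat <- function(wf) fourier_waveform(a0 = wf$a0, f = wf$f, K = wf$K)
  half <- function(wf) shift_waveform(wf, 1 / (2 * wf$f))
  if (tag == "model1") return(base)
  if (tag == "model2") {
    beta <- if (flatten_beta) flat(wk$beta) else wk$beta
    wing <- wing_kinematics(wk$phi, wk$theta, wk$alpha, beta, wk$beta_r)
    body <- body_kinematics(flat(bk$chi), flat(bk$u), flat(bk$w))
  } else if (tag == "model3") {
    wing <- wing_kinematics(wk$phi, wk$theta, wk$alpha, half(wk$beta), wk$beta_r)
    body <- body_kinematics(half(bk$chi), half(bk$u), half(bk$w))
  } else if (tag == "model1a") {
    beta <- if (flatten_beta) flat(wk$beta) else wk$beta
    wing <- wing_kinematics(wk$phi, wk$theta, wk$alpha, beta, wk$beta_r)
    body <- body_kinematics(flat(bk$chi), bk$u, bk$w)
  } else { # model1b
    wing <- wing_kinematics(wk$phi, wk$theta, wk$alpha, wk$beta, wk$beta_r)
    body <- body_kinematics(bk$chi, flat(bk$u), flat(bk$w))
  }
  moth_config(base$morph, wing, body, mt = base$mt, kL = base$kL,
              kD = base$kD, rho = base$rho, g = base$g,
              ambient_wind = base$ambient_wind)
}

#' Performance metrics of a simulated wingstroke
#'
#' Wingstroke-averaged and peak force magnitude, fore-aft and vertical
#' mean force, mean and peak aerodynamic power, the lift-to-drag ratio
#' (ratio of the area- and time-averaged lift and drag coefficients), and
#' the phase difference between body pitch and wing sweep.
#'
#' @param result A [simulate_wingstroke()] result computed with
#'   `detail = TRUE`.
#' @return A one-row tibble.
#' @export
performance_metrics <- function(result) {
  stopifnot(inherits(result, "wingstroke_result"))
  av <- result$averages
  if (is.null(av$CD_mean)) {
    stop("run `simulate_wingstroke()` with `detail = TRUE` for metrics",
         call. = FALSE)
  }
  if (av$CD_mean <= 0) stop("undefined lift-to-drag ratio: mean CD is zero",
                            call. = FALSE)
  cfg <- result$config
  phase <- tryCatch(
    phase_difference(cfg$body_kin$chi, cfg$wing_kin$phi),
    error = function(e) NA_real_)
  tibble::tibble(
    F_mean_N = av$F_mean_N, F_peak_N = av$F_peak_N,
    Fx_mean_N = av$Fx_N, Fz_mean_N = av$Fz_N,
    P_mean_W = av$P_W, P_peak_W = av$P_peak_W,
    LD_ratio = av$CL_mean / av$CD_mean,
    phase_chi_phi_deg = phase)
}

#' Compare body-kinematics model variants of one configuration
#'
#' Simulates each requested variant of `base` with identical wing angle
#' waveforms and reports performance metrics plus ratios against model 1.
#'
#' @param base A [moth_config()] (model 1).
#' @param tags Variants to include; must contain `"model1"`.
#' @param n_steps Time steps per wingstroke (default 1000).
#' @param flatten_beta Passed to [make_variant()].
#' @return A tibble, one row per variant, with metric columns and
#'   `P_ratio`, `P_peak_ratio`, `F_ratio` relative to model 1.
#' @export
compare_variants <- function(base, tags = c("model1", "model2", "model3"),
                             n_steps = 1000L, flatten_beta = TRUE) {
  stopifnot(is_moth_config(base))
  if (!"model1" %in% tags) stop("`tags` must include \"model1\"", call. = FALSE)
  rows <- purrr::map_dfr(tags, function(tag) {
    cfg <- make_variant(base, tag, flatten_beta = flatten_beta)
    res <- simulate_wingstroke(cfg, n_steps = n_steps, detail = TRUE)
    dplyr::bind_cols(tibble::tibble(variant = tag), performance_metrics(res))
  })
  ref <- rows[rows$variant == "model1", ]
  dplyr::mutate(rows,
                P_ratio = .data$P_mean_W / ref$P_mean_W,
                P_peak_ratio = .data$P_peak_W / ref$P_peak_W,
                F_ratio = .data$F_mean_N / ref$F_mean_N)
}

#' Correlation of body-pitch oscillation amplitude with wingbeat frequency
#' and wing loading
#'
#' Pearson correlations of the body-pitch amplitude across species against
#' the wingbeat period `1/f`, the wing loading `Ws` (total wing area over
#' total mass), and `1/(f Ws)`.
#'
#' @param species_summaries Data frame with columns `chi_a_deg`, `f_hz`,
#'   `Ws_m2_kg` (one row per species; at least 3 rows).
#' @return A tibble with one row per predictor: `predictor`, `r`,
#'   `p_value`.
#' @export
oscillation_correlations <- function(species_summaries) {
  need <- c("chi_a_deg", "f_hz", "Ws_m2_kg")
  if (!all(need %in% names(species_summaries))) {
    stop("`species_summaries` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(species_summaries) < 3L) {
    stop("need at least 3 species summaries", call. = FALSE)
  }
  y <- species_summaries$chi_a_deg
  preds <- list(inv_f = 1 / species_summaries$f_hz,
                Ws = species_summaries$Ws_m2_kg,
                inv_fWs = 1 / (species_summaries$f_hz *
                                 species_summaries$Ws_m2_kg))
  purrr::map_dfr(names(preds), function(nm) {
    x <- preds[[nm]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("undefined correlation: zero variance in `", nm, "` or amplitudes",
           call. = FALSE)
    }
    ct <- stats::cor.test(y, x)
    tibble::tibble(predictor = nm, r = unname(ct$estimate),
                   p_value = ct$p.value)
  })
}
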