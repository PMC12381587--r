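# End-to-end pipeline stages. Each stage reads/writes plain-text files
# (CSV/JSON), records a manifest of its inputs and settings, and is
# deterministic given its seed. A thin command-line dispatcher around
# these functions ships in `exec/wingbeat`.

write_manifest <- function(out_dir, stage, inputs, settings) {
  jsonlite::write_json(
    list(stage = stage,
         package = "wingbeat",
         version = as.character(utils::packageVersion("wingbeat")),
         inputs = inputs, settings = settings),
    file.path(out_dir, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

#' Pipeline stage: generate a synthetic moth and its landmark track
#'
#' Writes `morphology.csv` + `morphology.json`, `landmarks.csv`,
#' `kinematics_true.json` (the generating waveforms) and a manifest into
#' `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param species Species band for the parameter draws (see
#'   [silkmoth_bounds()]).
#' @param near_trim Construct an in-bounds equilibrium (slower).
#' @param noise_sd,n_strokes Passed to [synth_spec()].
#' @return The configuration, invisibly.
#' @export
run_synth <- function(out_dir, seed = 1L, species = "A_luna",
                      near_trim = FALSE, noise_sd = 1e-4, n_strokes = 3L) {
  ensure_dir(out_dir)
  sp <- synth_spec(seed = seed,
                   bounds = trim_bounds(silkmoth_bounds(species)[1:3]),
                   noise_sd = noise_sd, n_strokes = n_strokes)
  config <- synth_moth(sp, near_trim = near_trim)
  track <- synth_landmarks(config, sp)
  write_morphology(config$morph,
                   file.path(out_dir, "morphology.csv"),
                   file.path(out_dir, "morphology.json"),
                   total_mass = config$mt)
  write_landmarks(track, file.path(out_dir, "landmarks.csv"))
  write_kinematics_json(config$wing_kin, config$body_kin,
                        file.path(out_dir, "kinematics_true.json"),
                        kL = config$kL, kD = config$kD, mt = config$mt)
  if (!is.null(attr(config, "near_trim_bounds"))) {
    utils::write.csv(as.data.frame(attr(config, "near_trim_bounds")),
                     file.path(out_dir, "near_trim_bounds.csv"),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "synth", inputs = list(),
                 settings = list(seed = seed, species = species,
                                 near_trim = near_trim, noise_sd = noise_sd,
                                 n_strokes = n_strokes))
  invisible(config)
}

#' Pipeline stage: extract and fit kinematics from a landmark track
#'
#' Reads `landmarks.csv`, writes `kinematics.csv` (per-frame angles and
#' velocities) and `kinematics_fit.json` (Fourier coefficients).
#'
#' @param landmarks Path to a landmark CSV ([write_landmarks()] format).
#' @param out_dir Output directory.
#' @param f Optional known wingbeat frequency (Hz).
#' @return The fitted kinematics list, invisibly.
#' @export
run_fit <- function(landmarks, out_dir, f = NULL) {
  ensure_dir(out_dir)
  track <- read_landmarks(landmarks)
  kin <- extract_kinematics(track, f = f)
  fit <- fit_kinematics(kin)
  write_kinematics_csv(kin, file.path(out_dir, "kinematics.csv"))
  write_kinematics_json(fit$wing_kin, fit$body_kin,
                        file.path(out_dir, "kinematics_fit.json"))
  write_manifest(out_dir, "fit",
                 inputs = list(landmarks = landmarks),
                 settings = list(f = f))
  invisible(fit)
}

build_config_from_files <- function(morph_csv, morph_json, kinematics_json,
                                    mt = NULL) {
  morph <- read_morphology(morph_csv, morph_json)
  kin <- read_kinematics_json(kinematics_json)
  mt <- mt %||% kin$mt %||% attr(morph, "total_mass")
  if (is.null(mt)) {
    stop("total mass not found in `", kinematics_json, "` or `", morph_json,
         "`; pass `mt`", call. = FALSE)
  }
  moth_config(morph, kin$wing_kin, kin$body_kin, mt = mt,
              kL = kin$kL, kD = kin$kD)
}

#' Pipeline stage: trim search
#'
#' Builds the base configuration from morphology and kinematics files,
#' runs the multi-start bounded trim search, and writes
#' `trim_solutions.csv`.
#'
#' @param morph_csv,morph_json Morphology files ([write_morphology()]).
#' @param kinematics_json Fitted kinematics ([write_kinematics_json()]).
#' @param bounds_csv Bounds CSV with columns `parameter`, `min`, `max`.
#' @param out_dir Output directory.
#' @param n_solutions,tol,seed Passed to [search_trim()].
#' @param ... Further arguments to [search_trim()].
#' @return The `trim_result`, invisibly.
#' @export
run_trim <- function(morph_csv, morph_json, kinematics_json, bounds_csv,
                     out_dir, n_solutions = 10L, tol = 1e-6, seed = 1L, ...) {
  ensure_dir(out_dir)
  base <- build_config_from_files(morph_csv, morph_json, kinematics_json)
  if (!file.exists(bounds_csv)) {
    stop("bounds file not found: ", bounds_csv, call. = FALSE)
  }
  bounds <- trim_bounds(utils::read.csv(bounds_csv))
  trim <- search_trim(base, bounds, n_solutions = n_solutions, tol = tol,
                      seed = seed, ...)
  write_trim_solutions(trim, file.path(out_dir, "trim_solutions.csv"))
  write_manifest(out_dir, "trim",
                 inputs = list(morph_csv = morph_csv, morph_json = morph_json,
                               kinematics_json = kinematics_json,
                               bounds_csv = bounds_csv),
                 settings = list(n_solutions = n_solutions, tol = tol,
                                 seed = seed))
  invisible(trim)
}

#' Pipeline stage: simulate wingstrokes for body-kinematics variants
#'
#' Rebuilds the base configuration, applies the first (or a chosen) trim
#' solution, and writes one wingstroke CSV + JSON summary per variant.
#'
#' @inheritParams run_trim
#' @param solutions_csv Trim solutions ([write_trim_solutions()]).
#' @param variants Character vector of model tags.
#' @param solution Row of `solutions_csv` to use (default 1).
#' @param n_steps Time steps per wingstroke.
#' @return A named list of `wingstroke_result`s, invisibly.
#' @export
run_simulate <- function(morph_csv, morph_json, kinematics_json,
                         solutions_csv, out_dir,
                         variants = c("model1", "model2", "model3"),
                         solution = 1L, n_steps = 1000L) {
  ensure_dir(out_dir)
  base <- build_config_from_files(morph_csv, morph_json, kinematics_json)
  sols <- read_trim_solutions(solutions_csv)
  if (solution > nrow(sols)) {
    stop("requested solution ", solution, " but `", solutions_csv,
         "` holds ", nrow(sols), call. = FALSE)
  }
  th <- unlist(sols[solution, TRIM_PARAMS])
  trimmed <- apply_parameters(base, th)
  out <- list()
  for (tag in variants) {
    cfg <- make_variant(trimmed, tag)
    res <- simulate_wingstroke(cfg, n_steps = n_steps, detail = TRUE)
    write_wingstroke(res,
                     file.path(out_dir, paste0("wingstroke_", tag, ".csv")),
                     file.path(out_dir, paste0("wingstroke_", tag, ".json")))
    out[[tag]] <- res
  }
  write_manifest(out_dir, "simulate",
                 inputs = list(morph_csv = morph_csv, morph_json = morph_json,
                               kinematics_json = kinematics_json,
                               solutions_csv = solutions_csv),
                 settings = list(variants = variants, solution = solution,
                                 n_steps = n_steps))
  invisible(out)
}

#' Pipeline stage: compare body-kinematics variants
#'
#' @inheritParams run_simulate
#' @return The comparison tibble, invisibly; written to
#'   `variant_metrics.csv` and `variant_metrics.json`.
#' @export
run_compare <- function(morph_csv, morph_json, kinematics_json,
                        solutions_csv, out_dir,
                        variants = c("model1", "model2", "model3"),
                        solution = 1L, n_steps = 1000L) {
  ensure_dir(out_dir)
  base <- build_config_from_files(morph_csv, morph_json, kinematics_json)
  sols <- read_trim_solutions(solutions_csv)
  if (solution > nrow(sols)) {
    stop("requested solution ", solution, " but `", solutions_csv,
         "` holds ", nrow(sols), call. = FALSE)
  }
  th <- unlist(sols[solution, TRIM_PARAMS])
  trimmed <- apply_parameters(base, th)
  cmp <- compare_variants(trimmed, tags = variants, n_steps = n_steps)
  utils::write.csv(as.data.frame(cmp),
                   file.path(out_dir, "variant_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cmp, file.path(out_dir, "variant_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write_manifest(out_dir, "compare",
                 inputs = list(morph_csv = morph_csv, morph_json = morph_json,
                               kinematics_json = kinematics_json,
                               solutions_csv = solutions_csv),
                 settings = list(variants = variants, solution = solution,
                                 n_steps = n_steps))
  invisible(cmp)
}

#' Pipeline stage: per-wingstroke phase differences
#'
#' Fits per-stroke Fourier waveforms to an extracted kinematics CSV and
#' reports the body-pitch vs wing-sweep phase difference for each stroke.
#'
#' @param kinematics_csv A [write_kinematics_csv()] file.
#' @param out_dir Output directory.
#' @return A tibble (`stroke`, `phase_chi_phi_deg`), invisibly; written to
#'   `phases.csv`.
#' @export
run_phase <- function(kinematics_csv, out_dir) {
  ensure_dir(out_dir)
  if (!file.exists(kinematics_csv)) {
    stop("kinematics file not found: ", kinematics_csv, call. = FALSE)
  }
  first <- readLines(kinematics_csv, n = 1L)
  f <- if (grepl("^#\\s*f_hz:", first)) {
    as.numeric(sub("^#\\s*f_hz:\\s*", "", first))
  } else {
    stop("kinematics file ", kinematics_csv,
         " lacks the `# f_hz:` header", call. = FALSE)
  }
  kin <- utils::read.csv(kinematics_csv, comment.char = "#")
  need <- c("t_s", "chi_deg", "phi_deg", "stroke")
  if (!all(need %in% names(kin))) {
    stop("kinematics file ", kinematics_csv, " needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  phases <- purrr::map_dfr(sort(unique(kin$stroke)), function(s) {
    sub <- kin[kin$stroke == s, ]
    if (nrow(sub) < 7L) return(NULL)
    tibble::tibble(
      stroke = s,
      phase_chi_phi_deg = phase_difference(
        fit_fourier(sub$t_s, sub$chi_deg, f),
        fit_fourier(sub$t_s, sub$phi_deg, f)))
  })
  utils::write.csv(as.data.frame(phases), file.path(out_dir, "phases.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "phase",
                 inputs = list(kinematics_csv = kinematics_csv),
                 settings = list())
  invisible(phases)
}

#' Pipeline stage: combined JSON report
#'
#' Gathers the outputs of earlier stages found in `dir` (trim solutions,
#' variant metrics, phases) into one `report.json`.
#'
#' @param dir Directory holding earlier stage outputs.
#' @return The report list, invisibly.
#' @export
run_report <- function(dir) {
  report <- list()
  sol_path <- file.path(dir, "trim_solutions.csv")
  if (file.exists(sol_path)) {
    sols <- read_trim_solutions(sol_path)
    report$trim <- list(n_solutions = nrow(sols), G_min = min(sols$G),
                        G_max = max(sols$G))
  }
  met_path <- file.path(dir, "variant_metrics.csv")
  if (file.exists(met_path)) {
    report$variants <- utils::read.csv(met_path)
  }
  ph_path <- file.path(dir, "phases.csv")
  if (file.exists(ph_path)) {
    report$phases <- utils::read.csv(ph_path)
  }
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
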