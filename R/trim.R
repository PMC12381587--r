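TRIM_PARAMS <- c("f", "beta_r", "chi_a", "chi_m", "beta_a", "beta_m",
                 "phi_a", "phi_m", "alpha_a", "alpha_m", "theta_a", "theta_m",
                 "kL", "kD")

#' Trim-search parameter bounds
#'
#' The 14 trim parameters are the wingbeat frequency `f` (Hz), stroke-plane
#' roll `beta_r` (deg), the amplitude (`*_a`) and mean (`*_m`) of body
#' pitch `chi`, stroke-plane angle `beta`, sweep `phi`, feathering `alpha`
#' and deviation `theta` (deg), and the aerodynamic coefficient scalings
#' `kL` and `kD`. Bounds are usually the extrema observed across recorded
#' wingstrokes of a species.
#'
#' @param min,max Named numeric vectors (names from
#'   `wingbeat:::TRIM_PARAMS`) or a data frame with columns `parameter`,
#'   `min`, `max`.
#' @return A tibble of class `trim_bounds` with columns `parameter`,
#'   `min`, `max`.
#' @export
trim_bounds <- function(min, max = NULL) {
  if (is.data.frame(min)) {
    tab <- min
    need <- c("parameter", "min", "max")
    if (!all(need %in% names(tab))) {
      stop("bounds table needs columns `parameter`, `min`, `max`", call. = FALSE)
    }
  } else {
    stopifnot(!is.null(max), !is.null(names(min)), !is.null(names(max)))
    tab <- data.frame(parameter = names(min), min = unname(min),
                      max = unname(max[names(min)]))
  }
  missing <- setdiff(TRIM_PARAMS, tab$parameter)
  if (length(missing) > 0) {
    stop("bounds are missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[match(TRIM_PARAMS, tab$parameter), c("parameter", "min", "max")]
  if (any(tab$min > tab$max)) stop("min > max for some parameter", call. = FALSE)
  out <- tibble::as_tibble(tab)
  class(out) <- c("trim_bounds", class(out))
  out
}

#' Species trim-search bounds shipped with the package
#'
#' Per-species minimum/maximum bounds for the 14 trim parameters, with a
#' characteristic published trim solution per species, as distributed in
#' `inst/extdata/silkmoth_trim_bounds.csv`.
#'
#' @param species One of `"A_io"`, `"A_luna"`, `"A_polyphemus"`,
#'   `"H_euryalus"`, or `NULL` to return the full table.
#' @return A `trim_bounds` tibble (with an extra `trim` column giving the
#'   characteristic solution), or the full table when `species = NULL`.
#' @export
silkmoth_bounds <- function(species = NULL) {
  path <- system.file("extdata", "silkmoth_trim_bounds.csv",
                      package = "wingbeat", mustWork = TRUE)
  tab <- tibble::as_tibble(utils::read.csv(path))
  if (is.null(species)) return(tab)
  sp <- match.arg(species, unique(tab$species))
  sub <- tab[tab$species == sp, c("parameter", "min", "max", "trim")]
  out <- trim_bounds(sub)
  out$trim <- sub$trim[match(out$parameter, sub$parameter)]
  out
}

#' Trim residual of a simulated wingstroke
#'
#' The dimensionless cost
#' `G = (Fx/mg)^2 + (Fz/mg - 1)^2 + (My/(mg r2))^2` built from the
#' wingstroke-averaged fore-aft force, vertical force and pitch moment.
#' `G = 0` is perfect trim: thrust balance, weight support and zero mean
#' pitch moment.
#'
#' @param result A [simulate_wingstroke()] result, or a list with
#'   `averages` containing `Fx_N`, `Fz_N`, `My_Nm`.
#' @param mt Total mass (kg); defaults to the result's configuration.
#' @param g Gravitational acceleration (m/s^2).
#' @param r2 Radius of the second moment of wing area (m).
#' @return The residual `G` (dimensionless, >= 0).
#' @export
trim_cost <- function(result, mt = NULL, g = NULL, r2 = NULL) {
  av <- result$averages
  cfg <- result$config
  mt <- mt %||% cfg$mt
  g <- g %||% cfg$g
  r2 <- r2 %||% cfg$morph$r2
  if (is.null(r2) || !is.finite(r2) || r2 <= 0) {
    stop("`r2` must be positive", call. = FALSE)
  }
  mg <- mt * g
  (av$Fx_N / mg)^2 + (av$Fz_N / mg - 1)^2 + (av$My_Nm / (mg * r2))^2
}

#' Apply a 14-parameter trim vector to a configuration
#'
#' Rescales the `phi`, `theta`, `alpha`, `beta` and `chi` waveforms to the
#' requested means and amplitudes (shapes preserved), replaces `f`,
#' `beta_r`, `kL` and `kD`, and retimes the body-velocity waveforms to the
#' new frequency while keeping their means and shapes.
#'
#' @param base A [moth_config()].
#' @param theta_vec Named numeric vector over `wingbeat:::TRIM_PARAMS` (a
#'   bare numeric vector of length 14 in that order also works).
#' @return A new [moth_config()].
#' @export
apply_parameters <- function(base, theta_vec) {
  stopifnot(is_moth_config(base))
  if (is.null(names(theta_vec))) {
    stopifnot(length(theta_vec) == length(TRIM_PARAMS))
    names(theta_vec) <- TRIM_PARAMS
  }
  p <- as.list(theta_vec[TRIM_PARAMS])
  f <- p$f
  wk <- base$wing_kin; bk <- base$body_kin
  # peak-to-peak amplitude is invariant under retiming, so the base
  # amplitudes can be computed once and cached on the configuration
  amps <- attr(base, "base_amps") %||% base_waveform_amps(base)
  res <- function(wf, m, a, amp) {
    if (a == 0) return(fourier_waveform(a0 = m, f = f, K = wf$K))
    if (amp == 0) {
      stop("cannot rescale a zero-amplitude waveform to a nonzero amplitude",
           call. = FALSE)
    }
    s <- a / amp
    fourier_waveform(a0 = m, a = wf$a * s, b = wf$b * s, f = f, K = wf$K)
  }
  wing <- wing_kinematics(
    phi = res(wk$phi, p$phi_m, p$phi_a, amps[["phi"]]),
    theta = res(wk$theta, p$theta_m, p$theta_a, amps[["theta"]]),
    alpha = res(wk$alpha, p$alpha_m, p$alpha_a, amps[["alpha"]]),
    beta = res(wk$beta, p$beta_m, p$beta_a, amps[["beta"]]),
    beta_r = p$beta_r)
  body <- body_kinematics(
    chi = res(bk$chi, p$chi_m, p$chi_a, amps[["chi"]]),
    u = retime_waveform(bk$u, f),
    w = retime_waveform(bk$w, f))
  moth_config(base$morph, wing, body, mt = base$mt, kL = p$kL, kD = p$kD,
              rho = base$rho, g = base$g, ambient_wind = base$ambient_wind)
}

base_waveform_amps <- function(config) {
  wk <- config$wing_kin; bk <- config$body_kin
  list(phi = waveform_stats(wk$phi)$amplitude,
       theta = waveform_stats(wk$theta)$amplitude,
       alpha = waveform_stats(wk$alpha)$amplitude,
       beta = waveform_stats(wk$beta)$amplitude,
       chi = waveform_stats(bk$chi)$amplitude)
}

#' Current trim-parameter vector of a configuration
#'
#' @param config A [moth_config()].
#' @return Named numeric vector over the 14 trim parameters.
#' @export
trim_parameters <- function(config) {
  stopifnot(is_moth_config(config))
  wk <- config$wing_kin; bk <- config$body_kin
  st <- function(wf) waveform_stats(wf)
  s_phi <- st(wk$phi); s_theta <- st(wk$theta); s_alpha <- st(wk$alpha)
  s_beta <- st(wk$beta); s_chi <- st(bk$chi)
  c(f = config$f, beta_r = wk$beta_r,
    chi_a = s_chi$amplitude, chi_m = s_chi$mean,
    beta_a = s_beta$amplitude, beta_m = s_beta$mean,
    phi_a = s_phi$amplitude, phi_m = s_phi$mean,
    alpha_a = s_alpha$amplitude, alpha_m = s_alpha$mean,
    theta_a = s_theta$amplitude, theta_m = s_theta$mean,
    kL = config$kL, kD = config$kD)
}

# sinusoidal transform mapping unbounded optimizer coordinates into
# [min, max], in the style of bound-constrained simplex wrappers
bound_to_free <- function(x, lo, hi) {
  x <- pmin(pmax(x, lo), hi)
  frac <- ifelse(hi > lo, (x - lo) / (hi - lo), 0.5)
  asin(2 * frac - 1)
}
free_to_bound <- function(z, lo, hi) {
  lo + (hi - lo) * (sin(z) + 1) / 2
}

#' Multi-start bounded trim search
#'
#' Searches for parameter vectors inside `bounds` whose wingstroke-averaged
#' forces and pitch moment are in equilibrium (trim residual
#' [trim_cost()] below `tol`). Each restart draws a random initial vector
#' uniformly within the bounds and minimises the residual with a
#' Nelder-Mead simplex run through a sinusoidal bound transform, so
#' iterates can never leave the bounds. The search runs at reduced fidelity
#' (`n_strips_search` strips, `n_steps_search` steps) and every candidate
#' minimum is re-polished and re-evaluated at full fidelity
#' (`n_strips_final` x `n_steps_final`); the reported `G` is always the
#' full-fidelity value. Restarts continue until `n_solutions` pairwise
#' distinct solutions are found or the restart budget is exhausted.
#'
#' Two solutions are distinct when the largest bound-normalised parameter
#' difference exceeds `distinct_tol`.
#'
#' @param base A [moth_config()] providing the waveform shapes.
#' @param bounds A [trim_bounds()] table.
#' @param n_solutions Number of distinct solutions to collect (default 10).
#' @param tol Acceptance threshold on the full-fidelity residual
#'   (default 1e-6).
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param max_restarts Restart budget (default 60).
#' @param n_strips_search,n_steps_search Reduced search fidelity
#'   (default 50 strips, 200 steps).
#' @param n_strips_final,n_steps_final Full fidelity used for polishing and
#'   reporting (default 200 strips, 1000 steps).
#' @param maxit_search,maxit_polish Nelder-Mead iteration caps for the two
#'   phases.
#' @param distinct_tol Distinctness threshold on bound-normalised
#'   parameters (default 0.02).
#' @param start_at_base If `TRUE` the first restart starts from `base`'s
#'   own parameters instead of a random draw.
#' @return An object of class `trim_result`: a list with `solutions` (a
#'   tibble, one row per solution: the 14 parameters, `G`, `n_cost_evals`,
#'   `restart`), `configs` (trimmed configurations), `bounds`, `seed`, and
#'   `exhausted` (TRUE when the restart budget ran out first, with a
#'   warning).
#' @export
search_trim <- function(base, bounds, n_solutions = 10L, tol = 1e-6,
                        seed = 1L, max_restarts = 60L,
                        n_strips_search = 50L, n_steps_search = 200L,
                        n_strips_final = 200L, n_steps_final = 1000L,
                        maxit_search = 3000L, maxit_polish = 400L,
                        distinct_tol = 0.02, start_at_base = FALSE) {
  stopifnot(is_moth_config(base), inherits(bounds, "trim_bounds"),
            n_solutions >= 1L)
  lo <- bounds$min; hi <- bounds$max
  names(lo) <- names(hi) <- bounds$parameter
  # templates at the two fidelities (reuse morphology across evaluations)
  base_search <- base
  base_search$morph <- reduce_morphology(base$morph, n_strips_search)
  base_final <- base
  base_final$morph <- reduce_morphology(base$morph, n_strips_final)
  amps <- base_waveform_amps(base)
  attr(base_search, "base_amps") <- amps
  attr(base_final, "base_amps") <- amps

  n_evals <- 0L
  cost_on <- function(template, n_steps) {
    function(z) {
      th <- free_to_bound(z, lo, hi)
      names(th) <- TRIM_PARAMS
      cfg <- apply_parameters(template, th)
      av <- wingstroke_averages(cfg, n_steps)
      n_evals <<- n_evals + 1L
      trim_cost(list(averages = av, config = cfg))
    }
  }
  cost_search <- cost_on(base_search, n_steps_search)
  cost_final <- cost_on(base_final, n_steps_final)

  set.seed(as.integer(seed))
  sols <- list()
  configs <- list()
  restart <- 0L
  while (length(sols) < n_solutions && restart < max_restarts) {
    restart <- restart + 1L
    x0 <- if (start_at_base && restart == 1L) {
      pmin(pmax(trim_parameters(base)[TRIM_PARAMS], lo), hi)
    } else {
      stats::runif(length(lo), lo, hi)
    }
    z0 <- bound_to_free(x0, lo, hi)
    n0 <- n_evals
    opt <- stats::optim(z0, cost_search, method = "Nelder-Mead",
                        control = list(maxit = maxit_search,
                                       reltol = 1e-12))
    # a restart that did not approach zero at reduced fidelity cannot pass
    # at full fidelity either; skip it cheaply
    if (!is.finite(opt$value) || opt$value > max(100 * tol, 1e-4)) next
    # re-evaluate the candidate at full fidelity; polish there only when
    # the discretisation shift pushes it above tolerance
    G <- cost_final(opt$par)
    if (is.finite(G) && G > tol) {
      opt <- stats::optim(opt$par, cost_final, method = "Nelder-Mead",
                          control = list(maxit = maxit_polish,
                                         reltol = 1e-12))
      G <- opt$value
    }
    if (!is.finite(G) || G > tol) next
    th <- free_to_bound(opt$par, lo, hi)
    names(th) <- TRIM_PARAMS
    dup <- any(vapply(sols, function(s) {
      rng <- ifelse(hi > lo, hi - lo, 1)
      max(abs(th - s$par) / rng) <= distinct_tol
    }, logical(1)))
    if (dup) next
    cfg <- apply_parameters(base_final, th)
    sols[[length(sols) + 1L]] <- list(par = th, G = G,
                                      n_cost_evals = n_evals - n0,
                                      restart = restart)
    configs[[length(sols)]] <- cfg
  }
  exhausted <- length(sols) < n_solutions
  if (exhausted) {
    warning(sprintf(
      "search exhausted: found %d of %d distinct trim solutions in %d restarts",
      length(sols), n_solutions, restart), call. = FALSE)
  }
  solutions <- purrr::map_dfr(seq_along(sols), function(i) {
    s <- sols[[i]]
    dplyr::bind_cols(tibble::as_tibble(as.list(s$par)),
                     tibble::tibble(G = s$G, n_cost_evals = s$n_cost_evals,
                                    restart = s$restart))
  })
  structure(list(solutions = solutions, configs = configs, bounds = bounds,
                 seed = as.integer(seed), exhausted = exhausted,
                 n_steps_final = n_steps_final,
                 n_strips_final = n_strips_final),
            class = "trim_result")
}

#' @export
print.trim_result <- function(x, ...) {
  cat(sprintf("<trim_result> %d solution(s), seed %d%s\n",
              nrow(x$solutions), x$seed,
              if (x$exhausted) " (restart budget exhausted)" else ""))
  if (nrow(x$solutions) > 0) {
    cat(sprintf("  G range: %.2e .. %.2e\n",
                min(x$solutions$G), max(x$solutions$G)))
  }
  invisible(x)
}

#' @export
tidy.trim_result <- function(x, ...) x$solutions

#' @export
glance.trim_result <- function(x, ...) {
  tibble::tibble(n_solutions = nrow(x$solutions),
                 G_min = if (nrow(x$solutions)) min(x$solutions$G) else NA_real_,
                 G_max = if (nrow(x$solutions)) max(x$solutions$G) else NA_real_,
                 exhausted = x$exhausted, seed = x$seed)
}

#' Write trim solutions to CSV
#'
#' One row per solution: the 14 parameters, the residual `G`, the seed.
#'
#' @param trim A [search_trim()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trim_solutions <- function(trim, path) {
  stopifnot(inherits(trim, "trim_result"))
  tab <- trim$solutions
  tab$seed <- trim$seed
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read trim solutions written by [write_trim_solutions()]
#'
#' @param path CSV path.
#' @return A tibble of solutions.
#' @export
read_trim_solutions <- function(path) {
  if (!file.exists(path)) {
    stop("trim solutions file not found: ", path, call. = FALSE)
  }
  tab <- tibble::as_tibble(utils::read.csv(path))
  missing <- setdiff(TRIM_PARAMS, names(tab))
  if (length(missing) > 0) {
    stop("trim solutions file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}
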