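#' Periodic kinematic parameter as a truncated Fourier series
#'
#' A `fourier_waveform` stores one periodic kinematic parameter -- a wing or
#' body angle in degrees, or a velocity component in m/s -- as a mean plus
#' `K` harmonics of the wingbeat frequency:
#' \deqn{y(t) = a_0 + \sum_{k=1}^{K} a_k \cos(2\pi k f t) + b_k \sin(2\pi k f t)}
#' Third order (`K = 3`) is the default because it captures measured moth
#' wingstroke waveforms without over-fitting.
#'
#' @param a0 Mean value (units of the parameter).
#' @param a,b Numeric vectors of cosine and sine coefficients, one per
#'   harmonic. Padded with zeros to a common length.
#' @param f Wingbeat frequency in Hz.
#' @param K Number of harmonics kept (default 3, or longer if `a`/`b` are).
#' @return An object of class `fourier_waveform`.
#' @export
#' @examples
#' wf <- fourier_waveform(a0 = 10, a = c(5, 0, 1), f = 20)
#' eval_waveform(wf, c(0, 0.01))
fourier_waveform <- function(a0 = 0, a = numeric(), b = numeric(), f, K = max(3L, length(a), length(b))) {
  stopifnot(is.numeric(a0), length(a0) == 1L, is.finite(a0))
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f <= 0) {
    stop("`f` must be a single positive wingbeat frequency in Hz", call. = FALSE)
  }
  K <- as.integer(K)
  a <- c(a, numeric(max(0L, K - length(a))))[seq_len(K)]
  b <- c(b, numeric(max(0L, K - length(b))))[seq_len(K)]
  structure(list(a0 = a0, a = a, b = b, f = f, K = K),
            class = "fourier_waveform")
}

#' @export
print.fourier_waveform <- function(x, ...) {
  st <- waveform_stats(x)
  cat(sprintf("<fourier_waveform> f = %g Hz, K = %d, mean = %.4g, amplitude = %.4g\n",
              x$f, x$K, st$mean, st$amplitude))
  invisible(x)
}

is_fourier_waveform <- function(x) inherits(x, "fourier_waveform")

#' Evaluate a Fourier waveform or its analytic time derivatives
#'
#' Derivatives are taken analytically on the series, never by finite
#' differencing, so rates used in the aerodynamic model are exact for the
#' represented waveform.
#'
#' @param wf A [fourier_waveform()].
#' @param t Time(s) in seconds; may be a numeric vector (complex values are
#'   supported so the aerodynamic core can use complex-step differentiation).
#' @param deriv 0 for the value, 1 or 2 for the first or second time
#'   derivative.
#' @return Numeric vector the length of `t`, in parameter units (per s, per
#'   s^2 for derivatives).
#' @export
eval_waveform <- function(wf, t, deriv = 0L) {
  stopifnot(is_fourier_waveform(wf))
  if (!deriv %in% 0:2) stop("`deriv` must be 0, 1 or 2", call. = FALSE)
  w <- 2 * pi * wf$f
  out <- if (deriv == 0L) rep(wf$a0 + 0 * t[1], length(t)) else rep(0 * t[1], length(t))
  for (k in seq_len(wf$K)) {
    ak <- wf$a[k]; bk <- wf$b[k]
    if (ak == 0 && bk == 0) next
    wk <- k * w
    th <- wk * t
    out <- out + switch(as.character(deriv),
      "0" = ak * cos(th) + bk * sin(th),
      "1" = wk * (-ak * sin(th) + bk * cos(th)),
      "2" = -wk^2 * (ak * cos(th) + bk * sin(th)))
  }
  out
}

#' Mean and peak-to-peak amplitude of a waveform
#'
#' The mean is the arithmetic average over one period (which for a Fourier
#' series is exactly `a0`); the amplitude is the difference between the
#' maximum and minimum of the waveform over one period, located on a dense
#' grid and refined by local univariate optimisation so the result is
#' accurate to ~1e-9 of the amplitude.
#'
#' @param wf A [fourier_waveform()].
#' @param n_grid Number of grid points per period used to bracket the
#'   extrema (>= 256).
#' @return A list with elements `mean` and `amplitude`.
#' @export
waveform_stats <- function(wf, n_grid = 2048L) {
  stopifnot(is_fourier_waveform(wf))
  if (n_grid < 256L) stop("`n_grid` must be at least 256", call. = FALSE)
  if (all(wf$a == 0) && all(wf$b == 0)) {
    return(list(mean = wf$a0, amplitude = 0))
  }
  T0 <- 1 / wf$f
  tg <- seq(0, T0, length.out = n_grid + 1L)[-(n_grid + 1L)]
  y <- eval_waveform(wf, tg)
  h <- T0 / n_grid
  refine <- function(i, maximum) {
    lo <- tg[i] - h
    hi <- tg[i] + h
    opt <- stats::optimize(function(t) eval_waveform(wf, t), c(lo, hi),
                           maximum = maximum, tol = .Machine$double.eps^0.5 * T0)
    if (maximum) opt$objective else opt$objective
  }
  ymax <- refine(which.max(y), TRUE)
  ymin <- refine(which.min(y), FALSE)
  list(mean = wf$a0, amplitude = ymax - ymin)
}

#' Rescale a waveform to a new mean and amplitude, preserving its shape
#'
#' All harmonic coefficients are scaled by a common factor so the ratio
#' between harmonics (the waveform "shape") is unchanged; only the mean and
#' the peak-to-peak amplitude are adjusted. This is how a trim search moves
#' a measured waveform through the parameter space while keeping the
#' character of the motion.
#'
#' @param wf A [fourier_waveform()].
#' @param new_mean Target mean value.
#' @param new_amplitude Target peak-to-peak amplitude (max minus min).
#' @return A rescaled [fourier_waveform()].
#' @export
rescale_waveform <- function(wf, new_mean, new_amplitude) {
  stopifnot(is_fourier_waveform(wf))
  if (new_amplitude < 0) stop("`new_amplitude` must be non-negative", call. = FALSE)
  if (new_amplitude == 0) {
    return(fourier_waveform(a0 = new_mean, f = wf$f, K = wf$K))
  }
  amp <- waveform_stats(wf)$amplitude
  if (amp == 0) {
    stop("cannot rescale a zero-amplitude waveform to a nonzero amplitude",
         call. = FALSE)
  }
  s <- new_amplitude / amp
  fourier_waveform(a0 = new_mean, a = wf$a * s, b = wf$b * s, f = wf$f, K = wf$K)
}

#' Shift a waveform in time
#'
#' `shift_waveform(wf, dt)` returns the waveform evaluated at `t - dt`.
#' A half-period shift (`dt = 1/(2 f)`) flips the sign of every odd
#' harmonic, which phase-shifts the fundamental by 180 degrees; this is how
#' the antiphase body-kinematics configuration is built.
#'
#' @param wf A [fourier_waveform()].
#' @param dt Time shift in seconds.
#' @return A [fourier_waveform()].
#' @export
shift_waveform <- function(wf, dt) {
  stopifnot(is_fourier_waveform(wf))
  a <- wf$a; b <- wf$b
  for (k in seq_len(wf$K)) {
    ph <- 2 * pi * k * wf$f * dt
    # y(t - dt): cos(th - ph), sin(th - ph)
    a_new <- wf$a[k] * cos(ph) - wf$b[k] * sin(ph)
    b_new <- wf$a[k] * sin(ph) + wf$b[k] * cos(ph)
    a[k] <- a_new; b[k] <- b_new
  }
  fourier_waveform(a0 = wf$a0, a = a, b = b, f = wf$f, K = wf$K)
}

#' Change the frequency of a waveform keeping its shape
#'
#' The time base is rescaled so the waveform traces the same values over the
#' new period. Coefficients are unchanged; only `f` moves.
#'
#' @param wf A [fourier_waveform()].
#' @param new_f New wingbeat frequency in Hz.
#' @return A [fourier_waveform()].
#' @export
retime_waveform <- function(wf, new_f) {
  fourier_waveform(a0 = wf$a0, a = wf$a, b = wf$b, f = new_f, K = wf$K)
}

#' Least-squares Fourier fit of sampled periodic data
#'
#' Fits the order-`K` Fourier series at a known wingbeat frequency by linear
#' least squares on the design matrix of harmonic regressors. With at least
#' `2K + 1` samples spanning a period the normal equations are well posed
#' and the residual sum of squares is minimal over all order-`K` series.
#'
#' @param t Sample times in seconds.
#' @param y Sample values (parameter units).
#' @param f Wingbeat frequency in Hz.
#' @param K Series order (default 3).
#' @return A [fourier_waveform()].
#' @export
fit_fourier <- function(t, y, f, K = 3L) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  K <- as.integer(K)
  if (length(t) < 2L * K + 1L) {
    stop(sprintf("underdetermined fit: need at least %d samples for order %d",
                 2L * K + 1L, K), call. = FALSE)
  }
  X <- matrix(1, nrow = length(t), ncol = 2L * K + 1L)
  for (k in seq_len(K)) {
    th <- 2 * pi * k * f * t
    X[, 2L * k] <- cos(th)
    X[, 2L * k + 1L] <- sin(th)
  }
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  fourier_waveform(a0 = beta[1L], a = beta[2L * seq_len(K)],
                   b = beta[2L * seq_len(K) + 1L], f = f, K = K)
}

#' Phase difference between the fundamentals of two waveforms
#'
#' Each waveform's first harmonic is written as
#' \eqn{A \cos(2\pi f t - \delta)} with \eqn{\delta = \mathrm{atan2}(b_1, a_1)};
#' the phase difference is \eqn{\delta_b - \delta_a} reported in
#' \eqn{[0, 360)} degrees. With this convention
#' `phase_difference(cos, sin)` is 90 degrees (the second waveform lags the
#' first by a quarter period), and shifting either waveform by half a period
#' moves the difference by 180 degrees. The result is invariant to
#' amplitude rescaling of either waveform.
#'
#' @param wf_a,wf_b [fourier_waveform()] objects with nonzero fundamentals.
#' @return Phase difference in degrees, in `[0, 360)`.
#' @export
phase_difference <- function(wf_a, wf_b) {
  stopifnot(is_fourier_waveform(wf_a), is_fourier_waveform(wf_b))
  for (wf in list(wf_a, wf_b)) {
    if (wf$a[1] == 0 && wf$b[1] == 0) {
      stop("undefined phase: waveform has a zero fundamental harmonic",
           call. = FALSE)
    }
  }
  d <- atan2(wf_b$b[1], wf_b$a[1]) - atan2(wf_a$b[1], wf_a$a[1])
  (d * 180 / pi) %% 360
}

#' Antiderivative of a waveform (position from velocity)
#'
#' Returns a function of time giving the running integral of the waveform
#' from 0: the mean contributes a linear drift `a0 * t` and each harmonic
#' integrates in closed form. Used to place the centre of mass when
#' synthesising landmark tracks from body-velocity waveforms.
#'
#' @param wf A [fourier_waveform()].
#' @return A function `function(t)` returning the integral from 0 to `t`.
#' @export
integrate_waveform <- function(wf) {
  stopifnot(is_fourier_waveform(wf))
  force(wf)
  function(t) {
    out <- wf$a0 * t
    for (k in seq_len(wf$K)) {
      wk <- 2 * pi * k * wf$f
      if (wf$a[k] != 0) out <- out + wf$a[k] * sin(wk * t) / wk
      if (wf$b[k] != 0) out <- out + wf$b[k] * (1 - cos(wk * t)) / wk
    }
    out
  }
}

#' @export
tidy.fourier_waveform <- function(x, ...) {
  tibble::tibble(
    term = c("a0", paste0("a", seq_len(x$K)), paste0("b", seq_len(x$K))),
    estimate = c(x$a0, x$a, x$b)
  )
}

#' @export
glance.fourier_waveform <- function(x, ...) {
  st <- waveform_stats(x)
  tibble::tibble(f_hz = x$f, K = x$K, mean = st$mean, amplitude = st$amplitude)
}
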