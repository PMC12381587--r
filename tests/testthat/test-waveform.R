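test_that("evaluation matches the series definition and its analytic derivatives", {
  f <- 17
  wf <- fourier_waveform(a0 = 5, a = c(2, 0, -0.5), b = c(0, 1, 0.3), f = f)
  t <- seq(0, 1 / f, length.out = 11)
  direct <- 5 +
    2 * cos(2 * pi * f * t) - 0.5 * cos(6 * pi * f * t) +
    1 * sin(4 * pi * f * t) + 0.3 * sin(6 * pi * f * t)
  expect_equal(eval_waveform(wf, t), direct, tolerance = 1e-14)

  # constants: value everywhere, zero derivatives
  cw <- fourier_waveform(a0 = 5, f = f)
  expect_equal(eval_waveform(cw, c(0, 0.013)), c(5, 5))
  expect_equal(eval_waveform(cw, 0.1, deriv = 1), 0)

  # second derivative of the cosine fundamental at t = 0
  cosw <- fourier_waveform(0, a = c(3), f = f)
  expect_equal(eval_waveform(cosw, 0, deriv = 2), -(2 * pi * f)^2 * 3)

  # periodicity
  t0 <- 0.0123
  expect_equal(eval_waveform(wf, t0), eval_waveform(wf, t0 + 1 / f),
               tolerance = 1e-12)

  # derivative identities against complex-step differentiation
  h <- 1e-9
  expect_equal(eval_waveform(wf, t0, deriv = 1),
               Im(eval_waveform(wf, t0 + 1i * h)) / h, tolerance = 1e-9)
})

test_that("least-squares fit recovers exact series and matches the normal equations", {
  f <- 9
  wf <- fourier_waveform(a0 = 1.5, a = c(2, -1, 0.25), b = c(0.5, 0.7, -0.2),
                         f = f)
  t <- seq(0, 1 / f, length.out = 41)[-41]
  y <- eval_waveform(wf, t)
  fit <- fit_fourier(t, y, f)
  expect_equal(fit$a0, wf$a0, tolerance = 1e-10)
  expect_equal(fit$a, wf$a, tolerance = 1e-10)
  expect_equal(fit$b, wf$b, tolerance = 1e-10)

  # constant data
  cfit <- fit_fourier(t, rep(3, length(t)), f)
  expect_equal(cfit$a0, 3)
  expect_equal(cfit$a, rep(0, 3), tolerance = 1e-12)

  # noisy data: coefficients equal an independent normal-equations solve
  set.seed(42)
  yn <- y + rnorm(length(y), sd = 0.3)
  fitn <- fit_fourier(t, yn, f)
  X <- cbind(1, cos(2 * pi * f * t), sin(2 * pi * f * t),
             cos(4 * pi * f * t), sin(4 * pi * f * t),
             cos(6 * pi * f * t), sin(6 * pi * f * t))
  beta <- solve(crossprod(X), crossprod(X, yn))
  expect_equal(c(fitn$a0, fitn$a[1], fitn$b[1], fitn$a[2], fitn$b[2],
                 fitn$a[3], fitn$b[3]),
               drop(beta), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(fit_fourier(t[1:5], y[1:5], f), "underdetermined")
})

test_that("waveform stats: mean and refined peak-to-peak amplitude", {
  f <- 11
  # A cos + m -> (m, 2A)
  wf <- fourier_waveform(a0 = 2, a = c(3), f = f)
  st <- waveform_stats(wf)
  expect_equal(st$mean, 2)
  expect_equal(st$amplitude, 6, tolerance = 1e-9)

  cw <- fourier_waveform(a0 = 4, f = f)
  expect_equal(waveform_stats(cw), list(mean = 4, amplitude = 0))

  # two-harmonic waveform against a 1e6-point brute-force scan
  wf2 <- fourier_waveform(a0 = 1, a = c(2, 0.8), b = c(0.3, -1.1), f = f)
  tg <- seq(0, 1 / f, length.out = 1e6 + 1)[-(1e6 + 1)]
  y <- eval_waveform(wf2, tg)
  expect_equal(waveform_stats(wf2)$amplitude, max(y) - min(y),
               tolerance = 1e-6)
})

test_that("rescaling preserves shape and hits the target stats exactly", {
  f <- 14
  wf <- fourier_waveform(a0 = 7, a = c(2, 0.5, 0.1), b = c(-1, 0.2, 0), f = f)
  st <- waveform_stats(wf)
  same <- rescale_waveform(wf, st$mean, st$amplitude)
  expect_equal(same$a, wf$a, tolerance = 1e-12)
  expect_equal(same$b, wf$b, tolerance = 1e-12)

  rs <- rescale_waveform(wf, -3, 12)
  strs <- waveform_stats(rs)
  expect_equal(strs$mean, -3, tolerance = 1e-9)
  expect_equal(strs$amplitude, 12, tolerance = 1e-9)
  # harmonic ratios unchanged
  expect_equal(rs$a / rs$a[1], wf$a / wf$a[1], tolerance = 1e-12)

  # amplitude = 2 |a1| for a pure cosine: rescale to amplitude 10 -> a1 = 5
  cosw <- fourier_waveform(0, a = c(2), f = f)
  expect_equal(rescale_waveform(cosw, 0, 10)$a[1], 5, tolerance = 1e-9)

  flat <- rescale_waveform(wf, 1, 0)
  expect_equal(waveform_stats(flat), list(mean = 1, amplitude = 0))
  expect_error(rescale_waveform(flat, 0, 5), "zero-amplitude")
})

test_that("phase differences follow the atan2 convention on fundamentals", {
  f <- 8
  wcos <- fourier_waveform(0, a = c(1), f = f)
  wsin <- fourier_waveform(0, b = c(1), f = f)
  expect_equal(phase_difference(wcos, wsin), 90)
  expect_equal(phase_difference(wcos, wcos), 0)
  expect_equal(phase_difference(wcos, shift_waveform(wcos, 1 / (2 * f))), 180)
  # invariance to amplitude rescaling of either input
  wf <- fourier_waveform(0, a = c(2, 0.3), b = c(1, -0.2), f = f)
  wg <- fourier_waveform(0, a = c(-1, 0.1), b = c(0.5, 0.4), f = f)
  d0 <- phase_difference(wf, wg)
  expect_equal(phase_difference(rescale_waveform(wf, 5, 17), wg), d0,
               tolerance = 1e-9)
  expect_equal(phase_difference(wf, rescale_waveform(wg, -2, 0.01)), d0,
               tolerance = 1e-9)
  expect_error(phase_difference(fourier_waveform(1, f = f), wf),
               "zero fundamental")
})

test_that("time shifting and retiming act on coefficients as expected", {
  f <- 10
  wf <- fourier_waveform(2, a = c(1, 0.5, 0.2), b = c(0.3, -0.4, 0.1), f = f)
  sh <- shift_waveform(wf, 1 / (2 * f))
  # odd harmonics flip under a half-period shift
  expect_equal(sh$a, wf$a * c(-1, 1, -1), tolerance = 1e-12)
  expect_equal(sh$b, wf$b * c(-1, 1, -1), tolerance = 1e-12)
  # double shift is the identity
  sh2 <- shift_waveform(sh, 1 / (2 * f))
  expect_equal(sh2$a, wf$a, tolerance = 1e-12)
  # generic shift: y_shifted(t) == y(t - dt)
  dt <- 0.0173
  t <- c(0, 0.01, 0.05)
  expect_equal(eval_waveform(shift_waveform(wf, dt), t),
               eval_waveform(wf, t - dt), tolerance = 1e-12)
  # retiming keeps the amplitude
  expect_equal(waveform_stats(retime_waveform(wf, 2 * f))$amplitude,
               waveform_stats(wf)$amplitude, tolerance = 1e-12)
})

test_that("integration returns the running antiderivative", {
  f <- 6
  wf <- fourier_waveform(1.2, a = c(0.5), b = c(-0.3), f = f)
  Fint <- integrate_waveform(wf)
  expect_equal(Fint(0), 0)
  # against numerical quadrature
  val <- stats::integrate(function(s) eval_waveform(wf, s), 0, 0.21,
                          rel.tol = 1e-12)$value
  expect_equal(Fint(0.21), val, tolerance = 1e-9)
})
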