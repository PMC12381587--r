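# Fixtures are built in code at test time; nothing is read from disk
# except the package's own extdata.

# rectangular wing, fixed feathering, steady forward translation:
# the configuration whose total lift/drag has a closed form
steady_rect_config <- function(alpha_deg = 45, V = 2, chord = 0.02, R = 0.1,
                               f = 20, mt = 0.002, wing_mass = 1e-4) {
  wing <- build_strips(function(r) rep(chord, length(r)), R = R,
                       wing_mass = wing_mass)
  const <- function(v) fourier_waveform(a0 = v, f = f)
  wk <- wing_kinematics(phi = const(0), theta = const(0),
                        alpha = const(alpha_deg), beta = const(0),
                        beta_r = 0)
  bk <- body_kinematics(chi = const(0), u = const(V), w = const(0))
  moth_config(wing, wk, bk, mt = mt)
}

# flapping moth-like configuration with hand-picked waveforms (constant
# stroke plane available for exact landmark round trips)
flapping_config <- function(f = 13, theta_a = 18, beta_a = 0, beta_m = 65,
                            beta_r = 2, seed_shape = FALSE) {
  mk <- function(m, a, ph) {
    rescale_waveform(
      fourier_waveform(0, a = c(cos(ph * pi / 180), 0.1, 0.02),
                       b = c(sin(ph * pi / 180), 0.05, -0.03), f = f),
      m, a)
  }
  beta <- if (beta_a == 0) fourier_waveform(beta_m, f = f) else
    mk(beta_m, beta_a, -60)
  theta <- if (theta_a == 0) fourier_waveform(0, f = f) else
    mk(0, theta_a, 200)
  wk <- wing_kinematics(phi = mk(15, 110, 0), theta = theta,
                        alpha = mk(85, 40, 95), beta = beta,
                        beta_r = beta_r)
  bk <- body_kinematics(chi = mk(25, 22, -60), u = mk(2.5, 0.5, 120),
                        w = mk(0, 0.9, 30))
  morph <- synthetic_wing(seed = 1, wing_mass = 1e-4,
                          hinge_offset = c(0.004, -0.006, 0.003))
  moth_config(morph, wk, bk, mt = 0.0015)
}

# near-trim moths are expensive to construct; cache per seed for the session
.near_trim_cache <- new.env(parent = emptyenv())
cached_near_trim <- function(seed) {
  key <- as.character(seed)
  if (is.null(.near_trim_cache[[key]])) {
    .near_trim_cache[[key]] <- synth_moth(synth_spec(seed = seed),
                                          near_trim = TRUE)
  }
  .near_trim_cache[[key]]
}
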