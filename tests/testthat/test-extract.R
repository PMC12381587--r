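test_that("noiseless landmarks round-trip to the generating angles", {
  # zero deviation and constant stroke plane make the stroke-plane
  # decomposition unambiguous, so extraction must be exact
  cfg <- flapping_config(theta_a = 0, beta_a = 0, beta_m = 65, beta_r = 2)
  sp <- synth_spec(seed = 2, noise_sd = 0, n_strokes = 3)
  trk <- synth_landmarks(cfg, sp)
  kin <- extract_kinematics(trk)
  t <- kin$t_s
  expect_lt(max(abs(kin$chi_deg - eval_waveform(cfg$body_kin$chi, t))), 1e-6)
  expect_lt(max(abs(kin$phi_deg - eval_waveform(cfg$wing_kin$phi, t))), 1e-6)
  expect_lt(max(abs(kin$theta_deg)), 1e-6)
  expect_lt(max(abs(kin$alpha_deg - eval_waveform(cfg$wing_kin$alpha, t))),
            1e-6)
  expect_lt(max(abs(kin$beta_deg - 65)), 1e-6)
  expect_lt(max(abs(kin$betar_deg - 2)), 1e-6)
  expect_lt(max(abs(kin$u_ms - eval_waveform(cfg$body_kin$u, t))), 1e-3)
  expect_lt(max(abs(kin$w_ms - eval_waveform(cfg$body_kin$w, t))), 1e-3)
  expect_equal(attr(kin, "f_hz"), cfg$f, tolerance = 1e-4)

  # Fourier refit recovers the generating coefficients
  refit <- fit_fourier(t, kin$phi_deg, cfg$f)
  expect_equal(refit$a, cfg$wing_kin$phi$a, tolerance = 1e-10)
  expect_equal(refit$b, cfg$wing_kin$phi$b, tolerance = 1e-10)
})

test_that("degenerate geometries are recognised", {
  cfg <- flapping_config()
  trk <- synth_landmarks(cfg, synth_spec(seed = 3, noise_sd = 0))
  # body axis horizontal -> chi = 0
  pts <- trk$points
  flat <- pts
  flat$z_m[flat$point %in% c("head", "abdomen_tip")] <-
    mean(flat$z_m[flat$point == "thorax_abdomen"])
  trk_flat <- structure(list(points = flat, frame_rate = trk$frame_rate),
                        class = "landmark_track")
  kin <- extract_kinematics(trk_flat, f = cfg$f)
  expect_lt(max(abs(kin$chi_deg)), 1e-6)

  # collinear wingtip path -> no stroke plane
  bad <- pts
  sel_tip <- bad$point == "wingtip_R"
  sel_h <- bad$point == "hinge_R"
  bad$x_m[sel_tip] <- bad$x_m[sel_h] + seq_len(sum(sel_tip)) * 1e-4
  bad$y_m[sel_tip] <- bad$y_m[sel_h]
  bad$z_m[sel_tip] <- bad$z_m[sel_h]
  trk_bad <- structure(list(points = bad, frame_rate = trk$frame_rate),
                       class = "landmark_track")
  expect_error(extract_kinematics(trk_bad, f = cfg$f), "collinear")
})

test_that("wingtip path in the horizontal plane through the hinge gives beta = 0", {
  cfg <- flapping_config(theta_a = 0, beta_a = 0, beta_m = 0, beta_r = 0)
  trk <- synth_landmarks(cfg, synth_spec(seed = 4, noise_sd = 0))
  kin <- extract_kinematics(trk)
  expect_lt(max(abs(kin$beta_deg)), 1e-6)
})

test_that("tracking noise degrades angle recovery roughly in proportion", {
  cfg <- flapping_config(theta_a = 0, beta_a = 0)
  rms <- vapply(c(1e-4, 2e-4), function(sd) {
    sp <- synth_spec(seed = 11, noise_sd = sd, n_strokes = 3)
    trk <- synth_landmarks(cfg, sp)
    kin <- extract_kinematics(trk, f = cfg$f)
    sqrt(mean((kin$phi_deg - eval_waveform(cfg$wing_kin$phi, kin$t_s))^2))
  }, numeric(1))
  expect_gt(rms[2] / rms[1], 1.3)   # doubling the noise roughly doubles
  expect_lt(rms[2] / rms[1], 3.2)   # the recovery error
})

test_that("landmark tracks round-trip through CSV", {
  dir <- withr::local_tempdir()
  cfg <- flapping_config()
  trk <- synth_landmarks(cfg, synth_spec(seed = 6, n_strokes = 1))
  path <- file.path(dir, "landmarks.csv")
  write_landmarks(trk, path)
  back <- read_landmarks(path)
  expect_equal(back$frame_rate, trk$frame_rate)
  expect_equal(back$points$x_m, trk$points$x_m, tolerance = 1e-12)
  expect_equal(sort(unique(back$points$point)),
               sort(unique(trk$points$point)))
  expect_error(read_landmarks(file.path(dir, "nope.csv")), "nope.csv")
})
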