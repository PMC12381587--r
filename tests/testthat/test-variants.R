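test_that("variant construction: identities and wing-waveform preservation", {
  cfg <- flapping_config(beta_a = 10)

  # model 2 of an oscillation-free base is the base itself
  th <- trim_parameters(cfg)
  th[c("chi_a", "beta_a")] <- 0
  still <- apply_parameters(cfg, th)
  still$body_kin$u <- fourier_waveform(2.5, f = cfg$f)
  still$body_kin$w <- fourier_waveform(0, f = cfg$f)
  m2 <- make_variant(still, "model2")
  t <- seq(0, 1 / cfg$f, length.out = 100)
  f1 <- total_aero(still, t); f2 <- total_aero(m2, t)
  expect_equal(f2$Fx_N, f1$Fx_N, tolerance = 1e-12)
  expect_equal(f2$Fz_N, f1$Fz_N, tolerance = 1e-12)

  # two half-period shifts restore the base
  m3 <- make_variant(cfg, "model3")
  m33 <- make_variant(m3, "model3")
  expect_equal(m33$body_kin$chi$a, cfg$body_kin$chi$a, tolerance = 1e-12)
  expect_equal(m33$body_kin$w$b, cfg$body_kin$w$b, tolerance = 1e-12)
  expect_equal(m33$wing_kin$beta$a, cfg$wing_kin$beta$a, tolerance = 1e-12)

  # the antiphase model moves the body-pitch phase by 180 degrees
  ph1 <- phase_difference(cfg$body_kin$chi, cfg$wing_kin$phi)
  ph3 <- phase_difference(m3$body_kin$chi, m3$wing_kin$phi)
  expect_equal((ph3 - ph1) %% 360, 180, tolerance = 1e-9)

  # wing angle waveforms are never altered by any variant
  for (tag in c("model2", "model3", "model1a", "model1b")) {
    v <- make_variant(cfg, tag)
    for (wf in c("phi", "theta", "alpha")) {
      expect_identical(v$wing_kin[[wf]]$a, cfg$wing_kin[[wf]]$a)
      expect_identical(v$wing_kin[[wf]]$b, cfg$wing_kin[[wf]]$b)
    }
  }

  # intermediate models flatten only their targeted waveforms
  m1a <- make_variant(cfg, "model1a")
  expect_equal(waveform_stats(m1a$body_kin$chi)$amplitude, 0)
  expect_gt(waveform_stats(m1a$body_kin$u)$amplitude, 0)
  m1b <- make_variant(cfg, "model1b")
  expect_equal(waveform_stats(m1b$body_kin$u)$amplitude, 0)
  expect_gt(waveform_stats(m1b$body_kin$chi)$amplitude, 0)
  m1a_keep <- make_variant(cfg, "model1a", flatten_beta = FALSE)
  expect_gt(waveform_stats(m1a_keep$wing_kin$beta)$amplitude, 0)

  expect_error(make_variant(cfg, "model9"), "unknown model tag")
})

test_that("performance metrics: lift-to-drag ratio from coefficient means", {
  # fixed 45 deg angle of attack throughout: LD equals CL(45)/CD(45)
  cfg <- steady_rect_config(alpha_deg = 45, V = 2)
  res <- simulate_wingstroke(cfg, n_steps = 50, detail = TRUE)
  pm <- performance_metrics(res)
  cd <- lift_drag_coeffs(45)
  expect_equal(pm$LD_ratio, cd$CL / cd$CD, tolerance = 1e-9)
  # constant series: peak equals mean
  expect_equal(pm$P_peak_W, pm$P_mean_W, tolerance = 1e-9)
  # doubling kL doubles the ratio
  cfg2 <- steady_rect_config(alpha_deg = 45, V = 2)
  cfg2$kL <- 2
  pm2 <- performance_metrics(simulate_wingstroke(cfg2, n_steps = 50))
  expect_equal(pm2$LD_ratio, 2 * pm$LD_ratio, tolerance = 1e-9)
})

test_that("variant comparison ratios are invariant to air density", {
  cfg <- flapping_config(beta_a = 10)
  cmp1 <- compare_variants(cfg, n_steps = 200)
  cfg2 <- cfg; cfg2$rho <- 2 * cfg$rho
  cmp2 <- compare_variants(cfg2, n_steps = 200)
  expect_equal(cmp1$P_ratio, cmp2$P_ratio, tolerance = 1e-12)
  expect_equal(cmp1$F_ratio, cmp2$F_ratio, tolerance = 1e-12)
  expect_equal(cmp1$P_ratio[cmp1$variant == "model1"], 1)
  expect_error(compare_variants(cfg, tags = c("model2", "model3")),
               "model1")
})

test_that("correlations of body-pitch amplitude against frequency and wing loading", {
  # exact proportionality to 1/f
  d <- tibble::tibble(f_hz = c(8, 12, 16, 24),
                      Ws_m2_kg = c(3, 3, 3, 3) + c(0.1, -0.1, 0.2, 0),
                      chi_a_deg = 240 / c(8, 12, 16, 24))
  rr <- oscillation_correlations(d)
  expect_equal(rr$r[rr$predictor == "inv_f"], 1, tolerance = 1e-12)

  # exact anti-proportionality
  d2 <- d; d2$chi_a_deg <- -2 * d$Ws_m2_kg + 10
  rr2 <- oscillation_correlations(d2)
  expect_equal(rr2$r[rr2$predictor == "Ws"], -1, tolerance = 1e-12)

  expect_error(oscillation_correlations(d[1:2, ]), "at least 3")
  d3 <- d; d3$chi_a_deg <- rep(5, 4)
  expect_error(oscillation_correlations(d3), "zero variance")
})
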