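test_that("trim residual formula at reference force/moment combinations", {
  mk <- function(Fx, Fz, My, mt = 0.002, g = 9.81, r2 = 0.05) {
    trim_cost(list(averages = list(Fx_N = Fx, Fz_N = Fz, My_Nm = My)),
              mt = mt, g = g, r2 = r2)
  }
  mg <- 0.002 * 9.81
  expect_equal(mk(0, mg, 0), 0)       # perfect trim
  expect_equal(mk(0, 0, 0), 1)        # unsupported weight
  expect_equal(mk(mg, 2 * mg, 0), 2)  # thrust and double weight support
  expect_equal(mk(0, mg, mg * 0.05 * 0.5), 0.25)
  expect_error(mk(0, 0, 0, r2 = -1), "positive")
})

test_that("applying a parameter vector rescales waveforms as requested", {
  cfg <- flapping_config(beta_a = 10)
  th <- trim_parameters(cfg)
  same <- apply_parameters(cfg, th)
  # identity: waveform values agree everywhere
  t <- seq(0, 1 / cfg$f, length.out = 40)
  expect_equal(eval_waveform(same$wing_kin$phi, t),
               eval_waveform(cfg$wing_kin$phi, t), tolerance = 1e-9)
  expect_equal(eval_waveform(same$body_kin$chi, t),
               eval_waveform(cfg$body_kin$chi, t), tolerance = 1e-9)
  expect_equal(same$kL, cfg$kL)

  # flattening the body pitch gives a constant waveform
  th0 <- th; th0[["chi_a"]] <- 0
  flat <- apply_parameters(cfg, th0)
  expect_equal(waveform_stats(flat$body_kin$chi)$amplitude, 0)

  # doubling f halves the period of every waveform
  th2 <- th; th2[["f"]] <- 2 * th[["f"]]
  fast <- apply_parameters(cfg, th2)
  expect_equal(fast$f, 2 * cfg$f)
  t0 <- 0.0137
  expect_equal(eval_waveform(fast$wing_kin$alpha, t0),
               eval_waveform(fast$wing_kin$alpha, t0 + 1 / (2 * cfg$f)),
               tolerance = 1e-9)
  # requested stats are achieved exactly
  st <- waveform_stats(fast$wing_kin$phi)
  expect_equal(st$mean, th[["phi_m"]], tolerance = 1e-9)
  expect_equal(st$amplitude, th[["phi_a"]], tolerance = 1e-9)
})

test_that("bounds tables validate, order parameters, and round-trip via CSV", {
  b <- silkmoth_bounds("A_luna")
  expect_equal(b$parameter, wingbeat:::TRIM_PARAMS)
  expect_true(all(b$min <= b$trim & b$trim <= b$max + 0.02 * (b$max - b$min)))
  full <- silkmoth_bounds()
  expect_setequal(unique(full$species),
                  c("A_io", "A_luna", "A_polyphemus", "H_euryalus"))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bounds.csv")
  utils::write.csv(as.data.frame(b[1:3]), path, row.names = FALSE)
  back <- trim_bounds(utils::read.csv(path))
  expect_equal(back$min, b$min)
  shuffled <- b[sample(nrow(b)), 1:3]
  expect_equal(trim_bounds(shuffled)$parameter, wingbeat:::TRIM_PARAMS)
  expect_error(trim_bounds(b[-1, 1:3]), "missing parameters")
})

test_that("multi-start search recovers a constructed equilibrium deterministically", {
  cfg <- cached_near_trim(5)
  nb <- attr(cfg, "near_trim_bounds")
  tr <- search_trim(cfg, nb, n_solutions = 2L, tol = 1e-6, seed = 21L,
                    max_restarts = 10L)
  expect_gte(nrow(tr$solutions), 1L)
  expect_true(all(tr$solutions$G <= 1e-6))

  # all parameters within bounds
  lo <- stats::setNames(nb$min, nb$parameter)
  hi <- stats::setNames(nb$max, nb$parameter)
  for (i in seq_len(nrow(tr$solutions))) {
    th <- unlist(tr$solutions[i, wingbeat:::TRIM_PARAMS])
    expect_true(all(th >= lo - 1e-9 & th <= hi + 1e-9))
  }

  # re-simulating a returned solution reproduces its stored residual
  th1 <- unlist(tr$solutions[1, wingbeat:::TRIM_PARAMS])
  cfg1 <- apply_parameters(cfg, th1)
  cfg1$morph <- reduce_morphology(cfg1$morph, tr$n_strips_final)
  res <- simulate_wingstroke(cfg1, n_steps = tr$n_steps_final, detail = FALSE)
  expect_equal(trim_cost(res), tr$solutions$G[1], tolerance = 1e-10)
  # weight support at the solution
  expect_equal(res$averages$Fz_N / (cfg$mt * cfg$g), 1, tolerance = 1e-3)

  # determinism: same seed, same solutions
  tr2 <- search_trim(cfg, nb, n_solutions = 2L, tol = 1e-6, seed = 21L,
                     max_restarts = 10L)
  expect_equal(tr$solutions, tr2$solutions, tolerance = 1e-14)

  # solutions are pairwise distinct under the bound-normalised metric
  if (nrow(tr$solutions) > 1) {
    rng <- hi - lo
    d <- max(abs(unlist(tr$solutions[1, wingbeat:::TRIM_PARAMS]) -
                   unlist(tr$solutions[2, wingbeat:::TRIM_PARAMS])) / rng)
    expect_gt(d, 0.02)
  }
})

test_that("an exhausted restart budget warns and returns partial results", {
  # a heavy moth no in-bounds kinematics can support
  cfg <- flapping_config(beta_a = 10)
  cfg$mt <- 1   # 1 kg
  b <- silkmoth_bounds("A_luna")[1:3]
  expect_warning(
    tr <- search_trim(cfg, trim_bounds(b), n_solutions = 1L, seed = 2L,
                      max_restarts = 1L, maxit_search = 50L,
                      maxit_polish = 10L),
    "search exhausted")
  expect_equal(nrow(tr$solutions), 0L)
  expect_true(tr$exhausted)
})

test_that("trim solutions round-trip through CSV", {
  dir <- withr::local_tempdir()
  cfg <- cached_near_trim(5)
  nb <- attr(cfg, "near_trim_bounds")
  tr <- search_trim(cfg, nb, n_solutions = 1L, seed = 33L, max_restarts = 5L)
  path <- file.path(dir, "sols.csv")
  write_trim_solutions(tr, path)
  back <- read_trim_solutions(path)
  expect_equal(back$G, tr$solutions$G, tolerance = 1e-12)
  expect_equal(back$seed[1], 33L)
  expect_error(read_trim_solutions(file.path(dir, "missing.csv")),
               "missing.csv")
})
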