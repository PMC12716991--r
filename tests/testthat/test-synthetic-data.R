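test_that("coculture allocation is exact, complete and deterministic", {
  cfg <- coculture_config(n_events = 10000, fraction_phago = 0.2,
                          fraction_trogo = 0.6, fraction_neither = 0.2,
                          seed = 11)
  ev <- generate_coculture_events(cfg)
  expect_equal(nrow(ev), 10000)
  counts <- table(ev$true_label)
  expect_equal(as.integer(counts[c("phago", "trogo", "neither")]),
               c(2000, 6000, 2000))
  expect_identical(ev, generate_coculture_events(cfg))

  # odd fractions still sum exactly to n
  for (n in c(10, 97, 1003)) {
    cfg2 <- coculture_config(n_events = n, fraction_phago = 1 / 3,
                             fraction_trogo = 1 / 3,
                             fraction_neither = 1 / 3, seed = 1)
    expect_equal(sum(table(generate_coculture_events(cfg2)$true_label)), n)
  }
})

test_that("coculture config rejects invalid mixtures", {
  expect_error(coculture_config(fraction_phago = 0.2, fraction_trogo = 0.6,
                                fraction_neither = 0.3),
               "sum to 1")
  expect_error(coculture_config(n_events = 0), "positive integer")
  bad <- default_channel_params()
  bad$trogo$ch_rho <- c(2, 0)
  expect_error(coculture_config(channel_params = bad), "scale > 0")
})

test_that("aspiration series inverts the Laplace law and respects geometry", {
  asp <- generate_aspiration_series(1, 2.5, 7.5, pressure_noise_sd = 0,
                                    n = 5, seed = 3)
  expect_equal(asp$dP_suction_Pa, rep(2e-3 * (1 / 2.5e-6 - 1 / 7.5e-6) * 1, 5))
  expect_equal(asp$dP_suction_Pa, rep(533.3333, 5), tolerance = 1e-6)
  zero <- generate_aspiration_series(0, 2.5, 7.5, 0, n = 3, seed = 3)
  expect_equal(zero$dP_suction_Pa, rep(0, 3))
  expect_error(generate_aspiration_series(1, 2.5, 2.5, 0, 3, 1),
               "must exceed")
  noisy <- generate_aspiration_series(1, 2.5, 7.5, 25, n = 20, seed = 9)
  expect_identical(noisy,
                   generate_aspiration_series(1, 2.5, 7.5, 25, n = 20, seed = 9))
})

test_that("titration generator follows the sigmoid, clips, and is seeded", {
  cfg <- titration_config(a_true = 80, rho_crit_true = 500, d_true = 100,
                          densities = c(500), noise_sd = 0, replicates = 1)
  expect_equal(generate_titration(cfg)$efficiency_pct, 40)
  # decreasing orientation: efficiency vanishes at very high density
  hi <- titration_config(densities = c(1e6), noise_sd = 0, replicates = 1)
  expect_lt(generate_titration(hi)$efficiency_pct, 1e-6)
  expect_error(titration_config(d_true = -1), "d_true")
  expect_error(titration_config(densities = c(-5, 10)), "strictly positive")
  noisy_cfg <- titration_config(noise_sd = 40, seed = 5)
  noisy <- generate_titration(noisy_cfg)
  expect_true(all(noisy$efficiency_pct >= 0 & noisy$efficiency_pct <= 100))
  expect_identical(noisy, generate_titration(noisy_cfg))
})

test_that("bead generator is linear, seeded, and needs two levels", {
  b <- generate_calibration_beads(c(1e4, 1e5, 1e6), gain = 0.01,
                                  noise_cv = 0, beads_per_level = 1)
  expect_equal(b$intensity, c(100, 1000, 10000))
  expect_error(generate_calibration_beads(1e5, 0.01),
               "at least 2 distinct MESF levels")
  noisy <- generate_calibration_beads(c(1e4, 1e5), 0.01, noise_cv = 0.05,
                                      seed = 4)
  expect_identical(noisy,
                   generate_calibration_beads(c(1e4, 1e5), 0.01,
                                              noise_cv = 0.05, seed = 4))
})

test_that("noiseless generator output round-trips through each estimator", {
  # aspiration -> Laplace tension
  for (gam in c(0.26, 1, 11.7)) {
    asp <- generate_aspiration_series(gam, 2.5, 7.5, 0, n = 3, seed = 1)
    est <- tension_from_aspiration(asp$dP_suction_Pa, asp$R_pipette_um,
                                   asp$R_cell_um)
    expect_equal(est, rep(gam, 3), tolerance = 1e-9)
  }
  # beads -> MESF calibration gain (reciprocal of the bead gain)
  beads <- generate_calibration_beads(c(1e4, 1e5, 1e6), gain = 0.02,
                                      noise_cv = 0, beads_per_level = 10)
  cal <- fit_mesf_calibration(beads)
  expect_equal(cal$gain, 50, tolerance = 1e-9)
  # titration -> sigmoid fit
  tt <- generate_titration(titration_config(noise_sd = 0))
  f <- fit_sigmoid(tt)
  expect_equal(c(f$a, f$rho_crit, f$d), c(80, 500, 100), tolerance = 1e-9)
})
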