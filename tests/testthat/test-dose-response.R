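test_that("sigmoid fit recovers exact parameters from noiseless data", {
  f <- fit_sigmoid(exact_titration())
  expect_true(f$converged)
  expect_equal(f$a, 80, tolerance = 1e-6)
  expect_equal(f$rho_crit, 500, tolerance = 1e-6)
  expect_equal(f$d, 100, tolerance = 1e-6)
  # inflection identity: fitted curve equals a/2 at rho_crit
  expect_equal(sigmoid_response(f$rho_crit, f$a, f$rho_crit, f$d), f$a / 2)

  # mirrored (rising) orientation, as for trogocytosis rescue at high density
  x <- c(50, 150, 300, 450, 550, 700, 900, 1200)
  up <- data.frame(density_per_um2 = x,
                   efficiency_pct = sigmoid_response(x, 65, 400, 80,
                                                     "increasing"))
  fu <- fit_sigmoid(up, direction = "increasing")
  expect_equal(c(fu$a, fu$rho_crit, fu$d), c(65, 400, 80), tolerance = 1e-6)
  expect_equal(sigmoid_response(fu$rho_crit, fu$a, fu$rho_crit, fu$d,
                                "increasing"), fu$a / 2)
})

test_that("sigmoid fit flags degenerate inputs instead of fitting them", {
  flat <- data.frame(density_per_um2 = c(100, 200, 300, 400),
                     efficiency_pct = rep(35, 4))
  f <- fit_sigmoid(flat)
  expect_false(f$identifiable)
  expect_false(f$converged)
  expect_error(fit_sigmoid(exact_titration()[1:3, ]), "at least 4")
})

test_that("optimizer never ends above its initialization residual", {
  withr::with_seed(13, {
    for (rep in 1:15) {
      tt <- generate_titration(titration_config(noise_sd = 8,
                                                seed = sample.int(1e6, 1)))
      f <- fit_sigmoid(tt)
      pred0 <- sigmoid_response(tt$density_per_um2, f$start[["a"]],
                                f$start[["rho_crit"]], f$start[["d"]])
      rss0 <- sum((tt$efficiency_pct - pred0)^2)
      expect_lte(f$rss, rss0 + 1e-9)
    }
  })
})

test_that("bootstrap interval collapses on noiseless data and is seeded", {
  tt <- generate_titration(titration_config(noise_sd = 0))
  b <- bootstrap_rho_crit(tt, n_boot = 200, seed = 2)
  expect_lt(diff(b$interval), 1e-6 * 500)
  expect_true(b$interval[1] <= b$fit$rho_crit &&
                b$fit$rho_crit <= b$interval[2])

  noisy <- generate_titration(titration_config(noise_sd = 4, seed = 3))
  b1 <- bootstrap_rho_crit(noisy, n_boot = 300, seed = 17)
  b2 <- bootstrap_rho_crit(noisy, n_boot = 300, seed = 17)
  expect_identical(b1$interval, b2$interval)
  expect_true(b1$interval[1] <= b1$fit$rho_crit &&
                b1$fit$rho_crit <= b1$interval[2])

  flat <- data.frame(density_per_um2 = c(100, 200, 300, 400),
                     efficiency_pct = rep(35, 4))
  expect_error(bootstrap_rho_crit(flat, n_boot = 50, seed = 1),
               "did not converge")
})

test_that("rho_crit vs tension line fits exactly and bands stay honest", {
  pts <- data.frame(gamma_t = c(0.1, 0.4, 0.8, 1.5),
                    rho_crit = 1000 * c(0.1, 0.4, 0.8, 1.5) + 50)
  fit <- fit_rho_crit_vs_tension(pts, n_boot = 200, seed = 1)
  expect_equal(fit$slope, 1000, tolerance = 1e-9)
  expect_equal(fit$intercept, 50, tolerance = 1e-9)
  expect_true(fit$slope_positive)
  # exact data: zero-width envelope equal to the fitted line
  expect_equal(fit$band$lo, fit$band$fit, tolerance = 1e-9)
  expect_equal(fit$band$hi, fit$band$fit, tolerance = 1e-9)

  noisy <- pts
  noisy$rho_crit <- noisy$rho_crit + c(-60, 40, -20, 80)
  nf1 <- fit_rho_crit_vs_tension(noisy, n_boot = 400, seed = 9)
  nf2 <- fit_rho_crit_vs_tension(noisy, n_boot = 400, seed = 9)
  expect_identical(nf1$band, nf2$band)
  # band contains the point fit at every evaluated tension
  expect_true(all(nf1$band$lo <= nf1$band$fit + 1e-12))
  expect_true(all(nf1$band$hi >= nf1$band$fit - 1e-12))

  expect_error(fit_rho_crit_vs_tension(pts[1:2, ]), "at least 3")
  same_x <- data.frame(gamma_t = rep(0.5, 4), rho_crit = c(1, 2, 3, 4))
  expect_error(fit_rho_crit_vs_tension(same_x), "rank-deficient")
})

test_that("Pearson correlation behaves on exact and synthetic data", {
  down <- correlate_efficiency_tension(c(1, 2, 3, 4), c(80, 60, 40, 20))
  expect_equal(down$r, -1)
  up <- correlate_efficiency_tension(c(1, 2, 3), c(1, 2, 3))
  expect_equal(up$r, 1)
  expect_error(correlate_efficiency_tension(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")

  # three-cell-type style data generated with a negative dependence:
  # trogocytic efficiency declines sigmoidally in tension around the
  # predicted switch tension
  withr::with_seed(23, {
    gam <- rep(c(0.02, 0.05, 0.15), each = 5)       # three target lines
    eff <- pmin(100, pmax(0, sigmoid_response(
      gam, 75, predict_switch_tension(100, 1), 0.03) +
      rnorm(length(gam), 0, 3)))
    r <- correlate_efficiency_tension(gam, eff)$r
    expect_lt(r, -0.5)
  })
})
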