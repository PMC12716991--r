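test_that("stress law is linear in antibody density", {
  p <- mech_params()
  expect_equal(normal_stress(400, p), 100)
  expect_equal(normal_stress(0, p), 0)
  expect_equal(normal_stress(800, p), 2 * normal_stress(400, p))
  expect_error(normal_stress(-1, p), ">= 0")
  # pluggable alternative law
  expect_equal(normal_stress(400, p, law = function(r) sqrt(r)), 20)
})

test_that("deformation length scale matches the tension/stress balance", {
  expect_equal(r_min(0.1, 100), 1)     # high end of the predicted bite size
  expect_equal(r_min(0.01, 100), 0.1)  # low end
  expect_equal(r_min(0, 100), 0)
  expect_error(r_min(0.1, 0), "no engagement")
  # strictly increasing in tension, decreasing in density (linear law)
  expect_true(all(diff(r_min(c(0.01, 0.05, 0.2, 1), 100)) > 0))
  expect_true(all(diff(r_min(0.1, normal_stress(c(200, 400, 900, 2000)))) < 0))
  # bite-size consistency over the measured tension range at 100 Pa
  withr::with_seed(3, {
    gam <- 10^runif(200, -2, -1)
    rm <- r_min(gam, 100)
    expect_true(all(rm >= 0.1 - 1e-12 & rm <= 1 + 1e-12))
  })
})

test_that("bending-limited scale follows the cube-root balance", {
  expect_equal(bending_length(8e-20, 100), 0.0928, tolerance = 1e-3)
  expect_equal(bending_length(8e-20, 100 / 8),
               2 * bending_length(8e-20, 100), tolerance = 1e-12)
  expect_lt(bending_length(8e-20, 1e6), bending_length(8e-20, 100))
  expect_error(bending_length(0, 100), "> 0")
  # bending scale sits below the tension scale once gamma > (kappa sigma^2)^(1/3)
  withr::with_seed(4, {
    sig <- 10^runif(100, 1, 3)
    gam_si <- (8e-20 * sig^2)^(1 / 3) * 10^runif(100, 0.05, 2)
    gam <- gam_si * 1e3  # mN/m
    expect_true(all(bending_length(8e-20, sig) < r_min(gam, sig)))
  })
})

test_that("critical density is proportional to tension", {
  p <- mech_params()
  expect_equal(critical_density(0.1, p), 400)
  expect_equal(critical_density(0.2, p), 800)
  expect_equal(critical_density(0, p), 0)
  gam <- c(0.05, 0.1, 0.7, 3)
  expect_equal(critical_density(2 * gam, p), 2 * critical_density(gam, p))
})

test_that("behaviour classification follows the substitution chains", {
  p <- mech_params()
  expect_equal(classify_behaviour(50, 1, p), "no_engagement")
  # rho 1000 at 0.01 mN/m: sigma 250 Pa, R_min 0.04 um << 1 um
  expect_equal(classify_behaviour(1000, 0.01, p), "trogocytosis")
  # rho 200 at 1 mN/m: sigma 50 Pa, R_min 20 um >> 1 um
  expect_equal(classify_behaviour(200, 1, p), "phagocytosis")
  expect_equal(predict_switch_tension(100, 1), 0.1)
  expect_equal(predict_switch_tension(0, 1), 0)
  expect_equal(predict_switch_tension(1000, 1), 10 * predict_switch_tension(100, 1))
})

test_that("phase diagram composes classification and orders each row", {
  p <- mech_params()
  # 2x2 grid straddling the boundary equals four independent calls
  pd <- build_phase_diagram(rho_grid = c(200, 2000), gamma_grid = c(0.05, 5),
                            params = p)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(pd$labels[i, j],
                 classify_behaviour(pd$rho_grid[j], pd$gamma_grid[i], p))
  }
  # below the engagement threshold everywhere
  low <- build_phase_diagram(rho_grid = c(10, 20, 50), gamma_grid = c(0.1, 1),
                             params = p)
  expect_true(all(low$labels == "no_engagement"))

  # along any fixed-tension row: no_engagement, then phagocytosis, then
  # trogocytosis as density increases (bands may be empty, never reordered)
  pd2 <- build_phase_diagram(rho_grid = 10^seq(1, 4, length.out = 40),
                             gamma_grid = 10^seq(-3, 1, length.out = 30),
                             params = p)
  code <- matrix(match(pd2$labels,
                       c("no_engagement", "phagocytosis", "trogocytosis")),
                 nrow = nrow(pd2$labels))
  expect_true(all(apply(code, 1, function(r) all(diff(r) >= 0))))

  expect_error(build_phase_diagram(rho_grid = numeric(0)), "non-empty")
  expect_error(build_phase_diagram(rho_grid = c(10, 5)), "strictly increasing")
})

test_that("grid labels flip exactly at the predicted critical density", {
  p <- mech_params()
  pd <- build_phase_diagram(rho_grid = 10^seq(1, 4, length.out = 60),
                            gamma_grid = 10^seq(-3, 1, length.out = 25),
                            params = p)
  for (i in seq_along(pd$gamma_grid)) {
    rho_c <- pd$boundary$rho_crit_pred[i]
    row <- pd$labels[i, ]
    engaged <- pd$rho_grid >= p$rho_engage
    # every engaged cell strictly above the boundary is trogocytic, strictly
    # below it phagocytic
    expect_true(all(row[engaged & pd$rho_grid > rho_c * (1 + 1e-12)] ==
                      "trogocytosis"))
    expect_true(all(row[engaged & pd$rho_grid < rho_c * (1 - 1e-12)] ==
                      "phagocytosis"))
  }
})
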