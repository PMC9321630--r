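test_that("Campbell retention and conductivity follow their closed forms", {
  layer <- list(psi_e = -0.0005, b_soil = 4, theta_sat = 0.4, K_sat = 10)
  expect_equal(matric_potential(0.4, layer), -0.0005)
  expect_equal(matric_potential(0.2, layer), -0.0005 * 16)
  expect_equal(hydraulic_conductivity(0.4, layer), 10)
  expect_equal(hydraulic_conductivity(0.2, layer), 10 * 2^-11)
  th <- seq(0.02, 0.4, by = 0.01)
  expect_true(all(diff(matric_potential(th, layer)) > 0))   # toward psi_e
  expect_true(all(diff(hydraulic_conductivity(th, layer)) > 0))
  expect_error(matric_potential(0, layer))
  expect_error(hydraulic_conductivity(-0.1, layer))
})

test_that("default profile: six layers to 4.6 m, roots sum to one", {
  p <- soil_profile()
  expect_equal(nrow(p), 6)
  expect_equal(sum(p$thickness), 4.6)
  expect_equal(sum(p$root_frac), 1)
  ## root density (fraction per metre) decays with depth
  expect_true(all(diff(p$root_frac / p$thickness) < 0))
})

test_that("weighted soil potential shifts to deep layers as the surface dries", {
  p <- soil_profile()
  ## uniform moisture: weighted potential equals the common value, weights
  ## follow root fractions
  w <- weighted_soil_potential(p)
  expect_equal(w$psi_soil_w, matric_potential(p$theta[1], p[1, ]))
  expect_equal(w$weights, p$root_frac)
  ## dry surface, wet depth: weight mass moves downward
  p2 <- p
  p2$theta <- c(0.08, 0.1, 0.3, 0.42, 0.44, 0.44)
  w2 <- weighted_soil_potential(p2)
  expect_lt(sum(w2$weights[1:2]), sum(w$weights[1:2]))
  expect_gt(sum(w2$weights[4:6]), sum(w$weights[4:6]))
  ## single layer: its own potential, weight one
  p1 <- soil_profile(thickness = 1, theta = 0.3)
  w1 <- weighted_soil_potential(p1)
  expect_equal(w1$weights, 1)
  expect_equal(w1$psi_soil_w, matric_potential(0.3, p1[1, ]))
  ## no conductive uptake path anywhere: fall back to the deepest layer
  pd <- soil_profile(K_sat = 0, theta = 0.1)
  expect_warning(wd <- weighted_soil_potential(pd), "dry")
  expect_equal(wd$weights, c(0, 0, 0, 0, 0, 1))
  expect_equal(wd$psi_soil_w, matric_potential(0.1, pd[6, ]))
})

test_that("water balance bookkeeping conserves mass exactly", {
  p <- soil_profile()
  ## zero fluxes: unchanged
  r <- update_water_balance(p, 0, 0)
  expect_equal(r$profile$theta, p$theta)
  ## saturated profile: all infiltration becomes runoff
  ps <- p; ps$theta <- ps$theta_sat
  r <- update_water_balance(ps, 20, 0)
  expect_equal(r$fluxes$runoff + r$fluxes$drainage - 20, -r$fluxes$dstorage,
               tolerance = 1e-12)
  ps_dry <- ps
  ps_dry$K_sat <- 0  # suppress drainage to isolate the runoff path
  r2 <- update_water_balance(ps_dry, 20, 0)
  expect_equal(r2$fluxes$runoff, 20)
  expect_equal(r2$profile$theta, ps$theta_sat)
  ## extraction beyond what the profile holds is clipped and reported
  pe <- soil_profile(thickness = 0.1, theta = 0.05)
  r3 <- update_water_balance(pe, 0, 100)
  expect_gt(r3$fluxes$shortfall, 0)
  expect_equal(r3$fluxes$extraction + r3$fluxes$shortfall, 100)
  expect_true(all(r3$profile$theta >= 0))
})

test_that("1000 randomised steps keep the cumulative residual below 1e-9 mm", {
  set.seed(101)
  p <- soil_profile()
  s0 <- soil_storage_mm(p)
  total_in <- total_out <- 0
  for (i in 1:1000) {
    infil <- if (runif(1) < 0.3) rexp(1, 1 / 8) else 0
    extract <- runif(1, 0, 3)
    r <- update_water_balance(p, infil, extract)
    p <- r$profile
    total_in <- total_in + infil
    total_out <- total_out + r$fluxes$extraction + r$fluxes$runoff +
      r$fluxes$drainage
    expect_true(all(p$theta >= 0 & p$theta <= p$theta_sat + 1e-12))
  }
  residual <- (soil_storage_mm(p) - s0) - (total_in - total_out)
  expect_lt(abs(residual), 1e-9)
})

test_that("sustained drawdown makes the weighted potential monotone non-increasing", {
  p <- soil_profile()
  psi <- numeric(200)
  for (i in 1:200) {
    r <- update_water_balance(p, 0, 2)
    p <- r$profile
    psi[i] <- weighted_soil_potential(p)$psi_soil_w
  }
  expect_true(all(diff(psi) <= 1e-12))
})
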