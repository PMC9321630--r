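vc22 <- vulnerability_curve(b = 2, c = 2, kmax = 1.5)

test_that("hydraulic cost matches its closed form and bounds", {
  ## no drawdown: zero cost; conductance at kcrit: unit cost
  expect_equal(hydraulic_cost(-0.5, -0.5, vc22, 0.075), 0)
  psi_crit <- pxx(vc22, 1 - 0.05)  # k = 5% of kmax there
  expect_equal(hydraulic_cost(psi_crit, -0.5, vc22, 0.075), 1, tolerance = 1e-10)
  ## direct evaluation
  k_imax <- 1.5 * exp(-(0.5 / 2)^2)
  k_leaf <- 1.5 * exp(-(1.5 / 2)^2)
  expect_equal(hydraulic_cost(-1.5, -0.5, vc22, 0.075),
               (k_imax - k_leaf) / (k_imax - 0.075), tolerance = 1e-12)
  ## beyond-critical soil signals a dedicated condition
  expect_error(hydraulic_cost(-6, -5.9, vc22, 0.075), class = "beyond_critical")
})

test_that("leaf water potential solves the supply function on the stable branch", {
  expect_equal(solve_leaf_potential(0, -0.5, vc22), -0.5)
  ## against a 1e6-point dense scan of the supply curve
  for (E in c(0.1, 0.5, 0.8)) {
    root <- solve_leaf_potential(E, -0.5, vc22)
    expect_equal(root, grid_root_psi(E, -0.5, vc22), tolerance = 1e-4)
    ## residual of the steady-state relation
    expect_lt(abs(E - supply_direct(root, -0.5, vc22)), 1e-6)
  }
  ## beyond the supply maximum: infeasible
  E_max <- grid_max_supply(-0.5, vc22, psi_min = -20)
  expect_true(is.na(solve_leaf_potential(E_max * 1.001, -0.5, vc22)))
  expect_false(is.na(solve_leaf_potential(E_max * 0.999, -0.5, vc22)))
  ## vectorised call agrees with elementwise calls
  E <- c(0, 0.2, 0.8, 1.4)
  expect_equal(solve_leaf_potential(E, -0.5, vc22),
               vapply(E, solve_leaf_potential, numeric(1),
                      psi_soil_w = -0.5, curve = vc22))
})

test_that("critical transpiration agrees with dense-grid maximisation", {
  kcrit <- 0.05 * 1.5
  psi_crit <- pxx(vc22, 1 - 0.05)
  ## at the critical potential the supply window has zero width
  expect_equal(critical_transpiration(psi_crit, vc22, kcrit), 0, tolerance = 1e-9)
  for (psw in c(0, -0.5, -1.5, -3)) {
    psi <- seq(psi_crit, psw, length.out = 1e6)
    expect_equal(critical_transpiration(psw, vc22, kcrit),
                 max(supply_direct(psi, psw, vc22)), tolerance = 1e-8)
  }
  ## shrinks as the soil dries
  e <- vapply(c(-0.1, -1, -2, -3, -4), critical_transpiration, numeric(1),
              curve = vc22, kcrit = kcrit)
  expect_true(all(diff(e) < 0))
})

test_that("boundary conditions close the stomata", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus blakelyi"]]
  env <- leaf_environment(25, 1500, 400, 1.5)
  ## soil beyond the critical conductance
  psi_beyond <- pxx(tr$curve, 1 - 0.04)
  sol <- optimise_gas_exchange(env, psi_beyond, tr)
  expect_true(sol$closed)
  expect_equal(sol$g_sc, 0)
  expect_equal(sol$E_leaf, 0)
  expect_equal(sol$psi_leaf, psi_beyond)
  ## night
  night <- leaf_environment(15, 0, 400, 0.5)
  sol <- optimise_gas_exchange(night, -0.3, tr)
  expect_true(sol$closed)
  expect_lt(sol$A, 0)  # respiration continues
})

test_that("the returned candidate is the exhaustive-search optimum", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus blakelyi"]]
  env <- leaf_environment(25, 1400, 400, 2)
  sol <- optimise_gas_exchange(env, -0.5, tr)
  expect_false(sol$closed)
  expect_equal(sol$profit, sol$CG - sol$HC, tolerance = 1e-12)
  expect_true(sol$CG >= 0 && sol$CG <= 1)
  expect_true(sol$HC >= 0 && sol$HC <= 1)
  expect_true(sol$profit >= 0 && sol$profit <= 1)
  expect_lte(sol$psi_leaf, -0.5)
  ## independent re-evaluation of the chosen candidate (25 C constants)
  expect_equal(sol$A, farquhar_25(sol$Ci, 1400, tr$Vcmax25), tolerance = 1e-6)
  expect_equal(sol$g_sc, sol$A / (400 - sol$Ci), tolerance = 1e-10)
  expect_equal(sol$E_leaf, 1000 * 1.57 * sol$g_sc * 2 / 101.325,
               tolerance = 1e-10)
  expect_lt(abs(sol$E_leaf - supply_direct(sol$psi_leaf, -0.5, tr$curve)), 1e-6)
})

test_that("grid optimum matches the dense psi-axis co-optimisation oracle", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus blakelyi"]]
  env <- leaf_environment(28, 1400, 400, 2)
  sol <- optimise_gas_exchange(env, -0.5, tr)
  orc <- cooptimise_oracle(env, -0.5, tr)
  step <- (400 - temperature_adjusted_params(photosyn_params(tr$Vcmax25),
                                             28)$gamma_star) / 999
  expect_false(orc$closed)
  expect_lt(abs(sol$Ci - orc$Ci), step + 1e-9)
})

test_that("drought response: g_sw declines as the soil dries, psi_leaf below soil", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus melliodora"]]
  env <- leaf_environment(30, 1600, 400, 2.5)
  psw <- seq(-0.1, -8, by = -0.25)
  sols <- lapply(psw, function(p) optimise_gas_exchange(env, p, tr))
  gsw <- vapply(sols, `[[`, numeric(1), "g_sw")
  psi <- vapply(sols, `[[`, numeric(1), "psi_leaf")
  expect_true(all(diff(gsw) <= 1e-4))  # grid-resolution jitter allowed
  expect_true(all(psi <= psw + 1e-12))
})

test_that("doubling CO2 never increases transpiration at the optimum", {
  reg <- load_species_registry()
  set.seed(11)
  for (i in 1:20) {
    tr <- reg[[sample.int(15, 1)]]
    env1 <- leaf_environment(T_air = runif(1, 15, 35),
                             PAR_leaf = runif(1, 300, 1800),
                             Cs = 400, VPD_leaf = runif(1, 0.5, 4))
    env2 <- env1; env2$Cs <- 800
    psw <- runif(1, -3, -0.1)
    e1 <- optimise_gas_exchange(env1, psw, tr)$E_leaf
    e2 <- optimise_gas_exchange(env2, psw, tr)$E_leaf
    ## the doubled-CO2 grid is twice as coarse, so allow one grid step of
    ## jitter in the implied transpiration
    expect_lte(e2, e1 + 5e-3)
  }
})
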