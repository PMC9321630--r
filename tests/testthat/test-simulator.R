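fast_cfg <- function(...) run_config(n_ci = 300, spinup = FALSE, ...)

test_that("a saturated-soil midday step reproduces a direct optimiser call", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus blakelyi"]]
  f <- make_forcing(days = 1)[4:5, ]  # two regular steps around solar noon
  soil <- soil_profile(theta = 0.45)  # saturated
  cfg <- fast_cfg(LAI = 2)
  out <- run_site(f, tr, soil, cfg)
  wsp <- weighted_soil_potential(soil)
  vpd <- esat_kpa(f$T_air[1]) - f$e_air[1]
  par_leaf <- f$SW_down[1] * 2.3 * (1 - exp(-0.5 * 2)) / 2
  env <- leaf_environment(f$T_air[1], par_leaf, 400, vpd, 101.325, 2)
  sol <- optimise_gas_exchange(env, wsp$psi_soil_w, tr,
                               optimiser_settings(n_ci = 300))
  expect_equal(out$series$psi_leaf[1], sol$psi_leaf)
  expect_equal(out$series$A[1], sol$A)
  expect_equal(out$series$g_sw[1], sol$g_sw)
})

test_that("rainless high-demand forcing produces a monotone drought trajectory", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus camaldulensis"]]
  f <- make_forcing(days = 90, T_day = 32, sw_max = 900, precip = 0)
  out <- run_site(f, tr, soil_profile(), fast_cfg(LAI = 3))
  s <- out$series
  ## running minimum of psi_leaf never recovers without rain
  run_min <- cummin(s$psi_leaf)
  expect_true(all(diff(run_min) <= 0))
  ## soil potential declines monotonically
  expect_true(all(diff(s$psi_soil_w) <= 1e-12))
  ## embolism accumulates
  expect_gt(max(s$PLC[(nrow(s) - 80):nrow(s)]), s$PLC[1])
  expect_gt(summarise_run(out, tr)$max_PLC, 5)
})

test_that("runs are deterministic and reject gappy forcing", {
  reg <- load_species_registry()
  tr <- reg[[3]]
  f <- make_forcing(days = 5, precip = 1)
  o1 <- run_site(f, tr, soil_profile(), fast_cfg())
  o2 <- run_site(f, tr, soil_profile(), fast_cfg())
  expect_identical(o1$series, o2$series)
  fbad <- f; fbad$T_air[17] <- NaN
  expect_error(run_site(fbad, tr, soil_profile(), fast_cfg()), "gap|NaN")
})

test_that("canopy water extracted from soil equals LAI-scaled leaf transpiration", {
  reg <- load_species_registry()
  tr <- reg[[1]]
  f <- make_forcing(days = 10, precip = 0.5)
  lai <- 2.5
  out <- run_site(f, tr, soil_profile(), fast_cfg(LAI = lai))
  dt <- 10800
  demand_mm <- out$series$E_leaf * lai * dt * 18.015 * 1e-6
  ## no shortfall in a 10-day wet run: extraction equals demand
  expect_equal(sum(out$series$E_canopy_mm), sum(demand_mm), tolerance = 1e-9)
})

test_that("scenario engine applies the documented perturbations", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus viminalis"]]
  f <- make_forcing(days = 30, precip = 0.8)
  outs <- run_scenarios(f, tr, soil_profile(), fast_cfg())
  expect_named(outs, c("CTL", "rPPT", "eCO2_rPPT"))
  expect_equal(sum(outs$rPPT$series$precip_mm),
               0.8 * sum(outs$CTL$series$precip_mm), tolerance = 1e-12)
  expect_equal(outs$eCO2_rPPT$config$co2_scale, 2)
})

test_that("summaries count months below P50 correctly", {
  reg <- load_species_registry()
  tr <- reg[["Eucalyptus blakelyi"]]  # P50 = -4.51
  ## constructed 12-month series: 3 months' means below P50
  months <- seq(as.POSIXct("2017-01-15", tz = "UTC"), by = "month", length.out = 12)
  psi <- rep(-1, 12); psi[c(2, 5, 9)] <- -6
  out <- structure(list(
    series = data.frame(time = months, psi_leaf = psi, PLC = plc(psi, tr$curve),
                        daylight = TRUE),
    config = run_config()), class = "simulation_output")
  s <- summarise_run(out, tr)
  expect_equal(s$months_below_P50, 3)
  expect_equal(s$fraction_months_below_P50, 0.25)
  expect_equal(s$psi_min, -6)
  ## constant series above P50
  out$series$psi_leaf <- rep(-2, 12)
  out$series$PLC <- plc(rep(-2, 12), tr$curve)
  s2 <- summarise_run(out, tr)
  expect_equal(s2$psi_min, -2)
  expect_equal(s2$months_below_P50, 0)
})

test_that("range summaries weight PLC equally across species present", {
  reg <- load_species_registry()
  mk <- function(psi, curve) structure(list(
    series = data.frame(time = as.POSIXct("2017-06-01", tz = "UTC") + 0:29 * 86400,
                        psi_leaf = psi, PLC = plc(psi, curve), daylight = TRUE),
    config = run_config()), class = "simulation_output")
  spA <- "Eucalyptus blakelyi"; spB <- "Eucalyptus obliqua"
  outs <- list()
  outs[[spA]] <- list(s1 = mk(rep(-5, 30), reg[[spA]]$curve),
                      s2 = mk(rep(-2, 30), reg[[spA]]$curve))
  outs[[spB]] <- list(s1 = mk(rep(-3, 30), reg[[spB]]$curve))
  presence <- list(c("s1", "s2"), "s1")
  names(presence) <- c(spA, spB)
  rs <- range_summary(outs, presence, reg)
  ## species A: one of two sites has monthly mean below P50 (-4.51)
  rowA <- rs$per_species[rs$per_species$species == spA, ]
  expect_equal(rowA$prop_sites_below_P50, 0.5)
  expect_equal(rowA$n_sites, 2)
  ## site s1 weighted PLC: arithmetic mean of the two species
  expect_equal(unname(rs$site_weighted_PLC["s1"]),
               mean(c(plc(-5, reg[[spA]]$curve), plc(-3, reg[[spB]]$curve))))
  ## site s2 hosts only species A
  expect_equal(unname(rs$site_weighted_PLC["s2"]), plc(-2, reg[[spA]]$curve))
  ## zero-presence species are dropped with a warning
  presence$`Eucalyptus saligna` <- character(0)
  expect_warning(range_summary(outs, presence, reg), "zero presence")
})
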