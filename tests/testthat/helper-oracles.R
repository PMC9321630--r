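## Independent oracles used across the suite. These re-derive quantities by
## brute force (dense grids, direct accounting) and never call the code paths
## they check.

## supply function evaluated directly
supply_direct <- function(psi, psi_soil_w, curve) {
  curve$kmax * exp(-(abs(psi) / curve$b)^curve$c) * (psi_soil_w - psi)
}

## least-negative root of E = supply(psi) by dense-grid scan
grid_root_psi <- function(E, psi_soil_w, curve, n = 1e6, floor_mpa = -30) {
  psi <- seq(floor_mpa, psi_soil_w, length.out = n)
  s <- supply_direct(psi, psi_soil_w, curve)
  ok <- which(s >= E)
  if (!length(ok)) return(NA_real_)
  ## least-negative crossing: last index where supply still exceeds E
  psi[max(ok)]
}

## supply maximum by dense-grid scan
grid_max_supply <- function(psi_soil_w, curve, psi_min, n = 1e6) {
  psi <- seq(psi_min, psi_soil_w, length.out = n)
  max(supply_direct(psi, psi_soil_w, curve))
}

## independent Farquhar evaluation (mirrors the frozen constant table but
## written out directly, at 25 C only)
farquhar_25 <- function(Ci, PAR, Vcmax25 = 86.88) {
  Kc <- 404.9; Ko <- 278.4; gs <- 42.75; Oi <- 210
  Jmax <- 1.67 * Vcmax25; Rd <- 0.015 * Vcmax25
  I2 <- 0.26 * PAR
  J <- (I2 + Jmax - sqrt((I2 + Jmax)^2 - 4 * 0.7 * I2 * Jmax)) / (2 * 0.7)
  Ac <- Vcmax25 * (Ci - gs) / (Ci + Kc * (1 + Oi / Ko))
  Aj <- (J / 4) * (Ci - gs) / (Ci + 2 * gs)
  pmin(Ac, Aj) - Rd
}

## brute-force co-optimisation over a dense leaf-water-potential grid:
## psi -> E (supply) -> g_sw -> g_sc -> Ci (demand inversion by bisection)
## -> A -> profit. The optimiser searches the Ci axis; this oracle searches
## the psi axis, so agreement is a genuine cross-check of the scheme.
cooptimise_oracle <- function(env, psi_soil_w, traits, n_psi = 2e4,
                              kcrit_fraction = 0.05) {
  curve <- traits$curve
  kcrit <- kcrit_fraction * curve$kmax
  params <- temperature_adjusted_params(photosyn_params(traits$Vcmax25),
                                        env$T_air)
  psi_crit <- -curve$b * (-log(kcrit / curve$kmax))^(1 / curve$c)
  if (psi_soil_w <= psi_crit) return(list(closed = TRUE))
  psi <- seq(psi_crit, psi_soil_w, length.out = n_psi)
  k <- curve$kmax * exp(-(abs(psi) / curve$b)^curve$c)
  E <- k * (psi_soil_w - psi)
  ## keep the ascending branch only: psi no more negative than the supply max
  imax <- which.max(E)
  keep <- seq(imax, n_psi)
  psi <- psi[keep]; k <- k[keep]; E <- pmax(E[keep], 0)
  g_sw <- E * env$P_atm / (1000 * env$VPD_leaf)
  g_sc <- g_sw / 1.57
  ## invert demand: find Ci with A(Ci) = g_sc (Cs - Ci)
  lo <- rep(params$gamma_star, length(psi))
  hi <- rep(env$Cs, length(psi))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    f <- net_assimilation(mid, env, params) - g_sc * (env$Cs - mid)
    dn <- f < 0
    lo[dn] <- mid[dn]
    hi[!dn] <- mid[!dn]
  }
  Ci <- (lo + hi) / 2
  A <- net_assimilation(Ci, env, params)
  Amax <- max(A)
  CG <- if (Amax > 0) pmin(pmax(A, 0) / Amax, 1) else rep(0, length(A))
  k_imax <- curve$kmax * exp(-(abs(psi_soil_w) / curve$b)^curve$c)
  HC <- pmin(pmax((k_imax - k) / (k_imax - kcrit), 0), 1)
  profit <- CG - HC
  i <- which.max(profit)
  if (profit[i] <= 0) return(list(closed = TRUE))
  list(closed = FALSE, Ci = Ci[i], psi_leaf = psi[i], profit = profit[i],
       A = A[i], E_leaf = E[i])
}

## quick forcing fixture for simulator tests
make_forcing <- function(days, timestep = 10800, precip = 0, T_day = 25,
                         sw_max = 800, co2 = 400,
                         start = as.POSIXct("2017-01-01", tz = "UTC")) {
  spd <- 86400 / timestep
  n <- days * spd
  hour <- rep(seq(0, 24 - 24 / spd, by = 24 / spd), days)
  sw <- sw_max * pmax(sin(pi * (hour - 6) / 12), 0)
  T_air <- T_day - 5 * cos(2 * pi * (hour - 15) / 24)
  data.frame(time = start + (seq_len(n) - 1) * timestep,
             SW_down = sw, T_air = T_air,
             e_air = 0.5 * esat_kpa(T_air),
             precip = rep_len(precip, n),
             wind = 2, P_atm = 101.325, CO2 = co2)
}
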