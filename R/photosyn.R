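## Farquhar C3 photosynthesis and leaf-level gas exchange support for the
## stomatal optimiser. Biochemical temperature responses follow the standard
## Bernacchi-type constant set, frozen below so every run is reproducible.

#' Frozen biochemical constant table
#'
#' Base values at 25 C and temperature-response coefficients for the C3
#' photosynthesis model. Arrhenius scaling for Kc, Ko, Gamma-star and Rd;
#' peaked Arrhenius for Vcmax and Jmax. Units: Kc, Gamma-star umol mol-1;
#' Ko mmol mol-1; activation energies J mol-1; entropy terms J mol-1 K-1.
#'
#' @format Named list of numeric constants.
#' @export
PHOTOSYN_CONSTANTS <- list(
  Kc25 = 404.9, Ha_Kc = 79430,
  Ko25 = 278.4, Ha_Ko = 36380,
  gamma_star25 = 42.75, Ha_gamma_star = 37830,
  Ha_Rd = 46390,
  Ha_Vcmax = 65330, Hd_Vcmax = 200000, dS_Vcmax = 640,
  Ha_Jmax = 43540, Hd_Jmax = 200000, dS_Jmax = 640,
  Oi = 210,              # intercellular O2, mmol mol-1
  theta_J = 0.7,         # curvature of the light response
  alpha_J = 0.26,        # quantum yield of electron transport, mol mol-1
  jmax_vcmax_ratio = 1.67,
  rd_vcmax_ratio = 0.015,
  gsw_gsc_ratio = 1.57   # H2O:CO2 stomatal diffusivity ratio
)

R_GAS <- 8.314  # J mol-1 K-1

#' Photosynthetic parameter set
#'
#' Builds the parameter block consumed by [net_assimilation()]. Only Vcmax25
#' is species-specific; Jmax25 and Rd25 default to fixed ratios of Vcmax25
#' (1.67 and 0.015) and the Michaelis constants and compensation point come
#' from the frozen constant table.
#'
#' @param Vcmax25 Maximum carboxylation rate at 25 C, umol m-2 s-1.
#' @param Jmax25,Rd25 Optional overrides, umol m-2 s-1.
#' @param constants Constant table, see [PHOTOSYN_CONSTANTS].
#' @return Object of class `photosyn_params`.
#' @export
photosyn_params <- function(Vcmax25, Jmax25 = NULL, Rd25 = NULL,
                            constants = PHOTOSYN_CONSTANTS) {
  stopifnot(is.numeric(Vcmax25), Vcmax25 > 0)
  structure(list(
    Vcmax = Vcmax25,
    Jmax = if (is.null(Jmax25)) constants$jmax_vcmax_ratio * Vcmax25 else Jmax25,
    Rd = if (is.null(Rd25)) constants$rd_vcmax_ratio * Vcmax25 else Rd25,
    Kc = constants$Kc25,
    Ko = constants$Ko25,
    gamma_star = constants$gamma_star25,
    Tref = 25,
    constants = constants), class = "photosyn_params")
}

#' Leaf micro-environment for one timestep
#'
#' @param T_air Air temperature, C.
#' @param PAR_leaf Absorbed photosynthetically active radiation per unit leaf
#'   area, umol m-2 s-1.
#' @param Cs CO2 mole fraction at the leaf surface, umol mol-1.
#' @param VPD_leaf Leaf-to-air vapour pressure deficit, kPa.
#' @param P_atm Air pressure, kPa.
#' @param wind Wind speed, m s-1 (used only by the iterative leaf energy
#'   balance).
#' @return Object of class `leaf_environment`.
#' @export
leaf_environment <- function(T_air, PAR_leaf, Cs, VPD_leaf,
                             P_atm = 101.325, wind = 2) {
  if (Cs <= 0) stop("Cs must be positive")
  if (VPD_leaf < 0) stop("VPD_leaf must be >= 0")
  if (P_atm <= 0) stop("P_atm must be positive")
  structure(list(T_air = T_air, PAR_leaf = max(PAR_leaf, 0), Cs = Cs,
                 VPD_leaf = VPD_leaf, P_atm = P_atm, wind = wind),
            class = "leaf_environment")
}

arrhenius <- function(base, Ha, Tk) {
  base * exp(Ha * (Tk - 298.15) / (298.15 * R_GAS * Tk))
}

peaked_arrhenius <- function(base, Ha, Hd, dS, Tk) {
  num <- 1 + exp((298.15 * dS - Hd) / (298.15 * R_GAS))
  den <- 1 + exp((Tk * dS - Hd) / (Tk * R_GAS))
  arrhenius(base, Ha, Tk) * num / den
}

#' Temperature-adjust a photosynthetic parameter set
#'
#' Arrhenius scaling for Kc, Ko, Gamma-star and Rd; peaked Arrhenius for
#' Vcmax and Jmax. At 25 C the set is returned unchanged.
#'
#' @param base A [photosyn_params()] at 25 C.
#' @param T_leaf Leaf temperature, C, in (-10, 60).
#' @return A `photosyn_params` valid at `T_leaf`.
#' @export
temperature_adjusted_params <- function(base, T_leaf) {
  stopifnot(inherits(base, "photosyn_params"))
  if (T_leaf <= -10 || T_leaf >= 60) stop("T_leaf out of range (-10, 60) C")
  k <- base$constants
  Tk <- T_leaf + 273.15
  out <- base
  out$Kc <- arrhenius(base$Kc, k$Ha_Kc, Tk)
  out$Ko <- arrhenius(base$Ko, k$Ha_Ko, Tk)
  out$gamma_star <- arrhenius(base$gamma_star, k$Ha_gamma_star, Tk)
  out$Rd <- arrhenius(base$Rd, k$Ha_Rd, Tk)
  out$Vcmax <- peaked_arrhenius(base$Vcmax, k$Ha_Vcmax, k$Hd_Vcmax, k$dS_Vcmax, Tk)
  out$Jmax <- peaked_arrhenius(base$Jmax, k$Ha_Jmax, k$Hd_Jmax, k$dS_Jmax, Tk)
  out$Tref <- T_leaf
  out
}

#' Electron transport rate from absorbed PAR
#'
#' Non-rectangular hyperbola: the smaller root of
#' theta J^2 - (alpha I + Jmax) J + alpha I Jmax = 0.
#' @param PAR_leaf Absorbed PAR, umol m-2 s-1. Vectorised.
#' @param params A `photosyn_params` (already at leaf temperature).
#' @return J, umol m-2 s-1.
#' @keywords internal
electron_transport <- function(PAR_leaf, params) {
  k <- params$constants
  I2 <- k$alpha_J * PAR_leaf
  b <- I2 + params$Jmax
  (b - sqrt(pmax(b^2 - 4 * k$theta_J * I2 * params$Jmax, 0))) / (2 * k$theta_J)
}

#' Net CO2 assimilation at an intercellular CO2 concentration
#'
#' Farquhar C3 model: the minimum of the Rubisco-limited and
#' RuBP-regeneration-limited gross rates, less day respiration,
#' \deqn{A = \min\left(\frac{V_{cmax}(C_i-\Gamma^*)}{C_i+K_m},
#'   \frac{J}{4}\frac{C_i-\Gamma^*}{C_i+2\Gamma^*}\right) - R_d,}
#' with \eqn{K_m = K_c(1 + O_i/K_o)}. TPU limitation is not represented.
#'
#' @param Ci Intercellular CO2, umol mol-1, `>= gamma_star`. Vectorised.
#' @param env A [leaf_environment()].
#' @param params A `photosyn_params` already adjusted to leaf temperature.
#' @return Net assimilation A, umol m-2 s-1.
#' @export
net_assimilation <- function(Ci, env, params) {
  stopifnot(inherits(params, "photosyn_params"))
  if (any(Ci < params$gamma_star - 1e-9))
    stop("Ci below the CO2 compensation point gamma_star")
  Ci <- pmax(Ci, params$gamma_star)
  Km <- params$Kc * (1 + params$constants$Oi / params$Ko)
  Ac <- params$Vcmax * (Ci - params$gamma_star) / (Ci + Km)
  J <- electron_transport(env$PAR_leaf, params)
  Aj <- (J / 4) * (Ci - params$gamma_star) / (Ci + 2 * params$gamma_star)
  pmin(Ac, Aj) - params$Rd
}

#' Candidate intercellular CO2 grid
#'
#' `n` uniformly spaced candidates spanning `[gamma_star, Cs]` inclusive, the
#' discretisation over which the optimiser searches. At the default n = 1000
#' and typical Cs the spacing is about 0.35 umol mol-1.
#'
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @param Cs Leaf-surface CO2, umol mol-1, `> gamma_star`.
#' @param n Number of candidates, `>= 2`.
#' @return Strictly increasing numeric vector of length `n`.
#' @export
ci_grid <- function(gamma_star, Cs, n = 1000) {
  if (Cs <= gamma_star) stop("Cs must exceed gamma_star")
  if (n < 2) stop("n must be >= 2")
  seq(gamma_star, Cs, length.out = n)
}

#' Leaf transpiration from stomatal conductance
#'
#' Water vapour exchange proportional to stomatal conductance:
#' E = g_sw VPD / P_atm, returned in mmol m-2 s-1.
#'
#' @param g_sw Stomatal conductance to water vapour, mol m-2 s-1. Vectorised.
#' @param env A [leaf_environment()].
#' @return E_leaf, mmol m-2 s-1.
#' @export
leaf_transpiration <- function(g_sw, env) {
  if (any(g_sw < 0)) stop("g_sw must be >= 0")
  1000 * g_sw * env$VPD_leaf / env$P_atm
}

#' Saturation vapour pressure (Magnus), kPa
#' @param T_c Temperature, C. Vectorised.
#' @export
esat_kpa <- function(T_c) {
  0.61094 * exp(17.625 * T_c / (T_c + 243.04))
}

#' Leaf temperature via a simple energy balance
#'
#' In the default "isothermal" mode the leaf is assumed to be at air
#' temperature. In "iterative" mode leaf temperature is solved so that
#' absorbed net radiation balances sensible plus latent heat loss, using a
#' wind-dependent boundary-layer conductance to heat; iteration is capped at
#' `max_iter` with a `tol` C convergence threshold (non-convergence warns and
#' returns the last iterate).
#'
#' @param env A [leaf_environment()] (with `e_air`, air vapour pressure in
#'   kPa, attached for VPD recomputation; otherwise `VPD_leaf` is held fixed).
#' @param g_sw Stomatal conductance to water vapour, mol m-2 s-1.
#' @param rnet Absorbed net radiation, W m-2.
#' @param mode `"isothermal"` or `"iterative"`.
#' @param max_iter,tol Iteration cap and convergence tolerance (C).
#' @return Leaf temperature, C.
#' @export
leaf_energy_balance <- function(env, g_sw, rnet, mode = c("isothermal", "iterative"),
                                max_iter = 5, tol = 0.01) {
  mode <- match.arg(mode)
  if (mode == "isothermal") return(env$T_air)
  cp <- 29.2          # molar heat capacity of air, J mol-1 K-1
  lambda <- 44100     # latent heat of vaporisation, J mol-1
  d_leaf <- 0.05      # characteristic leaf dimension, m
  g_bH <- 0.15 * sqrt(max(env$wind, 0.1) / d_leaf)  # mol m-2 s-1, one side
  e_air <- if (!is.null(env$e_air)) env$e_air else esat_kpa(env$T_air) - env$VPD_leaf
  T_leaf <- env$T_air
  for (i in seq_len(max_iter)) {
    vpd <- max(esat_kpa(T_leaf) - e_air, 0)
    LE <- lambda * g_sw * vpd / env$P_atm  # mol m-2 s-1 x J mol-1 = W m-2
    H <- 2 * cp * g_bH * (T_leaf - env$T_air)
    resid <- rnet - LE - H
    ## Newton step: d(LE)/dT from the Magnus slope, d(H)/dT constant
    s <- esat_kpa(T_leaf) * 17.625 * 243.04 / (T_leaf + 243.04)^2
    dLE <- if (vpd > 0) lambda * g_sw * s / env$P_atm else 0
    step <- resid / (dLE + 2 * cp * g_bH)
    T_leaf <- T_leaf + step
    if (abs(step) < tol) return(T_leaf)
  }
  warning("leaf energy balance did not converge; returning last iterate")
  T_leaf
}
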