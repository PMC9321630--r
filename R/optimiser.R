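## The instantaneous gain-risk stomatal scheme. Each timestep, candidate
## operating points are laid out on a uniform intercellular-CO2 grid; each
## candidate implies an assimilation rate (Farquhar), a stomatal conductance
## (Fick), a transpiration rate and - through the steady-state supply
## function - a leaf water potential. The scheme returns the candidate
## maximising normalised carbon gain minus normalised hydraulic cost.

#' Optimiser settings
#'
#' @param n_ci Number of intercellular-CO2 candidates (default 1000, giving
#'   a grid spacing of roughly 0.35 umol mol-1 at typical ambient CO2).
#' @param kcrit_fraction Fraction of `kmax` treated as hydraulic failure
#'   (default 0.05: residual conductance below 5% of maximum means the
#'   pathway has failed).
#' @param psi_tol Leaf-water-potential root tolerance, MPa.
#' @param gate_ecrit Exclude candidates whose transpiration exceeds the
#'   critical (supply-maximum) rate.
#' @param gate_kcrit Exclude candidates whose leaf-level conductance falls
#'   below `kcrit`.
#' @param energy_balance `"isothermal"` (leaf at air temperature) or
#'   `"iterative"`.
#' @return Object of class `optimiser_settings`.
#' @export
optimiser_settings <- function(n_ci = 1000, kcrit_fraction = 0.05,
                               psi_tol = 1e-5, gate_ecrit = TRUE,
                               gate_kcrit = TRUE,
                               energy_balance = "isothermal") {
  if (kcrit_fraction <= 0 || kcrit_fraction >= 1)
    stop("kcrit_fraction must lie in (0, 1)")
  stopifnot(n_ci >= 2, psi_tol > 0)
  structure(list(n_ci = n_ci, kcrit_fraction = kcrit_fraction,
                 psi_tol = psi_tol, gate_ecrit = gate_ecrit,
                 gate_kcrit = gate_kcrit, energy_balance = energy_balance),
            class = "optimiser_settings")
}

#' Normalised hydraulic cost
#'
#' \deqn{HC = \frac{k_{imax} - k(\Psi_{leaf})}{k_{imax} - k_{crit}},}
#' where \eqn{k_{imax} = k(\Psi_{soil,w})} is the conductance the plant could
#' have at the current root-zone potential and \eqn{k_{crit}} the residual
#' conductance defining hydraulic failure. Zero when the leaf sits at the
#' soil potential, one at the point of failure; clipped to [0, 1].
#'
#' @param psi_leaf Leaf water potential, MPa. Vectorised.
#' @param psi_soil_w Weighted root-zone soil water potential, MPa.
#' @param curve A [vulnerability_curve()].
#' @param kcrit Critical conductance, mmol m-2 s-1 MPa-1.
#' @return HC in [0, 1], or an error of class `beyond_critical` when the
#'   soil itself is at or below the failure conductance (the caller must
#'   close stomata).
#' @export
hydraulic_cost <- function(psi_leaf, psi_soil_w, curve, kcrit) {
  k_imax <- conductance(psi_soil_w, curve)
  if (k_imax <= kcrit)
    stop(structure(class = c("beyond_critical", "error", "condition"),
                   list(message = "soil potential beyond the critical conductance",
                        call = sys.call())))
  hc <- (k_imax - conductance(psi_leaf, curve)) / (k_imax - kcrit)
  pmin(pmax(hc, 0), 1)
}

## magnitude of psi at which k/kmax = frac
psi_at_k_fraction <- function(curve, frac) {
  -curve$b * (-log(frac))^(1 / curve$c)
}

## supply function E(psi) = k(psi) (psi_soil - psi), mmol m-2 s-1
supply <- function(psi, psi_soil_w, curve) {
  conductance(psi, curve) * (psi_soil_w - psi)
}

## psi at the supply maximum (dE/dpsi = 0), found by golden-section on
## [psi_floor, psi_soil_w]; psi_floor is where k has decayed to 1e-8 kmax
psi_at_supply_max <- function(psi_soil_w, curve) {
  lo <- min(psi_at_k_fraction(curve, 1e-8), psi_soil_w - 1e-9)
  opt <- stats::optimize(function(p) supply(p, psi_soil_w, curve),
                         lower = lo, upper = psi_soil_w, maximum = TRUE,
                         tol = 1e-10)
  opt$maximum
}

#' Critical transpiration rate
#'
#' The maximum steady-state transpiration the hydraulic pathway can supply
#' at the current soil potential, restricted to leaf potentials no more
#' negative than the critical potential (where `k = kcrit`). Zero when the
#' soil is already at the critical potential.
#'
#' @inheritParams hydraulic_cost
#' @return E_crit, mmol m-2 s-1 (0 when the soil is at or beyond critical).
#' @export
critical_transpiration <- function(psi_soil_w, curve, kcrit) {
  psi_crit <- psi_at_k_fraction(curve, kcrit / curve$kmax)
  if (psi_soil_w <= psi_crit) return(0)
  opt <- stats::optimize(function(p) supply(p, psi_soil_w, curve),
                         lower = psi_crit, upper = psi_soil_w, maximum = TRUE,
                         tol = 1e-10)
  max(opt$objective, supply(psi_crit, psi_soil_w, curve), 0)
}

#' Solve the steady-state leaf water potential
#'
#' Inverts the supply function `E = k(psi)(psi_soil_w - psi)` for the
#' least-negative root - the physiologically stable ascending branch of the
#' supply curve - by bracketed bisection between the supply maximum and the
#' soil potential. Transpiration beyond the supply maximum has no
#' steady-state solution and returns `NA` ("infeasible").
#'
#' @param E_leaf Transpiration, mmol m-2 s-1, `>= 0`. Vectorised.
#' @param psi_soil_w Weighted soil potential, MPa.
#' @param curve A [vulnerability_curve()].
#' @param tol Bisection tolerance, MPa.
#' @return Leaf water potential, MPa (`NA` where infeasible).
#' @export
solve_leaf_potential <- function(E_leaf, psi_soil_w, curve, tol = 1e-8) {
  if (any(E_leaf < 0)) stop("E_leaf must be >= 0")
  psi_lo <- psi_at_supply_max(psi_soil_w, curve)
  E_max <- supply(psi_lo, psi_soil_w, curve)
  n <- length(E_leaf)
  lo <- rep(psi_lo, n)
  hi <- rep(psi_soil_w, n)
  infeasible <- E_leaf > E_max + 1e-12
  kmax <- curve$kmax; b <- curve$b; cc <- curve$c
  ## vectorised bisection on the ascending branch (E decreasing in psi -> 0
  ## at psi_soil_w, E_max at psi_lo); Weibull inlined for speed
  it <- max(ceiling(log2(max(psi_soil_w - psi_lo, tol) / tol)), 1) + 2
  for (i in seq_len(it)) {
    mid <- (lo + hi) * 0.5
    s <- kmax * exp(-((-mid) / b)^cc) * (psi_soil_w - mid)
    up <- s > E_leaf  # supply excess: root lies at less-negative psi
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- (lo + hi) * 0.5
  out[E_leaf == 0] <- psi_soil_w
  out[infeasible] <- NA_real_
  out
}

#' Optimise leaf gas exchange for one timestep
#'
#' Evaluates every candidate intercellular CO2 on a uniform grid between the
#' CO2 compensation point and leaf-surface CO2: assimilation via the Farquhar
#' model, stomatal conductance via Fick's law `g_sc = A/(Cs - Ci)`, water
#' vapour conductance `g_sw = 1.57 g_sc`, transpiration, and the steady-state
#' leaf water potential from the hydraulic supply function. Candidates whose
#' transpiration exceeds the critical rate, or whose conductance falls below
#' `kcrit`, are infeasible. The returned operating point maximises
#' `profit = CG - HC`, with carbon gain `CG = A/Amax` normalised by the
#' maximum feasible assimilation (negative A maps to CG = 0) and `HC` the
#' normalised hydraulic cost. When no candidate achieves positive profit
#' (night, or soil beyond the critical potential) stomata close:
#' `g_sc = 0`, `E_leaf = 0`, `psi_leaf = psi_soil_w`, `A = -Rd`.
#'
#' @param env A [leaf_environment()].
#' @param psi_soil_w Weighted root-zone soil water potential, MPa.
#' @param traits A [species_traits()] record (or any list with `curve` and
#'   `Vcmax25`).
#' @param settings An [optimiser_settings()].
#' @param params Optional pre-built [photosyn_params()]; defaults to one
#'   built from `traits$Vcmax25` and adjusted to leaf temperature.
#' @return Object of class `gas_exchange_solution`: a named list with
#'   `Ci, A, g_sc, g_sw, E_leaf, psi_leaf, CG, HC, profit, PLC, k_at_leaf,
#'   closed`.
#' @export
optimise_gas_exchange <- function(env, psi_soil_w, traits,
                                  settings = optimiser_settings(),
                                  params = NULL) {
  stopifnot(inherits(env, "leaf_environment"),
            inherits(settings, "optimiser_settings"))
  curve <- traits$curve
  kcrit <- settings$kcrit_fraction * curve$kmax

  if (is.null(params)) {
    T_leaf <- if (identical(settings$energy_balance, "isothermal"))
      env$T_air else env$T_air  # iterative mode refines below
    params <- temperature_adjusted_params(photosyn_params(traits$Vcmax25), T_leaf)
  }

  closed_solution <- function() {
    structure(list(Ci = NA_real_, A = -params$Rd, g_sc = 0, g_sw = 0,
                   E_leaf = 0, psi_leaf = psi_soil_w,
                   CG = 0, HC = 0, profit = 0,
                   PLC = plc(psi_soil_w, curve),
                   k_at_leaf = conductance(psi_soil_w, curve),
                   closed = TRUE), class = "gas_exchange_solution")
  }

  ## beyond-critical soil: stomata must close (the hydraulic-cost
  ## denominator vanishes)
  k_imax <- conductance(psi_soil_w, curve)
  if (k_imax <= kcrit) return(closed_solution())
  if (env$Cs <= params$gamma_star) return(closed_solution())
  ## night: every candidate has A = -Rd < 0, zero conductance and zero cost,
  ## so no candidate can achieve positive profit
  if (env$PAR_leaf <= 0) return(closed_solution())

  ci <- ci_grid(params$gamma_star, env$Cs, settings$n_ci)
  A <- net_assimilation(ci, env, params)
  dC <- env$Cs - ci
  g_sc <- numeric(length(ci))
  open <- A > 0
  g_sc[open] <- A[open] / dC[open]  # Fick; last grid point has A(Cs) finite, dC = 0
  g_sc[open & dC <= 0] <- Inf
  g_sw <- PHOTOSYN_CONSTANTS$gsw_gsc_ratio * g_sc
  E <- 1000 * g_sw * env$VPD_leaf / env$P_atm

  feasible <- is.finite(E)
  if (settings$gate_ecrit) {
    E_crit <- critical_transpiration(psi_soil_w, curve, kcrit)
    feasible <- feasible & (E <= E_crit + 1e-12)
  }
  psi_leaf <- rep(NA_real_, length(ci))
  solve_idx <- feasible & E > 0
  psi_leaf[solve_idx] <- solve_leaf_potential(E[solve_idx], psi_soil_w, curve,
                                              tol = settings$psi_tol * 1e-3)
  psi_leaf[feasible & E == 0] <- psi_soil_w
  feasible <- feasible & !is.na(psi_leaf)
  k_leaf <- rep(NA_real_, length(ci))
  k_leaf[feasible] <- curve$kmax *
    exp(-((-pmin(psi_leaf[feasible], 0)) / curve$b)^curve$c)
  if (settings$gate_kcrit) feasible <- feasible & (k_leaf >= kcrit)
  if (!any(feasible)) return(closed_solution())

  Amax <- max(A[feasible])
  CG <- rep(0, length(ci))
  if (Amax > 0) CG[feasible] <- pmin(pmax(A[feasible], 0) / Amax, 1)
  HC <- rep(NA_real_, length(ci))
  HC[feasible] <- pmin(pmax((k_imax - k_leaf[feasible]) / (k_imax - kcrit), 0), 1)
  profit <- ifelse(feasible, CG - HC, -Inf)

  best <- max(profit)
  if (best <= 0) return(closed_solution())
  ## tie-break: among equal-profit candidates prefer the least-negative
  ## (hydraulically safest) leaf water potential
  cand <- which(profit >= best - 1e-12)
  i <- cand[which.max(psi_leaf[cand])]

  structure(list(Ci = ci[i], A = A[i], g_sc = g_sc[i], g_sw = g_sw[i],
                 E_leaf = E[i], psi_leaf = psi_leaf[i],
                 CG = CG[i], HC = HC[i], profit = profit[i],
                 PLC = plc(psi_leaf[i], curve), k_at_leaf = k_leaf[i],
                 closed = FALSE), class = "gas_exchange_solution")
}

#' @export
print.gas_exchange_solution <- function(x, ...) {
  if (x$closed) {
    cat(sprintf("stomata closed: psi_leaf = %.3f MPa, A = %.3f umol m-2 s-1\n",
                x$psi_leaf, x$A))
  } else {
    cat(sprintf(paste0("Ci = %.1f umol mol-1, A = %.2f umol m-2 s-1, ",
                       "g_sw = %.3f mol m-2 s-1\nE_leaf = %.3f mmol m-2 s-1, ",
                       "psi_leaf = %.3f MPa, PLC = %.1f%%\n",
                       "CG = %.3f, HC = %.3f, profit = %.3f\n"),
                x$Ci, x$A, x$g_sw, x$E_leaf, x$psi_leaf, x$PLC,
                x$CG, x$HC, x$profit))
  }
  invisible(x)
}
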