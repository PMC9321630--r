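## Multilayer soil water store. Campbell retention/conductivity, a
## root-conductance-weighted root-zone water potential, and a tipping-bucket
## cascade with conductivity-limited drainage in place of a full Richards
## solver: the hydraulic scheme upstream consumes only the weighted potential,
## so the store needs to be conservative and directionally right, not a PDE.

#' Layered soil profile
#'
#' Builds a soil profile (surface to depth) with Campbell retention
#' parameters, per-layer root fractions and an initial moisture state. The
#' default is six layers totalling 4.6 m (0.1, 0.25, 0.65, 1.0, 1.3, 1.3 m)
#' with vertically uniform texture and an exponential root profile
#' (e-folding depth 0.5 m).
#'
#' @param thickness Layer thicknesses, m, surface first.
#' @param theta_sat Saturated volumetric water content, m3 m-3 (recycled).
#' @param psi_e Air-entry potential, MPa, small negative (recycled).
#' @param b_soil Campbell retention exponent, dimensionless (recycled).
#' @param K_sat Saturated hydraulic conductivity, mm per timestep (recycled).
#' @param root_frac Per-layer root fractions summing to 1, or `NULL` to use
#'   the exponential profile.
#' @param root_efold E-folding depth of the exponential root profile, m.
#' @param theta Initial water content, m3 m-3 (recycled); defaults to the
#'   field-capacity state (Campbell curve at -0.01 MPa), i.e. a profile
#'   drained to equilibrium.
#' @return Object of class `soil_profile`: a data.frame with one row per
#'   layer and columns `thickness, depth_top, depth_bottom, theta, theta_sat,
#'   psi_e, b_soil, K_sat, root_frac`.
#' @export
soil_profile <- function(thickness = c(0.1, 0.25, 0.65, 1.0, 1.3, 1.3),
                         theta_sat = 0.45, psi_e = -0.74e-3, b_soil = 6.4,
                         K_sat = 25, root_frac = NULL, root_efold = 0.5,
                         theta = NULL) {
  n <- length(thickness)
  stopifnot(n >= 1, all(thickness > 0))
  depth_bottom <- cumsum(thickness)
  depth_top <- depth_bottom - thickness
  if (is.null(root_frac)) {
    ## mass of exp(-z / efold) within each layer, renormalised over the profile
    cdf <- function(z) 1 - exp(-z / root_efold)
    root_frac <- (cdf(depth_bottom) - cdf(depth_top)) / cdf(max(depth_bottom))
  }
  if (is.null(theta)) {
    ## start drained to equilibrium: field capacity (-0.01 MPa)
    theta <- pmin(rep_len(theta_sat, n) *
                    (-0.01 / rep_len(psi_e, n))^(-1 / rep_len(b_soil, n)),
                  rep_len(theta_sat, n))
  }
  prof <- data.frame(thickness = thickness, depth_top = depth_top,
                     depth_bottom = depth_bottom,
                     theta = rep_len(theta, n),
                     theta_sat = rep_len(theta_sat, n),
                     psi_e = rep_len(psi_e, n),
                     b_soil = rep_len(b_soil, n),
                     K_sat = rep_len(K_sat, n),
                     root_frac = root_frac / sum(root_frac))
  if (any(prof$theta < 0 | prof$theta > prof$theta_sat))
    stop("initial theta outside [0, theta_sat]")
  if (any(prof$psi_e >= 0)) stop("psi_e must be negative")
  if (any(prof$b_soil <= 0)) stop("b_soil must be positive")
  class(prof) <- c("soil_profile", "data.frame")
  prof
}

#' Campbell matric potential
#'
#' \deqn{\Psi_s = \psi_e (\theta/\theta_{sat})^{-b},} returning `psi_e` at
#' saturation and growing more negative as the layer dries.
#'
#' @param theta Volumetric water content, m3 m-3, `> 0`. Vectorised with
#'   the layer parameters.
#' @param layer A one-row slice of a [soil_profile()] (or any list with
#'   `psi_e`, `b_soil`, `theta_sat`).
#' @return Matric potential, MPa (negative).
#' @export
matric_potential <- function(theta, layer) {
  if (any(theta <= 0)) stop("theta must be positive")
  layer$psi_e * (theta / layer$theta_sat)^(-layer$b_soil)
}

#' Campbell hydraulic conductivity
#'
#' \deqn{K = K_{sat} (\theta/\theta_{sat})^{2b+3}.}
#'
#' @inheritParams matric_potential
#' @return Conductivity in the units of `K_sat` (mm per timestep).
#' @export
hydraulic_conductivity <- function(theta, layer) {
  if (any(theta <= 0)) stop("theta must be positive")
  layer$K_sat * (theta / layer$theta_sat)^(2 * layer$b_soil + 3)
}

#' Root-conductance-weighted soil water potential
#'
#' The root-zone potential seen by the plant: per-layer matric potentials
#' averaged with weights proportional to root fraction times soil hydraulic
#' conductivity. Wet profiles weight the shallow, root-dense layers; as the
#' surface dries its conductivity collapses and the weight mass shifts to
#' deeper, wetter layers.
#'
#' @param profile A [soil_profile()].
#' @return List with `psi_soil_w` (MPa) and `weights` (per-layer, sum 1).
#' @export
weighted_soil_potential <- function(profile) {
  psi <- matric_potential(pmax(profile$theta, 1e-9), profile)
  raw <- profile$root_frac * hydraulic_conductivity(pmax(profile$theta, 1e-9), profile)
  if (sum(raw) <= 0 || !all(is.finite(raw))) {
    warning("fully dry root zone: falling back to deepest layer potential")
    w <- rep(0, nrow(profile)); w[length(w)] <- 1
    return(list(psi_soil_w = psi[length(psi)], weights = w))
  }
  w <- raw / sum(raw)
  list(psi_soil_w = sum(w * psi), weights = w)
}

## theta at "field capacity": Campbell inverted at -0.01 MPa (~ -10 kPa)
theta_fc <- function(profile, psi_fc = -0.01) {
  pmin(profile$theta_sat * (psi_fc / profile$psi_e)^(-1 / profile$b_soil),
       profile$theta_sat)
}

#' Advance the soil water store one timestep
#'
#' Bookkeeping, in order: (1) canopy extraction distributed over layers by
#' the current uptake weights, clipped to available water (shortfall
#' reported); (2) infiltration filling layers from the surface down, with
#' whatever cannot be stored anywhere becoming saturation-excess runoff;
#' (3) gravitational cascade drainage: each layer passes
#' `min(K(theta), water above field capacity)` to the layer below, the bottom
#' layer drains freely out of the profile. Mass balance is exact:
#' `d storage = infiltration - extraction - runoff - drainage`.
#'
#' @param profile A [soil_profile()].
#' @param infiltration Water reaching the soil surface this step, mm.
#' @param canopy_extraction Transpiration demand this step, mm.
#' @return List: `profile` (updated), `fluxes` (list with `infiltration`,
#'   `extraction` actually removed, `shortfall`, `runoff`, `drainage`,
#'   `per_layer_extraction` in mm), all per timestep.
#' @export
update_water_balance <- function(profile, infiltration, canopy_extraction) {
  if (infiltration < 0 || canopy_extraction < 0)
    stop("infiltration and canopy_extraction must be >= 0")
  n <- nrow(profile)
  theta <- profile$theta
  theta_sat <- profile$theta_sat
  K_sat <- profile$K_sat
  b_soil <- profile$b_soil
  mm <- profile$thickness * 1000  # mm of water per unit theta
  storage0 <- sum(theta * mm)

  ## 1. extraction by uptake weights, clipped per layer
  w <- if (canopy_extraction > 0) weighted_soil_potential(profile)$weights
       else profile$root_frac
  demand <- canopy_extraction * w
  avail <- theta * mm
  take <- pmin(demand, avail)
  shortfall <- canopy_extraction - sum(take)
  ## redistribute any clipped demand to layers that still hold water
  if (shortfall > 1e-12) {
    room <- avail - take
    if (sum(room) > 0) {
      extra <- pmin(shortfall * room / sum(room), room)
      take <- take + extra
      shortfall <- canopy_extraction - sum(take)
    }
  }
  theta <- theta - take / mm

  ## 2. infiltration, top down; overflow that fits nowhere is runoff
  water <- infiltration
  for (i in seq_len(n)) {
    if (water <= 0) break
    room <- (theta_sat[i] - theta[i]) * mm[i]
    added <- min(water, room)
    theta[i] <- theta[i] + added / mm[i]
    water <- water - added
  }
  runoff <- water

  ## 3. conductivity-limited cascade drainage; free drainage at the bottom
  fc <- theta_fc(profile)
  drain_in <- 0
  for (i in seq_len(n)) {
    theta[i] <- theta[i] + drain_in / mm[i]
    ## drainage into a layer may not exceed saturation; push excess onward
    over_sat <- max(theta[i] - theta_sat[i], 0) * mm[i]
    theta[i] <- min(theta[i], theta_sat[i])
    excess <- max(theta[i] - fc[i], 0) * mm[i]
    K <- K_sat[i] * (max(theta[i], 1e-9) / theta_sat[i])^(2 * b_soil[i] + 3)
    out <- min(K, excess)
    theta[i] <- theta[i] - out / mm[i]
    drain_in <- out + over_sat
  }
  drainage <- drain_in

  profile$theta <- theta
  storage1 <- sum(theta * mm)
  fluxes <- list(infiltration = infiltration,
                 extraction = canopy_extraction - shortfall,
                 shortfall = shortfall,
                 runoff = runoff, drainage = drainage,
                 per_layer_extraction = take,
                 dstorage = storage1 - storage0)
  list(profile = profile, fluxes = fluxes)
}

#' Total water stored in a profile, mm
#' @param profile A [soil_profile()].
#' @export
soil_storage_mm <- function(profile) {
  sum(profile$theta * profile$thickness * 1000)
}
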