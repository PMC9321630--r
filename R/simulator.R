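## Time-stepping driver: couples the meteorological forcing, a big-leaf
## canopy, the stomatal optimiser and the soil water store; scenario and
## sensitivity engines; per-site and range-level diagnostics.

MOLAR_MASS_WATER <- 18.015  # g mol-1
PAR_PER_SW <- 2.3           # umol PAR per J shortwave (4.6 umol/J x 0.5 PAR fraction)
BEER_EXTINCTION <- 0.5

#' Run configuration
#'
#' @param LAI Leaf area index, m2 m-2: a constant or a 12-value monthly
#'   climatology (January first). Prescribed, never prognostic.
#' @param precip_scale,co2_scale,lai_scale Uniform multipliers applied to
#'   precipitation, CO2 and LAI (scenario knobs; all default 1).
#' @param kmax,kcrit_fraction,n_ci Optimiser overrides (NULL keeps the
#'   species / default values).
#' @param spinup Spin-up policy: repeat the first forcing year until
#'   root-zone storage changes by less than `spinup_tol_mm` between cycles.
#' @param spinup_max_cycles,spinup_tol_mm Cap and tolerance for spin-up.
#' @param daylight_only_monthly Use only daylight steps when forming monthly
#'   mean leaf water potentials.
#' @param seed Integer seed recorded in the output metadata.
#' @return Object of class `run_config`.
#' @export
run_config <- function(LAI = 2, precip_scale = 1, co2_scale = 1, lai_scale = 1,
                       kmax = NULL, kcrit_fraction = NULL, n_ci = 1000,
                       spinup = TRUE, spinup_max_cycles = 10,
                       spinup_tol_mm = 0.1, daylight_only_monthly = FALSE,
                       seed = 1L) {
  stopifnot(precip_scale > 0, co2_scale > 0, lai_scale > 0)
  if (!length(LAI) %in% c(1L, 12L))
    stop("LAI must be a constant or a 12-value monthly climatology")
  structure(list(LAI = LAI, precip_scale = precip_scale,
                 co2_scale = co2_scale, lai_scale = lai_scale,
                 kmax = kmax, kcrit_fraction = kcrit_fraction, n_ci = n_ci,
                 spinup = spinup, spinup_max_cycles = spinup_max_cycles,
                 spinup_tol_mm = spinup_tol_mm,
                 daylight_only_monthly = daylight_only_monthly,
                 seed = as.integer(seed)), class = "run_config")
}

lai_at <- function(config, month) {
  lai <- if (length(config$LAI) == 12L) config$LAI[month] else config$LAI
  lai * config$lai_scale
}

## mean absorbed PAR per unit leaf area under Beer's law
absorbed_par_per_leaf <- function(par_above, lai) {
  if (lai <= 0) return(0)
  par_above * (1 - exp(-BEER_EXTINCTION * lai)) / lai
}

## mmol m-2 leaf s-1 -> mm per step over the canopy
eleaf_to_mm <- function(E_leaf, lai, dt) {
  E_leaf * lai * dt * MOLAR_MASS_WATER * 1e-6
}

step_dt_seconds <- function(forcing) {
  dt <- diff(as.numeric(forcing$time))
  if (length(dt) == 0) stop("forcing must contain at least two steps")
  if (max(abs(dt - dt[1])) > 1e-6) stop("forcing timestamps must be regular")
  dt[1]
}

check_forcing <- function(forcing) {
  need <- c("time", "SW_down", "T_air", "e_air", "precip", "P_atm", "wind", "CO2")
  miss <- setdiff(need, names(forcing))
  if (length(miss)) stop("forcing missing columns: ", paste(miss, collapse = ", "))
  for (v in setdiff(need, "time")) {
    bad <- which(!is.finite(forcing[[v]]))
    if (length(bad))
      stop(sprintf("forcing has a gap/NaN in '%s' at %s", v,
                   format(forcing$time[bad[1]])))
  }
  invisible(forcing)
}

run_core <- function(forcing, traits, soil, config, settings, params25) {
  dt <- step_dt_seconds(forcing)
  n <- nrow(forcing)
  months <- as.integer(format(forcing$time, "%m"))
  psi_leaf <- psi_soil_w <- PLC <- A <- g_sw <- E_leaf <- E_canopy <-
    rep(NA_real_, n)
  theta <- matrix(NA_real_, n, nrow(soil))
  prev_T <- NA_real_
  params <- NULL
  for (t in seq_len(n)) {
    lai <- lai_at(config, months[t])
    wsp <- weighted_soil_potential(soil)
    T_air <- forcing$T_air[t]
    if (!identical(T_air, prev_T)) {
      params <- temperature_adjusted_params(params25, T_air)
      prev_T <- T_air
    }
    vpd <- max(esat_kpa(T_air) - forcing$e_air[t], 0)
    par_leaf <- absorbed_par_per_leaf(forcing$SW_down[t] * PAR_PER_SW, lai)
    env <- leaf_environment(T_air = T_air, PAR_leaf = par_leaf,
                            Cs = forcing$CO2[t] * config$co2_scale,
                            VPD_leaf = vpd, P_atm = forcing$P_atm[t],
                            wind = forcing$wind[t])
    sol <- optimise_gas_exchange(env, wsp$psi_soil_w, traits, settings, params)
    e_mm <- eleaf_to_mm(sol$E_leaf, lai, dt)
    wb <- update_water_balance(soil, forcing$precip[t] * config$precip_scale, e_mm)
    soil <- wb$profile
    psi_leaf[t] <- sol$psi_leaf
    psi_soil_w[t] <- wsp$psi_soil_w
    PLC[t] <- sol$PLC
    A[t] <- sol$A
    g_sw[t] <- sol$g_sw
    E_leaf[t] <- sol$E_leaf
    E_canopy[t] <- wb$fluxes$extraction
    theta[t, ] <- soil$theta
  }
  out <- data.frame(time = forcing$time, psi_leaf = psi_leaf,
                    psi_soil_w = psi_soil_w, PLC = PLC, A = A, g_sw = g_sw,
                    E_leaf = E_leaf, E_canopy_mm = E_canopy,
                    precip_mm = forcing$precip * config$precip_scale,
                    daylight = forcing$SW_down > 0)
  list(series = out, theta = theta, soil = soil)
}

#' Run the coupled model at a single site
#'
#' Per step: (1) derive the leaf environment from the forcing (big-leaf
#' canopy, Beer's-law mean absorbed PAR at extinction 0.5, Magnus VPD);
#' (2) optimise gas exchange against the current root-zone potential;
#' (3) scale leaf transpiration by LAI to a canopy water flux in mm;
#' (4) advance the soil water store; (5) record diagnostics. Optional
#' spin-up repeats the first forcing year until the root-zone storage
#' stabilises. Deterministic given forcing and configuration.
#'
#' @param forcing Forcing data.frame (see [generate_forcing()]): regular,
#'   gap-free `time, SW_down, T_air, e_air, precip, P_atm, wind, CO2`.
#' @param traits A [species_traits()] record.
#' @param soil A [soil_profile()].
#' @param config A [run_config()].
#' @return Object of class `simulation_output`: list with `series`
#'   (per-step data.frame), `theta` (steps x layers matrix), `soil` (final
#'   state), `species`, `config`.
#' @export
run_site <- function(forcing, traits, soil = soil_profile(),
                     config = run_config()) {
  check_forcing(forcing)
  curve <- traits$curve
  if (!is.null(config$kmax))
    curve <- vulnerability_curve(curve$b, curve$c, kmax = config$kmax)
  traits$curve <- curve
  settings <- optimiser_settings(
    n_ci = config$n_ci,
    kcrit_fraction = if (is.null(config$kcrit_fraction)) 0.05 else config$kcrit_fraction)
  params25 <- photosyn_params(traits$Vcmax25)

  if (isTRUE(config$spinup)) {
    yr0 <- as.integer(format(forcing$time[1], "%Y"))
    first_year <- forcing[as.integer(format(forcing$time, "%Y")) == yr0, , drop = FALSE]
    prev <- soil_storage_mm(soil)
    for (cy in seq_len(config$spinup_max_cycles)) {
      res <- run_core(first_year, traits, soil, config, settings, params25)
      soil <- res$soil
      cur <- soil_storage_mm(soil)
      if (abs(cur - prev) < config$spinup_tol_mm) break
      prev <- cur
    }
  }

  res <- run_core(forcing, traits, soil, config, settings, params25)
  structure(list(series = res$series, theta = res$theta, soil = res$soil,
                 species = traits$species_name, config = config),
            class = "simulation_output")
}

#' Run the three drought/CO2 scenarios
#'
#' `CTL` is the base configuration; `rPPT` applies a uniform 20%
#' precipitation reduction (`precip_scale = 0.8`); `eCO2_rPPT` combines the
#' reduced precipitation with a doubling of atmospheric CO2
#' (`co2_scale = 2`). All three run on otherwise identical inputs.
#'
#' @inheritParams run_site
#' @param base_config A [run_config()] for the control run.
#' @return Named list of [run_site()] outputs: `CTL`, `rPPT`, `eCO2_rPPT`.
#' @export
run_scenarios <- function(forcing, traits, soil = soil_profile(),
                          base_config = run_config()) {
  cfg_rppt <- base_config; cfg_rppt$precip_scale <- 0.8 * base_config$precip_scale
  cfg_both <- cfg_rppt;    cfg_both$co2_scale <- 2 * base_config$co2_scale
  list(CTL = run_site(forcing, traits, soil, base_config),
       rPPT = run_site(forcing, traits, soil, cfg_rppt),
       eCO2_rPPT = run_site(forcing, traits, soil, cfg_both))
}

#' Single-site sensitivity experiments
#'
#' Reruns the base configuration with (1) the critical conductance fraction
#' doubled (`kcrit_x2`), (2) the maximum hydraulic conductance halved
#' (`kmax_half`), (3) LAI increased by 40% (`eLAI`), and (4) the LAI
#' increase combined with doubled CO2 (`eCO2_eLAI`).
#'
#' @inheritParams run_scenarios
#' @param kmax_base The unperturbed maximum conductance,
#'   mmol m-2 s-1 MPa-1.
#' @return Named list of [run_site()] outputs, including the base `CTL`.
#' @export
sensitivity_suite <- function(forcing, traits, soil = soil_profile(),
                              base_config = run_config(), kmax_base = 1.5) {
  base_kcf <- if (is.null(base_config$kcrit_fraction)) 0.05 else base_config$kcrit_fraction
  cfg1 <- base_config; cfg1$kcrit_fraction <- 2 * base_kcf
  cfg2 <- base_config; cfg2$kmax <- kmax_base / 2
  cfg3 <- base_config; cfg3$lai_scale <- 1.4 * base_config$lai_scale
  cfg4 <- cfg3;        cfg4$co2_scale <- 2 * base_config$co2_scale
  list(CTL = run_site(forcing, traits, soil, base_config),
       kcrit_x2 = run_site(forcing, traits, soil, cfg1),
       kmax_half = run_site(forcing, traits, soil, cfg2),
       eLAI = run_site(forcing, traits, soil, cfg3),
       eCO2_eLAI = run_site(forcing, traits, soil, cfg4))
}

#' Summarise one simulation
#'
#' Site-level drought diagnostics: the minimum leaf water potential reached
#' (`psi_min`), the maximum percent loss of conductivity (`max_PLC`),
#' calendar-month mean leaf water potentials, and the count/fraction of
#' months whose mean fell below the species' P50.
#'
#' @param output A [run_site()] output.
#' @param traits The [species_traits()] used for the run (supplies P50).
#' @param daylight_only Use only steps with positive shortwave when forming
#'   monthly means (default follows the run configuration).
#' @return List: `psi_min`, `max_PLC`, `monthly` (data.frame `month`,
#'   `mean_psi_leaf`, `below_P50`), `months_below_P50`,
#'   `fraction_months_below_P50`.
#' @export
summarise_run <- function(output, traits,
                          daylight_only = output$config$daylight_only_monthly) {
  s <- output$series
  if (nrow(s) == 0) stop("empty simulation output")
  keep <- if (isTRUE(daylight_only) && "daylight" %in% names(s)) s$daylight
          else rep(TRUE, nrow(s))
  ym <- format(s$time, "%Y-%m")
  mm <- tapply(s$psi_leaf[keep], ym[keep], mean)
  monthly <- data.frame(month = names(mm), mean_psi_leaf = as.numeric(mm))
  monthly$below_P50 <- monthly$mean_psi_leaf < traits$P50
  list(psi_min = min(s$psi_leaf, na.rm = TRUE),
       max_PLC = max(s$PLC, na.rm = TRUE),
       monthly = monthly,
       months_below_P50 = sum(monthly$below_P50),
       fraction_months_below_P50 = mean(monthly$below_P50))
}

#' Species-range summary across sites
#'
#' Aggregates per-site simulations over each species' distribution:
#' the distribution of site minimum leaf water potentials, the proportion of
#' occupied sites where any monthly mean leaf water potential fell below the
#' species' P50, and a per-site occurrence-weighted (equal weights across
#' species present) mean of maximum PLC.
#'
#' @param outputs Named list (species) of named lists (site) of
#'   [run_site()] outputs.
#' @param presence Named list (species) of character vectors of occupied
#'   site names; every listed site must appear in `outputs[[species]]`.
#' @param registry A `species_registry` (for P50 values).
#' @return Object of class `species_range_summary`: list with `per_species`
#'   (data.frame `species, n_sites, psi_min_median, psi_min_q25, psi_min_q75,
#'   prop_sites_below_P50`) and `site_weighted_PLC` (named numeric: per site,
#'   the equal-weight mean over species present of the site maximum PLC).
#' @export
range_summary <- function(outputs, presence, registry) {
  species <- names(presence)
  keep <- vapply(species, function(sp) length(presence[[sp]]) > 0, logical(1))
  if (any(!keep)) {
    warning("species with zero presence excluded: ",
            paste(species[!keep], collapse = ", "))
    species <- species[keep]
  }
  rows <- lapply(species, function(sp) {
    sites <- presence[[sp]]
    summ <- lapply(sites, function(st) summarise_run(outputs[[sp]][[st]],
                                                     registry[[sp]]))
    psi_min <- vapply(summ, `[[`, numeric(1), "psi_min")
    below <- vapply(summ, function(x) x$months_below_P50 > 0, logical(1))
    data.frame(species = sp, n_sites = length(sites),
               psi_min_median = stats::median(psi_min),
               psi_min_q25 = stats::quantile(psi_min, 0.25, names = FALSE),
               psi_min_q75 = stats::quantile(psi_min, 0.75, names = FALSE),
               prop_sites_below_P50 = mean(below))
  })
  all_sites <- unique(unlist(presence[species]))
  site_plc <- vapply(all_sites, function(st) {
    present <- species[vapply(species, function(sp) st %in% presence[[sp]], logical(1))]
    mean(vapply(present, function(sp)
      summarise_run(outputs[[sp]][[st]], registry[[sp]])$max_PLC, numeric(1)))
  }, numeric(1))
  names(site_plc) <- all_sites
  structure(list(per_species = do.call(rbind, rows),
                 site_weighted_PLC = site_plc),
            class = "species_range_summary")
}
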