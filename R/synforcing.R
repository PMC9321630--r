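## Synthetic sub-daily meteorological forcing and the Standardised
## Precipitation Index. The generator emulates 3-hourly station weather -
## solar-geometry shortwave, seasonal+diurnal temperature with autocorrelated
## noise, humidity bounded by realistic relative humidity, and Poisson
## occurrence x gamma depth rainfall - with an optional drought block that
## suppresses rain frequency over a chosen span.

#' Climate specification for the forcing generator
#'
#' @param map_mm Mean annual precipitation target, mm yr-1.
#' @param rain_day_freq Probability a given day is wet.
#' @param t_mean,t_seasonal_amp Annual mean air temperature and the
#'   amplitude of its seasonal cycle, C.
#' @param t_diurnal_amp Amplitude of the diurnal temperature cycle, C.
#' @param latitude Site latitude, degrees (negative south) - sets solar
#'   geometry and the phase of the seasons.
#' @param co2 Baseline CO2 mole fraction, umol mol-1.
#' @param rh_range Bounds kept on relative humidity (fraction).
#' @param drought_years Optional integer vector of year indices (1-based)
#'   over which the drought block applies.
#' @param drought_rain_factor Multiplier on rain-day frequency within the
#'   drought block.
#' @return Object of class `climate_spec`.
#' @export
climate_spec <- function(map_mm = 700, rain_day_freq = 0.25,
                         t_mean = 17, t_seasonal_amp = 7, t_diurnal_amp = 5,
                         latitude = -30.4, co2 = 400,
                         rh_range = c(0.2, 1.0),
                         drought_years = NULL, drought_rain_factor = 0.3) {
  if (map_mm <= 0) stop("mean annual precipitation must be positive")
  stopifnot(rain_day_freq > 0, rain_day_freq <= 1, co2 > 0,
            drought_rain_factor > 0)
  structure(list(map_mm = map_mm, rain_day_freq = rain_day_freq,
                 t_mean = t_mean, t_seasonal_amp = t_seasonal_amp,
                 t_diurnal_amp = t_diurnal_amp, latitude = latitude,
                 co2 = co2, rh_range = rh_range,
                 drought_years = drought_years,
                 drought_rain_factor = drought_rain_factor),
            class = "climate_spec")
}

## top-of-atmosphere-style clear-sky shortwave from solar geometry, W m-2
clearsky_sw <- function(doy, hour, latitude) {
  decl <- -23.45 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  lat <- latitude * pi / 180
  ha <- (hour - 12) * pi / 12
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
  1000 * pmax(cosz, 0)
}

#' Generate synthetic sub-daily meteorological forcing
#'
#' Builds a regular forcing series (default 3-hourly) with: shortwave from
#' solar geometry modulated by a daily transmissivity (lower on rain days);
#' air temperature as seasonal + diurnal harmonics plus AR(1) daily noise;
#' air vapour pressure derived from a bounded relative-humidity process
#' (never generated inconsistently with temperature); rainfall as Bernoulli
#' rain days with gamma depths tuned to the target mean annual
#' precipitation, spread over a few sub-daily steps; constant pressure and
#' CO2; lognormal-ish wind. Fully reproducible from `seed`.
#'
#' @param spec A [climate_spec()].
#' @param years Number of simulated years (365-day years, no leap days).
#' @param timestep Step length, s (default 10800 = 3 h; must divide 1 day).
#' @param seed Integer seed.
#' @param start Start timestamp (UTC).
#' @return Forcing data.frame with columns `time` (POSIXct), `SW_down`
#'   (W m-2), `T_air` (C), `e_air` (vapour pressure, kPa), `precip`
#'   (mm per step), `wind` (m s-1), `P_atm` (kPa), `CO2` (umol mol-1).
#' @export
generate_forcing <- function(spec, years = 3, timestep = 10800, seed = 1,
                             start = as.POSIXct("2017-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(spec, "climate_spec"))
  if (years < 1) stop("years must be >= 1")
  if ((86400 %% timestep) != 0) stop("timestep must divide one day")
  set.seed(as.integer(seed))
  spd <- 86400 %/% timestep              # steps per day
  ndays <- 365L * as.integer(years)
  n <- ndays * spd
  day <- rep(seq_len(ndays), each = spd)
  doy <- (day - 1L) %% 365L + 1L
  yr <- (day - 1L) %/% 365L + 1L
  hour <- rep(seq(0, 24 - 24 / spd, by = 24 / spd), ndays) + 12 / spd

  ## rainfall: Bernoulli rain days x gamma depths, drought block optional
  freq <- rep(spec$rain_day_freq, ndays)
  if (!is.null(spec$drought_years))
    freq[yr[seq(1, n, by = spd)] %in% spec$drought_years] <-
      spec$rain_day_freq * spec$drought_rain_factor
  wet <- stats::rbinom(ndays, 1L, freq) == 1L
  mean_depth <- spec$map_mm / (365 * spec$rain_day_freq)
  shape <- 0.75
  depths <- ifelse(wet, stats::rgamma(ndays, shape = shape,
                                      scale = mean_depth / shape), 0)
  ## spread each day's rain over 1-3 consecutive steps starting at random
  precip <- numeric(n)
  wet_days <- which(wet)
  if (length(wet_days)) {
    nsteps <- sample(1:3, length(wet_days), replace = TRUE)
    starts <- sample.int(spd, length(wet_days), replace = TRUE)
    for (j in seq_along(wet_days)) {
      d <- wet_days[j]
      idx <- (d - 1L) * spd + ((starts[j] + seq_len(nsteps[j]) - 2L) %% spd) + 1L
      precip[idx] <- precip[idx] + depths[d] / nsteps[j]
    }
  }

  ## temperature: seasonal (Jan warm in the southern hemisphere) + diurnal
  ## (peak mid-afternoon) + AR(1) daily anomaly
  season_phase <- if (spec$latitude < 0) 17 else 199  # warmest day of year
  t_season <- spec$t_mean +
    spec$t_seasonal_amp * cos(2 * pi * (doy - season_phase) / 365)
  anom_day <- as.numeric(stats::filter(stats::rnorm(ndays, 0, 1.6),
                                       0.7, method = "recursive"))
  t_air <- t_season + rep(anom_day, each = spd) +
    spec$t_diurnal_amp * cos(2 * pi * (hour - 15) / 24)

  ## shortwave: clear-sky geometry x daily transmissivity (cloudier when wet)
  tau_day <- ifelse(wet, stats::runif(ndays, 0.25, 0.55),
                    stats::runif(ndays, 0.6, 0.78))
  sw <- clearsky_sw(doy, hour, spec$latitude) * rep(tau_day, each = spd)

  ## humidity: bounded daily RH, wetter on rain days; e from daily-minimum
  ## temperature so RH never exceeds 1 within the day
  rh_day <- pmin(pmax(ifelse(wet, stats::runif(ndays, 0.65, 0.95),
                             stats::runif(ndays, 0.35, 0.7)),
                      spec$rh_range[1]), spec$rh_range[2])
  t_min_day <- t_season[seq(1, n, by = spd)] + anom_day - spec$t_diurnal_amp
  e_day <- rh_day * esat_kpa(t_min_day)
  e_air <- rep(e_day, each = spd)
  e_air <- pmin(e_air, esat_kpa(t_air))  # cap RH at 1 for every step

  wind <- pmax(stats::rlnorm(n, meanlog = log(2), sdlog = 0.4), 0.1)

  data.frame(time = start + (seq_len(n) - 1L) * timestep,
             SW_down = sw, T_air = t_air, e_air = e_air, precip = precip,
             wind = wind, P_atm = 101.325, CO2 = spec$co2)
}

#' Uniformly perturb a forcing series
#'
#' Scales precipitation and CO2 by constant factors, leaving every other
#' field bit-identical - the construction behind the reduced-rainfall and
#' CO2-doubling scenarios.
#'
#' @param forcing A forcing data.frame.
#' @param precip_scale,co2_scale Positive multipliers.
#' @return The perturbed forcing.
#' @export
perturb_forcing <- function(forcing, precip_scale = 1, co2_scale = 1) {
  stopifnot(precip_scale > 0, co2_scale > 0)
  forcing$precip <- forcing$precip * precip_scale
  forcing$CO2 <- forcing$CO2 * co2_scale
  forcing
}

## Thom approximation for gamma ML estimates
thom_gamma <- function(x) {
  xbar <- mean(x)
  A <- log(xbar) - mean(log(x))
  shape <- (1 + sqrt(1 + 4 * A / 3)) / (4 * A)
  list(shape = shape, rate = shape / xbar)
}

#' Standardised Precipitation Index
#'
#' McKee-style SPI: `window`-month rolling precipitation sums are fitted
#' with a gamma distribution over a baseline period (maximum likelihood,
#' falling back to the Thom approximation if the ML fit fails; months with
#' zero accumulated precipitation are handled by the mixture CDF
#' `H(x) = q + (1 - q) G(x)` with `q` the baseline zero fraction), and each
#' sum is mapped through the fitted CDF and the standard normal quantile.
#'
#' @param monthly_precip Numeric vector of monthly precipitation totals, mm.
#' @param window Accumulation window, months (default 6).
#' @param baseline Integer indices (into `monthly_precip`) of the baseline
#'   months; defaults to the whole series. At least 30 baseline window sums
#'   are required.
#' @return Numeric vector the length of `monthly_precip`; the first
#'   `window - 1` entries are `NA`.
#' @export
spi <- function(monthly_precip, window = 6, baseline = seq_along(monthly_precip)) {
  if (any(monthly_precip < 0, na.rm = TRUE)) stop("negative monthly precipitation")
  n <- length(monthly_precip)
  sums <- rep(NA_real_, n)
  if (n >= window)
    sums[window:n] <- as.numeric(stats::filter(monthly_precip, rep(1, window),
                                               sides = 1))[window:n]
  base_sums <- sums[intersect(baseline, which(!is.na(sums)))]
  if (length(base_sums) < 30)
    stop("need at least 30 baseline window sums to fit the SPI distribution")
  q0 <- mean(base_sums == 0)
  pos <- base_sums[base_sums > 0]
  fit <- tryCatch(
    MASS::fitdistr(pos, "gamma", lower = c(1e-8, 1e-8)),
    error = function(e) NULL)
  par <- if (!is.null(fit)) list(shape = fit$estimate[["shape"]],
                                 rate = fit$estimate[["rate"]])
         else thom_gamma(pos)
  H <- function(x) {
    p <- ifelse(x <= 0, q0,
                q0 + (1 - q0) * stats::pgamma(x, shape = par$shape, rate = par$rate))
    pmin(pmax(p, 1e-6), 1 - 1e-6)  # keep the normal quantile finite
  }
  stats::qnorm(H(sums))
}
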