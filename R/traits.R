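#' Xylem vulnerability curve
#'
#' Constructs a cumulative-Weibull vulnerability curve describing the decline
#' of whole-plant (soil-to-canopy) hydraulic conductance with water potential,
#' \deqn{k(\Psi) = k_{max}\, e^{-(|\Psi|/b)^c},}
#' where `b` (MPa) sets the sensitivity (the potential at which conductance has
#' fallen to \eqn{k_{max}/e}) and `c` (dimensionless) the steepness of the
#' decline.
#'
#' @param b Sensitivity parameter, MPa. Positive magnitude.
#' @param c Shape parameter, dimensionless, positive.
#' @param kmax Maximum soil-to-canopy hydraulic conductance per unit leaf
#'   area, mmol m-2 s-1 MPa-1. Defaults to 1.5, the fixed cross-species value
#'   used throughout the package.
#'
#' @return An object of class `vulnerability_curve` (a named list with
#'   elements `b`, `c`, `kmax`).
#' @examples
#' vc <- vulnerability_curve(b = 5.03, c = 3.36)
#' conductance(-4.51, vc)   # about half of kmax
#' @export
vulnerability_curve <- function(b, c, kmax = 1.5) {
  stopifnot(is.numeric(b), is.numeric(c), is.numeric(kmax),
            length(b) == 1L, length(c) == 1L, length(kmax) == 1L)
  if (!is.finite(b) || b <= 0) stop("'b' must be a positive water-potential scale (MPa)")
  if (!is.finite(c) || c <= 0) stop("'c' must be a positive shape parameter")
  if (!is.finite(kmax) || kmax <= 0) stop("'kmax' must be positive")
  structure(list(b = b, c = c, kmax = kmax), class = "vulnerability_curve")
}

#' @export
print.vulnerability_curve <- function(x, ...) {
  cat(sprintf("Weibull vulnerability curve: b = %.3g MPa, c = %.3g, kmax = %.3g mmol m-2 s-1 MPa-1\n",
              x$b, x$c, x$kmax))
  cat(sprintf("  P12 = %.2f  P50 = %.2f  P88 = %.2f MPa\n",
              pxx(x, 0.12), pxx(x, 0.50), pxx(x, 0.88)))
  invisible(x)
}

#' Hydraulic conductance at a water potential
#'
#' Evaluates the Weibull vulnerability curve. Water potentials are negative
#' (tension) throughout the package; the curve operates on their magnitude.
#'
#' @param psi Water potential, MPa, `<= 0`. Vectorised.
#' @param curve A [vulnerability_curve()].
#' @return Hydraulic conductance, mmol m-2 s-1 MPa-1, in `(0, kmax]`.
#' @export
conductance <- function(psi, curve) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(psi > 0, na.rm = TRUE)) stop("water potential must be <= 0 (MPa, tension)")
  curve$kmax * exp(-(abs(psi) / curve$b)^curve$c)
}

#' Percent loss of hydraulic conductivity
#'
#' PLC = 100 (1 - k(psi)/kmax): the fraction of maximum conductance lost to
#' embolism at tension `psi`, the standard vulnerability diagnostic.
#'
#' @inheritParams conductance
#' @return PLC in percent, in `[0, 100)`. Vectorised over `psi`.
#' @export
plc <- function(psi, curve) {
  100 * (1 - conductance(psi, curve) / curve$kmax)
}

#' Water potential inducing a given fractional conductance loss
#'
#' Inverts the Weibull curve: returns the (negative) potential at which the
#' fractional loss of conductivity equals `x`, i.e. the generalised "Pxx"
#' threshold (P12, P50, P88 for x = 0.12, 0.50, 0.88).
#'
#' @param curve A [vulnerability_curve()].
#' @param x Fractional loss in (0, 1). Vectorised.
#' @return Water potential, MPa (negative).
#' @examples
#' pxx(vulnerability_curve(5.03, 3.36), 0.50)  # -4.51
#' @export
pxx <- function(curve, x) {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (any(x <= 0 | x >= 1, na.rm = TRUE)) stop("'x' must lie strictly in (0, 1)")
  -curve$b * (-log(1 - x))^(1 / curve$c)
}

#' Fit Weibull parameters from P12 and P50 thresholds
#'
#' Solves for the (b, c) pair whose Weibull curve passes exactly through the
#' two reported thresholds. Only P12 and P50 are used: printed P88 values in
#' trait compilations are frequently not Weibull-consistent with the fitted
#' (b, c) and are treated as metadata, never as fitting constraints.
#'
#' @param p12 Water potential at 12% loss, MPa (negative).
#' @param p50 Water potential at 50% loss, MPa (negative, more negative than
#'   `p12`).
#' @return Named numeric vector `c(b = , c = )`.
#' @export
fit_bc_from_pxx <- function(p12, p50) {
  stopifnot(is.numeric(p12), is.numeric(p50), length(p12) == 1L, length(p50) == 1L)
  if (!(p50 < p12 && p12 < 0))
    stop("require p50 < p12 < 0 (MPa): thresholds ordered toward more negative")
  ## |P50|/|P12| = (ln 2 / -ln 0.88)^(1/c)
  cc <- log(log(2) / -log(0.88)) / log(abs(p50) / abs(p12))
  b <- abs(p50) / log(2)^(1 / cc)
  c(b = b, c = cc)
}

#' Per-species trait record
#'
#' Bundles a species' vulnerability curve with its reported hydraulic
#' thresholds and photosynthetic capacity.
#'
#' @param species_name Species name.
#' @param curve A [vulnerability_curve()].
#' @param P12,P50,P88 Reported thresholds, MPa (negative), ordered
#'   `P12 >= P50 >= P88`.
#' @param Vcmax25 Maximum Rubisco carboxylation rate at 25 C,
#'   umol m-2 s-1. Defaults to the cross-eucalypt mean 86.88.
#' @param provenance Free-text citation for the trait values.
#' @return An object of class `species_traits`.
#' @export
species_traits <- function(species_name, curve, P12, P50, P88,
                           Vcmax25 = 86.88, provenance = "") {
  stopifnot(inherits(curve, "vulnerability_curve"))
  if (!(P12 < 0 && P50 < 0 && P88 < 0)) stop("P12, P50, P88 must be negative (MPa)")
  if (!(P12 >= P50 && P50 >= P88)) stop("require P12 >= P50 >= P88 (ordered toward more negative)")
  if (!is.finite(Vcmax25) || Vcmax25 <= 0) stop("Vcmax25 must be positive")
  structure(list(species_name = species_name, curve = curve,
                 P12 = P12, P50 = P50, P88 = P88,
                 Vcmax25 = Vcmax25, provenance = provenance),
            class = "species_traits")
}

#' @export
print.species_traits <- function(x, ...) {
  cat(sprintf("%s: b = %.2f MPa, c = %.2f, kmax = %.2f; P50 = %.2f MPa; Vcmax25 = %.2f umol m-2 s-1\n",
              x$species_name, x$curve$b, x$curve$c, x$curve$kmax, x$P50, x$Vcmax25))
  invisible(x)
}

#' Cross-species default Vcmax25 (umol m-2 s-1) used where no species-specific
#' estimate exists.
#' @export
DEFAULT_VCMAX25 <- 86.88

#' Load a species trait registry from CSV
#'
#' Reads a trait table (one row per species, columns
#' `species,b_MPa,c,P12_MPa,P50_MPa,P88_MPa,Vcmax25,kmax,reference`) into a
#' named list of [species_traits()] records. Blank `Vcmax25` falls back to
#' the cross-species default 86.88; blank `kmax` to 1.5.
#'
#' @param source Path to the CSV. Defaults to the packaged registry of 15
#'   south-eastern Australian eucalypt species.
#' @return Named list of `species_traits`, class `species_registry`.
#' @examples
#' reg <- load_species_registry()
#' length(reg)                       # 15
#' reg[["Eucalyptus saligna"]]$Vcmax25
#' @export
load_species_registry <- function(source = system.file("extdata", "eucalypt_traits.csv",
                                                       package = "profitmax")) {
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  required <- c("species", "b_MPa", "c", "P12_MPa", "P50_MPa", "P88_MPa")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("trait table missing required columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$species))
    stop("duplicate species in trait table: ",
         paste(unique(tab$species[duplicated(tab$species)]), collapse = ", "))
  if (!"Vcmax25" %in% names(tab)) tab$Vcmax25 <- NA_real_
  if (!"kmax" %in% names(tab)) tab$kmax <- NA_real_
  if (!"reference" %in% names(tab)) tab$reference <- ""
  bad <- !stats::complete.cases(tab[required])
  if (any(bad))
    stop("malformed trait rows (missing hydraulic values): ",
         paste(tab$species[bad], collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    species_traits(
      species_name = r$species,
      curve = vulnerability_curve(r$b_MPa, r$c,
                                  kmax = if (is.na(r$kmax)) 1.5 else r$kmax),
      P12 = r$P12_MPa, P50 = r$P50_MPa, P88 = r$P88_MPa,
      Vcmax25 = if (is.na(r$Vcmax25)) DEFAULT_VCMAX25 else r$Vcmax25,
      provenance = r$reference)
  })
  names(out) <- tab$species
  structure(out, class = "species_registry")
}

#' @export
print.species_registry <- function(x, ...) {
  cat(sprintf("Species trait registry: %d species\n", length(x)))
  for (s in x) print(s)
  invisible(x)
}
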