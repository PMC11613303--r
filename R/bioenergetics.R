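## Individual-level energy fluxes: ingestion -> assimilation -> mobilisation
## -> maintenance -> net energy. All functions are vectorised over their
## numeric arguments and carry energy as grams of prey-mass equivalents per
## year for one individual of somatic mass w.

#' Oxygen dose-response of energy mobilisation
#'
#' Hill function `o2^h / (o2^h + k_o2^h)`: 0 at anoxia, 1/2 at the
#' half-saturation point `k_o2` regardless of `h`, saturating towards 1.
#'
#' @param o2 Dissolved oxygen saturation (percent), `>= 0`.
#' @param k_o2 Half-saturation constant (percent).
#' @param h Hill exponent.
#' @return Fraction in `[0, 1)`.
#' @export
oxygenFactor <- function(o2, k_o2, h) {
  if (any(o2 < 0)) stop("negative oxygen saturation")
  o2h <- o2^h
  o2h / (o2h + k_o2^h)
}

#' Temperature response of energy mobilisation
#'
#' Arrhenius increase normalised to 1 at the peak temperature `t_peak`, with
#' an exponential decline `exp(-lambda * (T - t_peak))` multiplying the
#' Arrhenius term above the peak. For the factor to actually decline above
#' the peak, `lambda` must exceed `e_mob / (kB * T_K^2)` (about 0.07 per
#' deg C for e_mob = 0.52 eV at 15 deg C); the calibration checks this.
#'
#' @param tC Temperature (deg C), vectorised.
#' @param e_mob Activation energy (eV).
#' @param t_peak Peak temperature (deg C).
#' @param lambda Supra-peak decline rate (per deg C).
#' @return Dimensionless factor in `(0, 1]` when `lambda` is in the declining
#'   regime.
#' @export
thermalFactor <- function(tC, e_mob, t_peak, lambda) {
  if (any(is.na(t_peak))) stop("t_peak is NA: species not calibrated")
  base <- arrhenius(tC, e_mob) / arrhenius(t_peak, e_mob)
  above <- tC > t_peak
  base[above] <- base[above] * exp(-lambda * (tC[above] - t_peak))
  base
}

#' Ingestion rate (Holling type I with satiety plateau)
#'
#' `I = w^beta * min(kappa0 * P, s * i_max)`: ingestion rises linearly with
#' accessible prey biomass `P` and plateaus at the satiety level
#' `s * i_max * w^beta`, where `s` is the life-stage multiplier. The
#' mass-specific clearance coefficient `kappa0 = i_max / p_sat` places the
#' satiety threshold at the accessible-biomass level `p_sat` (grams per cell
#' here), independent of body mass and stage-proportional to `s`.
#'
#' @param p_accessible Accessible prey biomass (g within the cell), `>= 0`.
#' @param w Somatic mass (g), `> 0`.
#' @param stage_mult Stage multiplier of `i_max` (eta_early below age 1,
#'   otherwise 1).
#' @param i_max,beta Maximum mass-specific ingestion rate and its exponent.
#' @param kappa0 Mass-specific clearance coefficient (per year per unit prey
#'   biomass). Defaults to `i_max / p_sat_g` when `p_sat_g` is given.
#' @param p_sat_g Satiety threshold biomass in grams (alternative to
#'   `kappa0`).
#' @return Ingested energy rate (g prey per year per individual).
#' @export
ingestionRate <- function(p_accessible, w, stage_mult, i_max, beta,
                          kappa0 = NULL, p_sat_g = NULL) {
  if (any(w <= 0)) stop("non-positive somatic mass")
  if (any(p_accessible < 0)) stop("negative prey biomass")
  if (is.null(kappa0)) {
    if (is.null(p_sat_g)) stop("provide kappa0 or p_sat_g")
    kappa0 <- i_max / p_sat_g
  }
  w^beta * pmin(kappa0 * p_accessible, stage_mult * i_max)
}

#' Maintenance energy rate
#'
#' `E_m = c_m * w^beta_m * exp(-e_maint / (kB * T_K))`: Arrhenius increase
#' with temperature, allometric in mass.
#'
#' @param w Somatic mass (g), `> 0`.
#' @param tC Temperature (deg C).
#' @param c_m Maintenance coefficient.
#' @param beta_m Maintenance allometric exponent.
#' @param e_maint Activation energy (eV).
#' @return Maintenance rate (g prey equivalents per year).
#' @export
maintenanceRate <- function(w, tC, c_m, beta_m, e_maint) {
  if (any(w <= 0)) stop("non-positive somatic mass")
  c_m * w^beta_m * arrhenius(tC, e_maint)
}

#' Mobilised energy rate
#'
#' `E_M = A * f_O2(O2) * phi_T(T)`: the assimilated rate scaled by the
#' oxygen dose-response and the peaked temperature response. Nondecreasing
#' in oxygen, bounded by `A * phi_T(T)` and hence by `A`.
#'
#' @param a Assimilated energy rate (g prey per year), `>= 0`.
#' @param tC Temperature (deg C).
#' @param o2 Dissolved oxygen saturation (percent), `>= 0`.
#' @param species A calibrated [SpeciesParams-class] (supplies `k_o2`,
#'   `h_o2`, `e_mob`, `t_peak`, `lambda`).
#' @return Mobilised energy rate (g prey per year).
#' @export
mobilisedEnergy <- function(a, tC, o2, species) {
  if (any(a < 0)) stop("negative assimilated energy")
  a * oxygenFactor(o2, species@k_o2, species@h_o2) *
    thermalFactor(tC, species@e_mob, species@t_peak, species@lambda)
}

#' Net energy and the full flux breakdown
#'
#' Composes ingestion, assimilation (`A = xi * I`), mobilisation and
#' maintenance into the net (production) energy rate `E_P = E_M - E_m`,
#' which may be negative.
#'
#' @param p_accessible Accessible prey biomass (g), `>= 0`.
#' @param w Somatic mass (g), `> 0`.
#' @param stage_mult Stage multiplier of ingestion.
#' @param tC Temperature (deg C).
#' @param o2 Oxygen saturation (percent).
#' @param species A calibrated [SpeciesParams-class].
#' @return data.frame with columns `I`, `A`, `E_M`, `E_m`, `E_P` (all g prey
#'   equivalents per year, one row per input element).
#' @export
netEnergy <- function(p_accessible, w, stage_mult, tC, o2, species) {
  I <- ingestionRate(p_accessible, w, stage_mult,
                     species@i_max, species@beta,
                     p_sat_g = species@p_sat * 1e6)
  A <- species@xi * I
  E_M <- mobilisedEnergy(A, tC, o2, species)
  E_m <- maintenanceRate(w, tC, species@c_m, species@beta_m, species@e_maint)
  n <- max(length(I), length(E_m), length(E_M))
  data.frame(I = rep_len(I, n), A = rep_len(A, n), E_M = rep_len(E_M, n),
             E_m = rep_len(E_m, n), E_P = rep_len(E_M, n) - rep_len(E_m, n))
}

## Net energy rate under satiety ingestion at a given oxygen level: the
## workhorse for fundamental and counterfactual curves. Vectorised over
## (w, tC, o2, stage_mult).
satiatedNetEnergy <- function(species, stage_mult, w, tC, o2 = 100) {
  a <- species@xi * stage_mult * species@i_max * w^species@beta
  em <- mobilisedEnergy(a, tC, o2, species)
  em - maintenanceRate(w, tC, species@c_m, species@beta_m, species@e_maint)
}
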