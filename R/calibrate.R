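## Calibration of species thermal responses to prescribed characteristic
## points, and construction of fundamental thermal performance curves.
##
## The fundamental TPC is the net energy rate under satiety ingestion and
## 100% dissolved oxygen saturation. Calibration solves, at the reference
## mass w_ref and adult ingestion (stage multiplier 1):
##   E_P(t_min) = 0 and E_P(t_max) = 0  -> (c_m, e_maint), a 2x2 linear
##     system in (log c_m, e_maint) given the mobilisation parameters;
##   argmax_T E_P = t_opt               -> t_peak, by a one-dimensional root
##     search nesting the linear solve.

## Solve (c_m, e_maint) so the fundamental curve crosses zero at t_min/t_max
## for a given t_peak. Returns list(c_m, e_maint) or NULL when infeasible.
solveMaintenance <- function(species, t_peak) {
  a_star <- species@xi * species@i_max * species@w_ref^species@beta *
    oxygenFactor(100, species@k_o2, species@h_o2)
  phi <- thermalFactor(c(species@t_min, species@t_max),
                       species@e_mob, t_peak, species@lambda)
  y <- log(a_star * phi)
  x <- 1 / (.kB * celsiusToKelvin(c(species@t_min, species@t_max)))
  e_maint <- (y[2] - y[1]) / (x[1] - x[2])
  if (!is.finite(e_maint) || e_maint <= 0) return(NULL)
  c_m <- exp(y[1] + e_maint * x[1]) / species@w_ref^species@beta_m
  list(c_m = c_m, e_maint = e_maint)
}

## Fundamental curve argmax for a candidate t_peak (continuous search then
## a fine bracket refinement around the optimum).
argmaxForPeak <- function(species, t_peak) {
  sol <- solveMaintenance(species, t_peak)
  if (is.null(sol)) return(NA_real_)
  f <- function(tc) {
    a <- species@xi * species@i_max * species@w_ref^species@beta *
      oxygenFactor(100, species@k_o2, species@h_o2)
    a * thermalFactor(tc, species@e_mob, t_peak, species@lambda) -
      sol$c_m * species@w_ref^species@beta_m * arrhenius(tc, sol$e_maint)
  }
  ## golden-section is robust to the kink at t_peak
  stats::optimize(f, c(species@t_min, species@t_max), maximum = TRUE,
                  tol = 1e-7)$maximum
}

#' Calibrate a species' thermal responses to its characteristic points
#'
#' Solves the maintenance parameters (`c_m`, `e_maint`) and the mobilisation
#' peak temperature (`t_peak`) so that the fundamental TPC at the reference
#' mass `w_ref` has zeros at `t_min` and `t_max` and its maximum at `t_opt`.
#' The solution is deterministic. The returned species passes a verification
#' on a 0.01 deg C grid: `|E_P|` below `tol_flux` times the curve maximum at
#' both zeros, argmax within `tol_topt` of `t_opt`, and a single sign change
#' of the successive differences between the zeros (dome shape).
#'
#' @param species A [SpeciesParams-class] carrying `t_min < t_opt < t_max`.
#' @param tol_flux Relative tolerance on the flux scale at the zeros
#'   (default 1e-6).
#' @param tol_topt Tolerance on the optimum temperature (deg C, default 0.1).
#' @param verify Run the dense-grid verification (default TRUE).
#' @return The calibrated [SpeciesParams-class].
#' @export
calibrateSpecies <- function(species, tol_flux = 1e-6, tol_topt = 0.1,
                             verify = TRUE) {
  stopifnot(is(species, "SpeciesParams"))
  if (!(species@t_min < species@t_opt && species@t_opt < species@t_max))
    stop(sprintf("%s: infeasible characteristic points (need t_min < t_opt < t_max)",
                 species@name))
  ## lambda must put the mobilisation factor in its declining regime above
  ## the peak, otherwise no dome is possible
  lam_min <- species@e_mob / (.kB * celsiusToKelvin(species@t_opt)^2)
  if (species@lambda <= lam_min)
    stop(sprintf("%s: lambda = %.3g too small for a supra-peak decline (needs > %.3g)",
                 species@name, species@lambda, lam_min))

  span <- species@t_max - species@t_min
  ## the maintenance solve needs a positive activation energy, i.e. the
  ## mobilisation factor at t_max must still exceed the one at t_min after
  ## the supra-peak decline: lambda * (t_max - t_peak) < L0
  L0 <- species@e_mob / .kB *
    (1 / celsiusToKelvin(species@t_min) - 1 / celsiusToKelvin(species@t_max))
  lo <- max(species@t_min + 0.02 * span,
            species@t_max - L0 / species@lambda + 1e-3 * span)
  hi <- species@t_max - 1e-3 * span
  if (lo >= species@t_opt)
    stop(sprintf("%s: infeasible characteristic points for lambda = %.3g (feasible optima start at %.2f degC); reduce lambda",
                 species@name, species@lambda, lo))
  g <- function(tp) {
    am <- argmaxForPeak(species, tp)
    if (is.na(am)) NA_real_ else am - species@t_opt
  }
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi))
    stop(sprintf("%s: maintenance solve infeasible; reduce lambda or widen (t_min, t_max)",
                 species@name))
  if (glo * ghi > 0)
    stop(sprintf("%s: calibration cannot bracket t_opt = %.2f (argmax range %.2f..%.2f)",
                 species@name, species@t_opt, lo + glo, hi + ghi))
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-6)
  t_peak <- root$root
  sol <- solveMaintenance(species, t_peak)
  if (is.null(sol))
    stop(sprintf("%s: calibration solver failed to converge", species@name))

  species@t_peak <- t_peak
  species@c_m <- sol$c_m
  species@e_maint <- sol$e_maint

  if (verify) {
    grid <- seq(species@t_min, species@t_max, by = 0.01)
    ep <- satiatedNetEnergy(species, 1, species@w_ref, grid)
    scale <- max(ep)
    if (abs(ep[1]) > tol_flux * scale || abs(ep[length(ep)]) > tol_flux * scale)
      stop(sprintf("%s: calibrated curve misses its zeros (%.2g, %.2g on flux scale %.3g)",
                   species@name, ep[1], ep[length(ep)], scale))
    t_hat <- grid[which.max(ep)]
    if (abs(t_hat - species@t_opt) > tol_topt)
      stop(sprintf("%s: calibrated argmax %.3f deviates from t_opt %.3f by more than %.2f degC",
                   species@name, t_hat, species@t_opt, tol_topt))
    signs <- sign(diff(ep))
    flips <- sum(diff(signs[signs != 0]) != 0)
    if (flips != 1L)
      stop(sprintf("%s: calibrated curve is not dome-shaped (%d sign changes)",
                   species@name, flips))
  }
  species
}

#' Fundamental net energy at arbitrary (stage, mass, temperature)
#'
#' Net energy rate under satiety ingestion for the stage and 100 percent
#' oxygen saturation. Vectorised over `w` and `tC`.
#'
#' @param species A calibrated [SpeciesParams-class].
#' @param stage "early", "juvenile" or "adult" (early applies the
#'   `eta_early` ingestion multiplier).
#' @param w Somatic mass (g).
#' @param tC Temperature (deg C).
#' @return Net energy rate (g prey equivalents per year).
#' @export
fundamentalNetEnergy <- function(species, stage, w, tC) {
  if (!isCalibrated(species))
    stop(sprintf("species '%s' is not calibrated", species@name))
  s <- if (identical(stage, "early")) species@eta_early else 1
  satiatedNetEnergy(species, s, w, tC, o2 = 100)
}

#' Fundamental thermal performance curve
#'
#' Evaluates the fundamental TPC of a calibrated species on a temperature
#' grid and derives its characteristic points: the zeros bracketing the
#' positive range (linear interpolation between grid points) and the grid
#' argmax.
#'
#' @param species A calibrated [SpeciesParams-class].
#' @param stage Life stage ("early" uses the elevated ingestion multiplier).
#' @param w Somatic mass (g, scalar). Defaults to the calibration reference
#'   mass.
#' @param t_grid Temperature grid (deg C), strictly increasing. Defaults to
#'   0.01-degree steps across the species thermal range.
#' @return A [TPCCurve-class].
#' @export
fundamentalTPC <- function(species, stage = "adult", w = species@w_ref,
                           t_grid = NULL) {
  if (!isCalibrated(species))
    stop(sprintf("species '%s' is not calibrated", species@name))
  if (is.null(t_grid)) {
    ## the early-stage curve is wider: the elevated ingestion multiplier
    ## pushes the zeros outward by several degrees
    pad_lo <- if (identical(stage, "early")) 14 else 2
    pad_hi <- if (identical(stage, "early")) 12 else 2
    t_grid <- seq(species@t_min - pad_lo, species@t_max + pad_hi, by = 0.01)
  }
  ep <- fundamentalNetEnergy(species, stage, w, t_grid)
  ch <- curvePoints(t_grid, ep)
  new("TPCCurve", temperature = t_grid, value = ep,
      species = species@name, stage = stage, mass = w,
      t_lo = unname(ch["t_lo"]), t_hi = unname(ch["t_hi"]),
      t_opt = unname(ch["t_opt"]))
}

## Zeros (interpolated) and argmax of a curve sampled on a grid.
curvePoints <- function(tc, ep) {
  i_max <- which.max(ep)
  t_opt <- tc[i_max]
  cross <- which(ep[-length(ep)] * ep[-1] < 0 | ep[-length(ep)] == 0)
  interp <- function(i) {
    if (ep[i] == 0) return(tc[i])
    tc[i] + (tc[i + 1] - tc[i]) * (0 - ep[i]) / (ep[i + 1] - ep[i])
  }
  lo <- cross[cross < i_max]
  hi <- cross[cross >= i_max]
  c(t_lo = if (length(lo)) interp(max(lo)) else NA_real_,
    t_hi = if (length(hi)) interp(min(hi)) else NA_real_,
    t_opt = t_opt)
}

#' Characteristic points of a TPC curve
#' @param curve A [TPCCurve-class].
#' @return Named vector `c(t_lo, t_hi, t_opt)` (zeros and argmax).
#' @export
tpcCharacteristics <- function(curve) {
  c(t_lo = curve@t_lo, t_hi = curve@t_hi, t_opt = curve@t_opt)
}

## Interpolator for the fundamental maximum net energy as a function of mass
## (per species and stage): max_T E_fund(w, T) evaluated on a log-mass grid
## and interpolated. Used by the near-zero guard of the deviation statistic.
fundamentalMaxFun <- function(species, stage, w_range) {
  w_lo <- max(min(w_range), 1e-6)
  w_hi <- max(max(w_range), w_lo * (1 + 1e-9))
  wg <- exp(seq(log(w_lo), log(w_hi), length.out = 60))
  tg <- seq(species@t_min - 2, species@t_max + 2, by = 0.05)
  vals <- vapply(wg, function(w)
    max(fundamentalNetEnergy(species, stage, w, tg)), numeric(1))
  if (length(unique(wg)) == 1L) return(function(w) rep(vals[1], length(w)))
  af <- stats::approxfun(log(wg), vals, rule = 2)
  function(w) af(log(w))
}

#' @describeIn fundamentalTPC Display a TPC curve summary.
#' @param object A [TPCCurve-class].
#' @export
setMethod("show", "TPCCurve", function(object) {
  cat(sprintf("TPCCurve %s/%s at w = %.3g g: %d points on [%.2f, %.2f] degC\n",
              object@species, object@stage, object@mass,
              length(object@temperature),
              min(object@temperature), max(object@temperature)))
  cat(sprintf("  max E_P %.4g at %.2f degC; zeros at %.2f / %.2f degC\n",
              max(object@value), object@t_opt, object@t_lo, object@t_hi))
  invisible(object)
})
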