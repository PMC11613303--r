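#' Construct species parameters
#'
#' Builds a [SpeciesParams-class] object with sensible physiological defaults.
#' The thermal response of mobilisation and maintenance (`t_peak`, `c_m`,
#' `e_maint`) is left uncalibrated (`NA`) until [calibrateSpecies()] solves it
#' from the prescribed characteristic points.
#'
#' @param name Species name.
#' @param t_min,t_opt,t_max Characteristic points of the fundamental TPC
#'   (deg C), `t_min < t_opt < t_max`.
#' @param i_max Mass-specific maximum ingestion rate (g prey g^-beta per
#'   year).
#' @param beta Ingestion allometric exponent (default 0.75).
#' @param eta_early Early-life ingestion multiplier, in `[1.4, 1.9]` for the
#'   demonstration species (default 1.6).
#' @param xi Assimilation efficiency (default 0.7).
#' @param k_o2,h_o2 Oxygen dose-response half-saturation (percent) and Hill
#'   exponent.
#' @param e_mob Activation energy of mobilisation (eV, default 0.52).
#' @param lambda Supra-peak mobilisation decline rate (per deg C).
#' @param beta_m Maintenance allometric exponent (default 1: maintenance
#'   proportional to mass).
#' @param lw_c,lw_b Length-mass allometry `w = lw_c * L^lw_b`.
#' @param r_min,r_max Predator:prey mass-ratio bounds (prey mass within
#'   `[w/r_max, w/r_min]`).
#' @param mat_intercept,mat_slope Maturation reaction-norm midpoint
#'   (length in cm as a linear function of age in years).
#' @param rel_fec Relative fecundity multiplier (eggs = rel_fec * gonad mass
#'   / egg mass).
#' @param egg_mass Egg mass (g).
#' @param egg_survival Egg-to-recruit survival applied at spawning.
#' @param egg_capacity Beverton-Holt egg capacity per spawning step
#'   (default 1e15): bounds recruitment at extreme spawner abundance.
#' @param gonad_alloc Post-maturation fraction of positive net energy
#'   allocated to gonads.
#' @param p_sat Satiety threshold as accessible prey biomass per cell
#'   (tonnes).
#' @param habitat Integer cell indices; `integer(0)` = whole grid.
#' @param ltl_access Stage-resolved LTL accessibility overrides (see
#'   [SpeciesParams-class]); default `list()` applies the vertical-class and
#'   size-window rule to all stages.
#' @param vertical "pelagic", "demersal" or "benthic".
#' @param spawn_steps Steps of year with spawning.
#' @param m_bg,m_early Background and additional early-life mortality rates
#'   (per year).
#' @param max_age Species longevity (years); schools are removed beyond it.
#' @param w_ref Reference mass (g) for calibration.
#' @param t_peak,c_m,e_maint Normally left `NA` and filled by calibration;
#'   accepted here so calibrated parameter tables can be re-imported.
#' @return A [SpeciesParams-class].
#' @export
speciesParams <- function(name, t_min, t_opt, t_max,
                          i_max = 15, beta = 0.75, eta_early = 1.6, xi = 0.7,
                          k_o2 = 28, h_o2 = 2,
                          e_mob = 0.52, lambda = 0.12, beta_m = 1,
                          lw_c = 0.01, lw_b = 3,
                          r_min = 10, r_max = 1e5,
                          mat_intercept = 15, mat_slope = 0,
                          rel_fec = 1, egg_mass = 1e-3, egg_survival = 0.05,
                          egg_capacity = 1e15, gonad_alloc = 0.3,
                          p_sat = 1.5,
                          habitat = integer(0), ltl_access = list(),
                          vertical = "demersal",
                          spawn_steps = 5:8,
                          m_bg = 0.5, m_early = 1.2, max_age = 10, w_ref = 100,
                          t_peak = NA_real_, c_m = NA_real_,
                          e_maint = NA_real_) {
  new("SpeciesParams", name = name,
      t_min = t_min, t_opt = t_opt, t_max = t_max,
      i_max = i_max, beta = beta, eta_early = eta_early, xi = xi,
      k_o2 = k_o2, h_o2 = h_o2,
      e_mob = e_mob, t_peak = t_peak, lambda = lambda,
      c_m = c_m, beta_m = beta_m, e_maint = e_maint,
      lw_c = lw_c, lw_b = lw_b, r_min = r_min, r_max = r_max,
      mat_intercept = mat_intercept, mat_slope = mat_slope,
      rel_fec = rel_fec, egg_mass = egg_mass, egg_survival = egg_survival,
      egg_capacity = egg_capacity,
      gonad_alloc = gonad_alloc, p_sat = p_sat,
      habitat = as.integer(habitat), ltl_access = ltl_access,
      vertical = vertical,
      spawn_steps = as.integer(spawn_steps),
      m_bg = m_bg, m_early = m_early, max_age = max_age, w_ref = w_ref)
}

#' Is a species thermally calibrated?
#' @param species A [SpeciesParams-class].
#' @return Logical scalar.
#' @export
isCalibrated <- function(species) {
  !is.na(species@t_peak) && !is.na(species@c_m) && !is.na(species@e_maint)
}

#' Species name accessor
#' @param species A [SpeciesParams-class].
#' @export
speciesName <- function(species) species@name

#' Thermal characteristic points of a species
#' @param species A [SpeciesParams-class].
#' @return Named numeric vector `c(t_min, t_opt, t_max)`.
#' @export
thermalPoints <- function(species) {
  c(t_min = species@t_min, t_opt = species@t_opt, t_max = species@t_max)
}

#' Length from mass through the species allometry
#' @param species A [SpeciesParams-class].
#' @param w Somatic mass (g), vectorised.
#' @return Length in cm.
#' @export
lengthFromMass <- function(species, w) (w / species@lw_c)^(1 / species@lw_b)

## Stage-of-life ingestion multiplier: eta_early while age < 1, 1 afterwards.
stageMultiplier <- function(species, age) {
  ifelse(age < 1, species@eta_early, 1)
}

#' Export / import calibrated species parameters
#'
#' Flat key-value CSV (columns `species`, `parameter`, `value` plus character
#' columns carried as strings) so a calibration can be archived and reloaded
#' reproducibly.
#'
#' @param species_list List of [SpeciesParams-class] objects.
#' @param path CSV path.
#' @return `writeSpeciesCSV()`: `path` invisibly; `readSpeciesCSV()`: list of
#'   [SpeciesParams-class].
#' @export
writeSpeciesCSV <- function(species_list, path) {
  num_slots <- c("t_min", "t_opt", "t_max", "i_max", "beta", "eta_early", "xi",
                 "k_o2", "h_o2", "e_mob", "t_peak", "lambda", "c_m", "beta_m",
                 "e_maint", "lw_c", "lw_b", "r_min", "r_max", "mat_intercept",
                 "mat_slope", "rel_fec", "egg_mass", "egg_survival", "egg_capacity",
                 "gonad_alloc", "p_sat", "m_bg", "m_early", "max_age", "w_ref")
  rows <- lapply(species_list, function(sp) {
    vals <- vapply(num_slots, function(s) as.numeric(slot(sp, s)), numeric(1))
    acc <- paste(vapply(names(sp@ltl_access), function(st) {
      v <- sp@ltl_access[[st]]
      if (is.character(v)) v <- stats::setNames(rep(1, length(v)), v)
      paste0(st, "=", paste(names(v), v, sep = ":", collapse = ","))
    }, character(1)), collapse = "|")
    data.frame(species = sp@name,
               parameter = c(num_slots, "vertical", "spawn_steps", "habitat",
                             "ltl_access"),
               value = c(as.character(vals), sp@vertical,
                         paste(sp@spawn_steps, collapse = ";"),
                         paste(sp@habitat, collapse = ";"), acc),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpeciesCSV
#' @export
readSpeciesCSV <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$species), function(d) {
    getv <- function(p) d$value[match(p, d$parameter)]
    num <- function(p) as.numeric(getv(p))
    ints <- function(p) {
      s <- getv(p)
      if (is.na(s) || !nzchar(s)) integer(0)
      else as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    }
    acc_str <- getv("ltl_access")
    ltl_access <- list()
    if (!is.na(acc_str) && nzchar(acc_str)) {
      for (part in strsplit(acc_str, "|", fixed = TRUE)[[1]]) {
        kv <- strsplit(part, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2 || !nzchar(kv[2])) {
          ltl_access[[kv[1]]] <- character(0)
        } else {
          pairs <- strsplit(strsplit(kv[2], ",", fixed = TRUE)[[1]], ":",
                            fixed = TRUE)
          ltl_access[[kv[1]]] <- stats::setNames(
            vapply(pairs, function(p) as.numeric(p[2]), numeric(1)),
            vapply(pairs, `[`, character(1), 1))
        }
      }
    }
    speciesParams(
      name = d$species[1],
      t_min = num("t_min"), t_opt = num("t_opt"), t_max = num("t_max"),
      i_max = num("i_max"), beta = num("beta"), eta_early = num("eta_early"),
      xi = num("xi"), k_o2 = num("k_o2"), h_o2 = num("h_o2"),
      e_mob = num("e_mob"), lambda = num("lambda"), beta_m = num("beta_m"),
      lw_c = num("lw_c"), lw_b = num("lw_b"),
      r_min = num("r_min"), r_max = num("r_max"),
      mat_intercept = num("mat_intercept"), mat_slope = num("mat_slope"),
      rel_fec = num("rel_fec"), egg_mass = num("egg_mass"),
      egg_survival = num("egg_survival"), egg_capacity = num("egg_capacity"),
      gonad_alloc = num("gonad_alloc"),
      p_sat = num("p_sat"), habitat = ints("habitat"),
      ltl_access = ltl_access,
      vertical = getv("vertical"), spawn_steps = ints("spawn_steps"),
      m_bg = num("m_bg"), m_early = num("m_early"),
      max_age = num("max_age"), w_ref = num("w_ref"),
      t_peak = num("t_peak"), c_m = num("c_m"), e_maint = num("e_maint"))
  })
}

#' @describeIn speciesParams Display a species parameter set.
#' @param object A [SpeciesParams-class].
#' @export
setMethod("show", "SpeciesParams", function(object) {
  cat(sprintf("SpeciesParams '%s' (%s): Tmin %.1f / Topt %.1f / Tmax %.1f degC%s\n",
              object@name, object@vertical,
              object@t_min, object@t_opt, object@t_max,
              if (isCalibrated(object)) "" else "  [uncalibrated]"))
  cat(sprintf("  i_max %.3g g^(1-%.2f)/y, eta_early %.2f, xi %.2f, K_O2 %.0f%%, w_ref %.3g g\n",
              object@i_max, object@beta, object@eta_early, object@xi,
              object@k_o2, object@w_ref))
  if (isCalibrated(object))
    cat(sprintf("  calibrated: t_peak %.2f degC, c_m %.4g, E_A(maint) %.3f eV\n",
                object@t_peak, object@c_m, object@e_maint))
  invisible(object)
})
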