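#' @import methods
NULL

#' Regular spatial grid
#'
#' A rectangular grid of square cells. Cells are indexed in row-major order
#' (`cell = (row - 1) * nCols + col`); row 1 is the southern edge. The
#' latitude proxy of a row is `(row - 1) / (nRows - 1)`, i.e. 0 at the
#' southern edge and 1 at the northern edge (0.5 for a single-row grid).
#'
#' @slot n_rows,n_cols Grid dimensions (positive integers).
#' @slot cell_size Cell edge length in km.
#' @export
setClass("Grid",
  representation(n_rows = "integer", n_cols = "integer", cell_size = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@n_rows) != 1L || is.na(object@n_rows) || object@n_rows < 1L)
      msg <- c(msg, "n_rows must be a positive integer")
    if (length(object@n_cols) != 1L || is.na(object@n_cols) || object@n_cols < 1L)
      msg <- c(msg, "n_cols must be a positive integer")
    if (length(object@cell_size) != 1L || !is.finite(object@cell_size) ||
        object@cell_size <= 0)
      msg <- c(msg, "cell_size must be a positive number (km)")
    if (length(msg)) msg else TRUE
  }
)

#' Forcing scenario
#'
#' A fully parameterised recipe for a synthetic forcing climatology:
#' latitudinal temperature gradient, seasonal cycle, oxygen baseline with
#' optional hypoxic patch, and one row per low-trophic-level (LTL) prey group
#' describing its mean biomass, seasonal bloom and temperature covariation.
#' Given a grid and the scenario seed, the generated climatology is fully
#' determined.
#'
#' @slot name Scenario name.
#' @slot t_base Vertically integrated temperature at the southern edge
#'   (deg C) averaged over the year.
#' @slot t_gradient Temperature decrease from the southern to the northern
#'   edge (deg C).
#' @slot t_season_amp,t_season_phase Amplitude (deg C) and phase (step of
#'   year at which the seasonal maximum occurs) of the seasonal temperature
#'   cycle.
#' @slot t_noise_sd Standard deviation of additive temperature noise (deg C).
#' @slot o2_base,o2_season_amp,o2_season_phase Oxygen saturation baseline
#'   (percent), seasonal depression amplitude and phase of maximal depression.
#' @slot bot_t_offset,bot_o2_offset Additive offsets turning integrated
#'   fields into bottom fields (typically negative: cooler, less oxygenated).
#' @slot hypox_rows,hypox_steps,hypox_severity Rows and steps of year touched
#'   by a seasonal bottom hypoxic patch, and its severity (percentage points
#'   subtracted from bottom oxygen saturation).
#' @slot ltl data.frame with one row per LTL group: `name`, `vertical`
#'   ("planktonic" or "benthic"), `tl` (fixed trophic level), `item_mass`
#'   (nominal individual mass, g), `mean_biomass` (tonnes per cell),
#'   `bloom_amp` (relative seasonal amplitude), `bloom_phase` (step of year
#'   of bloom peak), `rho` (signed temperature-covariation coefficient) and
#'   `noise_sd` (lognormal noise sd).
#' @slot seed RNG seed of the scenario.
#' @export
setClass("ForcingScenario",
  representation(
    name = "character",
    t_base = "numeric", t_gradient = "numeric",
    t_season_amp = "numeric", t_season_phase = "numeric", t_noise_sd = "numeric",
    o2_base = "numeric", o2_season_amp = "numeric", o2_season_phase = "numeric",
    bot_t_offset = "numeric", bot_o2_offset = "numeric",
    hypox_rows = "integer", hypox_steps = "integer", hypox_severity = "numeric",
    ltl = "data.frame", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    need <- c("name", "vertical", "tl", "item_mass", "mean_biomass",
              "bloom_amp", "bloom_phase", "rho", "noise_sd")
    missing_cols <- setdiff(need, names(object@ltl))
    if (length(missing_cols))
      msg <- c(msg, paste0("ltl table lacks columns: ",
                           paste(missing_cols, collapse = ", ")))
    else {
      if (any(!object@ltl$vertical %in% c("planktonic", "benthic")))
        msg <- c(msg, "ltl$vertical must be 'planktonic' or 'benthic'")
      if (any(object@ltl$mean_biomass < 0))
        msg <- c(msg, "ltl$mean_biomass must be >= 0")
      if (any(object@ltl$tl < 1))
        msg <- c(msg, "ltl$tl must be >= 1")
      if (any(!is.finite(object@ltl$rho)))
        msg <- c(msg, "ltl$rho must be finite")
    }
    if (object@o2_base < 0) msg <- c(msg, "o2_base must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Forcing climatology
#'
#' Per time-step-of-year and per cell: vertically integrated and bottom
#' temperature (deg C), dissolved oxygen saturation (percent), and biomass of
#' each low-trophic-level prey group (tonnes per cell). The climatology is
#' periodic: forcing at simulation step t is the climatology at
#' `((t - 1) %% steps_per_year) + 1`.
#'
#' @slot grid The [Grid-class] the fields live on.
#' @slot steps_per_year Number of time steps per year.
#' @slot t_int,t_bot,o2_int,o2_bot Matrices `[steps_per_year, nCells]`.
#' @slot biomass Array `[steps_per_year, nCells, nGroups]` (tonnes per cell).
#' @slot groups data.frame with `name`, `vertical`, `tl`, `item_mass` per
#'   LTL group (same order as the biomass array's third dimension).
#' @slot scenario_name Name of the generating scenario.
#' @export
setClass("ForcingClimatology",
  representation(
    grid = "Grid", steps_per_year = "integer",
    t_int = "matrix", t_bot = "matrix", o2_int = "matrix", o2_bot = "matrix",
    biomass = "array", groups = "data.frame", scenario_name = "character"
  ),
  validity = function(object) {
    msg <- character()
    ncell <- as.integer(object@grid@n_rows) * as.integer(object@grid@n_cols)
    dims <- dim(object@t_int)
    if (!identical(dims, c(object@steps_per_year, ncell)))
      msg <- c(msg, "t_int has wrong dimensions")
    for (nm in c("t_bot", "o2_int", "o2_bot"))
      if (!identical(dim(slot(object, nm)), dims))
        msg <- c(msg, paste(nm, "shape differs from t_int"))
    bd <- dim(object@biomass)
    if (length(bd) != 3L || !identical(bd[1:2], dims) ||
        bd[3] != nrow(object@groups))
      msg <- c(msg, "biomass array shape inconsistent with grid/groups")
    if (any(object@biomass < 0)) msg <- c(msg, "negative LTL biomass")
    if (any(object@o2_int < 0) || any(object@o2_bot < 0))
      msg <- c(msg, "negative oxygen saturation")
    if (length(msg)) msg else TRUE
  }
)

#' Species parameters
#'
#' All per-species physiological, allometric, life-history and habitat
#' parameters. Thermal response parameters of energy mobilisation
#' (`t_peak`) and maintenance (`c_m`, `e_maint`) are `NA` until
#' [calibrateSpecies()] solves them from the prescribed characteristic
#' points (`t_min`, `t_opt`, `t_max`) of the fundamental thermal
#' performance curve.
#'
#' Units: masses in g, lengths in cm, rates per year, temperatures in deg C,
#' activation energies in eV, oxygen saturation in percent. Energy fluxes are
#' carried in grams of prey-mass equivalents per year.
#'
#' @slot name Species name.
#' @slot t_min,t_opt,t_max Characteristic points of the fundamental TPC
#'   (deg C) at reference mass `w_ref`; `t_min < t_opt < t_max`.
#' @slot i_max Mass-specific maximum ingestion rate: satiety ingestion is
#'   `i_max * w^beta` (g prey per year).
#' @slot beta Ingestion allometric exponent.
#' @slot eta_early Early-life multiplier of `i_max` (applies while age < 1 y).
#' @slot xi Assimilation efficiency.
#' @slot k_o2,h_o2 Half-saturation (percent saturation) and shape exponent of
#'   the oxygen dose-response of energy mobilisation.
#' @slot e_mob Activation energy of mobilisation (eV).
#' @slot t_peak Mobilisation peak temperature (deg C; calibrated).
#' @slot lambda Supra-peak decline rate of mobilisation (per deg C).
#' @slot c_m,beta_m,e_maint Maintenance coefficient, allometric exponent and
#'   activation energy; `c_m` and `e_maint` are calibrated.
#' @slot lw_c,lw_b Length-mass allometry `w = lw_c * L^lw_b` (w g, L cm).
#' @slot r_min,r_max Predator:prey mass-ratio bounds; accessible prey
#'   individual mass lies in `[w/r_max, w/r_min]` (closed bounds).
#' @slot mat_intercept,mat_slope Maturation reaction-norm midpoint:
#'   maturation occurs when length (cm) reaches
#'   `mat_intercept + mat_slope * age`.
#' @slot rel_fec,egg_mass Relative fecundity (eggs per g of gonad mass times
#'   `1/egg_mass`) and egg mass (g).
#' @slot egg_capacity Beverton-Holt pre-recruitment capacity (eggs per
#'   species per spawning step): effective eggs are
#'   `eggs / (1 + eggs / egg_capacity)`, a standard density-dependent
#'   closure that bounds recruitment when food does not.
#' @slot egg_survival Egg-to-recruit survival applied at spawning (folds
#'   pre-recruitment larval mortality).
#' @slot gonad_alloc Fraction of positive net energy allocated to gonads
#'   after maturation (biphasic growth).
#' @slot p_sat Satiety threshold expressed as accessible prey biomass per
#'   cell (tonnes): ingestion saturates when accessible biomass reaches
#'   `p_sat`. The implied mass-specific clearance coefficient is
#'   `i_max / p_sat`.
#' @slot habitat Integer cell indices of the species habitat; `integer(0)`
#'   means the whole grid.
#' @slot ltl_access Stage-resolved LTL accessibility overrides: a named list
#'   with entries `early`, `juvenile` and/or `adult`. Each entry is either a
#'   character vector of accessible LTL group names (coefficient 1), or a
#'   named numeric vector of accessibility coefficients in `[0, 1]` scaling
#'   the pool biomass that stage perceives; groups not listed get 0. An
#'   empty entry means no LTL group at all (a strictly piscivorous stage).
#'   Stages without an entry follow the vertical-class and size-window rule
#'   alone (coefficient 1).
#' @slot vertical Vertical class: "pelagic", "demersal" or "benthic".
#'   Pelagic and demersal species experience vertically integrated
#'   temperature and oxygen; benthic species experience bottom values.
#'   Benthic LTL groups are accessible to demersal and benthic species only.
#' @slot spawn_steps Steps of year during which mature schools spawn.
#' @slot m_bg,m_early Background mortality rate (per year) and additional
#'   early-life (age < 1) mortality rate.
#' @slot max_age Species longevity (years); schools older than this are
#'   removed.
#' @slot w_ref Reference somatic mass (g) at which the fundamental TPC is
#'   calibrated.
#' @export
setClass("SpeciesParams",
  representation(
    name = "character",
    t_min = "numeric", t_opt = "numeric", t_max = "numeric",
    i_max = "numeric", beta = "numeric", eta_early = "numeric", xi = "numeric",
    k_o2 = "numeric", h_o2 = "numeric",
    e_mob = "numeric", t_peak = "numeric", lambda = "numeric",
    c_m = "numeric", beta_m = "numeric", e_maint = "numeric",
    lw_c = "numeric", lw_b = "numeric",
    r_min = "numeric", r_max = "numeric",
    mat_intercept = "numeric", mat_slope = "numeric",
    rel_fec = "numeric", egg_mass = "numeric", egg_survival = "numeric",
    egg_capacity = "numeric",
    gonad_alloc = "numeric",
    p_sat = "numeric",
    habitat = "integer", ltl_access = "list", vertical = "character",
    spawn_steps = "integer",
    m_bg = "numeric", m_early = "numeric", max_age = "numeric",
    w_ref = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (!(object@t_min < object@t_opt && object@t_opt < object@t_max))
      msg <- c(msg, sprintf("%s: need t_min < t_opt < t_max", object@name))
    if (object@i_max <= 0) msg <- c(msg, sprintf("%s: i_max must be > 0", object@name))
    if (object@xi <= 0 || object@xi > 1)
      msg <- c(msg, sprintf("%s: xi must be in (0, 1]", object@name))
    if (object@eta_early < 1)
      msg <- c(msg, sprintf("%s: eta_early must be >= 1", object@name))
    if (object@r_min >= object@r_max)
      msg <- c(msg, sprintf("%s: need r_min < r_max", object@name))
    if (object@r_min <= 0) msg <- c(msg, sprintf("%s: r_min must be > 0", object@name))
    if (!object@vertical %in% c("pelagic", "demersal", "benthic"))
      msg <- c(msg, sprintf("%s: unknown vertical class '%s'", object@name, object@vertical))
    if (object@p_sat <= 0) msg <- c(msg, sprintf("%s: p_sat must be > 0", object@name))
    if (object@egg_mass <= 0) msg <- c(msg, sprintf("%s: egg_mass must be > 0", object@name))
    if (object@max_age <= 0) msg <- c(msg, sprintf("%s: max_age must be > 0", object@name))
    if (object@egg_capacity <= 0)
      msg <- c(msg, sprintf("%s: egg_capacity must be > 0", object@name))
    if (object@gonad_alloc < 0 || object@gonad_alloc > 1)
      msg <- c(msg, sprintf("%s: gonad_alloc must be in [0, 1]", object@name))
    if (length(object@ltl_access)) {
      if (!all(names(object@ltl_access) %in% c("early", "juvenile", "adult")))
        msg <- c(msg, sprintf("%s: ltl_access entries must be named early/juvenile/adult",
                              object@name))
      bad <- vapply(object@ltl_access, function(x) {
        if (is.character(x)) FALSE
        else !(is.numeric(x) && (length(x) == 0 ||
                 (!is.null(names(x)) && all(x >= 0 & x <= 1))))
      }, logical(1))
      if (any(bad))
        msg <- c(msg, sprintf("%s: ltl_access coefficients must be named numerics in [0, 1] or group-name vectors",
                              object@name))
    }
    if (length(msg)) msg else TRUE
  }
)

#' Thermal performance curve on a temperature grid
#'
#' Net energy rate evaluated on a strictly increasing temperature grid, with
#' characteristic points (zeros and argmax) derived from the grid.
#'
#' @slot temperature Temperature grid (deg C), strictly increasing.
#' @slot value Net energy rate on the grid (g prey equivalents per year).
#' @slot species,stage Provenance of the curve.
#' @slot mass Somatic mass (g) at which the curve was evaluated.
#' @slot t_lo,t_hi,t_opt Derived characteristic points: zeros bracketing the
#'   positive range and the grid argmax.
#' @export
setClass("TPCCurve",
  representation(
    temperature = "numeric", value = "numeric",
    species = "character", stage = "character", mass = "numeric",
    t_lo = "numeric", t_hi = "numeric", t_opt = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@temperature) != length(object@value))
      msg <- c(msg, "temperature and value lengths differ")
    if (length(object@temperature) > 1 && any(diff(object@temperature) <= 0))
      msg <- c(msg, "temperature grid must be strictly increasing")
    if (length(msg)) msg else TRUE
  }
)

#' Result of a community simulation
#'
#' @slot records School-level analysis records emitted after spin-up: one row
#'   per school and time step with columns `step`, `cell`, `species`, `stage`,
#'   `age`, `mass`, `n`, `ep` (mass-specific net energy rate), `temperature`
#'   and `oxygen` (the values forcing that school's bioenergetics).
#' @slot diets Aggregated diet matrix over the analysis window: rows are
#'   predator species x stage, columns prey species x stage and LTL groups,
#'   entries biomass eaten (g).
#' @slot final_schools The school table at the end of the run.
#' @slot forcing The [ForcingClimatology-class] used.
#' @slot steps_per_year,years,spinup_years Protocol actually run.
#' @slot seed Root seed of the run.
#' @slot conservation Named numeric: `overdraw` (largest relative overdraw
#'   of any prey item over the whole run) and `imbalance` (largest relative
#'   gap between summed predator intakes and summed prey removals in any
#'   step). Both should sit at numerical zero.
#' @export
setClass("SimulationResult",
  representation(
    records = "data.frame", diets = "matrix", final_schools = "data.frame",
    forcing = "ForcingClimatology",
    steps_per_year = "integer", years = "numeric", spinup_years = "numeric",
    seed = "integer", conservation = "numeric"
  )
)
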