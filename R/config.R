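## Configuration: construction, YAML I/O and validation.

#' Demonstration configuration
#'
#' A desk-scale community of three demersal/benthic species spanning about
#' one trophic level, on a 10 x 10 grid of 30 km cells with 24 steps per
#' year, forced by one of the named presets:
#' \describe{
#'   \item{forage}{A small, short-lived pelagic planktivore (sprat-like):
#'     cold thermal preference; small zooplankton as larva, large
#'     zooplankton as juvenile, with the generous macrozooplankton pool
#'     entering the diet only around maturation size.}
#'   \item{flatfish}{A benthic intermediate species (dab-like): bottom
#'     temperature and oxygen, zooplankton as larva, benthos and small fish
#'     later.}
#'   \item{piscivore}{A demersal top predator (gadoid-like): zooplankton
#'     as larva, macrozooplankton, benthos and small fish as juvenile, and a
#'     strictly fish diet as an adult (flatfish juveniles, forage fish, own
#'     young), encoded by its stage accessibility matrix.}
#' }
#' The ontogenetic diet shifts are not prescribed: they emerge from the
#' size-ratio windows, the nominal LTL item masses and the vertical
#' accessibility rule.
#'
#' @param preset Forcing preset name (see [scenarioPreset()]).
#' @param n_rows,n_cols,cell_size Grid specification.
#' @param years,spinup_years Total and spin-up duration (years); analysis
#'   records cover the remainder.
#' @param steps_per_year Temporal resolution (default 24).
#' @param seed Root seed; all stage seeds derive from it.
#' @param food_factor Only for `preset = "uniform_limitation"`.
#' @return Configuration list understood by [runSimulation()] and
#'   [runAll()].
#' @export
demoConfig <- function(preset = "covarying", n_rows = 10, n_cols = 10,
                       cell_size = 30, years = 20, spinup_years = 10,
                       steps_per_year = 24, seed = 1L, food_factor = 0.5) {
  scenario <- list(preset = preset)
  if (preset == "uniform_limitation") scenario$food_factor <- food_factor
  species <- demoSpecies()
  ## static habitat bands keep each species inside its thermally suitable
  ## latitudes: the cold-adapted forage fish away from the warmest southern
  ## rows (with a northern refuge from the piscivore), the warm-adapted
  ## flatfish and the piscivore in the southern/central rows
  species[[1]]@habitat <- integer(0)  # whole grid
  species[[2]]@habitat <- southernBand(n_rows, n_cols, 0.7)
  species[[3]]@habitat <- southernBand(n_rows, n_cols, 0.7)
  list(
    schema_version = 1L,
    grid = list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size),
    steps_per_year = as.integer(steps_per_year),
    years = years, spinup_years = spinup_years,
    scenario = scenario,
    species = species,
    sim = list(rho_e = 1, m_starv = 6, n_spawn_schools = 24L, min_n = 1e-2,
               init_n0 = c(2e7, 3e5, 3e4), init_z0 = 0.8, init_max_age = 6),
    analysis = list(eps_frac = 0.01, bin_width = 0.5),
    seed = as.integer(seed)
  )
}

#' Demonstration species
#'
#' The three [SpeciesParams-class] objects of [demoConfig()], uncalibrated.
#' @return List of three [SpeciesParams-class] objects.
#' @export
demoSpecies <- function() {
  list(
    speciesParams(
      name = "forage", t_min = -1, t_opt = 10, t_max = 19,
      i_max = 18, eta_early = 1.7, p_sat = 5.2, beta_m = 0.75,
      e_mob = 0.75, lambda = 0.18,
      lw_c = 0.0045, lw_b = 3.05,
      r_min = 20, r_max = 4e4,
      ltl_access = list(adult = c(zoo_large = 0.35, macrozoo = 0.105)),
      mat_intercept = 12.5, mat_slope = 0.25,
      egg_mass = 1.2e-3, egg_survival = 0.25, gonad_alloc = 0.35,
      vertical = "pelagic", spawn_steps = 5:8,
      m_bg = 0.6, m_early = 1.5, max_age = 7, w_ref = 30),
    speciesParams(
      name = "flatfish", t_min = 1, t_opt = 12, t_max = 23,
      i_max = 14, eta_early = 1.5, p_sat = 7.2, beta_m = 0.75,
      e_mob = 0.75, lambda = 0.18,
      lw_c = 0.0105, lw_b = 3,
      r_min = 40, r_max = 2.5e4,
      mat_intercept = 19, mat_slope = 0.4,
      egg_mass = 2.5e-3, egg_survival = 0.2, gonad_alloc = 0.3,
      vertical = "benthic", spawn_steps = 3:6,
      m_bg = 0.45, m_early = 1.2, max_age = 8, w_ref = 250),
    speciesParams(
      name = "piscivore", t_min = 0, t_opt = 11, t_max = 21,
      i_max = 11, eta_early = 1.5, p_sat = 1.0, beta_m = 0.75,
      e_mob = 0.75, lambda = 0.18,
      lw_c = 0.0085, lw_b = 3,
      r_min = 6, r_max = 16000,
      ltl_access = list(early = c(zoo_small = 0.17, zoo_large = 0.17),
                        juvenile = c(zoo_large = 0.17, macrozoo = 0.035),
                        adult = c(macrozoo = 0.026)),
      mat_intercept = 30, mat_slope = 0.6,
      egg_mass = 2e-3, egg_survival = 0.04, gonad_alloc = 0.28,
      vertical = "demersal", spawn_steps = 2:5,
      m_bg = 0.5, m_early = 1.5, max_age = 15, w_ref = 600)
  )
}

## Southern band of a grid (rows 1..ceil(frac * n_rows)) as habitat cells.
southernBand <- function(n_rows, n_cols, frac) {
  rows <- seq_len(max(1L, as.integer(ceiling(frac * n_rows))))
  as.integer(outer((rows - 1L) * n_cols, seq_len(n_cols), `+`))
}

## Northern band: the last ceil(frac * n_rows) rows.
northernBand <- function(n_rows, n_cols, frac) {
  n <- max(1L, as.integer(ceiling(frac * n_rows)))
  rows <- seq.int(n_rows - n + 1L, n_rows)
  as.integer(outer((rows - 1L) * n_cols, seq_len(n_cols), `+`))
}

#' Load, validate and write configurations (YAML)
#'
#' The on-disk format mirrors [demoConfig()]'s list structure with species
#' expanded into plain parameter maps. `loadConfig()` applies documented
#' defaults (steps_per_year 24, spin-up half of the run), validates, and
#' reports all failures at once with field paths.
#'
#' @param path YAML file path.
#' @return `loadConfig()`: a validated configuration list.
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    schema_version = raw$schema_version %||% 1L,
    grid = list(
      n_rows = raw$grid$n_rows %||% 10L,
      n_cols = raw$grid$n_cols %||% 10L,
      cell_size = raw$grid$cell_size %||% 30),
    steps_per_year = as.integer(raw$steps_per_year %||% 24L),
    years = raw$years %||% 20,
    spinup_years = raw$spinup_years %||% ((raw$years %||% 20) / 2),
    scenario = raw$scenario %||% list(preset = "covarying"),
    sim = utils::modifyList(
      list(rho_e = 1, m_starv = 3, n_spawn_schools = 4L, min_n = 1e-2,
           init_n0 = 1e7, init_z0 = 0.8, init_max_age = 6),
      raw$sim %||% list()),
    analysis = utils::modifyList(
      list(eps_frac = 0.01, bin_width = 0.5), raw$analysis %||% list()),
    seed = as.integer(raw$seed %||% 1L)
  )
  cfg$species <- lapply(raw$species %||% list(), function(s)
    do.call(speciesParams, speciesArgsFromList(s)))
  validateConfig(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

speciesArgsFromList <- function(s) {
  known <- names(formals(speciesParams))
  args <- s[intersect(names(s), known)]
  for (nm in c("habitat", "spawn_steps"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(unlist(args[[nm]]))
  if (!is.null(args$ltl_access))
    args$ltl_access <- lapply(args$ltl_access, function(g) {
      v <- unlist(g)
      if (is.null(v)) character(0) else v
    })
  args
}

#' @rdname loadConfig
#' @param config A configuration list.
#' @return `validateConfig()`: the config, invisibly; errors list every
#'   failing field.
#' @export
validateConfig <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(config$grid$n_rows >= 1 && config$grid$n_cols >= 1,
      "grid.n_rows/n_cols: must be >= 1")
  chk(config$steps_per_year >= 1, "steps_per_year: must be >= 1")
  chk(config$years > 0, "years: must be > 0")
  chk(config$spinup_years >= 0 && config$spinup_years < config$years,
      "spinup_years: must lie in [0, years)")
  if (is.list(config$scenario) && !is(config$scenario, "ForcingScenario"))
    chk(!is.null(config$scenario$preset) &&
          config$scenario$preset %in% c("optimal", "uniform_limitation",
                                        "covarying"),
        sprintf("scenario.preset: unknown preset '%s'",
                config$scenario$preset %||% "<missing>"))
  ncell <- config$grid$n_rows * config$grid$n_cols
  for (i in seq_along(config$species)) {
    sp <- config$species[[i]]
    if (!is(sp, "SpeciesParams")) {
      chk(FALSE, sprintf("species[%d]: not a SpeciesParams object", i))
      next
    }
    v <- validObject(sp, test = TRUE)
    if (!isTRUE(v))
      errs <- c(errs, sprintf("species[%d] (%s): %s", i, sp@name,
                              paste(v, collapse = "; ")))
    if (length(sp@habitat) && any(sp@habitat < 1 | sp@habitat > ncell))
      chk(FALSE, sprintf("species[%d] (%s): habitat cells outside grid",
                         i, sp@name))
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(config)
}

#' @rdname loadConfig
#' @export
writeConfig <- function(config, path) {
  out <- config
  out$scenario <- if (is(config$scenario, "ForcingScenario"))
    list(preset = config$scenario@name) else config$scenario
  num_slots <- c("t_min", "t_opt", "t_max", "i_max", "beta", "eta_early",
                 "xi", "k_o2", "h_o2", "e_mob", "lambda", "beta_m", "lw_c",
                 "lw_b", "r_min", "r_max", "mat_intercept", "mat_slope",
                 "rel_fec", "egg_mass", "egg_survival", "egg_capacity", "gonad_alloc",
                 "p_sat", "m_bg", "m_early", "max_age", "w_ref", "t_peak",
                 "c_m", "e_maint")
  out$species <- lapply(config$species, function(sp) {
    vals <- lapply(num_slots, function(s) slot(sp, s))
    names(vals) <- num_slots
    vals <- vals[!vapply(vals, function(x) length(x) == 1 && is.na(x),
                         logical(1))]
    c(list(name = sp@name, vertical = sp@vertical,
           spawn_steps = sp@spawn_steps),
      if (length(sp@habitat)) list(habitat = sp@habitat),
      ## explicit maps so YAML keeps the group names on the coefficients
      if (length(sp@ltl_access))
        list(ltl_access = lapply(sp@ltl_access, function(v) {
          if (is.character(v)) v <- stats::setNames(rep(1, length(v)), v)
          as.list(v)
        })),
      vals)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
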