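## Shared fixtures: a tiny calibrated species, small grids and forcing, and
## lazily computed full-pipeline runs reused across acceptance tests.

tinySpecies <- function(name = "tiny", t_min = 5, t_opt = 12, t_max = 20,
                        ...) {
  calibrateSpecies(speciesParams(name, t_min = t_min, t_opt = t_opt,
                                 t_max = t_max, w_ref = 16, ...))
}

## cache of expensive pipeline runs, computed at most once per test session
.run_cache <- new.env(parent = emptyenv())

cachedRun <- function(key, fun) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fun()
  .run_cache[[key]]
}

demoPipeline <- function(preset, seed) {
  cachedRun(paste(preset, seed, sep = "#"), function() {
    cfg <- demoConfig(preset = preset, seed = seed)
    sim <- runSimulation(cfg, seed = seed)
    species <- lapply(cfg$species, function(s)
      if (isCalibrated(s)) s else calibrateSpecies(s))
    samples <- collectSamples(sim)
    dev <- deviationStats(samples, species,
                          eps_frac = cfg$analysis$eps_frac,
                          bin_width = cfg$analysis$bin_width)
    tl <- trophicLevels(sim@diets,
                        setNames(sim@forcing@groups$tl,
                                 sim@forcing@groups$name))
    list(cfg = cfg, sim = sim, species = species, samples = samples,
         dev = dev, tl = tl)
  })
}

## Independent scalar re-implementation of the energy fluxes, used as the
## oracle for the vectorised bioenergetics (kept deliberately naive).
oracleFluxes <- function(p, w, s, tC, o2, sp) {
  kB <- 8.617333262e-5
  I <- w^sp@beta * min(sp@i_max / (sp@p_sat * 1e6) * p, s * sp@i_max)
  A <- sp@xi * I
  f_o2 <- o2^sp@h_o2 / (o2^sp@h_o2 + sp@k_o2^sp@h_o2)
  arr <- function(tc, e) exp(-e / (kB * (tc + 273.15)))
  phi <- arr(tC, sp@e_mob) / arr(sp@t_peak, sp@e_mob)
  if (tC > sp@t_peak) phi <- phi * exp(-sp@lambda * (tC - sp@t_peak))
  E_M <- A * f_o2 * phi
  E_m <- sp@c_m * w^sp@beta_m * arr(tC, sp@e_maint)
  c(I = I, A = A, E_M = E_M, E_m = E_m, E_P = E_M - E_m)
}
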