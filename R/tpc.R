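## Realised-TPC pipeline: build per-(species, stage, cell, step) samples from
## simulation records, compare them with the fundamental curve, and decompose
## the mean relative deviation into oxygen- and food-attributable parts.

#' Classify a life stage
#'
#' Early life runs from hatching to age 1; juveniles are older immature
#' fish; adults are mature. Vectorised.
#'
#' @param age Age in years, `>= 0`.
#' @param mature Logical maturity flag.
#' @return Character vector: "early", "juvenile" or "adult".
#' @export
classifyStage <- function(age, mature) {
  if (any(age < 0)) stop("negative age")
  ifelse(age < 1, "early", ifelse(mature, "adult", "juvenile"))
}

#' Collect realised-TPC samples from simulation records
#'
#' One sample per occupied (species, stage, cell, step): the school-weighted
#' mean mass-specific net energy rate (g prey g^-beta per year) of all
#' schools of that stage in the cell at that step, paired with the
#' temperature and oxygen saturation that forced them (vertically integrated
#' for pelagic and demersal species, bottom for benthic) and the mean
#' somatic mass. Mass-specific rates make the cell average insensitive to
#' the mix of school masses when the maintenance and ingestion allometries
#' share one exponent.
#'
#' @param records School-level record table (see
#'   [SimulationResult-class]), or a [SimulationResult-class].
#' @return data.frame with columns `species`, `stage`, `cell`, `step`,
#'   `ep`, `mass`, `temperature`, `oxygen`, `n_schools`.
#' @export
collectSamples <- function(records) {
  if (is(records, "SimulationResult")) records <- records@records
  need <- c("step", "cell", "species", "stage", "ep", "mass",
            "temperature", "oxygen")
  if (!all(need %in% names(records)))
    stop("records lack required columns: ",
         paste(setdiff(need, names(records)), collapse = ", "))
  if (nrow(records) == 0L)
    return(data.frame(species = character(0), stage = character(0),
                      cell = integer(0), step = integer(0), ep = numeric(0),
                      mass = numeric(0), temperature = numeric(0),
                      oxygen = numeric(0), n_schools = integer(0)))
  key <- paste(records$species, records$stage, records$cell, records$step,
               sep = "\r")
  cnt <- rowsum(rep(1, nrow(records)), key)
  sums <- rowsum(records[, c("ep", "mass", "temperature", "oxygen")], key)
  ord <- match(rownames(cnt), key)
  out <- data.frame(
    species = records$species[ord], stage = records$stage[ord],
    cell = records$cell[ord], step = records$step[ord],
    ep = sums$ep / cnt[, 1], mass = sums$mass / cnt[, 1],
    temperature = sums$temperature / cnt[, 1],
    oxygen = sums$oxygen / cnt[, 1],
    n_schools = as.integer(cnt[, 1]))
  rownames(out) <- NULL
  out[order(out$species, out$stage, out$step, out$cell), , drop = FALSE]
}

#' Mean relative deviation of realised from fundamental net energy
#'
#' `D = (1/n) * sum_j (E_fund(T_j) - E_j) / E_fund(T_j)` over retained
#' samples, where `E_fund` is the fundamental net energy at the sample's
#' stage, mass and temperature. Samples whose fundamental value is at or
#' below `eps_frac` times the fundamental maximum (at the same stage and
#' mass) are excluded — the ratio diverges at the TPC zeros — and reported
#' in `n_excluded`.
#'
#' @param species A calibrated [SpeciesParams-class].
#' @param samples Sample table for one species (see [collectSamples()]);
#'   the `stage` column must be constant or absent deviations are computed
#'   per row's own stage.
#' @param eps_frac Near-zero guard as a fraction of the fundamental maximum
#'   (default 0.01).
#' @param values Optional replacement for `samples$ep` (used for
#'   counterfactual curves); defaults to the realised values.
#' @return List with `D` (NA when no sample survives the guard), `n`,
#'   `n_excluded` and the logical vector `retained`.
#' @export
tpcDeviation <- function(species, samples, eps_frac = 0.01, values = NULL) {
  if (is.null(values)) values <- samples$ep
  stopifnot(length(values) == nrow(samples))
  if (nrow(samples) == 0L)
    return(list(D = NA_real_, n = 0L, n_excluded = 0L, retained = logical(0)))
  e_fund <- fundamentalBy(species, samples$stage, samples$mass,
                          samples$temperature)
  thr <- fundamentalMaxBy(species, samples$stage, samples$mass)
  ## two-level guard: the sample's fundamental value must be well above zero
  ## relative to the dome height at its mass, and the dome itself must be
  ## non-degenerate relative to the mass-specific flux scale (fish close to
  ## their asymptotic mass have a vanishing dome and no meaningful relative
  ## deviation)
  s <- ifelse(samples$stage == "early", species@eta_early, 1)
  flux_scale <- species@xi * s * species@i_max *
    oxygenFactor(100, species@k_o2, species@h_o2)
  retained <- thr > eps_frac * flux_scale & e_fund > eps_frac * thr
  n <- sum(retained)
  D <- if (n == 0L) NA_real_ else
    mean((e_fund[retained] - values[retained]) / e_fund[retained])
  list(D = D, n = as.integer(n), n_excluded = as.integer(sum(!retained)),
       retained = retained)
}

## Mass-specific fundamental net energy for per-row stages (vectorised over
## rows): E_fund / w^beta. When the maintenance exponent equals the
## ingestion exponent this is independent of mass.
fundamentalBy <- function(species, stage, w, tC) {
  s <- ifelse(stage == "early", species@eta_early, 1)
  satiatedNetEnergy(species, s, w, tC, o2 = 100) / w^species@beta
}

## Mass-specific fundamental maximum for per-row stages via the per-stage
## mass interpolators.
fundamentalMaxBy <- function(species, stage, w) {
  out <- numeric(length(w))
  for (st in unique(stage)) {
    i <- stage == st
    f <- fundamentalMaxFun(species, st, range(w[i]))
    out[i] <- f(w[i]) / w[i]^species@beta
  }
  out
}

#' Counterfactual oxygen-only deviation
#'
#' Recomputes each sample's net energy under optimal food (satiety
#' ingestion at the sample's stage and mean mass) but the actual
#' temperature and oxygen saturation the sample experienced, and measures
#' the deviation of these counterfactual values from the fundamental curve
#' over exactly the same retained sample set as the total deviation (which
#' makes the food/oxygen decomposition exactly additive).
#'
#' @inheritParams tpcDeviation
#' @return List as [tpcDeviation()], plus `values` (the counterfactual net
#'   energy per sample).
#' @export
oxygenDeviation <- function(species, samples, eps_frac = 0.01) {
  if (nrow(samples) == 0L)
    return(list(D = NA_real_, n = 0L, n_excluded = 0L,
                retained = logical(0), values = numeric(0)))
  s <- ifelse(samples$stage == "early", species@eta_early, 1)
  e_cf <- satiatedNetEnergy(species, s, samples$mass, samples$temperature,
                            o2 = samples$oxygen) / samples$mass^species@beta
  res <- tpcDeviation(species, samples, eps_frac = eps_frac, values = e_cf)
  res$values <- e_cf
  res
}

#' Food component of the deviation
#'
#' Energy fluxes are additive, so the food-limitation component is the
#' total deviation minus the oxygen component, exactly.
#'
#' @param d_total Total deviation `D_O2B`.
#' @param d_oxygen Oxygen deviation `D_O2` computed on the same sample set.
#' @return `d_total - d_oxygen`.
#' @export
decomposeDeviation <- function(d_total, d_oxygen) d_total - d_oxygen

#' Realised optimum temperature
#'
#' Bins samples by temperature, averages net energy per bin and returns the
#' centre of the maximal bin; ties break towards the lower temperature.
#'
#' @param temperature,ep Paired sample temperature and net energy vectors.
#' @param bin_width Bin width in deg C (default 0.5).
#' @return Bin-centre temperature (deg C), or `NA` for empty input.
#' @export
realisedTopt <- function(temperature, ep, bin_width = 0.5) {
  stopifnot(length(temperature) == length(ep))
  if (!length(temperature)) return(NA_real_)
  centre <- floor(temperature / bin_width) * bin_width + bin_width / 2
  means <- rowsum(ep, centre) / as.vector(rowsum(rep(1, length(ep)), centre))
  centres <- as.numeric(rownames(means))
  best <- which(means[, 1] >= max(means[, 1]) - 0)
  min(centres[best])
}

#' Deviation statistics per species and life stage
#'
#' The package's headline table: for every species x stage with at least
#' one retained sample, the total deviation of the realised from the
#' fundamental TPC (`d_total`), its oxygen component (`d_oxygen`,
#' counterfactual with optimal food), the food component
#' (`d_food = d_total - d_oxygen`, exact), sample counts, and realised vs
#' fundamental optimum temperatures.
#'
#' @param sim A [SimulationResult-class], or a sample table from
#'   [collectSamples()].
#' @param species_list List of calibrated [SpeciesParams-class] objects.
#' @param eps_frac Near-zero guard (fraction of the fundamental maximum).
#' @param bin_width Temperature bin width for the realised optimum.
#' @return data.frame with one row per species x stage: `species`, `stage`,
#'   `d_total`, `d_oxygen`, `d_food`, `n`, `n_excluded`, `realised_topt`,
#'   `fundamental_topt`.
#' @export
deviationStats <- function(sim, species_list, eps_frac = 0.01,
                           bin_width = 0.5) {
  samples <- if (is(sim, "SimulationResult")) collectSamples(sim) else sim
  by_name <- stats::setNames(species_list,
                             vapply(species_list, speciesName, character(1)))
  rows <- list()
  for (spn in intersect(names(by_name), unique(samples$species))) {
    spp <- by_name[[spn]]
    for (st in intersect(stageLabels, unique(samples$stage[samples$species == spn]))) {
      sub <- samples[samples$species == spn & samples$stage == st, ,
                     drop = FALSE]
      tot <- tpcDeviation(spp, sub, eps_frac = eps_frac)
      oxy <- oxygenDeviation(spp, sub, eps_frac = eps_frac)
      ret <- sub[tot$retained, , drop = FALSE]
      f_topt <- fundamentalTPC(spp, stage = st,
                               w = stats::median(sub$mass))@t_opt
      rows[[length(rows) + 1L]] <- data.frame(
        species = spn, stage = st,
        d_total = tot$D, d_oxygen = oxy$D,
        d_food = decomposeDeviation(tot$D, oxy$D),
        n = tot$n, n_excluded = tot$n_excluded,
        realised_topt = realisedTopt(ret$temperature, ret$ep, bin_width),
        fundamental_topt = f_topt)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), stage = character(0),
               d_total = numeric(0), d_oxygen = numeric(0),
               d_food = numeric(0), n = integer(0), n_excluded = integer(0),
               realised_topt = numeric(0), fundamental_topt = numeric(0))
  out$stage <- factor(out$stage, levels = stageLabels)
  out[order(out$species, out$stage), , drop = FALSE]
}

#' Binned realised TPC
#'
#' The visual counterpart of the sample-wise statistics: mean net energy per
#' temperature bin for one species x stage sample set.
#'
#' @param samples Sample table (one species x stage).
#' @param bin_width Bin width (deg C).
#' @return data.frame with `temperature` (bin centre), `ep` (mean net
#'   energy) and `n` (samples per bin).
#' @export
binnedRealisedTPC <- function(samples, bin_width = 0.5) {
  if (nrow(samples) == 0L)
    return(data.frame(temperature = numeric(0), ep = numeric(0),
                      n = integer(0)))
  centre <- floor(samples$temperature / bin_width) * bin_width + bin_width / 2
  cnt <- rowsum(rep(1, nrow(samples)), centre)
  means <- rowsum(samples$ep, centre) / cnt
  data.frame(temperature = as.numeric(rownames(cnt)), ep = means[, 1],
             n = as.integer(cnt[, 1]), row.names = NULL)
}
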