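## Individual-based multispecies simulation. The biological unit is a school
## (a super-individual): a cohort of identical fish sharing species, age,
## somatic mass, gonadic mass, abundance and cell. Within every time step the
## processes run in a fixed order: movement -> predation -> bioenergetics ->
## maturation/reproduction -> ageing (incl. background mortality).
##
## Schools are carried as a data.frame with columns:
##   species (integer index into the species list), age (y), w (g),
##   gonad (g per individual), n (abundance), cell, mature (logical)

#' Assemble the simulation context
#'
#' Precomputes per-species parameter vectors, habitat masks, the grid
#' neighbourhood and the LTL accessibility rule used by the step functions.
#' Vertical accessibility: planktonic LTL groups are accessible to all
#' vertical classes, benthic groups only to demersal and benthic species.
#'
#' @param species_list List of calibrated [SpeciesParams-class] objects.
#' @param forcing A [ForcingClimatology-class].
#' @param dt Step length in years (default `1 / steps_per_year`).
#' @param rho_e Tissue energy density (g prey equivalents per g of tissue;
#'   shared across species).
#' @param m_starv Starvation mortality coefficient (per year, applied to the
#'   unmet maintenance fraction).
#' @param n_spawn_schools New age-0 schools per species per spawning step
#'   (eggs are pooled across spawners).
#' @param min_n Abundance below which a school is removed.
#' @return A list used by the step functions (opaque).
#' @export
simContext <- function(species_list, forcing, dt = 1 / forcing@steps_per_year,
                       rho_e = 1, m_starv = 3, n_spawn_schools = 4L,
                       min_n = 1e-2) {
  stopifnot(length(species_list) >= 0)
  grid <- forcing@grid
  nsp <- length(species_list)
  ncell <- nCells(grid)
  getv <- function(s) vapply(species_list, function(x) slot(x, s), numeric(1))
  sp <- list(
    name = vapply(species_list, function(x) x@name, character(1)),
    i_max = getv("i_max"), beta = getv("beta"), eta = getv("eta_early"),
    xi = getv("xi"), k_o2 = getv("k_o2"), h_o2 = getv("h_o2"),
    e_mob = getv("e_mob"), t_peak = getv("t_peak"), lambda = getv("lambda"),
    c_m = getv("c_m"), beta_m = getv("beta_m"), e_maint = getv("e_maint"),
    r_min = getv("r_min"), r_max = getv("r_max"),
    kappa0 = getv("i_max") / (getv("p_sat") * 1e6),
    lw_c = getv("lw_c"), lw_b = getv("lw_b"),
    mat_a = getv("mat_intercept"), mat_b = getv("mat_slope"),
    rel_fec = getv("rel_fec"), egg_mass = getv("egg_mass"),
    egg_survival = getv("egg_survival"), egg_capacity = getv("egg_capacity"),
    gonad_alloc = getv("gonad_alloc"),
    m_bg = getv("m_bg"), m_early = getv("m_early"),
    max_age = getv("max_age"),
    vertical = vapply(species_list, function(x) x@vertical, character(1))
  )
  habitat_ok <- matrix(FALSE, max(nsp, 1L), ncell)
  habitats <- vector("list", nsp)
  for (k in seq_len(nsp)) {
    h <- species_list[[k]]@habitat
    if (!length(h)) h <- seq_len(ncell)
    habitats[[k]] <- as.integer(h)
    habitat_ok[k, h] <- TRUE
  }
  groups <- forcing@groups
  class_access <- rbind(
    pelagic = groups$vertical == "planktonic",
    demersal = rep(TRUE, nrow(groups)),
    benthic = rep(TRUE, nrow(groups))
  )
  colnames(class_access) <- groups$name
  ## stage-resolved LTL accessibility coefficients in [0, 1]: the
  ## vertical-class rule gives 0/1 defaults, optionally reweighted per
  ## species and stage (row index (species-1)*3 + stage). The coefficient
  ## scales the pool biomass the predator perceives.
  ltl_allowed <- matrix(1, max(3L * nsp, 1L), nrow(groups))
  for (k in seq_len(nsp)) {
    base <- as.numeric(class_access[sp$vertical[k], ])
    acc <- species_list[[k]]@ltl_access
    for (si in seq_along(stageLabels)) {
      st <- stageLabels[si]
      row <- base
      if (!is.null(acc[[st]])) {
        ov <- acc[[st]]
        if (is.character(ov)) ov <- stats::setNames(rep(1, length(ov)), ov)
        coef <- stats::setNames(rep(0, nrow(groups)), groups$name)
        coef[names(ov)] <- as.numeric(ov)
        row <- base * coef
      }
      ltl_allowed[(k - 1L) * 3L + si, ] <- row
    }
  }
  list(species_list = species_list, sp = sp, nsp = nsp,
       grid = grid, forcing = forcing, groups = groups,
       class_access = class_access, ltl_allowed = ltl_allowed,
       neighbors = gridNeighbors(grid),
       habitat_ok = habitat_ok, habitats = habitats,
       spawn_steps = lapply(species_list, function(x) x@spawn_steps),
       benthic_sp = sp$vertical == "benthic",
       dt = dt, rho_e = rho_e, m_starv = m_starv,
       n_spawn = as.integer(n_spawn_schools), min_n = min_n,
       steps_per_year = forcing@steps_per_year)
}

## Empty school table with the canonical columns.
emptySchools <- function() {
  data.frame(species = integer(0), age = numeric(0), w = numeric(0),
             gonad = numeric(0), n = numeric(0), cell = integer(0),
             mature = logical(0))
}

#' Initial population
#'
#' Seeds each species with schools over a ladder of ages. Masses follow the
#' growth trajectory obtained by integrating the fundamental net energy at
#' the species optimum temperature; abundances decay with age at rate `z0`.
#' Schools are placed uniformly in the species habitat.
#'
#' @param ctx A [simContext()].
#' @param n0 Recruit-scale abundance per species (numeric vector recycled to
#'   the number of species).
#' @param z0 Age decay rate of initial abundance (per year).
#' @param max_age Oldest seeded age (years).
#' @param schools_per_age Schools per species and age step.
#' @return School data.frame.
#' @export
initialPopulation <- function(ctx, n0, z0 = 0.8, max_age = 6,
                              schools_per_age = 2L) {
  nsp <- ctx$nsp
  if (nsp == 0L) return(emptySchools())
  n0 <- rep_len(n0, nsp)
  out <- list()
  for (k in seq_len(nsp)) {
    spk <- ctx$species_list[[k]]
    ages <- seq(0.5, max_age, by = 0.5)
    w <- growthTrajectory(spk, ages, ctx$rho_e)
    for (a in seq_along(ages)) {
      nn <- n0[k] * exp(-z0 * ages[a]) / schools_per_age
      cells <- sample(ctx$habitats[[k]], schools_per_age, replace = TRUE)
      L <- lengthFromMass(spk, w[a])
      out[[length(out) + 1L]] <- data.frame(
        species = k, age = ages[a], w = w[a], gonad = 0, n = nn,
        cell = cells,
        mature = L >= spk@mat_intercept + spk@mat_slope * ages[a])
    }
  }
  do.call(rbind, out)
}

## Somatic mass at given ages under satiety feeding at the species optimum
## temperature (coarse monthly Euler integration from the egg mass).
growthTrajectory <- function(species, ages, rho_e) {
  dt <- 1 / 12
  tmax <- max(ages)
  tt <- seq(0, tmax, by = dt)
  w <- numeric(length(tt))
  w[1] <- species@egg_mass
  for (i in seq_len(length(tt) - 1L)) {
    s <- if (tt[i] < 1) species@eta_early else 1
    ep <- satiatedNetEnergy(species, s, w[i], species@t_opt)
    w[i + 1] <- w[i] + max(ep, 0) * dt / rho_e
  }
  stats::approx(tt, w, xout = ages, rule = 2)$y
}

#' Move schools by one random-walk step
#'
#' Each school picks uniformly among staying put and its four rook
#' neighbours; moves leaving the grid or the species habitat are rejected
#' (the school stays), which makes the walk's stationary distribution
#' uniform over the habitat.
#'
#' @param schools School data.frame.
#' @param ctx A [simContext()].
#' @return The school data.frame with updated cells.
#' @export
moveSchools <- function(schools, ctx) {
  ns <- nrow(schools)
  if (ns == 0L) return(schools)
  rc <- rowColAt(ctx$grid, schools$cell)
  dir <- sample.int(5L, ns, replace = TRUE)  # 1 = stay, 2..5 = N/S/E/W
  dr <- c(0L, 1L, -1L, 0L, 0L)[dir]
  dc <- c(0L, 0L, 0L, 1L, -1L)[dir]
  r2 <- rc$row + dr
  c2 <- rc$col + dc
  ok <- r2 >= 1L & r2 <= ctx$grid@n_rows & c2 >= 1L & c2 <= ctx$grid@n_cols
  target <- schools$cell
  target[ok] <- cellAt(ctx$grid, r2[ok], c2[ok])
  in_hab <- ctx$habitat_ok[cbind(schools$species, target)]
  schools$cell <- ifelse(in_hab, target, schools$cell)
  schools
}

#' Accessible prey of one school
#'
#' Prey are (i) co-located schools whose individual mass falls within the
#' predator's size window `[w/r_max, w/r_min]` (closed bounds, the school
#' itself excluded; benthic-species schools are out of reach of pelagic
#' predators) and (ii) co-located LTL groups whose nominal item mass falls
#' within the window and which are accessible to the predator's vertical
#' class.
#'
#' @param schools School data.frame.
#' @param i Row index of the predator school.
#' @param ltl_cell Named vector of LTL biomass (g) in the predator's cell.
#' @param ctx A [simContext()].
#' @return List with `total` (g), `school_idx`, `school_biomass`,
#'   `ltl_idx`, `ltl_biomass`.
#' @export
accessiblePrey <- function(schools, i, ltl_cell, ctx) {
  w <- schools$w[i]
  k <- schools$species[i]
  lo <- w / ctx$sp$r_max[k]
  hi <- w / ctx$sp$r_min[k]
  here <- which(schools$cell == schools$cell[i])
  here <- here[here != i]
  sel <- here[schools$w[here] >= lo & schools$w[here] <= hi]
  if (ctx$sp$vertical[k] == "pelagic")
    sel <- sel[ctx$sp$vertical[schools$species[sel]] != "benthic"]
  sb <- schools$w[sel] * schools$n[sel]
  gm <- ctx$groups$item_mass
  si <- stageIndex(schools$age[i], schools$mature[i])
  coef <- ctx$ltl_allowed[(k - 1L) * 3L + si, ]
  gsel <- which(gm >= lo & gm <= hi & coef > 0)
  lb <- as.numeric(ltl_cell[gsel]) * coef[gsel]
  list(total = sum(sb) + sum(lb),
       school_idx = sel, school_biomass = sb,
       ltl_idx = gsel, ltl_biomass = lb)
}

#' Predation step
#'
#' Opportunistic size-based predation with a single-pass proportional
#' competition rule. Every school's desired intake is its Holling type I
#' ingestion at the accessible biomass, spread across accessible prey items
#' proportionally to their biomass; when the summed demands on an item
#' exceed its biomass, all takes from that item are scaled down by the same
#' factor. Eaten biomass is removed from LTL pools and prey-school
#' abundances, and diet records are accumulated.
#'
#' @param schools School data.frame.
#' @param ltl_g Matrix cells x groups of LTL biomass in grams for this step.
#' @param ctx A [simContext()].
#' @param diets Optional running diet matrix to accumulate into (predator
#'   species x stage rows, prey species x stage and LTL group columns).
#' @return List: `schools` (with an `intake` column, g per school per step),
#'   `ltl_g` (depleted pools), `diets`, and `checks` (named numeric:
#'   `overdraw` = largest relative overdraw of any prey item, `imbalance` =
#'   relative gap between summed intakes and summed removals).
#' @export
predationStep <- function(schools, ltl_g, ctx, diets = NULL) {
  ns <- nrow(schools)
  if (is.null(diets)) diets <- emptyDietMatrix(ctx)
  schools$intake <- numeric(ns)
  schools$irate <- numeric(ns)
  checks <- c(overdraw = 0, imbalance = 0)
  if (ns == 0L)
    return(list(schools = schools, ltl_g = ltl_g, diets = diets, checks = checks))

  sp <- ctx$sp
  stage_idx <- stageIndex(schools$age, schools$mature)
  smult <- ifelse(schools$age < 1, sp$eta[schools$species], 1)
  total_intake <- 0
  total_removed <- 0

  for (cell in unique(schools$cell)) {
    idx <- which(schools$cell == cell)
    k <- schools$species[idx]
    w <- schools$w[idx]
    nn <- schools$n[idx]
    b <- w * nn
    m <- length(idx)
    lo <- w / sp$r_max[k]
    hi <- w / sp$r_min[k]

    ## school-on-school accessibility (closed bounds, self excluded);
    ## benthic-species schools are out of reach of pelagic predators
    wj <- matrix(w, m, m, byrow = TRUE)
    acc <- wj >= lo & wj <= hi
    diag(acc) <- FALSE
    pel_pred <- sp$vertical[k] == "pelagic"
    benth_prey <- sp$vertical[k] == "benthic"
    acc <- acc & !outer(pel_pred, benth_prey, `&`)
    ## LTL accessibility: size window times the species x stage coefficient
    gm <- ctx$groups$item_mass
    ng <- length(gm)
    accl <- (outer(lo, gm, `<=`) & outer(hi, gm, `>=`)) *
      ctx$ltl_allowed[(k - 1L) * 3L + stage_idx[idx], , drop = FALSE]
    pool <- ltl_g[cell, ]

    P <- as.numeric(acc %*% b) + as.numeric(accl %*% pool)
    irate <- w^sp$beta[k] *
      pmin(sp$kappa0[k] * P, smult[idx] * sp$i_max[k])
    demand <- irate * nn * ctx$dt
    share <- ifelse(P > 0, demand / P, 0)

    want_s <- acc * outer(share, b)          # predators x prey schools
    want_l <- accl * outer(share, pool)      # predators x groups
    tot_s <- colSums(want_s)
    tot_l <- colSums(want_l)
    f_s <- ifelse(tot_s > b & tot_s > 0, b / tot_s, 1)
    f_l <- ifelse(tot_l > pool & tot_l > 0, pool / tot_l, 1)
    take_s <- sweep(want_s, 2, f_s, `*`)
    take_l <- sweep(want_l, 2, f_l, `*`)

    got <- rowSums(take_s) + rowSums(take_l)
    rem_s <- colSums(take_s)
    rem_l <- colSums(take_l)

    schools$intake[idx] <- got
    ## per-capita ingestion rate fixed at ingestion time (abundance may be
    ## reduced by predation before the bioenergetics step runs)
    schools$irate[idx] <- ifelse(nn > 0, got / (nn * ctx$dt), 0)
    schools$n[idx] <- pmax(nn - rem_s / w, 0)
    ltl_g[cell, ] <- pmax(pool - rem_l, 0)

    ## bookkeeping for the conservation invariant
    if (any(b > 0))
      checks["overdraw"] <- max(checks["overdraw"],
                                max((rem_s - b) / pmax(b, 1e-300)))
    if (any(pool > 0))
      checks["overdraw"] <- max(checks["overdraw"],
                                max((rem_l - pool) / pmax(pool, 1e-300)))
    total_intake <- total_intake + sum(got)
    total_removed <- total_removed + sum(rem_s) + sum(rem_l)

    ## diet records: predator species x stage -> prey keys (prey keys can
    ## repeat across schools, so aggregate both margins before adding)
    pk <- (k - 1L) * 3L + stage_idx[idx]
    prey_sk <- (schools$species[idx] - 1L) * 3L + stage_idx[idx]
    by_pred_s <- rowsum(take_s, pk)
    by_pred_l <- rowsum(take_l, pk)
    pks <- as.integer(rownames(by_pred_s))
    by_both <- t(rowsum(t(by_pred_s), prey_sk))
    preyks <- as.integer(colnames(by_both))
    diets[pks, preyks] <- diets[pks, preyks, drop = FALSE] + by_both
    diets[pks, 3L * ctx$nsp + seq_len(ng)] <-
      diets[pks, 3L * ctx$nsp + seq_len(ng), drop = FALSE] + by_pred_l
  }
  if (total_removed > 0)
    checks["imbalance"] <- abs(total_intake - total_removed) / total_removed
  list(schools = schools, ltl_g = ltl_g, diets = diets, checks = checks)
}

## Stage index 1 = early, 2 = juvenile, 3 = adult.
stageIndex <- function(age, mature) {
  ifelse(age < 1, 1L, ifelse(mature, 3L, 2L))
}

stageLabels <- c("early", "juvenile", "adult")

## Empty diet matrix: predator species x stage rows, prey species x stage and
## LTL group columns.
emptyDietMatrix <- function(ctx) {
  pred_keys <- as.vector(t(outer(ctx$sp$name, stageLabels, paste, sep = "|")))
  if (!length(pred_keys)) pred_keys <- character(0)
  prey_keys <- c(pred_keys, ctx$groups$name)
  matrix(0, nrow = length(pred_keys), ncol = length(prey_keys),
         dimnames = list(pred_keys, prey_keys))
}

#' Bioenergetics step
#'
#' Converts each school's realised intake into the full energy flux
#' breakdown at the temperature and oxygen saturation of its cell (vertical
#' class decides between vertically integrated and bottom forcing), then
#' allocates positive net energy to somatic growth (immature) or splits it
#' between soma and gonads (mature, fraction `gonad_alloc` to gonads).
#' Negative net energy triggers starvation mortality proportional to the
#' unmet maintenance fraction: `n <- n * exp(-m_starv * unmet * dt)`.
#'
#' @param schools School data.frame carrying the `intake` (g per school per
#'   step) and `irate` (g per individual per year, fixed at ingestion time)
#'   columns produced by [predationStep()].
#' @param fstep Forcing for the step, from [forcingAt()].
#' @param ctx A [simContext()].
#' @return List: `schools` (grown), `records` (one row per school: step
#'   placeholder `NA`, cell, species, stage, age, mass, n, ep, temperature,
#'   oxygen).
#' @export
bioenergeticsStep <- function(schools, fstep, ctx) {
  ns <- nrow(schools)
  if (ns == 0L)
    return(list(schools = schools, records = NULL))
  sp <- ctx$sp
  k <- schools$species
  benthic <- ctx$benthic_sp[k]
  tC <- ifelse(benthic, fstep$t_bot[schools$cell], fstep$t_int[schools$cell])
  o2 <- ifelse(benthic, fstep$o2_bot[schools$cell], fstep$o2_int[schools$cell])

  irate <- schools$irate
  A <- sp$xi[k] * irate
  f_o2 <- oxygenFactor(o2, sp$k_o2[k], sp$h_o2[k])
  phi <- thermalFactorVec(tC, sp$e_mob[k], sp$t_peak[k], sp$lambda[k])
  E_M <- A * f_o2 * phi
  E_m <- sp$c_m[k] * schools$w^sp$beta_m[k] * arrhenius(tC, sp$e_maint[k])
  E_P <- E_M - E_m

  ## analysis records carry the mass-specific net energy rate
  ## (g prey g^-beta per year): with maintenance sharing the ingestion
  ## exponent this makes cell averages independent of the mass mix
  records <- data.frame(
    step = NA_integer_, cell = schools$cell, species = sp$name[k],
    stage = stageLabels[stageIndex(schools$age, schools$mature)],
    age = schools$age, mass = schools$w, n = schools$n,
    ep = E_P / schools$w^sp$beta[k],
    temperature = tC, oxygen = o2)

  dE <- pmax(E_P, 0) * ctx$dt / ctx$rho_e
  to_gonad <- ifelse(schools$mature, sp$gonad_alloc[k], 0)
  schools$w <- schools$w + (1 - to_gonad) * dE
  schools$gonad <- schools$gonad + to_gonad * dE

  unmet <- ifelse(E_P < 0 & E_m > 0, pmin(1, -E_P / E_m), 0)
  schools$n <- schools$n * exp(-ctx$m_starv * unmet * ctx$dt)

  list(schools = schools, records = records)
}

## thermalFactor with per-element (t_peak, lambda): used when schools of
## several species are processed in one vector.
thermalFactorVec <- function(tC, e_mob, t_peak, lambda) {
  if (any(is.na(t_peak))) stop("t_peak is NA: species not calibrated")
  base <- exp(-e_mob / (.kB * celsiusToKelvin(tC))) /
    exp(-e_mob / (.kB * celsiusToKelvin(t_peak)))
  above <- tC > t_peak
  base[above] <- base[above] * exp(-lambda[above] * (tC[above] - t_peak[above]))
  base
}

#' Maturation and reproduction step
#'
#' A school matures when its length crosses the maturation reaction-norm
#' midpoint (a deterministic linear age-length threshold). During the
#' species' spawning steps, the pooled gonad mass of its mature schools is
#' converted into eggs (`rel_fec * gonad mass / egg_mass`), survival
#' `egg_survival` is applied, and the recruits enter as new age-0 schools of
#' egg mass placed in random habitat cells; spawners' gonads reset to zero.
#'
#' @param schools School data.frame.
#' @param step_of_year Step of year (1..steps_per_year).
#' @param ctx A [simContext()].
#' @return Updated school data.frame.
#' @export
maturationReproductionStep <- function(schools, step_of_year, ctx) {
  ns <- nrow(schools)
  if (ns == 0L) return(schools)
  sp <- ctx$sp
  k <- schools$species
  L <- (schools$w / sp$lw_c[k])^(1 / sp$lw_b[k])
  schools$mature <- schools$mature |
    (L >= sp$mat_a[k] + sp$mat_b[k] * schools$age)

  recruits <- list()
  for (s in seq_len(ctx$nsp)) {
    if (!(step_of_year %in% ctx$spawn_steps[[s]])) next
    spawners <- which(schools$species == s & schools$mature &
                        schools$gonad > 0 & schools$n > 0)
    if (!length(spawners)) next
    total_gonad <- sum(schools$gonad[spawners] * schools$n[spawners])
    eggs <- sp$rel_fec[s] * total_gonad / sp$egg_mass[s]
    eggs <- eggs / (1 + eggs / sp$egg_capacity[s])
    n_rec <- eggs * sp$egg_survival[s]
    schools$gonad[spawners] <- 0
    if (n_rec < 1) next
    nb <- ctx$n_spawn
    cells <- sample(ctx$habitats[[s]], nb, replace = TRUE)
    recruits[[length(recruits) + 1L]] <- data.frame(
      species = s, age = 0, w = sp$egg_mass[s], gonad = 0,
      n = n_rec / nb, cell = cells, mature = FALSE)
  }
  if (length(recruits)) {
    schools <- rbind(schools[, c("species", "age", "w", "gonad", "n",
                                 "cell", "mature")],
                     do.call(rbind, recruits))
  } else {
    schools <- schools[, c("species", "age", "w", "gonad", "n", "cell",
                           "mature")]
  }
  schools
}

## Ageing and background mortality; drops dead schools.
ageingStep <- function(schools, ctx) {
  if (nrow(schools) == 0L) return(schools)
  sp <- ctx$sp
  k <- schools$species
  m <- sp$m_bg[k] + ifelse(schools$age < 1, sp$m_early[k], 0)
  schools$n <- schools$n * exp(-m * ctx$dt)
  schools$age <- schools$age + ctx$dt
  keep <- schools$n >= ctx$min_n & schools$w > 0 &
    schools$age <= sp$max_age[k]
  schools[keep, , drop = FALSE]
}

#' Run the community simulation
#'
#' Executes the full protocol: for every step, movement, predation,
#' bioenergetics, maturation/reproduction and ageing, with analysis records
#' (school-level net energy paired with the forcing temperature and oxygen)
#' emitted after the spin-up period. Reproducible: the same configuration
#' and seed give bit-identical outputs.
#'
#' @param config Configuration list as built by [demoConfig()] or
#'   [loadConfig()].
#' @param seed Root seed (overrides `config$seed` when given).
#' @param forcing Optional pre-generated [ForcingClimatology-class]; by
#'   default it is generated from `config$scenario`.
#' @return A [SimulationResult-class].
#' @export
runSimulation <- function(config, seed = NULL, forcing = NULL) {
  seed <- as.integer(if (is.null(seed)) config$seed else seed)
  S <- as.integer(config$steps_per_year)
  if (is.null(forcing)) {
    grid <- makeGrid(config$grid$n_rows, config$grid$n_cols,
                     config$grid$cell_size)
    scen <- resolveScenario(config$scenario, seed)
    forcing <- generateForcing(grid, scen, S)
  }
  species <- lapply(config$species, function(s)
    if (isCalibrated(s)) s else calibrateSpecies(s))

  simopts <- config$sim
  ctx <- simContext(species, forcing,
                    rho_e = simopts$rho_e, m_starv = simopts$m_starv,
                    n_spawn_schools = simopts$n_spawn_schools,
                    min_n = simopts$min_n)

  years <- config$years
  spinup <- config$spinup_years
  if (spinup >= years) stop("spinup_years must be smaller than years")
  steps_total <- as.integer(round(years * S))
  spinup_steps <- as.integer(round(spinup * S))

  rec_list <- vector("list", steps_total)
  diets <- emptyDietMatrix(ctx)
  checks <- c(overdraw = 0, imbalance = 0)

  withSeed(deriveSeed(seed, "simulation"), {
    schools <- if (ctx$nsp == 0L) emptySchools()
      else initialPopulation(ctx, n0 = rep_len(simopts$init_n0, ctx$nsp),
                             z0 = simopts$init_z0,
                             max_age = simopts$init_max_age)
    for (t in seq_len(steps_total)) {
      if (nrow(schools) == 0L) {
        if (ctx$nsp > 0L)
          warning(sprintf("all species extinct at step %d; returning partial outputs", t))
        break
      }
      fstep <- forcingAt(forcing, t)
      ltl_g <- fstep$biomass * 1e6
      analysis <- t > spinup_steps

      schools <- moveSchools(schools, ctx)
      pred <- predationStep(schools, ltl_g, ctx,
                            diets = if (analysis) diets else NULL)
      if (analysis) diets <- pred$diets
      checks <- pmax(checks, pred$checks)
      bio <- bioenergeticsStep(pred$schools, fstep, ctx)
      schools <- bio$schools
      if (analysis && !is.null(bio$records)) {
        bio$records$step <- t
        rec_list[[t]] <- bio$records
      }
      schools <- maturationReproductionStep(schools, fstep$step_of_year, ctx)
      schools <- ageingStep(schools, ctx)
    }
    records <- do.call(rbind, rec_list[!vapply(rec_list, is.null, logical(1))])
    if (is.null(records))
      records <- data.frame(step = integer(0), cell = integer(0),
                            species = character(0), stage = character(0),
                            age = numeric(0), mass = numeric(0),
                            n = numeric(0), ep = numeric(0),
                            temperature = numeric(0), oxygen = numeric(0))
    schools$intake <- NULL
    schools$irate <- NULL
    new("SimulationResult",
        records = records, diets = diets, final_schools = schools,
        forcing = forcing, steps_per_year = S,
        years = years, spinup_years = spinup, seed = seed,
        conservation = checks)
  })
}

## Resolve a scenario entry of the configuration: either a ForcingScenario
## object, or a list like list(preset = "covarying", food_factor = ...).
resolveScenario <- function(scenario, seed) {
  if (is(scenario, "ForcingScenario")) return(scenario)
  if (is.list(scenario) && !is.null(scenario$preset)) {
    args <- scenario[setdiff(names(scenario), "preset")]
    if (is.null(args$seed)) args$seed <- deriveSeed(seed, "scenario")
    do.call(scenarioPreset, c(list(name = scenario$preset), args))
  } else stop("unknown scenario specification")
}

#' @describeIn runSimulation Display a simulation result.
#' @param object A [SimulationResult-class].
#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %g years (%g spin-up), %d steps/year, seed %d\n",
              object@years, object@spinup_years, object@steps_per_year,
              object@seed))
  cat(sprintf("  %d analysis records, %d schools alive at the end\n",
              nrow(object@records), nrow(object@final_schools)))
  if (nrow(object@records)) {
    tab <- table(object@records$species, object@records$stage)
    print(tab)
  }
  invisible(object)
})
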