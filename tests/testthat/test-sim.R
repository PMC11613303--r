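## Step-level tests run on tiny hand-built states so every expectation can be
## checked by hand.

miniContext <- function(n_rows = 3, n_cols = 3, species = NULL,
                        preset = "optimal") {
  if (is.null(species))
    species <- list(tinySpecies("a", vertical = "demersal"),
                    tinySpecies("b", t_min = 4, t_opt = 11, t_max = 19,
                                vertical = "benthic"))
  grid <- makeGrid(n_rows, n_cols, 30)
  forcing <- generateForcing(grid, scenarioPreset(preset, seed = 1L), 24)
  simContext(species, forcing)
}

schoolRow <- function(species, age, w, n, cell, mature = FALSE, gonad = 0) {
  data.frame(species = species, age = age, w = w, gonad = gonad, n = n,
             cell = cell, mature = mature)
}

test_that("movement respects the habitat map and is reproducible", {
  one_cell <- tinySpecies("stay", habitat = 5L)
  ctx <- miniContext(species = list(one_cell))
  sch <- schoolRow(1L, 2, 50, 100, 5L)
  set.seed(1)
  for (i in 1:50) sch <- moveSchools(sch, ctx)
  expect_equal(sch$cell, 5L)

  ctx2 <- miniContext()
  sch2 <- rbind(schoolRow(1L, 2, 50, 100, 1L), schoolRow(2L, 3, 80, 10, 9L))
  set.seed(99); a <- moveSchools(moveSchools(sch2, ctx2), ctx2)
  set.seed(99); b <- moveSchools(moveSchools(sch2, ctx2), ctx2)
  expect_identical(a, b)
})

test_that("long random walks occupy a uniform habitat uniformly", {
  ## 100 walkers, positions recorded every 25 steps after a burn-in, so the
  ## 10^4 pooled draws are effectively decorrelated
  ctx <- miniContext(4, 4, species = list(tinySpecies("w")))
  sch <- do.call(rbind, lapply(1:100, function(i)
    schoolRow(1L, 2, 50, 100, ((i - 1L) %% 16L) + 1L)))
  set.seed(123)
  visits <- integer(nCells(ctx$grid))
  for (i in seq_len(2600)) {
    sch <- moveSchools(sch, ctx)
    if (i > 100 && i %% 25 == 0) {
      tab <- tabulate(sch$cell, nCells(ctx$grid))
      visits <- visits + tab
    }
  }
  expect_equal(sum(visits), 100 * 100)
  p <- chisq.test(visits)$p.value
  expect_gt(p, 0.01)
})

test_that("accessible prey combines size windows, vertical class and biomass", {
  ## predator 'a' (demersal) at w = 100 with r_min = 10, r_max = 1e5:
  ## prey window [0.001, 10] g
  sp_a <- tinySpecies("a", r_min = 10, r_max = 1e5, vertical = "demersal")
  sp_c <- tinySpecies("c", t_min = 4, t_opt = 11, t_max = 19)
  ctx <- miniContext(species = list(sp_a, sp_c))
  sch <- rbind(
    schoolRow(1L, 3, 100, 10, 5L),    # the predator
    schoolRow(2L, 1.2, 5, 200, 5L),   # in window: biomass 1000 g
    schoolRow(2L, 4, 50, 20, 5L),     # too large (50 > 10)
    schoolRow(2L, 1.5, 8, 30, 4L))    # wrong cell
  ltl <- c(zoo_small = 1e6, zoo_large = 2e6, macrozoo = 3e6, benthos = 4e6)
  ap <- accessiblePrey(sch, 1L, ltl, ctx)
  ## LTL items in [0.001, 10]: zoo_large (8e-3), macrozoo (0.5), benthos (1)
  expect_setequal(ap$ltl_idx, c(2L, 3L, 4L))
  expect_equal(ap$school_idx, 2L)
  expect_equal(ap$total, 5 * 200 + 2e6 + 3e6 + 4e6)

  ## an empty cell with no accessible LTL yields zero prey
  lone <- schoolRow(1L, 3, 100, 10, 7L)
  expect_equal(accessiblePrey(lone, 1L, ltl * 0, ctx)$total, 0)

  ## closed lower bound: prey exactly at w / r_max is included
  edge <- rbind(schoolRow(1L, 3, 100, 10, 5L),
                schoolRow(2L, 0.5, 100 / 1e5, 1000, 5L))
  ap_edge <- accessiblePrey(edge, 1L, ltl * 0, ctx)
  expect_equal(ap_edge$school_idx, 2L)
})

test_that("predation shares limited prey proportionally to demand", {
  sp <- tinySpecies("a", p_sat = 1)
  ctx <- miniContext(species = list(sp))
  ## one predator with superabundant prey reaches the satiety plateau
  sch1 <- schoolRow(1L, 3, 100, 10, 5L)
  ltl1 <- matrix(1e12, nCells(ctx$grid), 4,
                 dimnames = list(NULL, ctx$groups$name))
  out1 <- predationStep(sch1, ltl1, ctx)
  plateau <- sp@i_max * 100^sp@beta * 10 * ctx$dt
  expect_equal(out1$schools$intake, plateau, tolerance = 1e-12)

  ## two identical predators at the satiety plateau sharing a pool equal to
  ## one predator's demand: each gets half
  pool2 <- sp@p_sat * 1e6              # at the satiety threshold exactly
  n2 <- pool2 / (sp@i_max * 100^sp@beta * ctx$dt)  # demand == pool each
  sch2 <- rbind(schoolRow(1L, 3, 100, n2, 5L), schoolRow(1L, 3, 100, n2, 5L))
  ltl2 <- ltl1 * 0
  ltl2[5, "macrozoo"] <- pool2
  out2 <- predationStep(sch2, ltl2, ctx)
  expect_equal(out2$schools$intake, rep(pool2 / 2, 2), tolerance = 1e-9)

  ## three unequal demands against a limited pool: allocations equal
  ## demand * pool / total demand (arithmetic oracle)
  nn <- c(1e5, 3e5, 6e5)
  sch3 <- rbind(schoolRow(1L, 3, 100, nn[1], 5L),
                schoolRow(1L, 3, 100, nn[2], 5L),
                schoolRow(1L, 3, 100, nn[3], 5L))
  pool <- 500
  ltl3 <- ltl1 * 0
  ltl3[5, "macrozoo"] <- pool
  out3 <- predationStep(sch3, ltl3, ctx)
  kappa0 <- sp@i_max / (sp@p_sat * 1e6)
  want <- 100^sp@beta * min(kappa0 * pool, sp@i_max) * nn * ctx$dt
  expect_gt(sum(want), pool)           # the pool is genuinely contested
  expected <- want * pool / sum(want)
  expect_equal(out3$schools$intake, expected, tolerance = 1e-9)
  expect_equal(unname(sum(out3$schools$intake) + out3$ltl_g[5, "macrozoo"]),
               pool, tolerance = 1e-9)
})

test_that("predation never overdraws prey and removals equal intakes", {
  run <- demoPipeline("covarying", 1L)
  expect_lt(run$sim@conservation["overdraw"], 1e-9)
  expect_lt(run$sim@conservation["imbalance"], 1e-9)
})

test_that("bioenergetics allocates growth by maturity and starves by the unmet fraction", {
  sp <- tinySpecies("a")
  ctx <- miniContext(species = list(sp))
  fstep <- forcingAt(ctx$forcing, 10)

  ## immature school with positive net energy grows only in soma
  ## (masses kept near w_ref so the thermal scope is comfortably positive)
  imm <- schoolRow(1L, 2, 20, 100, 5L)
  imm$intake <- sp@i_max * 20^sp@beta * 100 * ctx$dt
  imm$irate <- sp@i_max * 20^sp@beta
  out <- bioenergeticsStep(imm, fstep, ctx)
  ep <- out$records$ep * 20^sp@beta   # records carry mass-specific rates
  expect_gt(ep, 0)
  expect_equal(out$schools$w, 20 + ep * ctx$dt / ctx$rho_e)
  expect_equal(out$schools$gonad, 0)

  ## mature school splits soma and gonads at the allocation fraction
  mat <- schoolRow(1L, 4, 40, 50, 5L, mature = TRUE)
  mat$intake <- sp@i_max * 40^sp@beta * 50 * ctx$dt
  mat$irate <- sp@i_max * 40^sp@beta
  outm <- bioenergeticsStep(mat, fstep, ctx)
  dw <- outm$schools$w - 40
  dg <- outm$schools$gonad
  expect_gt(dg, 0)
  expect_equal(dg / (dw + dg), sp@gonad_alloc)

  ## zero intake: the school pays maintenance it cannot cover and its
  ## abundance declines as exp(-m_starv * unmet * dt)
  starv <- schoolRow(1L, 2, 50, 1000, 5L)
  starv$intake <- 0
  starv$irate <- 0
  outs <- bioenergeticsStep(starv, fstep, ctx)
  expect_equal(outs$schools$n, 1000 * exp(-ctx$m_starv * 1 * ctx$dt))

  ## a 10% maintenance shortfall gives exp(-m_starv * 0.1 * dt)
  tC <- fstep$t_int[5]
  E_m <- maintenanceRate(50, tC, sp@c_m, sp@beta_m, sp@e_maint)
  f_o2 <- oxygenFactor(fstep$o2_int[5], sp@k_o2, sp@h_o2)
  phi <- thermalFactor(tC, sp@e_mob, sp@t_peak, sp@lambda)
  irate_needed <- 0.9 * E_m / (sp@xi * f_o2 * phi)
  short <- schoolRow(1L, 2, 50, 1000, 5L)
  short$intake <- irate_needed * 1000 * ctx$dt
  short$irate <- irate_needed
  outp <- bioenergeticsStep(short, fstep, ctx)
  expect_equal(outp$schools$n, 1000 * exp(-ctx$m_starv * 0.1 * ctx$dt),
               tolerance = 1e-9)
})

test_that("maturation crosses the reaction norm and spawning divides gonads into eggs", {
  sp <- tinySpecies("a", mat_intercept = 15, mat_slope = 0,
                    egg_mass = 1e-3, egg_survival = 1, rel_fec = 1,
                    lw_c = 0.01, lw_b = 3)
  ctx <- miniContext(species = list(sp))

  ## below the norm at every age: never matures
  small <- schoolRow(1L, 6, 0.01 * 10^3, 100, 5L)    # 10 cm < 15 cm
  out <- maturationReproductionStep(small, 3L, ctx)
  expect_false(out$mature)

  ## above the norm: matures
  big <- schoolRow(1L, 3, 0.01 * 20^3, 100, 5L)      # 20 cm
  outb <- maturationReproductionStep(big, 1L, ctx)   # not a spawning step
  expect_true(outb$mature)

  ## gonad 10 g at egg mass 1e-3 g: 10,000 eggs per individual; spawned as
  ## n_spawn new age-0 schools, gonads reset
  spawner <- schoolRow(1L, 3, 0.01 * 20^3, 1, 5L, mature = TRUE, gonad = 10)
  set.seed(5)
  outs <- maturationReproductionStep(spawner, 5L, ctx)  # 5 is a spawn step
  recruits <- outs[outs$age == 0, ]
  expect_equal(sum(recruits$n), 10000)
  expect_true(all(recruits$w == sp@egg_mass))
  expect_equal(outs$gonad[outs$age > 0], 0)

  ## no gonads: no offspring
  dry <- schoolRow(1L, 3, 0.01 * 20^3, 1, 5L, mature = TRUE, gonad = 0)
  outd <- maturationReproductionStep(dry, 5L, ctx)
  expect_equal(nrow(outd), 1L)
})

test_that("an empty community runs without error and yields empty outputs", {
  cfg <- demoConfig(years = 1, spinup_years = 0.5)
  cfg$species <- list()
  cfg$sim$init_n0 <- numeric(0)
  sim <- runSimulation(cfg, seed = 1L)
  expect_equal(nrow(sim@records), 0L)
  expect_equal(nrow(sim@final_schools), 0L)
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- demoConfig(preset = "covarying", n_rows = 4, n_cols = 4,
                    years = 3, spinup_years = 1)
  a <- runSimulation(cfg, seed = 7L)
  b <- runSimulation(cfg, seed = 7L)
  expect_identical(a@records, b@records)
  expect_identical(a@diets, b@diets)
  c_ <- runSimulation(cfg, seed = 8L)
  expect_false(identical(a@records, c_@records))
})
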