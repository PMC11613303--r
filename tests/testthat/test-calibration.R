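test_that("calibration reproduces the characteristic points on a dense grid", {
  ## oracle: dense 0.01-degree grid evaluation after solving
  sp <- tinySpecies("cal", t_min = 5, t_opt = 12, t_max = 20)
  grid <- seq(5, 20, by = 0.01)
  ep <- fundamentalNetEnergy(sp, "adult", sp@w_ref, grid)
  scale <- max(ep)
  expect_lt(abs(ep[1]) / scale, 1e-6)
  expect_lt(abs(ep[length(ep)]) / scale, 1e-6)
  expect_lt(abs(grid[which.max(ep)] - 12), 0.1)

  ## symmetric request with t_opt exactly midway
  sym <- tinySpecies("sym", t_min = 6, t_opt = 13, t_max = 20)
  g2 <- seq(6, 20, by = 0.01)
  e2 <- fundamentalNetEnergy(sym, "adult", sym@w_ref, g2)
  expect_lt(abs(e2[1]) / max(e2), 1e-6)
  expect_lt(abs(e2[length(e2)]) / max(e2), 1e-6)
  expect_lt(abs(g2[which.max(e2)] - 13), 0.1)

  ## deterministic: identical inputs give identical parameters
  sp_b <- tinySpecies("cal", t_min = 5, t_opt = 12, t_max = 20)
  expect_identical(c(sp@t_peak, sp@c_m, sp@e_maint),
                   c(sp_b@t_peak, sp_b@c_m, sp_b@e_maint))
})

test_that("infeasible characteristic points are rejected", {
  expect_error(speciesParams("bad", t_min = 12, t_opt = 8, t_max = 20),
               "t_min < t_opt < t_max")
  broken <- speciesParams("x", 5, 12, 20)
  broken@t_opt <- 4
  expect_error(calibrateSpecies(broken), "infeasible|t_min < t_opt")
  ## an extreme supra-peak decline makes a cold optimum unreachable
  expect_error(calibrateSpecies(speciesParams("steep", t_min = 5, t_opt = 6.2,
                                              t_max = 20, lambda = 0.4)),
               "infeasible|reduce lambda")
})

test_that("fundamental curves are dome-shaped with a single sign change", {
  for (sp in lapply(demoSpecies(), calibrateSpecies)) {
    for (stage in c("early", "adult")) {
      grid <- seq(sp@t_min, sp@t_max, by = 0.01)
      ep <- fundamentalNetEnergy(sp, stage, sp@w_ref, grid)
      signs <- sign(diff(ep))
      flips <- sum(diff(signs[signs != 0]) != 0)
      expect_equal(flips, 1L)
    }
  }
})

test_that("the early-life curve dominates the adult curve at equal mass", {
  sp <- tinySpecies()
  grid <- seq(sp@t_min - 3, sp@t_max + 3, by = 0.05)
  early <- fundamentalNetEnergy(sp, "early", 10, grid)
  adult <- fundamentalNetEnergy(sp, "adult", 10, grid)
  expect_true(all(early >= adult))
  expect_gt(max(early), max(adult))
})

test_that("fundamentalTPC derives zeros and argmax from the grid", {
  sp <- tinySpecies("cal2", t_min = 4, t_opt = 10, t_max = 17)
  curve <- fundamentalTPC(sp)
  ch <- tpcCharacteristics(curve)
  expect_lt(abs(ch["t_lo"] - 4), 0.02)
  expect_lt(abs(ch["t_hi"] - 17), 0.02)
  expect_lt(abs(ch["t_opt"] - 10), 0.1)
  expect_error(fundamentalTPC(speciesParams("raw", 4, 10, 17)),
               "not calibrated")
})

test_that("uniform food limitation lowers, narrows and cold-shifts the curve", {
  ## scaling ingestion by c < 1 at 100% oxygen: lower maximum, narrower
  ## positive range, argmax at or below the fundamental optimum (a species
  ## with a deep scope margin so the c = 0.5 curve keeps a positive range)
  sp <- calibrateSpecies(demoSpecies()[[2]])
  grid <- seq(sp@t_min - 2, sp@t_max + 2, by = 0.01)
  full <- fundamentalNetEnergy(sp, "adult", sp@w_ref, grid)
  prev_max <- max(full)
  prev_range <- diff(range(grid[full > 0]))
  prev_topt <- grid[which.max(full)]
  for (cfac in c(0.9, 0.7, 0.5)) {
    lim <- cfac * (full + maintenanceRate(sp@w_ref, grid, sp@c_m, sp@beta_m,
                                          sp@e_maint)) -
      maintenanceRate(sp@w_ref, grid, sp@c_m, sp@beta_m, sp@e_maint)
    expect_lt(max(lim), prev_max)
    expect_gt(max(lim), 0)
    rng <- diff(range(grid[lim > 0]))
    expect_lt(rng, prev_range)
    expect_lte(grid[which.max(lim)], prev_topt)
    prev_max <- max(lim); prev_range <- rng; prev_topt <- grid[which.max(lim)]
  }
})

test_that("calibrated parameters survive the CSV round trip", {
  sps <- lapply(demoSpecies()[1:2], calibrateSpecies)
  path <- tempfile(fileext = ".csv")
  writeSpeciesCSV(sps, path)
  back <- readSpeciesCSV(path)
  for (sp in sps) {
    b <- back[[sp@name]]
    expect_equal(b@t_peak, sp@t_peak)
    expect_equal(b@c_m, sp@c_m)
    expect_equal(b@e_maint, sp@e_maint)
    expect_equal(b@ltl_access, sp@ltl_access)
    expect_equal(b@spawn_steps, sp@spawn_steps)
  }
  unlink(path)
})
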