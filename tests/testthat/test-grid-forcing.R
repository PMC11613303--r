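test_that("grid construction, area and index bijection behave", {
  g1 <- makeGrid(1, 1, 30)
  expect_equal(nCells(g1), 1L)
  expect_equal(g1@cell_size^2, 900)

  g <- makeGrid(10, 10, 30)
  expect_equal(nCells(g), 100L)

  g23 <- makeGrid(2, 3, 30)
  expect_equal(cellAt(g23, 1, 2), 2L)
  rc <- rowColAt(g23, cellAt(g23, 2, 3))
  expect_equal(c(rc$row, rc$col), c(2L, 3L))
  ## full round-trip over every cell
  all_rc <- rowColAt(g23, 1:6)
  expect_equal(cellAt(g23, all_rc$row, all_rc$col), 1:6)

  expect_error(makeGrid(0, 5), "positive")
  expect_error(makeGrid(3, -1), "positive")
})

test_that("latitude proxy spans [0, 1] south to north", {
  g <- makeGrid(5, 2, 30)
  lp <- latitudeProxy(g)
  expect_equal(min(lp), 0)
  expect_equal(max(lp), 1)
  expect_equal(latitudeProxy(makeGrid(1, 4, 30)), rep(0.5, 4))
})

test_that("forcing generation is deterministic and periodic", {
  g <- makeGrid(6, 6, 30)
  sc <- scenarioPreset("covarying", seed = 11L)
  f1 <- generateForcing(g, sc, 24)
  f2 <- generateForcing(g, sc, 24)
  expect_identical(f1, f2)

  a <- forcingAt(f1, 5)
  b <- forcingAt(f1, 5 + 24)
  expect_identical(a, b)

  f3 <- generateForcing(g, scenarioPreset("covarying", seed = 12L), 24)
  expect_false(identical(f1@biomass, f3@biomass))
})

test_that("no scenario can produce negative biomass or oxygen", {
  g <- makeGrid(4, 4, 30)
  harsh <- forcingScenario("harsh", o2_base = 10, o2_season_amp = 30,
                           bot_o2_offset = -20, hypox_rows = 1:2,
                           hypox_steps = 1:24, hypox_severity = 50,
                           ltl = demoLTLGroups(noise_sd = rep(1.5, 4)),
                           seed = 3L)
  f <- generateForcing(g, harsh, 24)
  expect_true(all(f@o2_int >= 0))
  expect_true(all(f@o2_bot >= 0))
  expect_true(all(f@biomass >= 0))
})

test_that("the optimal preset is saturating and fully oxygenated", {
  g <- makeGrid(5, 5, 30)
  f <- generateForcing(g, scenarioPreset("optimal", seed = 1L), 24)
  expect_true(all(f@o2_int == 100))
  expect_true(all(f@o2_bot == 100))
  ## biomass far above any demo species satiety threshold
  expect_true(all(f@biomass >= 1e10))
})

test_that("rho controls the prey-temperature covariation monotonically", {
  g <- makeGrid(8, 8, 30)

  ## rho = 0, zero noise: prey is independent of the temperature anomaly
  flat <- demoLTLGroups(bloom_amp = rep(0, 4), noise_sd = rep(0, 4),
                        rho = rep(0, 4))
  f0 <- generateForcing(g, forcingScenario("flat", t_noise_sd = 0,
                                           ltl = flat, seed = 5L), 24)
  expect_equal(cov(as.vector(f0@biomass[, , 1]), as.vector(f0@t_int)), 0)

  ## rho > 0, zero noise: positive rank correlation across cells in season
  make <- function(r) {
    tab <- demoLTLGroups(bloom_amp = rep(0.5, 4), noise_sd = rep(0, 4),
                         rho = rep(r, 4))
    generateForcing(g, forcingScenario("rho", t_noise_sd = 0, ltl = tab,
                                       seed = 5L), 24)
  }
  f_mid <- make(0.3)
  expect_gt(cor(f_mid@biomass[12, , 1], f_mid@t_int[12, ],
                method = "spearman"), 0)

  ## rank correlation over the whole field increases with rho
  cors <- vapply(list(make(0.1), f_mid, make(0.8)), function(f)
    cor(as.vector(f@biomass[, , 1]), as.vector(f@t_int),
        method = "spearman"), numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("forcing climatologies round-trip through long-format CSV", {
  g <- makeGrid(3, 4, 30)
  f <- generateForcing(g, scenarioPreset("covarying", seed = 2L), 12)
  path <- tempfile(fileext = ".csv")
  writeForcingCSV(f, path)
  f2 <- readForcingCSV(path)
  expect_equal(f2@t_int, f@t_int)
  expect_equal(f2@o2_bot, f@o2_bot)
  expect_equal(f2@biomass, f@biomass)
  expect_equal(f2@groups$item_mass, f@groups$item_mass)
  unlink(c(path, paste0(path, ".groups.csv")))
})
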