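test_that("ingestion follows a type I functional response with a plateau", {
  expect_equal(ingestionRate(0, w = 16, stage_mult = 1, i_max = 2,
                             beta = 0.75, kappa0 = 1), 0)
  ## hand evaluation of the two branches: with a clearance such that the
  ## mass-specific encounter term times w^beta is 1 per unit biomass,
  ## I = min(P, i_max * w^0.75) = min(10, 2 * 16^0.75) = 10
  I <- ingestionRate(10, w = 16, stage_mult = 1, i_max = 2, beta = 0.75,
                     kappa0 = 1 / 16^0.75)
  expect_equal(I, 10)
  ## at and beyond the satiety threshold the plateau is exact
  I_sat <- ingestionRate(c(32, 50, 1e6), w = 16, stage_mult = 1, i_max = 2,
                         beta = 0.75, kappa0 = 1 / 16^0.75)
  expect_equal(I_sat, rep(2 * 16^0.75, 3))
  ## nondecreasing and piecewise linear in P
  p <- seq(0, 40, by = 0.5)
  I_p <- ingestionRate(p, 16, 1, 2, 0.75, kappa0 = 1 / 16^0.75)
  expect_true(all(diff(I_p) >= 0))
  expect_error(ingestionRate(5, w = 0, 1, 2, 0.75, kappa0 = 1),
               "non-positive")
})

test_that("oxygen dose-response has the half-saturation identity and saturates", {
  for (h in c(1, 2, 3.7))
    expect_equal(oxygenFactor(30, k_o2 = 30, h = h), 0.5)
  expect_lt(abs(oxygenFactor(1e9, 30, 2) - 1), 1e-10)
  o2 <- seq(0, 150, by = 1)
  expect_true(all(diff(oxygenFactor(o2, 28, 2)) > 0))
  expect_error(oxygenFactor(-1, 30, 2), "negative")
})

test_that("maintenance follows the Arrhenius law in temperature and scales with mass", {
  ## independent scalar evaluation with kB in eV/K
  kB <- 8.617333262e-5
  expected <- 1 * 1 * exp(-0.43 / (kB * (10 + 273.15)))
  expect_equal(maintenanceRate(w = 1, tC = 10, c_m = 1, beta_m = 1,
                               e_maint = 0.43), expected)
  expect_lt(maintenanceRate(1, 5, 1, 1, 0.43),
            maintenanceRate(1, 15, 1, 1, 0.43))
  ## beta_m = 1: doubling the mass doubles maintenance
  expect_equal(maintenanceRate(2, 10, 1, 1, 0.43),
               2 * maintenanceRate(1, 10, 1, 1, 0.43))
})

test_that("mobilised energy saturates in oxygen and respects its bounds", {
  sp <- tinySpecies()
  expect_equal(mobilisedEnergy(0, 12, 50, sp), 0)
  phi <- thermalFactor(12, sp@e_mob, sp@t_peak, sp@lambda)
  expect_lt(abs(mobilisedEnergy(10, 12, 1e9, sp) - 10 * phi), 1e-8)
  o2 <- seq(0, 120, by = 2)
  em <- mobilisedEnergy(5, 12, o2, sp)
  expect_true(all(diff(em) >= 0))
  expect_true(all(em <= 5 * phi + 1e-12))
})

test_that("net energy equals the composition of its sub-fluxes (scalar oracle)", {
  sp <- tinySpecies()
  set.seed(42)
  for (i in 1:50) {
    p <- runif(1, 0, 3e6)
    w <- runif(1, 0.01, 500)
    s <- sample(c(1, sp@eta_early), 1)
    tC <- runif(1, 2, 24)
    o2 <- runif(1, 5, 110)
    got <- netEnergy(p, w, s, tC, o2, sp)
    want <- oracleFluxes(p, w, s, tC, o2, sp)
    expect_equal(unlist(got[1, ]), want, tolerance = 1e-12)
  }
  ## flux identities on a batch
  fx <- netEnergy(runif(20, 0, 2e6), runif(20, 1, 100), 1,
                  runif(20, 5, 18), runif(20, 20, 100), sp)
  expect_equal(fx$A, sp@xi * fx$I)
  expect_true(all(fx$E_M >= 0 & fx$E_M <= fx$A + 1e-12))
  expect_equal(fx$E_P, fx$E_M - fx$E_m)
})

test_that("vectorised evaluation matches element-wise scalar evaluation", {
  sp <- tinySpecies()
  set.seed(7)
  n <- 200
  p <- runif(n, 0, 4e6); w <- runif(n, 0.01, 800)
  tC <- runif(n, 0, 25); o2 <- runif(n, 0, 120)
  batch <- netEnergy(p, w, 1, tC, o2, sp)
  single <- t(vapply(seq_len(n), function(i)
    oracleFluxes(p[i], w[i], 1, tC[i], o2[i], sp), numeric(5)))
  expect_equal(as.matrix(batch), single, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("net energy is nondecreasing in oxygen with everything else fixed", {
  sp <- tinySpecies()
  set.seed(11)
  n <- 10000
  tC <- runif(n, 2, 24); w <- runif(n, 0.05, 600)
  p <- runif(n, 0, 3e6)
  o2_lo <- runif(n, 0, 100)
  o2_hi <- o2_lo + runif(n, 0, 40)
  lo <- netEnergy(p, w, 1, tC, o2_lo, sp)$E_P
  hi <- netEnergy(p, w, 1, tC, o2_hi, sp)$E_P
  expect_true(all(hi >= lo - 1e-12))
})

test_that("a given oxygen drop cuts net energy relatively less at higher ingestion", {
  ## the ontogenetic hypoxia mechanism: the same relative reduction in
  ## mobilised energy hits the smaller ingestion multiplier harder because
  ## maintenance does not shrink with it
  sp <- tinySpecies()
  w <- sp@w_ref
  for (tC in c(9, 12, 15)) {
    drop_for <- function(s) {
      full <- satiatedNetEnergy(sp, s, w, tC, o2 = 100)
      hypo <- satiatedNetEnergy(sp, s, w, tC, o2 = sp@k_o2)
      (full - hypo) / full
    }
    expect_lt(drop_for(sp@eta_early), drop_for(1))
  }
})
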