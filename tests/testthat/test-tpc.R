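test_that("life stages classify by age and maturity", {
  expect_equal(classifyStage(0.5, FALSE), "early")
  expect_equal(classifyStage(2, FALSE), "juvenile")
  expect_equal(classifyStage(1.5, TRUE), "adult")
  expect_equal(classifyStage(c(0.1, 1, 3), c(FALSE, FALSE, TRUE)),
               c("early", "juvenile", "adult"))
  expect_error(classifyStage(-1, FALSE), "negative")
})

test_that("collectSamples averages schools within (species, stage, cell, step)", {
  rec <- data.frame(
    step = c(1L, 1L, 1L, 1L, 2L),
    cell = c(4L, 4L, 4L, 4L, 4L),
    species = "a",
    stage = c("early", "early", "adult", "adult", "adult"),
    age = c(0.5, 0.6, 3, 4, 3),
    mass = c(1, 3, 100, 300, 120),
    n = 1, ep = c(2, 4, 10, 30, 5),
    temperature = 10, oxygen = 95)
  s <- collectSamples(rec)
  expect_equal(nrow(s), 3L)                      # one per stage x step
  early <- s[s$stage == "early", ]
  expect_equal(early$ep, 3)                      # mean of 2 and 4
  expect_equal(early$mass, 2)
  expect_equal(early$n_schools, 2L)
  adult1 <- s[s$stage == "adult" & s$step == 1L, ]
  expect_equal(adult1$ep, 20)
  ## a single school gives exactly one sample with its own values
  expect_equal(s[s$step == 2L, "ep"], 5)
  ## empty input: empty output, no error
  expect_equal(nrow(collectSamples(rec[0, ])), 0L)
})

test_that("the deviation statistic matches a brute-force spreadsheet sum", {
  sp <- tinySpecies()
  ## samples equal to the fundamental: D = 0
  tc <- c(8, 10, 12, 14, 16)
  w <- rep(sp@w_ref, 5)
  e_fund <- fundamentalNetEnergy(sp, "adult", w, tc) / w^sp@beta
  base <- data.frame(species = sp@name, stage = "adult", cell = 1L,
                     step = 1:5, ep = e_fund, mass = w, temperature = tc,
                     oxygen = 100, n_schools = 1L)
  expect_equal(tpcDeviation(sp, base)$D, 0)

  ## every sample at exactly half its fundamental value: D = 0.5
  halved <- base; halved$ep <- e_fund / 2
  expect_equal(tpcDeviation(sp, halved)$D, 0.5)

  ## five hand-written samples against the curve: brute-force sum
  hand <- base; hand$ep <- e_fund * c(0.9, 0.8, 0.5, 1.0, 0.65)
  manual <- mean((e_fund - hand$ep) / e_fund)
  got <- tpcDeviation(sp, hand)
  expect_equal(got$D, manual)
  expect_equal(got$n, 5L)
  expect_equal(got$n_excluded, 0L)

  ## order invariance and split/merge invariance
  shuffled <- hand[c(3, 1, 5, 2, 4), ]
  expect_equal(tpcDeviation(sp, shuffled)$D, got$D)
  part <- tpcDeviation(sp, hand[1:2, ])
  rest <- tpcDeviation(sp, hand[3:5, ])
  expect_equal((2 * part$D + 3 * rest$D) / 5, got$D)
})

test_that("the near-zero guard excludes samples at the TPC edges", {
  sp <- tinySpecies()
  tc <- c(sp@t_min + 0.01, sp@t_opt)   # first sits at the zero crossing
  w <- rep(sp@w_ref, 2)
  e_fund <- fundamentalNetEnergy(sp, "adult", w, tc) / w^sp@beta
  d <- data.frame(species = sp@name, stage = "adult", cell = 1L, step = 1:2,
                  ep = e_fund, mass = w, temperature = tc, oxygen = 100,
                  n_schools = 1L)
  res <- tpcDeviation(sp, d)
  expect_equal(res$n, 1L)
  expect_equal(res$n_excluded, 1L)
  ## all samples guarded out: D is missing, not zero
  edge_only <- d[1, ]
  res2 <- tpcDeviation(sp, edge_only)
  expect_true(is.na(res2$D))
  expect_equal(res2$n, 0L)
})

test_that("the oxygen counterfactual vanishes at full saturation and matches a closed form", {
  sp <- tinySpecies()
  tc <- seq(9, 15, by = 1.5)
  w <- rep(20, length(tc))
  e_fund <- fundamentalNetEnergy(sp, "adult", w, tc) / w^sp@beta
  full <- data.frame(species = sp@name, stage = "adult", cell = 1L,
                     step = seq_along(tc), ep = e_fund * 0.7, mass = w,
                     temperature = tc, oxygen = 100, n_schools = 1L)
  expect_equal(oxygenDeviation(sp, full)$D, 0)

  ## at reduced oxygen the counterfactual drop follows the dose-response
  ## ratio analytically, per sample
  o2 <- 60
  red <- full; red$oxygen <- o2
  got <- oxygenDeviation(sp, red)
  f_ratio <- oxygenFactor(o2, sp@k_o2, sp@h_o2) /
    oxygenFactor(100, sp@k_o2, sp@h_o2)
  s_mult <- 1
  a_spec <- sp@xi * s_mult * sp@i_max * oxygenFactor(100, sp@k_o2, sp@h_o2) *
    thermalFactor(tc, sp@e_mob, sp@t_peak, sp@lambda)
  expected_per_sample <- a_spec * (1 - f_ratio) / e_fund
  expect_equal(got$D, mean(expected_per_sample), tolerance = 1e-10)

  ## empty input: missing
  expect_true(is.na(oxygenDeviation(sp, full[0, ])$D))
})

test_that("the food/oxygen decomposition is exact", {
  expect_equal(decomposeDeviation(0.48, 0.068), 0.412)
  expect_equal(decomposeDeviation(0.3, 0.3), 0)
  expect_equal(decomposeDeviation(0.7, 0), 0.7)
})

test_that("the realised optimum comes from binned means with low-tie breaking", {
  ## samples generated from an exact dome recover the argmax within a bin
  tc <- seq(5, 20, by = 0.1)
  ep <- -(tc - 12.3)^2 + 60
  expect_lt(abs(realisedTopt(tc, ep, 0.5) - 12.3), 0.5)
  ## a single sample returns its own bin centre
  expect_equal(realisedTopt(11.3, 5, 0.5), 11.25)
  ## two exactly tied bins: the lower centre wins
  expect_equal(realisedTopt(c(10.1, 14.1), c(3, 3), 0.5), 10.25)
  expect_true(is.na(realisedTopt(numeric(0), numeric(0))))
})

test_that("deviationStats assembles the per species x stage table additively", {
  run <- demoPipeline("covarying", 1L)
  dev <- run$dev
  expect_true(all(c("d_total", "d_oxygen", "d_food", "n", "n_excluded",
                    "realised_topt", "fundamental_topt") %in% names(dev)))
  ## additivity is exact by construction
  expect_equal(dev$d_food, dev$d_total - dev$d_oxygen, tolerance = 1e-15)
  ## sample counts match the retained sets
  expect_true(all(dev$n > 0))
})
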