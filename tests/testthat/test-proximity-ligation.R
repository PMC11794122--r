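test_that("per-EV detection probability has the Poisson closed form", {
  expect_identical(detectionProbability(0, 5, 1), 0)
  expect_equal(detectionProbability(50, 50, 1), 1, tolerance = 1e-9)
  expect_equal(detectionProbability(1, 1, 1), (1 - exp(-1))^2,
               tolerance = 1e-12)
  expect_equal(detectionProbability(2, 3, 0.5),
               0.5 * (1 - exp(-2)) * (1 - exp(-3)), tolerance = 1e-12)
  expect_error(detectionProbability(-1, 1, 1), "lam1")
  expect_error(detectionProbability(1, 1, 2), "p_ligate")
})

test_that("PLA simulation pairs conjugates by min(bound_1, bound_2)", {
  single <- manualLabeled(bound_1 = c(3L, 5L, 2L), bound_2 = c(0L, 0L, 0L))
  out <- simulatePLA(single, plaConfig(p_ligate = 1, background_rate = 0),
                     seed = 1)
  expect_identical(templateCount(out), 0L)

  lab <- manualLabeled(bound_1 = c(2L, 4L, 1L), bound_2 = c(3L, 1L, 1L))
  out <- simulatePLA(lab, plaConfig(p_ligate = 1, background_rate = 0),
                     seed = 2)
  expect_identical(templateCount(out), sum(pmin(lab$bound_1, lab$bound_2)))
})

test_that("mean EV-derived templates match the exact expectation", {
  withr::with_seed(41, {
    b1 <- rpois(300, 1.5); b2 <- rpois(300, 1.0)
  })
  lab <- manualLabeled(b1, b2)
  p_lig <- 0.6
  exact <- p_lig * sum(pmin(b1, b2))   # thinning expectation, counts fixed
  sims <- vapply(1:4000, function(s)
    simulatePLA(lab, plaConfig(p_ligate = p_lig, background_rate = 0),
                seed = s)@from_ev, 0L)
  expect_equal(mean(sims), exact, tolerance = 0.02)
})

test_that("templates are conserved as from_ev + from_background", {
  lab <- manualLabeled(c(1L, 2L, 0L), c(2L, 1L, 4L))
  for (s in 1:50) {
    out <- simulatePLA(lab, plaConfig(p_ligate = 0.5, background_rate = 2),
                       seed = s)
    expect_identical(out@templates, out@from_ev + out@from_background)
    expect_true(out@from_ev >= 0 && out@from_background >= 0)
  }
})

test_that("expected template yield is monotone in antigen load, binding and ligation", {
  mean_templates <- function(antigen_mean, p_bind, p_ligate, seeds = 1:30) {
    mean(vapply(seeds, function(s) {
      ss <- spawnSeeds(s, 3)
      pop <- simulatePopulation(
        evPopulationParams(n_ev = 20000, tumor_fraction = 0.8,
                           antigen_mean = antigen_mean,
                           nonspecific_rate = 0), seed = ss[1])
      lab <- labelPopulation(pop, p_bind = p_bind, dual_label = TRUE,
                             seed = ss[2])
      as.numeric(templateCount(simulatePLA(
        lab, plaConfig(p_ligate = p_ligate, background_rate = 0),
        seed = ss[3])))
    }, 0))
  }
  expect_lte(mean_templates(5, 0.3, 0.8), mean_templates(20, 0.3, 0.8))
  expect_lte(mean_templates(10, 0.1, 0.8), mean_templates(10, 0.4, 0.8))
  expect_lte(mean_templates(10, 0.3, 0.3), mean_templates(10, 0.3, 0.9))
})

test_that("zero antigen and zero background yield exactly zero templates", {
  pop <- simulatePopulation(
    evPopulationParams(n_ev = 5000, tumor_fraction = 0, antigen_mean = 50,
                       nonspecific_rate = 0), seed = 1)
  lab <- labelPopulation(pop, p_bind = 0.5, dual_label = TRUE, seed = 2)
  for (s in 1:20)
    expect_identical(
      templateCount(simulatePLA(lab, plaConfig(background_rate = 0),
                                seed = s)), 0L)
})

test_that("PLA never worsens the LOD at zero background and certain ligation", {
  # matched inputs: every conjugate pair pre-formed, one reporter per pair,
  # so both arms see identical amplifiable concentrations
  lab <- manualLabeled(rep(1L, 5000), rep(1L, 5000), dna_per = 1)
  lab$dna_strands <- pmin(lab$bound_1, lab$bound_2)
  scen <- list(labeled = lab, eluate_volume_ul = 1e-6,
               pla = plaConfig(p_ligate = 1, background_rate = 0))
  res <- plaVsDirectGain(scen, dilutions = 10^-(0:8), noise_sd = 0, seed = 3)
  expect_equal(res$pla_conc, res$direct_conc)
  expect_lte(res$lod_pla, res$lod_direct)
  expect_equal(res$ratio, 1)

  # sub-unit ligation shrinks the PLA arm's material, never the direct arm's
  scen2 <- list(labeled = manualLabeled(rep(2L, 5000), rep(2L, 5000)),
                eluate_volume_ul = 1e-6,
                pla = plaConfig(p_ligate = 0.5, background_rate = 0))
  res2 <- plaVsDirectGain(scen2, dilutions = 10^-(0:8), noise_sd = 0,
                          seed = 4)
  expect_lte(res2$pla_conc, res2$direct_conc)
})
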