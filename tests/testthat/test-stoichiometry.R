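test_that("Poisson pmf evaluates the closed form and normalizes", {
  expect_identical(poissonPMF(0, 0), 1)
  expect_equal(poissonPMF(1, 1), exp(-1))
  expect_equal(sum(poissonPMF(0:50, 0.0125)), 1, tolerance = 1e-12)
  expect_error(poissonPMF(-1, 1), "non-negative")
  expect_error(poissonPMF(1, -0.1), "lam")
})

test_that("multivalent-antibody probability matches its closed form", {
  expect_identical(probMultivalentAntibody(0), 0)
  expect_equal(probMultivalentAntibody(0.1),
               1 - exp(-0.1) - 0.1 * exp(-0.1), tolerance = 1e-12)
  expect_equal(probMultivalentAntibody(0.1), 0.004679, tolerance = 1e-4)
  # at the assay's quoted 1:80 antibody:streptavidin ratio
  expect_identical(signif(probMultivalentAntibody(1 / 80), 2), 7.7e-5)
  expect_error(probMultivalentAntibody(-1), "lam")
})

test_that("multivalency probability is increasing, bounded, ~ lam^2/2 for small lam", {
  lams <- c(1e-4, 1e-3, 0.0125, 0.03, 0.05, 0.1, 0.5, 1, 5, 20)
  p <- vapply(lams, probMultivalentAntibody, 0)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
  small <- lams[lams <= 0.05]
  approx2 <- small^2 / 2 - small^3 / 3
  rel <- abs(vapply(small, probMultivalentAntibody, 0) - approx2) / approx2
  expect_true(all(rel < 0.01))
})

test_that("lambda follows from mix moles, with degenerate mixes handled", {
  expect_equal(lambdaFromMix(conjugationMix(ab_conc = 1, ab_vol = 2,
                                            sa_conc = 2, sa_vol = 1)), 1)
  # the packaged default mix arithmetic gives 0.6 pmol / 4.8 pmol = 1:8
  expect_equal(lambdaFromMix(conjugationMix()), 0.125)
  expect_equal(lambdaFromMix(conjugationMix(ab_conc = 0)), 0)
  expect_error(lambdaFromMix(conjugationMix(sa_conc = 0)), "streptavidin")
})

test_that("site occupancy enumeration matches the binomial closed form", {
  # saturating DNA puts all mass on (0, 4, 0)
  sat <- occupancyTable(enumerateSiteOccupancy(0, 1))
  expect_equal(sat$prob[sat$n_dna == 4 & sat$n_ab == 0], 1)
  expect_equal(sum(sat$prob), 1, tolerance = 1e-12)
  # half-occupancy DNA: Binomial(4, 0.5) mode
  half <- occupancyTable(enumerateSiteOccupancy(0, 0.5))
  expect_equal(sum(half$prob[half$n_dna == 2]), 0.375)
  # enumeration vs independent-binomial marginals (oracle), random pairs
  withr::with_seed(21, {
    for (i in 1:20) {
      p_ab <- runif(1, 0, 0.6); p_dna <- runif(1, 0, 1 - p_ab)
      tb <- occupancyTable(enumerateSiteOccupancy(p_ab, p_dna))
      expect_equal(sum(tb$prob), 1, tolerance = 1e-12)
      marg_ab <- vapply(0:4, function(k) sum(tb$prob[tb$n_ab == k]), 0)
      marg_dna <- vapply(0:4, function(k) sum(tb$prob[tb$n_dna == k]), 0)
      expect_equal(marg_ab, dbinom(0:4, 4, p_ab), tolerance = 1e-12)
      expect_equal(marg_dna, dbinom(0:4, 4, p_dna), tolerance = 1e-12)
    }
  })
  expect_error(enumerateSiteOccupancy(0.7, 0.7), "exceed")
  expect_error(enumerateSiteOccupancy(-0.1, 0.5), "probability")
})

test_that("Poisson antibody model agrees with the 4-site binomial at small lam", {
  # per-site probability lam/4 makes the tetramer marginal Binomial(4, lam/4),
  # whose P(n_ab > 1) converges to the Poisson form as lam -> 0
  for (lam in c(0.0125, 0.05)) {
    tb <- occupancyTable(enumerateSiteOccupancy(lam / 4, 0.5))
    p_multi <- sum(tb$prob[tb$n_ab > 1])
    expect_equal(p_multi, probMultivalentAntibody(lam), tolerance = 0.05)
  }
})

test_that("conditional DNA load of single-antibody conjugates is E[n_dna | n_ab = 1]", {
  # antibody rare, DNA saturating: the nominal 1-antibody/3-DNA conjugate
  expect_equal(meanDnaPerConjugate(enumerateSiteOccupancy(1e-6, 1 - 1e-6)),
               3, tolerance = 1e-5)
  expect_equal(meanDnaPerConjugate(enumerateSiteOccupancy(0.2, 0)), 0)
  # rare antibody, DNA at p = 0.5: 3 spare sites x 0.5 by linearity
  expect_equal(meanDnaPerConjugate(enumerateSiteOccupancy(1e-9, 0.5)), 1.5,
               tolerance = 1e-7)
  expect_error(meanDnaPerConjugate(enumerateSiteOccupancy(0, 0.5)),
               "undefined")
})
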