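test_that("Ct simulation evaluates the curve and censors correctly", {
  crv <- standardCurve()   # Ct = 4.059 X + 8.144
  expect_equal(simulateCt(1, crv, noise_sd = 0), 12.203)
  expect_equal(simulateCt(0, crv, noise_sd = 0), 8.144)
  expect_true(is.na(simulateCt(Inf, crv, noise_sd = 0)))       # zero template
  expect_true(is.na(simulateCt(8, crv, noise_sd = 0)))         # > 40 cycles
  expect_identical(simulateCt(1:3, crv, seed = 5),
                   simulateCt(1:3, crv, seed = 5))
})

test_that("standard-curve fitting recovers noiseless parameters and R^2", {
  x <- rep(0:4, each = 3)
  fit <- fitStandardCurve(x, 4.059 * x + 8.144)
  expect_equal(curveSlope(fit), 4.059, tolerance = 1e-9)
  expect_equal(curveIntercept(fit), 8.144, tolerance = 1e-9)
  expect_equal(curveRsquared(fit), 1, tolerance = 1e-9)

  two <- fitStandardCurve(c(0, 2), c(10, 14))
  expect_equal(curveSlope(two), 2)
  expect_equal(curveRsquared(two), 1)

  expect_error(fitStandardCurve(c(1, 1), c(10, 11)), "distinct")
  expect_error(fitStandardCurve(numeric(0), numeric(0)), "distinct")
})

test_that("fitting is unbiased under replicate noise and invariant to ordering", {
  truth <- standardCurve()
  x <- rep(0:4, each = 3)
  slopes <- vapply(1:200, function(s) {
    ct <- simulateCt(x, truth, noise_sd = 0.2, seed = s)
    curveSlope(fitStandardCurve(x, ct))
  }, 0)
  expect_equal(mean(slopes), 4.059, tolerance = 0.02)

  ct <- simulateCt(x, truth, noise_sd = 0.2, seed = 99)
  perm <- sample(seq_along(x))
  f1 <- fitStandardCurve(x, ct)
  f2 <- fitStandardCurve(x[perm], ct[perm])
  f3 <- fitStandardCurve(c(x, x), c(ct, ct))   # duplicated replicate set
  expect_equal(curveSlope(f2), curveSlope(f1), tolerance = 1e-12)
  expect_equal(curveSlope(f3), curveSlope(f1), tolerance = 1e-12)
  expect_equal(curveIntercept(f3), curveIntercept(f1), tolerance = 1e-12)
})

test_that("inversion is the exact inverse of noiseless simulation", {
  crv <- standardCurve(x_range = c(0, 10))
  expect_equal(invertCt(8.144, crv), 0)
  expect_equal(invertCt(12.203, crv), 1)
  withr::with_seed(31, {
    x <- runif(20, 0, 7)
    expect_equal(invertCt(simulateCt(x, crv, noise_sd = 0), crv), x,
                 tolerance = 1e-12)
  })
  expect_error(invertCt(NA_real_, crv), "undetermined")
  expect_warning(invertCt(60, crv), "extrapolating")
})

test_that("LOD is the most dilute level with all replicates determined", {
  series <- list(`10` = c(14, 14.1, 13.9),   # nM
                 `1` = c(18, 18.2, 17.9),
                 `0.1` = c(22.1, 22.0, 22.3),
                 `0.01` = c(26, NA, NA),
                 `0.001` = c(NA, NA, NA))
  expect_equal(estimateLod(series), 0.1)     # the 100 pM level
  expect_equal(estimateLod(series[1:3]), 0.1)
  expect_true(is.na(estimateLod(series[4:5])))
  expect_error(estimateLod(list()), "empty")
})

test_that("amplification efficiency follows from the slope", {
  expect_equal(amplificationEfficiency(standardCurve(slope = log2(10) / 1)),
               1, tolerance = 1e-3)
  expect_equal(amplificationEfficiency(standardCurve()), 0.764,
               tolerance = 1e-3)
  slopes <- seq(3, 6, by = 0.25)
  eff <- vapply(slopes, function(s)
    amplificationEfficiency(standardCurve(slope = s)), 0)
  expect_true(all(diff(eff) < 0))
})

test_that("noise and stricter censoring never make the expected LOD more dilute", {
  # grid kept interior to the 40-cycle floor (deepest noiseless Ct 36.6):
  # noise can then only push determined levels over the limit, never rescue
  # an already-censored one (a level sitting just past the floor can be
  # rescued by a lucky late amplification, which is out of scope here)
  base <- 10   # nM
  dil <- 10^-(0:7)
  lods <- vapply(1:200, function(s) c(
    quiet = lodForConcentration(base, dilutions = dil, noise_sd = 0, seed = s),
    noisy = lodForConcentration(base, dilutions = dil, noise_sd = 2, seed = s),
    strict = lodForConcentration(base, dilutions = dil, noise_sd = 0,
                                 max_cycles = 30, seed = s)), c(0, 0, 0))
  # higher concentration = worse (less dilute) LOD; NA = nothing detected
  meanLod <- function(v) mean(v, na.rm = TRUE)
  expect_gte(meanLod(lods["noisy", ]), meanLod(lods["quiet", ]))
  expect_gte(meanLod(lods["strict", ]), meanLod(lods["quiet", ]))
})

test_that("plate CSV and curve JSON round-trip", {
  plate <- qpcrPlate(target = c("standard", "standard", "target"),
                     ct = c(10.2, NA, 22.5), dilution_x = c(0, 1, NA))
  tf <- withr::local_tempfile(fileext = ".csv")
  writePlate(plate, tf)
  expect_identical(readPlate(tf), plate)
  expect_error(qpcrPlate("a", ct = -1), "positive")

  crv <- standardCurve(slope = 3.9, intercept = 9.1, r_squared = 0.998,
                       x_range = c(0, 4))
  cf <- withr::local_tempfile(fileext = ".json")
  writeCurve(crv, cf)
  back <- readCurve(cf)
  expect_equal(curveSlope(back), 3.9)
  expect_equal(curveRsquared(back), 0.998)
})

test_that("concentration anchoring maps both ways", {
  expect_equal(concToX(10, 10), 0)
  expect_equal(concToX(0.1, 10), 2)
  expect_identical(concToX(0, 10), Inf)
  expect_equal(xToConc(concToX(2.41, 10), 10), 2.41, tolerance = 1e-12)
})
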