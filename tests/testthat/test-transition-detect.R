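tGrid12 <- seq(100, 210, by = 10)

test_that("low-temperature harmonic fit is exact on designed lines", {
  s <- TemperatureSeries(tGrid12, 0.002 * tGrid12)
  f <- fitHarmonicLow(s)
  expect_equal(f$slope, 0.002, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-10)
  expect_lt(f$sigma, 1e-12)

  fc <- fitHarmonicLow(TemperatureSeries(tGrid12, rep(0.08, 12)))
  expect_equal(fc$slope, 0, tolerance = 1e-14)

  expect_error(fitHarmonicLow(TemperatureSeries(c(100, 120, 200), c(1, 2, 3)),
                              tMin = 100, tMax = 130), ">= 3 points")
})

test_that("harmonic slope estimates cover the design value", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    y <- 0.01 + 5e-4 * tGrid12 + rnorm(12, 0, 0.002)
    f <- fitHarmonicLow(TemperatureSeries(tGrid12, y), tMin = 100, tMax = 210)
    if (abs(f$slope - 5e-4) <= 3 * f$slopeSe) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("breakpoint search localises an exact two-slope curve", {
  y <- ifelse(tGrid12 <= 160, 0.01 + 5e-4 * tGrid12,
              0.01 + 5e-4 * 160 + 1e-3 * (tGrid12 - 160))
  seg <- detectTlow(TemperatureSeries(tGrid12, y), fitSpace = "linear")
  expect_gte(breakpoint(seg), 155)
  expect_lte(breakpoint(seg), 165)
  expect_lt(seg@sse, 1e-12)
  expect_lt(seg@pTwoRegime, 0.01)

  # a single exact line carries no second regime
  segLine <- detectTlow(TemperatureSeries(tGrid12, 0.01 + 5e-4 * tGrid12),
                        fitSpace = "linear")
  expect_equal(segLine@pTwoRegime, 1)

  expect_error(detectTlow(TemperatureSeries(tGrid12[1:5], rep(1, 5))), ">= 6 points")
  expect_error(detectTlow(TemperatureSeries(tGrid12, y - 0.2)), "positive values")
})

test_that("breakpoint search equals exhaustive enumeration on small series", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:15, 1)
    x <- sort(sample(seq(100, 300, 5), n))
    kink <- x[sample(4:(n - 3), 1)]
    y <- 0.1 + 0.001 * x + 0.004 * pmax(0, x - kink) + rnorm(n, 0, 0.01)
    seg <- detectTlow(TemperatureSeries(x, y), tCap = 300, fitSpace = "linear")
    oracle <- bruteForceSegmented(x, y)
    expect_equal(breakpoint(seg), oracle$breakpoint, tolerance = 1e-10)
    expect_equal(seg@sse, oracle$sse, tolerance = 1e-8)
  }
})

test_that("enthalpy intersection reproduces the analytic transition point", {
  tg <- seq(100, 300, by = 10)
  y <- ifelse(tg < 223, 1 + 0.01 * tg, -1.23 + 0.02 * tg)
  fit <- detectTdEnthalpy(TemperatureSeries(tg, y))
  expect_true(fit@transitionDetected)
  expect_equal(transitionTemperature(fit), 223, tolerance = 1e-8)
  expect_equal(deltaCp(fit), 0.01, tolerance = 1e-10)
  expect_equal(fit@cpLow, 0.01, tolerance = 1e-10)
  expect_equal(fit@cpHigh, 0.02, tolerance = 1e-10)

  # an exact single line is a single regime
  single <- detectTdEnthalpy(TemperatureSeries(tg, 5 + 0.8 * tg))
  expect_false(single@transitionDetected)
  expect_true(is.na(transitionTemperature(single)))
  expect_identical(single@diagnostic, "single-regime")

  expect_error(detectTdEnthalpy(TemperatureSeries(tg[1:6], y[1:6])), ">= 8 points")
})

test_that("increasing transition designs preserve T_D and delta_Cp orderings", {
  tds <- c(210, 240, 270)
  dcs <- c(0.2, 0.35, 0.5)
  for (seed in 1:5) {
    est <- t(sapply(1:3, function(i) {
      h <- makeEnthalpyCurve(tds[i], cpLow = 1, cpHigh = 1 + dcs[i],
                             noiseAbs = 0.5, seed = seed * 10 + i)
      f <- detectTdEnthalpy(h)
      c(f@tD, f@deltaCp)
    }))
    expect_true(all(diff(est[, 1]) > 0))
    expect_true(all(diff(est[, 2]) > 0))
  }
})

test_that("MSF deviation onset obeys the persistence rule", {
  tg <- seq(100, 300, by = 10)
  base <- 0.01 + 5e-4 * pmin(tg, 160) + 1e-3 * pmax(0, tg - 160)
  lin <- TemperatureSeries(tg, base)
  segLin <- detectTlow(lin, fitSpace = "linear")
  expect_true(is.na(detectTdMsf(lin, segLin)))

  withTd <- TemperatureSeries(tg, base + 3e-3 * pmax(0, tg - 223)^2 / 100)
  segW <- detectTlow(withTd, fitSpace = "linear")
  expect_equal(detectTdMsf(withTd, segW), 230)

  # a single outlier above the cap must not trigger an onset
  spike <- base
  spike[tg == 250] <- spike[tg == 250] * 1.5
  segS <- detectTlow(TemperatureSeries(tg, spike), fitSpace = "linear")
  expect_true(is.na(detectTdMsf(TemperatureSeries(tg, spike), segS)))
})

test_that("per-residue reports flag both transitions only when designed in", {
  spec <- SyntheticSpec(seed = 5)
  ds <- makePerResidueDataset(spec)
  rep1 <- detectResidueTransitions(ds, tLow = 160, tD = 223)
  expect_identical(nrow(rep1), 20L)
  expect_true(all(rep1$hasTlowSlopeChange))
  expect_true(all(rep1$hasTdDeviation))
  expect_true(all(is.finite(rep1$amplitudeAboveTd[rep1$hasTdDeviation])))

  # hydrophilic amplitudes dominate hydrophobic ones above T_D (hydrated mode)
  seqv <- strsplit(trpCageSequence(), "")[[1]]
  cls <- classifyResidue(seqv)
  inner <- 2:19
  ampPhil <- mean(rep1$amplitudeAboveTd[inner][cls[inner] == "hydrophilic"])
  ampPhob <- mean(rep1$amplitudeAboveTd[inner][cls[inner] == "hydrophobic"])
  expect_gt(ampPhil / ampPhob, 1)

  # purely linear curves: neither flag
  tg <- seq(100, 300, by = 10)
  flat <- list(`1` = TemperatureSeries(tg, 0.01 + 5e-4 * tg))
  rep2 <- detectResidueTransitions(flat, 160, 223)
  expect_false(rep2$hasTlowSlopeChange)
  expect_false(rep2$hasTdDeviation)
  expect_true(is.na(rep2$amplitudeAboveTd))

  # one residue without the designed transition stays unflagged for T_D
  noTd <- SyntheticSpec(tD = NA, seed = 6)
  ds[["3"]] <- makeMsfCurve(noTd)
  rep3 <- detectResidueTransitions(ds, 160, 223)
  expect_false(rep3$hasTdDeviation[rep3$residueIndex == 3])
  expect_identical(sum(!rep3$hasTdDeviation), 1L)
})

test_that("methyl-hydrogen branches are recovered exactly and under noise", {
  tg <- seq(100, 300, by = 10)
  exact <- 0.1 * exp(0.01 * tg)
  f <- fitMethyl(TemperatureSeries(tg, exact), tLow = 160)
  expect_equal(f$exponential$logIntercept, log(0.1), tolerance = 1e-10)
  expect_equal(f$exponential$rate, 0.01, tolerance = 1e-12)
  expect_lt(f$exponential$sigma, 1e-12)
  # the exponential continues above tLow: linear fit sees curvature
  expect_gt(f$linear$sigma, 0)

  expect_error(fitMethyl(TemperatureSeries(tg, exact - 1), 160), "positive")

  rates <- sapply(1:20, function(s) {
    cu <- makeMethylCurve(SyntheticSpec(seed = s))
    fitMethyl(cu, tLow = 160)$exponential$rate
  })
  expect_true(all(abs(rates - 0.01) / 0.01 < 0.10))
})

test_that("breakpoints and flags are scale-equivariant", {
  spec <- SyntheticSpec(tGrid = tGrid12, tD = NA, seed = 8)
  s1 <- makeMsfCurve(spec)
  s2 <- TemperatureSeries(s1@temperatures, 7.3 * s1@values, 7.3 * s1@errors)
  f1 <- detectTlow(s1)
  f2 <- detectTlow(s2)
  expect_equal(breakpoint(f2), breakpoint(f1))
  expect_equal(f2@pTwoRegime, f1@pTwoRegime, tolerance = 1e-8)
  expect_equal(f2@slopeLow, f1@slopeLow, tolerance = 1e-8)
  expect_equal(f2@interceptLow - f1@interceptLow, log(7.3), tolerance = 1e-8)

  h1 <- makeEnthalpyCurve(223, 1, 1.5, noiseAbs = 2, seed = 9)
  h2 <- TemperatureSeries(h1@temperatures, 3 * h1@values, 3 * h1@errors)
  d1 <- detectTdEnthalpy(h1); d2 <- detectTdEnthalpy(h2)
  expect_identical(d2@transitionDetected, d1@transitionDetected)
  expect_equal(d2@tD, d1@tD, tolerance = 1e-8)
  expect_equal(d2@deltaCp, 3 * d1@deltaCp, tolerance = 1e-8)
})
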