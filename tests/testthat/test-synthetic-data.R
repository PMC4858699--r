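test_that("noise-free MSF curves are exactly piecewise linear", {
  spec <- SyntheticSpec(tGrid = seq(100, 210, 10), tD = NA, noiseRel = 0)
  s <- makeMsfCurve(spec)
  tg <- s@temperatures
  expected <- 0.01 + 5e-4 * pmin(tg, 160) + 1e-3 * pmax(0, tg - 160)
  expect_equal(s@values, expected, tolerance = 1e-12)

  # below tLow the curve is independent of the upper slope
  spec2 <- SyntheticSpec(tGrid = seq(100, 210, 10), tD = NA, noiseRel = 0,
                         slopeHarm2 = 5e-3)
  s2 <- makeMsfCurve(spec2)
  low <- tg <= 160
  expect_equal(s2@values[low], s@values[low], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s2@values[!low], s@values[!low])))
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- SyntheticSpec(seed = 17)
  expect_equal(makeMsfCurve(spec)@values, makeMsfCurve(spec)@values)
  expect_false(isTRUE(all.equal(makeMsfCurve(SyntheticSpec(seed = 18))@values,
                                makeMsfCurve(spec)@values)))
  cfgA <- makePowderConfig(nProteins = 2, nWaters = 25, seed = 4)
  cfgB <- makePowderConfig(nProteins = 2, nWaters = 25, seed = 4)
  expect_identical(cfgA@waters, cfgB@waters)
  trA <- makeTrajectory(syntheticTopology(), 0.1, 5, seed = 6)
  trB <- makeTrajectory(syntheticTopology(), 0.1, 5, seed = 6)
  expect_identical(trA@coords, trB@coords)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); r1 <- runif(1)
  set.seed(1); invisible(makeMsfCurve(spec)); r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("noise-free enthalpy curves give exact transition recovery", {
  h <- makeEnthalpyCurve(223, cpLow = 1, cpHigh = 1.5, noiseAbs = 0)
  fit <- detectTdEnthalpy(h)
  expect_true(fit@transitionDetected)
  expect_equal(fit@tD, 223, tolerance = 1e-6)
  expect_equal(fit@deltaCp, 0.5, tolerance = 1e-8)

  # equal slopes emulate the dehydrated single-regime system
  flat <- makeEnthalpyCurve(223, cpLow = 1, cpHigh = 1, noiseAbs = 0)
  expect_false(detectTdEnthalpy(flat)@transitionDetected)
})

test_that("delta_Cp estimates are unbiased at the design noise", {
  est <- sapply(1:20, function(s) {
    detectTdEnthalpy(makeEnthalpyCurve(223, 1, 1.5, noiseAbs = 2, seed = s))@deltaCp
  })
  mcSe <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.5), 4 * mcSe + 0.01)
})

test_that("designed per-atom MSF targets are realised by the trajectory generator", {
  top <- syntheticTopology()
  trZero <- makeTrajectory(top, 0, nFrames = 6, rigidMotion = FALSE, seed = 1)
  expect_lt(max(perAtomMSF(computeMSF(trZero, "all", alignSelection = "none"))), 1e-20)

  # two-state atom with alternating occupancy: MSF = p(1-p) d^2 = 1 exactly
  tr2 <- makeTrajectory(top, 0, nFrames = 100, anharmonicAtoms = 5L,
                        jumpDistance = 2, switchProb = 1, rigidMotion = FALSE,
                        seed = 2)
  res2 <- computeMSF(tr2, "all", alignSelection = "none")
  expect_equal(unname(perAtomMSF(res2)[["5"]]), 1.0, tolerance = 1e-10)

  nF <- 4000
  tr3 <- makeTrajectory(top, 0.30, nFrames = nF, rigidMotion = FALSE, seed = 3)
  msf <- ensembleMSF(computeMSF(tr3, "all", alignSelection = "none"))
  expect_equal(msf, 0.30, tolerance = 3 / sqrt(nF))
  expect_error(makeTrajectory(top, 0.1, nFrames = 1), ">= 2")
  expect_error(makeTrajectory(top, -0.1, nFrames = 5), "non-negative")
})

test_that("per-residue datasets encode the hydration-dependent amplitudes", {
  seqv <- strsplit(trpCageSequence(), "")[[1]]
  hyd <- makePerResidueDataset(SyntheticSpec(seed = 1))
  w <- attr(hyd, "amplitudeWeights")
  # hydrated mode: arginine outweighs leucine above T_D
  expect_gt(w[["16"]], w[["2"]])   # R16 vs L2
  expect_gt(w[["16"]], w[["7"]])   # R16 vs L7

  deh <- makePerResidueDataset(SyntheticSpec(seed = 1, hydrationMode = "dehydrated"))
  wd <- attr(deh, "amplitudeWeights")
  inner <- as.character(2:19)
  # dehydrated mode: the hydrophobic L2, W6, L7 sit in the upper half
  expect_true(all(wd[c("2", "6", "7")] > median(wd[inner])))

  # equal explicit amplitudes and no noise give identical curves
  eq <- makePerResidueDataset(SyntheticSpec(noiseRel = 0,
                                            residueAmplitudes = rep(1, 20)))
  for (r in 2:20) expect_equal(eq[[r]]@values, eq[[1]]@values, tolerance = 1e-12)
})

test_that("methyl curves switch from exponential to linear at tLow", {
  spec <- SyntheticSpec(noiseRel = 0)
  s <- makeMethylCurve(spec)
  low <- s@temperatures < 160
  expect_equal(log(s@values[low]),
               log(0.02) + 0.01 * s@temperatures[low], tolerance = 1e-10)
  hi <- !low
  fitHi <- lm(s@values[hi] ~ s@temperatures[hi])
  expect_lt(max(abs(resid(fitHi))), 1e-12)   # exactly linear above tLow
})

test_that("powder configurations respect composition and placement rules", {
  cfg <- makePowderConfig(nProteins = 16, nWaters = 771, seed = 1)
  expect_equal(round(hydrationLevel(cfg), 2), 0.40)
  expect_identical(nrow(cfg@waters), 771L)

  expect_equal(hydrationLevel(makePowderConfig(nProteins = 3, nWaters = 0, seed = 2)), 0)

  # minimum pairwise separation among sites
  w <- as.matrix(cfg@waters[, c("x", "y", "z")])
  sub <- w[sample(nrow(w), 80), ]
  dmin <- min(dist(sub))
  expect_gte(dmin, 1.5)

  expect_error(makePowderConfig(nProteins = 0, nWaters = 500, box = c(8, 8, 8),
                                seed = 3), "box too small")
})

test_that("the full synthetic curve closes the loop with both detectors", {
  # noise-free: recovery within one candidate step across the design grid
  for (tl in c(140, 160, 180)) for (td in c(210, 223, 240, NA)) {
    spec <- SyntheticSpec(tLow = tl, tD = td, noiseRel = 0, seed = 1)
    cu <- makeMsfCurve(spec)
    expect_lte(abs(breakpoint(detectTlow(cu)) - tl), 5)
    onset <- detectTdMsf(cu, detectTlow(cu, fitSpace = "linear"))
    if (is.na(td)) {
      expect_true(is.na(onset))
    } else {
      gridStep <- 10
      firstAbove <- min(cu@temperatures[cu@temperatures > td])
      expect_equal(onset, firstAbove, tolerance = 1e-9)
      expect_lte(abs(onset - td), gridStep)
    }
  }

  # at the 1% design noise the T_low mean over seeds stays on target and the
  # T_D onset lands within one grid step in most seeds
  bps <- sapply(1:20, function(s) {
    breakpoint(detectTlow(makeMsfCurve(SyntheticSpec(tGrid = seq(100, 210, 10),
                                                     tD = NA, seed = s))))
  })
  expect_lte(abs(mean(bps) - 160), 5)

  onsets <- sapply(1:20, function(s) {
    cu <- makeMsfCurve(SyntheticSpec(seed = s))
    detectTdMsf(cu, detectTlow(cu, fitSpace = "linear"))
  })
  expect_gte(mean(!is.na(onsets) & abs(onsets - 223) <= 10), 0.8)
})
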