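test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)

  fit <- kabschAlign(ref, ref)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
  expect_lt(fit$rmsd, 1e-12)

  th <- pi / 2
  R90 <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  mob <- ref %*% t(R90) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  fit <- kabschAlign(mob, ref)
  aligned <- mob %*% t(fit$rotation) + matrix(fit$translation, 10, 3, byrow = TRUE)
  expect_lt(sqrt(mean(rowSums((aligned - ref)^2))), 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  collinear <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschAlign(collinear + 0, collinear + 1), "degenerate")
  expect_error(kabschAlign(ref[1:2, ], ref[1:2, ]), ">= 3 points")
})

test_that("Kabsch fit is optimal against random-rotation search and bio3d", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  mob <- ref %*% t(rot) + matrix(rnorm(30, 0, 0.3), 10, 3) +
    matrix(c(2, 1, -1), 10, 3, byrow = TRUE)

  preRmsd <- sqrt(mean(rowSums((mob - ref)^2)))
  fit <- kabschAlign(mob, ref)
  expect_lte(fit$rmsd, preRmsd)

  # no random proper rotation (optimal translation each time) does better
  cm <- colMeans(mob); cr <- colMeans(ref)
  P <- sweep(mob, 2, cm); Q <- sweep(ref, 2, cr)
  for (i in 1:2000) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    Rq <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1]),
      2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1]),
      2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    rmsdQ <- sqrt(mean(rowSums((P %*% t(Rq) - Q)^2)))
    expect_gte(rmsdQ, fit$rmsd - 1e-9)
  }

  # independent implementation agrees
  flatRef <- as.numeric(t(ref)); flatMob <- as.numeric(t(mob))
  bio <- bio3d::fit.xyz(fixed = flatRef, mobile = flatMob,
                        fixed.inds = 1:30, mobile.inds = 1:30)
  alignedBio <- matrix(bio, 10, 3, byrow = TRUE)
  rmsdBio <- sqrt(mean(rowSums((alignedBio - ref)^2)))
  expect_equal(rmsdBio, fit$rmsd, tolerance = 1e-6)
})

test_that("selections partition atoms as declared", {
  top <- syntheticTopology(nProteins = 2)
  methyl <- selectAtoms(top, "methyl-h")
  expect_setequal(unique(top@atoms$residueIndex[methyl]), c(2L, 4L, 7L))
  expect_length(selectAtoms(top, "heavy & hydrogen"), 0)
  allH <- selectAtoms(top, "hydrogen")
  nonMethyl <- selectAtoms(top, "non-methyl-h")
  expect_setequal(c(methyl, nonMethyl), allH)
  expect_length(intersect(methyl, nonMethyl), 0)
  termini <- selectAtoms(top, "residue(1) | residue(20)")
  expect_setequal(unique(top@atoms$residueIndex[termini]), c(1L, 20L))
  expect_setequal(unique(top@atoms$proteinIndex[selectAtoms(top, "protein(1)")]), 1L)
  expect_error(selectAtoms(top, "sidechain"), "unknown selection token")
})

test_that("MSF is zero for static frames and exact for a two-site atom", {
  top <- syntheticTopology()
  nA <- nrow(top@atoms)

  coords <- array(rep(top@refCoords, each = 6), c(6, nA, 3))
  tr <- trajectoryFromArray(top, coords)
  expect_lt(max(perAtomMSF(computeMSF(tr, "all"))), 1e-20)

  # one hydrogen alternating between x and x+2 Angstrom, alignment on the
  # static heavy atoms: variance of +/-1 about the mean = 1 A^2
  hIdx <- which(!top@atoms$isHeavy)[1]
  coords[c(2, 4, 6), hIdx, 1] <- coords[c(2, 4, 6), hIdx, 1] + 2
  tr <- trajectoryFromArray(top, coords)
  res <- computeMSF(tr, "all", alignSelection = "heavy")
  expect_equal(unname(perAtomMSF(res)[as.character(hIdx)]), 1.0, tolerance = 1e-10)
  others <- setdiff(seq_len(nA), hIdx)
  expect_lt(max(perAtomMSF(res)[as.character(others)]), 1e-18)
})

test_that("superposition removes per-frame rigid motion; MSF is rigid-motion invariant", {
  top <- syntheticTopology(nProteins = 2)
  # internally static frames under random per-protein rigid motion
  tr <- makeTrajectory(top, 0, nFrames = 8, seed = 12)  # rigidMotion default on
  expect_lt(max(perAtomMSF(computeMSF(tr, "all"))), 1e-18)

  # applying one global rigid motion to every frame leaves MSF unchanged
  tr2 <- makeTrajectory(top, 0.2, nFrames = 40, rigidMotion = FALSE, seed = 13)
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shifted <- tr2@coords
  for (f in 1:40) {
    shifted[f, , ] <- tr2@coords[f, , ] %*% t(rot) +
      matrix(c(5, -3, 2), dim(shifted)[2], 3, byrow = TRUE)
  }
  tr3 <- trajectoryFromArray(top, shifted)
  expect_equal(perAtomMSF(computeMSF(tr3)), perAtomMSF(computeMSF(tr2)),
               tolerance = 1e-8)

  # frame-order permutation invariance (frame 1 stays the alignment reference)
  perm <- c(1, sample(2:40))
  tr4 <- trajectoryFromArray(top, tr2@coords[perm, , ])
  expect_equal(ensembleMSF(computeMSF(tr4)), ensembleMSF(computeMSF(tr2)),
               tolerance = 1e-10)
})

test_that("Gaussian displacements converge to MSF = 3 sigma^2 per atom", {
  top <- syntheticTopology()
  nF <- 4000
  tr <- makeTrajectory(top, 0.30, nFrames = nF, rigidMotion = FALSE, seed = 3)
  res <- computeMSF(tr, "all", alignSelection = "none")
  expect_equal(ensembleMSF(res), 0.30, tolerance = 3 / sqrt(nF))
})

test_that("MSF equals the brute-force formula on tiny systems", {
  for (seed in 1:4) {
    set.seed(seed)
    nA <- sample(3:5, 1)
    nF <- sample(4:8, 1)
    top <- toyTopology(nA, seed = seed)
    coords <- array(NA_real_, c(nF, nA, 3))
    for (f in seq_len(nF)) {
      coords[f, , ] <- top@refCoords + matrix(rnorm(nA * 3, 0, 0.4), nA, 3)
    }
    tr <- trajectoryFromArray(top, coords)
    mine <- unname(perAtomMSF(computeMSF(tr, "all", alignSelection = "all")))
    oracle <- bruteForceMSF(tr)
    expect_equal(mine, oracle, tolerance = 1e-8)
  }
})

test_that("mass-averaged aggregates respect their bounds and definitions", {
  top <- syntheticTopology(nProteins = 2)
  tr <- makeTrajectory(top, runif(nrow(top@atoms), 0.05, 0.5), nFrames = 60,
                       rigidMotion = FALSE, seed = 21)
  res <- computeMSF(tr)
  expect_true(all(perAtomMSF(res) >= 0))
  expect_equal(ensembleMSF(res), mean(res@perProtein), tolerance = 1e-12)
  expect_gte(min(res@perProtein), min(perAtomMSF(res)))
  expect_lte(max(res@perProtein), max(perAtomMSF(res)))

  # per-residue = mass-weighted mean of its atoms
  pr <- perResidueMSF(res)
  a <- top@atoms
  sel <- res@atomIndex
  row1 <- pr[pr$proteinIndex == 0 & pr$residueIndex == 5, ]
  atoms5 <- sel[a$proteinIndex[sel] == 0 & a$residueIndex[sel] == 5]
  w <- a$mass[atoms5]
  expect_equal(row1$msf,
               sum(perAtomMSF(res)[as.character(atoms5)] * w) / sum(w),
               tolerance = 1e-10)
})

test_that("block errors follow the sd/sqrt(n) closed form", {
  # one free atom visiting +/- sqrt(b) per block: block MSFs exactly 1..5
  top <- toyTopology(1)
  vals <- sqrt(1:5)
  x <- as.numeric(rbind(vals, -vals))  # 10 frames, pairs per block
  coords <- array(0, c(10, 1, 3))
  coords[, 1, 1] <- x
  tr <- trajectoryFromArray(top, coords)
  be <- blockErrors(tr, "all", alignSelection = "none", nBlocks = 5)
  expect_equal(unname(be$perAtomSe), sqrt(2.5) / sqrt(5), tolerance = 1e-10)
  expect_equal(be$ensembleSe, sqrt(2.5) / sqrt(5), tolerance = 1e-10)

  # identical blocks -> zero error
  coords[, 1, 1] <- rep(c(1, -1), 5)
  be0 <- blockErrors(trajectoryFromArray(top, coords), "all",
                     alignSelection = "none", nBlocks = 5)
  expect_equal(unname(be0$perAtomSe), 0, tolerance = 1e-12)

  # remainder frames are dropped from the tail: 11th frame ignored
  coords11 <- array(0, c(11, 1, 3))
  coords11[, 1, 1] <- c(as.numeric(rbind(vals, -vals)), 99)
  be11 <- blockErrors(trajectoryFromArray(top, coords11), "all",
                      alignSelection = "none", nBlocks = 5)
  expect_equal(unname(be11$perAtomSe), sqrt(2.5) / sqrt(5), tolerance = 1e-10)

  expect_error(blockErrors(tr, "all", nBlocks = 1), ">= 2")
  expect_error(computeMSF(trajectoryFromArray(top, coords[1, , , drop = FALSE]), "all"),
               "at least 2 frames")
})

test_that("block standard errors shrink as 1/sqrt(block count)", {
  top <- toyTopology(1)
  set.seed(31)
  coords <- array(0, c(3200, 1, 3))
  coords[, 1, ] <- rnorm(3200 * 3, 0, 0.5)
  tr <- trajectoryFromArray(top, coords)
  se4 <- blockErrors(tr, "all", alignSelection = "none", nBlocks = 4)$ensembleSe
  se16 <- blockErrors(tr, "all", alignSelection = "none", nBlocks = 16)$ensembleSe
  # ratio ~ sqrt(16/4) = 2 within generous Monte-Carlo slack
  expect_gt(se4 / se16, 1.0)
  expect_lt(se4 / se16, 4.0)
})
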