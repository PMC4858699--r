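# Fixtures are generated in code; nothing is stored on disk.

# Minimal topology of nAtoms independent pseudo-residues (one CA per residue),
# for oracle-scale MSF checks.
toyTopology <- function(nAtoms, seed = 1L) {
  atoms <- data.frame(
    atomId = seq_len(nAtoms), name = "CA", element = "C", mass = 12.011,
    residueIndex = seq_len(nAtoms), residueName = "GLY", proteinIndex = 0L,
    isHeavy = TRUE, isMethylHydrogen = FALSE, bfactor = 0,
    stringsAsFactors = FALSE)
  set.seed(seed)
  ref <- matrix(runif(3 * nAtoms, 0, 10), nAtoms, 3)
  new("Topology", atoms = atoms, nProteins = 1L, sequence = strrep("G", nAtoms),
      waterCount = 0L, ions = data.frame(species = character(0), charge = numeric(0)),
      refCoords = ref, sourceIndices = seq_len(nAtoms),
      sourceAtomCount = as.integer(nAtoms))
}

trajectoryFromArray <- function(topology, coords, box = NULL) {
  new("Trajectory", topology = topology, coords = coords, box = box,
      times = seq_len(dim(coords)[1]) - 1)
}

# Write a Trajectory as concatenated GRO frames (Angstrom -> nm).
writeGroFixture <- function(tr, path, dropAtomsInFrame = NULL) {
  a <- tr@topology@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(dim(tr@coords)[1])) {
    rows <- seq_len(nrow(a))
    if (!is.null(dropAtomsInFrame) && f == dropAtomsInFrame) rows <- rows[-1]
    writeLines(sprintf("synthetic powder frame t= %.3f", tr@times[f]), con)
    writeLines(sprintf("%d", length(rows)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residueIndex[rows], a$residueName[rows], a$name[rows],
                       seq_along(rows),
                       tr@coords[f, rows, 1] / 10, tr@coords[f, rows, 2] / 10,
                       tr@coords[f, rows, 3] / 10), con)
    writeLines("   8.00000   8.00000   8.00000", con)
  }
}

# Independent MSF oracle: align every frame to frame 1 with bio3d::fit.xyz,
# then apply the variance-about-the-mean formula directly.
bruteForceMSF <- function(tr) {
  nF <- dim(tr@coords)[1]
  nA <- dim(tr@coords)[2]
  flat <- t(vapply(seq_len(nF), function(f) as.numeric(t(tr@coords[f, , ])),
                   numeric(3 * nA)))
  fitted <- bio3d::fit.xyz(fixed = flat[1, ], mobile = flat,
                           fixed.inds = seq_len(3 * nA),
                           mobile.inds = seq_len(3 * nA))
  arr <- array(NA_real_, c(nF, nA, 3))
  for (f in seq_len(nF)) arr[f, , ] <- matrix(fitted[f, ], nA, 3, byrow = TRUE)
  mu <- apply(arr, c(2, 3), mean)
  sapply(seq_len(nA), function(i) {
    mean(rowSums((arr[, i, , drop = TRUE] - matrix(mu[i, ], nF, 3, byrow = TRUE))^2))
  })
}

# Independent two-segment enumeration with stats::lm, for the breakpoint
# search oracle.
bruteForceSegmented <- function(x, y, minSeg = 3) {
  n <- length(x)
  cands <- (x[-n] + x[-1]) / 2
  cands <- cands[vapply(cands, function(cc) sum(x < cc) >= minSeg &&
                          sum(x > cc) >= minSeg, logical(1))]
  sse <- vapply(cands, function(cc) {
    lo <- x < cc
    sum(resid(lm(y[lo] ~ x[lo]))^2) + sum(resid(lm(y[!lo] ~ x[!lo]))^2)
  }, numeric(1))
  list(breakpoint = cands[which.min(sse)], sse = min(sse))
}

# Constant-energy function: every removal is energetically neutral.
neutralEnergy <- function(config) 0
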