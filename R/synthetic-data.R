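#' @include dehydration.R
NULL

# Per-residue side-chain atom templates (name, element). Backbone atoms are
# shared; methyl-bearing residues carry their full methyl groups so that
# selections by methyl/non-methyl hydrogens behave as in a real topology.
# This is a synthetic reduced topology, not a crystallographic structure.
.sideChainTemplate <- function(one) {
  t3 <- function(...) {
    v <- c(...)
    if (!length(v)) {
      return(data.frame(name = character(0), element = character(0),
                        stringsAsFactors = FALSE))
    }
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    data.frame(name = m[, 1L], element = m[, 2L], stringsAsFactors = FALSE)
  }
  switch(one,
    G = t3(),
    A = t3("CB", "C", "HB1", "H", "HB2", "H", "HB3", "H"),
    V = t3("CB", "C", "HB", "H",
           "CG1", "C", "HG11", "H", "HG12", "H", "HG13", "H",
           "CG2", "C", "HG21", "H", "HG22", "H", "HG23", "H"),
    L = t3("CB", "C", "HB1", "H", "HB2", "H", "CG", "C", "HG", "H",
           "CD1", "C", "HD11", "H", "HD12", "H", "HD13", "H",
           "CD2", "C", "HD21", "H", "HD22", "H", "HD23", "H"),
    I = t3("CB", "C", "HB", "H",
           "CG1", "C", "HG12", "H", "HG13", "H",
           "CG2", "C", "HG21", "H", "HG22", "H", "HG23", "H",
           "CD1", "C", "HD11", "H", "HD12", "H", "HD13", "H"),
    M = t3("CB", "C", "HB1", "H", "HB2", "H", "CG", "C", "HG1", "H", "HG2", "H",
           "SD", "S", "CE", "C", "HE1", "H", "HE2", "H", "HE3", "H"),
    T = t3("CB", "C", "HB", "H", "OG1", "O", "HG1", "H",
           "CG2", "C", "HG21", "H", "HG22", "H", "HG23", "H"),
    # all other residues: a reduced side chain
    t3("CB", "C", "HB1", "H", "HB2", "H")
  )
}

#' Synthetic reduced topology of a protein powder
#'
#' Builds a [Topology-class] programmatically from per-residue atom-name
#' templates: full backbone (N, H, CA, HA, C, O) plus reduced side chains,
#' with complete methyl groups (carbon + three hydrogens) for Ala, Ile, Leu,
#' Met, Thr and Val so that methyl-hydrogen selections behave as on a real
#' structure. Coordinates are deterministic, non-degenerate placeholders
#' (an extended pseudo-chain; protein units on a 20 Angstrom grid). Intended
#' as the fixture-free stand-in for a crystallographic topology.
#'
#' @param sequence one-letter sequence (default the Trp-cage sequence).
#' @param nProteins number of identical protein units (default 1).
#' @param nWaters water count recorded in the topology (default 0).
#' @return a [Topology-class].
#' @export
syntheticTopology <- function(sequence = trpCageSequence(), nProteins = 1L,
                              nWaters = 0L) {
  res <- .checkStandardSequence(sequence)
  three <- attr(residueMasses(), "three")
  rawList <- list(); coordList <- list()
  for (k in seq_len(nProteins) - 1L) {
    origin <- c(20 * (k %% 4L), 20 * (k %/% 4L), 0)
    for (r in seq_along(res)) {
      one <- res[r]
      backbone <- data.frame(
        name = c("N", "H", "CA", "HA", "C", "O"),
        element = c("N", "H", "C", "H", "C", "O"), stringsAsFactors = FALSE)
      if (one == "P") backbone <- backbone[backbone$name != "H", ]
      atoms <- rbind(backbone, .sideChainTemplate(one))
      i <- seq_len(nrow(atoms))
      xyz <- cbind(3.8 * r + 0.9 * ((i * 7) %% 5) / 5,
                   origin[2L] + 1.7 * ((i * 3) %% 7) / 7 + 0.1 * r,
                   origin[3L] + 1.3 * ((i * 5) %% 11) / 11)
      xyz[, 1L] <- xyz[, 1L] + origin[1L]
      rawList[[length(rawList) + 1L]] <- data.frame(
        name = atoms$name, resname = unname(three[one]), resid = r,
        chain = .chainLetter(k), bfactor = 0, stringsAsFactors = FALSE)
      coordList[[length(coordList) + 1L]] <- xyz
    }
  }
  top <- .buildTopology(do.call(rbind, rawList), do.call(rbind, coordList))
  top@waterCount <- as.integer(nWaters)
  top
}

# ---- temperature-series generators ----------------------------------------

.msfBase <- function(spec, tGrid = spec@tGrid, anharmScale = 1) {
  base <- spec@intercept + spec@slopeHarm1 * pmin(tGrid, spec@tLow) +
    spec@slopeHarm2 * pmax(0, tGrid - spec@tLow)
  if (!is.na(spec@tD)) {
    base <- base + anharmScale * spec@anharmCoeff * pmax(0, tGrid - spec@tD)^2
  }
  base
}

#' Generate a synthetic average-MSF curve
#'
#' Piecewise-linear harmonic MSF(T) with a slope change at tLow, plus a
#' quadratic anharmonic excess above tD (when present), with multiplicative
#' Gaussian noise: value = base(T) * (1 + eps), eps ~ N(0, noiseRel). The
#' reported errors are noiseRel * base(T).
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [TemperatureSeries-class].
#' @examples
#' s <- makeMsfCurve(SyntheticSpec(seed = 7))
#' detectTlow(s)
#' @export
makeMsfCurve <- function(spec) {
  base <- .msfBase(spec)
  eps <- withSeed(spec@seed, stats::rnorm(length(base), 0, spec@noiseRel))
  TemperatureSeries(spec@tGrid, base * (1 + eps), spec@noiseRel * base,
                    label = "average MSF (synthetic)")
}

#' Generate a synthetic bilinear enthalpy curve
#'
#' Continuous bilinear enthalpy vs temperature hinged at tD with slopes
#' cpLow below and cpHigh above (the heat-capacity jump), plus additive
#' Gaussian noise. With cpHigh = cpLow the curve is a single line, emulating
#' a dehydrated powder with no dynamical transition.
#'
#' @param tD hinge temperature, K (ignored when cpHigh == cpLow).
#' @param cpLow,cpHigh segment slopes, kJ/mol/K.
#' @param noiseAbs additive Gaussian sd, kJ/mol.
#' @param tGrid temperature grid, K.
#' @param seed RNG seed.
#' @param h0 enthalpy at the first grid temperature, kJ/mol.
#' @return a [TemperatureSeries-class].
#' @export
makeEnthalpyCurve <- function(tD, cpLow, cpHigh, noiseAbs = 0,
                              tGrid = seq(100, 300, by = 10), seed = 1L,
                              h0 = 0) {
  base <- h0 + cpLow * (tGrid - tGrid[1L]) + (cpHigh - cpLow) * pmax(0, tGrid - tD)
  eps <- withSeed(seed, stats::rnorm(length(base), 0, noiseAbs))
  TemperatureSeries(tGrid, base + eps, rep(noiseAbs, length(base)),
                    label = "enthalpy (synthetic)")
}

#' Generate a synthetic methyl-hydrogen MSF curve
#'
#' Exponential growth below tLow (value = methylAmp * exp(methylRate * T)),
#' continued above tLow by a value- and slope-matched straight line, with
#' multiplicative Gaussian noise; the two regimes of methyl rotor dynamics.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a [TemperatureSeries-class].
#' @export
makeMethylCurve <- function(spec) {
  tg <- spec@tGrid
  vLow <- spec@methylAmp * exp(spec@methylRate * tg)
  vAt <- spec@methylAmp * exp(spec@methylRate * spec@tLow)
  slope <- spec@methylRate * vAt
  base <- ifelse(tg < spec@tLow, vLow, vAt + slope * (tg - spec@tLow))
  eps <- withSeed(spec@seed, stats::rnorm(length(base), 0, spec@noiseRel))
  TemperatureSeries(tg, base * (1 + eps), spec@noiseRel * base,
                    label = "methyl-H MSF (synthetic)")
}

#' Generate per-residue synthetic MSF datasets
#'
#' One MSF(T) curve per residue, all sharing the spec's transition
#' temperatures, with the anharmonic amplitude scaled per residue: in
#' "hydrated" mode hydrophilic residues get the larger amplitudes above tD,
#' in "dehydrated" mode hydrophobic residues do (rank-based weights in
#' [0.5, 1.5]); the terminal residues receive a fixed amplitude bonus (+0.5)
#' reflecting their weaker bonding restraints. Explicit
#' \code{residueAmplitudes} in the spec override the rank-derived weights.
#'
#' @param spec a [SyntheticSpec-class].
#' @param hydropathy a [HydropathyTable-class].
#' @param sequence one-letter sequence.
#' @return named list (residue index as name) of [TemperatureSeries-class];
#'   the weight used for each residue is attached as attribute
#'   \code{"amplitudeWeights"} on the list.
#' @export
makePerResidueDataset <- function(spec, hydropathy = eisenbergHydropathy(),
                                  sequence = trpCageSequence()) {
  res <- .checkStandardSequence(sequence)
  L <- length(res)
  if (length(spec@residueAmplitudes) == L) {
    w <- spec@residueAmplitudes
  } else {
    hv <- hydropathy@values[res]
    rk <- if (spec@hydrationMode == "hydrated") rank(-hv, ties.method = "first")
          else rank(hv, ties.method = "first")
    w <- 0.5 + (rk - 1) / (L - 1)
    w[c(1L, L)] <- w[c(1L, L)] + 0.5
  }
  out <- withSeed(spec@seed, {
    lapply(seq_len(L), function(r) {
      base <- .msfBase(spec, anharmScale = w[r])
      eps <- stats::rnorm(length(base), 0, spec@noiseRel)
      TemperatureSeries(spec@tGrid, base * (1 + eps), spec@noiseRel * base,
                        label = sprintf("residue %d (%s)", r, res[r]))
    })
  })
  names(out) <- seq_len(L)
  attr(out, "amplitudeWeights") <- stats::setNames(w, seq_len(L))
  out
}

# ---- trajectory generator --------------------------------------------------

#' Generate a synthetic trajectory with designed per-atom MSF
#'
#' Builds frames as reference coordinates plus i.i.d. Gaussian displacements
#' with per-axis variance target/3, so the designed MSF of each atom is met
#' in the large-frame limit. Selected atoms can additionally hop between two
#' sites +/- d/2 along a fixed random axis via a two-state Markov chain
#' (switch probability q per frame), contributing the occupancy variance
#' p(1-p) d^2 to their MSF. Optionally each protein unit receives a random
#' rigid rotation and translation per frame, which the MSF engine's
#' superposition must remove.
#'
#' @param topology a [Topology-class].
#' @param perAtomMsf designed MSF targets, Angstrom^2: scalar or one value
#'   per atom.
#' @param nFrames number of frames (>= 2).
#' @param anharmonicAtoms integer atom indices that hop between two sites.
#' @param jumpDistance site separation d, Angstrom (default 2).
#' @param switchProb per-frame switch probability q (default 0.1; q = 1
#'   alternates deterministically, giving exactly equal occupancy for even
#'   frame counts).
#' @param rigidMotion apply a random whole-protein rigid motion per frame
#'   (default TRUE; the MSF superposition must remove it).
#' @param seed RNG seed.
#' @return a [Trajectory-class] (no periodic box).
#' @export
makeTrajectory <- function(topology, perAtomMsf, nFrames,
                           anharmonicAtoms = integer(0), jumpDistance = 2,
                           switchProb = 0.1, rigidMotion = TRUE, seed = 1L) {
  if (nFrames < 2L) .stopf("nFrames must be >= 2")
  nA <- nrow(topology@atoms)
  targets <- rep_len(as.numeric(perAtomMsf), nA)
  if (any(targets < 0)) .stopf("MSF targets must be non-negative")
  ref <- topology@refCoords
  coords <- withSeed(seed, {
    arr <- array(0, dim = c(nFrames, nA, 3L))
    sdAxis <- sqrt(targets / 3)
    for (i in seq_len(nA)) {
      arr[, i, ] <- matrix(stats::rnorm(3L * nFrames, 0, sdAxis[i]), nFrames, 3L)
      arr[, i, ] <- sweep(arr[, i, , drop = TRUE], 2L, ref[i, ], "+")
    }
    for (i in anharmonicAtoms) {
      axis <- stats::rnorm(3L); axis <- axis / sqrt(sum(axis^2))
      state <- integer(nFrames); state[1L] <- 1L
      flips <- stats::runif(nFrames - 1L) < switchProb
      for (f in 2L:nFrames) state[f] <- if (flips[f - 1L]) -state[f - 1L] else state[f - 1L]
      arr[, i, ] <- arr[, i, ] + outer(state * jumpDistance / 2, axis)
    }
    if (rigidMotion) {
      for (f in seq_len(nFrames)) {
        for (k in unique(topology@atoms$proteinIndex)) {
          rows <- which(topology@atoms$proteinIndex == k)
          rot <- randomRotation()
          trans <- stats::runif(3L, -5, 5)
          ctr <- colMeans(ref[rows, , drop = FALSE])
          arr[f, rows, ] <- sweep(sweep(arr[f, rows, , drop = TRUE], 2L, ctr) %*% t(rot),
                                  2L, ctr + trans, "+")
        }
      }
    }
    arr
  })
  new("Trajectory", topology = topology, coords = coords, box = NULL,
      times = seq_len(nFrames) - 1)
}

# ---- powder configuration generator ----------------------------------------

#' Generate a toy powder configuration
#'
#' Rigid dummy-site protein clusters on a grid and randomly placed,
#' non-overlapping single-site waters, each tagged with a binding class
#' ("weak" or "strong") drawn with the given strong-water fraction and the
#' corresponding binding energy. Deterministic under the seed. Used as the
#' fixture generator for the dehydration protocol.
#'
#' @param nProteins number of protein units.
#' @param nWaters number of waters.
#' @param boundFraction fraction of strongly bound waters (default 0.5).
#' @param bindingEnergyLevels kJ/mol, named c(weak=, strong=)
#'   (default 1 and 20).
#' @param box orthorhombic box lengths, Angstrom (default 80^3).
#' @param temperature K for beta (default 300).
#' @param seed RNG seed.
#' @param sequence protein sequence for mass bookkeeping (default Trp-cage).
#' @return a [PowderConfig-class].
#' @export
makePowderConfig <- function(nProteins = 16L, nWaters = 771L,
                             boundFraction = 0.5,
                             bindingEnergyLevels = c(weak = 1, strong = 20),
                             box = c(80, 80, 80), temperature = 300,
                             seed = 1L, sequence = trpCageSequence()) {
  if (nProteins < 0 || nWaters < 0) .stopf("counts must be non-negative")
  withSeed(seed, {
    sites <- list()
    for (k in seq_len(nProteins) - 1L) {
      ctr <- c(10 + 18 * (k %% 4L), 10 + 18 * ((k %/% 4L) %% 4L), 10 + 18 * (k %/% 16L))
      offs <- matrix(c(0, 0, 0, 2, 0, 0, 0, 2, 0, 0, 0, 2,
                       -2, 0, 0, 0, -2, 0, 0, 0, -2, 1.5, 1.5, 1.5),
                     ncol = 3L, byrow = TRUE)
      sites[[k + 1L]] <- data.frame(proteinIndex = k,
                                    x = ctr[1L] + offs[, 1L],
                                    y = ctr[2L] + offs[, 2L],
                                    z = ctr[3L] + offs[, 3L],
                                    charge = 0, eps = 0.5, sigma = 3.5)
    }
    proteinSites <- if (nProteins > 0L) do.call(rbind, sites)
                    else data.frame(proteinIndex = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    charge = numeric(0), eps = numeric(0),
                                    sigma = numeric(0))
    placed <- matrix(NA_real_, nWaters, 3L)
    existing <- as.matrix(proteinSites[, c("x", "y", "z")])
    tries <- 0L
    maxTries <- 1000L * max(nWaters, 1L)
    n <- 0L
    while (n < nWaters) {
      tries <- tries + 1L
      if (tries > maxTries) .stopf("box too small for non-overlapping water placement")
      cand <- stats::runif(3L) * box
      all_ <- rbind(existing, placed[seq_len(n), , drop = FALSE])
      if (nrow(all_) == 0L ||
          min(sqrt(rowSums(sweep(all_, 2L, cand)^2))) >= 1.5) {
        n <- n + 1L
        placed[n, ] <- cand
      }
    }
    if (nWaters == 0L) {
      waters <- data.frame(waterId = integer(0), x = numeric(0), y = numeric(0),
                           z = numeric(0), charge = numeric(0), eps = numeric(0),
                           sigma = numeric(0), bindingClass = character(0),
                           bindingEnergy = numeric(0))
    } else {
      cls <- ifelse(stats::runif(nWaters) < boundFraction, "strong", "weak")
      waters <- data.frame(waterId = seq_len(nWaters),
                           x = placed[, 1L], y = placed[, 2L], z = placed[, 3L],
                           charge = 0, eps = 0.65, sigma = 3.166,
                           bindingClass = cls,
                           bindingEnergy = unname(bindingEnergyLevels[cls]))
    }
    new("PowderConfig",
        proteinSites = proteinSites, waters = waters,
        ions = data.frame(species = character(0), charge = numeric(0),
                          x = numeric(0), y = numeric(0), z = numeric(0)),
        sequence = sequence, nProteins = as.integer(nProteins),
        box = as.numeric(box), beta = inverseBeta(temperature),
        rngSeed = as.integer(seed))
  })
}
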