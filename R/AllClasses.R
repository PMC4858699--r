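#' @include utils.R
NULL

#' Topology of a protein powder system
#'
#' Holds the protein atoms of a powder system (waters and ions are counted but
#' never analysed), with per-atom element, mass, residue and protein-unit
#' assignment, and flags for heavy atoms and methyl-group hydrogens. Reference
#' coordinates (the frame the topology was built from, in Angstrom) are kept so
#' that annotated structures can be written back out.
#'
#' @slot atoms data.frame with columns \code{atomId}, \code{name},
#'   \code{element}, \code{mass} (Da), \code{residueIndex} (1-based within each
#'   protein), \code{residueName} (3-letter), \code{proteinIndex} (0-based
#'   powder unit), \code{isHeavy}, \code{isMethylHydrogen}, \code{bfactor}.
#' @slot nProteins integer number of protein units.
#' @slot sequence one-letter sequence shared by all protein units.
#' @slot waterCount integer number of water molecules in the source system.
#' @slot ions data.frame with columns \code{species}, \code{charge}.
#' @slot refCoords numeric matrix (nAtoms x 3), Angstrom.
#' @slot sourceIndices integer positions of the protein atoms within the source
#'   file's full atom list (used to subset trajectory frames).
#' @slot sourceAtomCount total atom count of the source file, waters included.
#'
#' @seealso [readTopology()], [selectAtoms()], [computeMSF()]
#' @export
setClass("Topology", representation(
  atoms = "data.frame",
  nProteins = "integer",
  sequence = "character",
  waterCount = "integer",
  ions = "data.frame",
  refCoords = "matrix",
  sourceIndices = "integer",
  sourceAtomCount = "integer"
))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("atomId", "name", "element", "mass", "residueIndex", "residueName",
            "proteinIndex", "isHeavy", "isMethylHydrogen")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (any(a$mass <= 0)) return("all atomic masses must be positive")
  if (any((a$element == "H") == a$isHeavy)) {
    return("isHeavy must be TRUE exactly for non-hydrogen elements")
  }
  if (any(a$isMethylHydrogen & a$element != "H")) {
    return("isMethylHydrogen implies element H")
  }
  for (k in unique(a$proteinIndex)) {
    ri <- a$residueIndex[a$proteinIndex == k]
    if (!all(sort(unique(ri)) == seq_len(max(ri)))) {
      return(sprintf("residue indices of protein unit %d are not contiguous 1..L", k))
    }
  }
  if (nrow(a) > 0 && is.unsorted(a$proteinIndex)) {
    return("atom order must group by protein unit")
  }
  if (nrow(object@refCoords) != nrow(a) || ncol(object@refCoords) != 3L) {
    return("refCoords must be nAtoms x 3")
  }
  TRUE
})

#' Multi-frame coordinate trajectory
#'
#' Coordinates of the protein atoms of a [Topology-class] over N_F frames, in
#' Angstrom, with optional per-frame orthorhombic box lengths and frame times.
#'
#' @slot topology the [Topology-class].
#' @slot coords numeric array, nFrames x nAtoms x 3, Angstrom.
#' @slot box per-frame orthorhombic box lengths (nFrames x 3 matrix, Angstrom)
#'   or NULL when no periodic box applies.
#' @slot times frame times in ps (frame index when the source has no times).
#' @export
setClass("Trajectory", representation(
  topology = "Topology",
  coords = "array",
  box = "ANY",
  times = "numeric"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[3L] != 3L) return("coords must be nFrames x nAtoms x 3")
  if (d[2L] != nrow(object@topology@atoms)) {
    return("atom count of coords does not match the topology")
  }
  if (length(object@times) != d[1L]) return("times must have one entry per frame")
  if (!is.null(object@box)) {
    b <- object@box
    if (!is.matrix(b) || nrow(b) != d[1L] || ncol(b) != 3L) {
      return("box must be NULL or an nFrames x 3 matrix")
    }
  }
  TRUE
})

#' Mean-square fluctuation result
#'
#' MSF of a selection at every aggregation level: per atom, per residue
#' (mass-averaged within each residue), per protein unit (mass-averaged over
#' the selection), and the ensemble value (unweighted mean over protein
#' units), together with block-averaged standard errors where computed.
#' All values in Angstrom^2.
#'
#' @slot perAtom named numeric, MSF per selected atom (names = atomId).
#' @slot atomIndex integer indices of the selected atoms in the topology.
#' @slot perResidue data.frame: \code{proteinIndex}, \code{residueIndex},
#'   \code{residueName}, \code{msf}, \code{se}.
#' @slot perProtein,perProteinSe numeric per protein unit.
#' @slot ensemble,ensembleSe numeric scalars.
#' @slot perAtomSe named numeric (NA when blocks were not requested).
#' @slot selectionLabel selection expression the result was computed for.
#' @slot nFrames,nBlocks integers.
#' @export
setClass("MSFResult", representation(
  perAtom = "numeric",
  perAtomSe = "numeric",
  atomIndex = "integer",
  perResidue = "data.frame",
  perProtein = "numeric",
  perProteinSe = "numeric",
  ensemble = "numeric",
  ensembleSe = "numeric",
  selectionLabel = "character",
  nFrames = "integer",
  nBlocks = "integer"
))

setValidity("MSFResult", function(object) {
  if (any(object@perAtom < -1e-12)) return("MSF values must be non-negative")
  if (length(object@perProtein) > 0 &&
      abs(object@ensemble - mean(object@perProtein)) >
        1e-8 * max(1, abs(object@ensemble))) {
    return("ensemble MSF must equal the mean of the per-protein values")
  }
  TRUE
})

#' Temperature series
#'
#' A (temperature, value, error) series: MSF (Angstrom^2) or enthalpy (kJ/mol)
#' against temperature (K). Temperatures are strictly increasing.
#'
#' @slot temperatures K, strictly increasing.
#' @slot values series values.
#' @slot errors non-negative errors, same units as values.
#' @slot label free-text description.
#' @export
setClass("TemperatureSeries", representation(
  temperatures = "numeric",
  values = "numeric",
  errors = "numeric",
  label = "character"
))

setValidity("TemperatureSeries", function(object) {
  n <- length(object@temperatures)
  if (length(object@values) != n || length(object@errors) != n) {
    return("temperatures, values and errors must have equal length")
  }
  if (n > 1 && any(diff(object@temperatures) <= 0)) {
    return("temperatures must be strictly increasing (no duplicates)")
  }
  if (any(object@errors < 0)) return("errors must be non-negative")
  TRUE
})

#' Two-segment linear fit of a temperature series
#'
#' Result of the exhaustive breakpoint search: two independent OLS lines in
#' \code{fitSpace} ("linear" or "log") split at the breakpoint, with the
#' total SSE, the single-line SSE and a scan-adjusted two-regime p-value.
#'
#' @slot breakpoint K; midpoint candidate minimising the total SSE.
#' @slot slopeLow,interceptLow,slopeHigh,interceptHigh segment lines (fit space).
#' @slot sse,sseSingle fit-space sums of squared residuals.
#' @slot pTwoRegime p of the two-line vs single-line F test, Bonferroni-adjusted
#'   for the number of breakpoint candidates scanned.
#' @slot fitSpace "linear" or "log".
#' @slot residSigmaLow,residSigmaHigh residual standard deviations per segment.
#' @slot range temperature range of the fitted data (K).
#' @slot nCandidates number of breakpoint candidates scanned.
#' @export
setClass("SegmentedFit", representation(
  breakpoint = "numeric",
  slopeLow = "numeric", interceptLow = "numeric",
  slopeHigh = "numeric", interceptHigh = "numeric",
  sse = "numeric", sseSingle = "numeric",
  pTwoRegime = "numeric",
  fitSpace = "character",
  residSigmaLow = "numeric", residSigmaHigh = "numeric",
  range = "numeric",
  nCandidates = "integer"
))

setValidity("SegmentedFit", function(object) {
  if (object@breakpoint <= object@range[1L] || object@breakpoint >= object@range[2L]) {
    return("breakpoint must lie strictly inside the fitted temperature range")
  }
  if (object@sse > object@sseSingle + 1e-8 * max(1, object@sseSingle)) {
    return("two-segment SSE cannot exceed the single-line SSE")
  }
  if (!object@fitSpace %in% c("linear", "log")) {
    return('fitSpace must be "linear" or "log"')
  }
  TRUE
})

#' Bilinear enthalpy fit
#'
#' The two free enthalpy fit lines and their intersection T_D, the segment
#' slopes (heat capacities) and the heat-capacity jump delta_Cp, plus the
#' detection decision. When no transition is detected T_D and delta_Cp are NA
#' and the single-line slope is reported in \code{cpLow}.
#'
#' @slot tD K (NA when not detected).
#' @slot cpLow,cpHigh segment slopes in the input's value units per K.
#' @slot deltaCp cpHigh - cpLow (NA when not detected).
#' @slot transitionDetected logical.
#' @slot pTwoRegime scan-adjusted two-regime p-value.
#' @slot diagnostic "ok", "single-regime", "parallel-lines" or
#'   "intersection-outside-range".
#' @export
setClass("EnthalpyFit", representation(
  tD = "numeric",
  cpLow = "numeric", cpHigh = "numeric", deltaCp = "numeric",
  transitionDetected = "logical",
  pTwoRegime = "numeric",
  diagnostic = "character"
))

setValidity("EnthalpyFit", function(object) {
  if (object@transitionDetected && (is.na(object@tD) || !is.finite(object@deltaCp))) {
    return("a detected transition requires finite tD and deltaCp")
  }
  if (!object@transitionDetected && !is.na(object@tD)) {
    return("tD must be NA when no transition is detected")
  }
  TRUE
})

#' Hydropathy scale
#'
#' Per-residue hydropathy values (one-letter codes) with the threshold used to
#' classify residues as hydrophobic (value > threshold) or hydrophilic.
#'
#' @slot values named numeric covering the 20 standard residues.
#' @slot threshold classification threshold (default 0).
#' @slot name scale name.
#' @export
setClass("HydropathyTable", representation(
  values = "numeric",
  threshold = "numeric",
  name = "character"
))

setValidity("HydropathyTable", function(object) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  if (!all(std %in% names(object@values))) {
    return("hydropathy table must cover all 20 standard residues")
  }
  TRUE
})

#' Powder configuration for the dehydration protocol
#'
#' Rigid protein site clusters, removable waters and ions, with the inverse
#' temperature beta used by the Metropolis water-removal criterion. Sites
#' carry point charges (e) and Lennard-Jones parameters (epsilon kJ/mol,
#' sigma Angstrom) for the toy interaction energy.
#'
#' @slot proteinSites data.frame: \code{proteinIndex}, \code{x,y,z},
#'   \code{charge}, \code{eps}, \code{sigma}.
#' @slot waters data.frame: \code{waterId}, \code{x,y,z}, \code{charge},
#'   \code{eps}, \code{sigma}, \code{bindingClass}, \code{bindingEnergy}
#'   (kJ/mol, magnitude of the binding of that water).
#' @slot ions data.frame: \code{species}, \code{charge}, \code{x,y,z}.
#' @slot sequence one-letter protein sequence (per unit), for mass bookkeeping.
#' @slot nProteins integer.
#' @slot box orthorhombic box lengths, Angstrom.
#' @slot beta inverse thermal energy, mol/kJ.
#' @slot rngSeed integer seed for the removal protocol.
#' @export
setClass("PowderConfig", representation(
  proteinSites = "data.frame",
  waters = "data.frame",
  ions = "data.frame",
  sequence = "character",
  nProteins = "integer",
  box = "numeric",
  beta = "numeric",
  rngSeed = "integer"
))

setValidity("PowderConfig", function(object) {
  if (object@beta <= 0) return("beta must be positive")
  if (object@nProteins < 0) return("nProteins must be non-negative")
  TRUE
})

#' Specification for synthetic temperature-series and trajectory generators
#'
#' Encodes the functional forms the generators emulate: a piecewise-linear
#' harmonic MSF(T) whose slope changes at \code{tLow}, a quadratic anharmonic
#' excess switched on above \code{tD} (absent when \code{tD} is NA), an
#' exponential methyl-hydrogen branch below \code{tLow}, multiplicative
#' Gaussian noise, and per-residue amplitude scaling.
#'
#' @slot tGrid temperature grid, K.
#' @slot tLow,tD K (tD = NA means no dynamical transition).
#' @slot slopeHarm1,slopeHarm2 harmonic slopes below/above tLow, Angstrom^2/K;
#'   slopeHarm2 > slopeHarm1 > 0.
#' @slot intercept Angstrom^2.
#' @slot anharmCoeff Angstrom^2/K^2, quadratic excess above tD.
#' @slot methylAmp,methylRate methyl branch value = methylAmp * exp(methylRate*T).
#' @slot noiseRel relative noise level (sd of the multiplicative Gaussian).
#' @slot seed integer RNG seed.
#' @slot hydrationMode "hydrated" or "dehydrated" (controls which residue class
#'   gets the larger anharmonic amplitudes).
#' @slot residueAmplitudes optional per-residue scale factors (empty = derive
#'   from hydropathy ranks).
#' @export
setClass("SyntheticSpec", representation(
  tGrid = "numeric",
  tLow = "numeric", tD = "numeric",
  slopeHarm1 = "numeric", slopeHarm2 = "numeric",
  intercept = "numeric", anharmCoeff = "numeric",
  methylAmp = "numeric", methylRate = "numeric",
  noiseRel = "numeric",
  seed = "integer",
  hydrationMode = "character",
  residueAmplitudes = "numeric"
))

setValidity("SyntheticSpec", function(object) {
  if (!is.na(object@tD) && object@tLow >= object@tD) return("tLow must be below tD")
  if (!(object@slopeHarm2 > object@slopeHarm1 && object@slopeHarm1 > 0)) {
    return("harmonic slopes must satisfy slopeHarm2 > slopeHarm1 > 0")
  }
  if (object@noiseRel < 0) return("noiseRel must be non-negative")
  if (!object@hydrationMode %in% c("hydrated", "dehydrated")) {
    return('hydrationMode must be "hydrated" or "dehydrated"')
  }
  TRUE
})
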