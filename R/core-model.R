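#' @include tables.R
NULL

# ---- constructors ----------------------------------------------------------

#' Construct a temperature series
#'
#' @param temperatures K, strictly increasing.
#' @param values series values (Angstrom^2 for MSF, kJ/mol for enthalpy).
#' @param errors non-negative errors; default 0.
#' @param label description string.
#' @return a [TemperatureSeries-class].
#' @export
TemperatureSeries <- function(temperatures, values,
                              errors = rep(0, length(values)), label = "") {
  new("TemperatureSeries",
      temperatures = as.numeric(temperatures), values = as.numeric(values),
      errors = as.numeric(errors), label = label)
}

#' Construct a synthetic-data specification
#'
#' Defaults encode the study conditions the generators emulate: a 100--300 K
#' grid at 10 K spacing, the harmonic slope change at 160 K with a slope ratio
#' of two, the dynamical transition at 223 K, and 1\% relative noise (error
#' bars comparable to plot symbol sizes). See the package vignette for the
#' rationale behind each default.
#'
#' @param tGrid temperature grid (K).
#' @param tLow lower transition (K).
#' @param tD dynamical transition (K); NA for systems with no transition.
#' @param slopeHarm1,slopeHarm2 harmonic slopes (Angstrom^2/K) below/above tLow.
#' @param intercept Angstrom^2.
#' @param anharmCoeff quadratic anharmonic coefficient (Angstrom^2/K^2).
#' @param methylAmp,methylRate methyl-hydrogen branch value
#'   = methylAmp * exp(methylRate * T).
#' @param noiseRel relative noise (sd of multiplicative Gaussian).
#' @param seed RNG seed.
#' @param hydrationMode "hydrated" or "dehydrated".
#' @param residueAmplitudes optional per-residue scale factors.
#' @return a [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(tGrid = seq(100, 300, by = 10),
                          tLow = 160, tD = 223,
                          slopeHarm1 = 5e-4, slopeHarm2 = 1e-3,
                          intercept = 0.01, anharmCoeff = 3e-4,
                          methylAmp = 0.02, methylRate = 0.01,
                          noiseRel = 0.01, seed = 1L,
                          hydrationMode = "hydrated",
                          residueAmplitudes = numeric(0)) {
  new("SyntheticSpec",
      tGrid = as.numeric(tGrid), tLow = as.numeric(tLow), tD = as.numeric(tD),
      slopeHarm1 = slopeHarm1, slopeHarm2 = slopeHarm2,
      intercept = intercept, anharmCoeff = anharmCoeff,
      methylAmp = methylAmp, methylRate = methylRate,
      noiseRel = noiseRel, seed = as.integer(seed),
      hydrationMode = hydrationMode,
      residueAmplitudes = as.numeric(residueAmplitudes))
}

# ---- residue-level operations ---------------------------------------------

.checkStandardSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    .stopf("sequence must be a non-empty one-letter character string")
  }
  res <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(res, names(residueMasses()))
  if (length(bad)) {
    .stopf("non-standard residue code(s): %s", paste(unique(bad), collapse = ", "))
  }
  res
}

#' Classify a residue as hydrophobic or hydrophilic
#'
#' A residue is hydrophobic when its hydropathy value exceeds the table's
#' threshold, hydrophilic otherwise.
#'
#' @param code one-letter residue code (vectorised).
#' @param table a [HydropathyTable-class]; default [eisenbergHydropathy()].
#' @return character vector, "hydrophobic" or "hydrophilic".
#' @examples
#' classifyResidue(c("R", "W", "S"))
#' @export
classifyResidue <- function(code, table = eisenbergHydropathy()) {
  code <- toupper(code)
  unknown <- setdiff(code, names(table@values))
  if (length(unknown)) {
    .stopf("unknown residue code(s): %s", paste(unique(unknown), collapse = ", "))
  }
  ifelse(table@values[code] > table@threshold, "hydrophobic", "hydrophilic")
}

#' Net formal charge of a protein sequence at neutral pH
#'
#' Standard charge assignment: Lys and Arg +1, Asp and Glu -1, His neutral,
#' plus +1 for the N-terminus and -1 for the C-terminus.
#'
#' @param sequence one-letter sequence (standard residues only).
#' @return integer net charge in units of e.
#' @examples
#' netFormalCharge(trpCageSequence())  # +1
#' @export
netFormalCharge <- function(sequence) {
  res <- .checkStandardSequence(sequence)
  pos <- sum(res %in% c("K", "R"))
  neg <- sum(res %in% c("D", "E"))
  as.integer(pos - neg + 1L - 1L)
}

#' Average molecular mass of a protein chain
#'
#' Sum of average residue masses plus one water (18.015 Da) for the termini.
#'
#' @param sequence one-letter sequence.
#' @return mass in Da.
#' @export
proteinMass <- function(sequence) {
  res <- .checkStandardSequence(sequence)
  sum(residueMasses()[res]) + .waterMass
}

# ---- accessors -------------------------------------------------------------

#' Accessors for TemperatureSeries
#' @param x a [TemperatureSeries-class].
#' @name TemperatureSeries-accessors
#' @aliases temperatures seriesValues seriesErrors
NULL

#' @rdname TemperatureSeries-accessors
#' @export
setMethod("temperatures", "TemperatureSeries", function(x) x@temperatures)

#' @rdname TemperatureSeries-accessors
#' @export
setMethod("seriesValues", "TemperatureSeries", function(x) x@values)

#' @rdname TemperatureSeries-accessors
#' @export
setMethod("seriesErrors", "TemperatureSeries", function(x) x@errors)

#' Accessors for SegmentedFit
#' @param x a [SegmentedFit-class].
#' @name SegmentedFit-accessors
NULL

#' @rdname SegmentedFit-accessors
#' @export
setMethod("breakpoint", "SegmentedFit", function(x) x@breakpoint)

#' Accessors for EnthalpyFit
#' @param x an [EnthalpyFit-class].
#' @name EnthalpyFit-accessors
NULL

#' @rdname EnthalpyFit-accessors
#' @export
setMethod("transitionTemperature", "EnthalpyFit", function(x) x@tD)

#' @rdname EnthalpyFit-accessors
#' @export
setMethod("deltaCp", "EnthalpyFit", function(x) x@deltaCp)

#' Accessors for MSFResult
#' @param x an [MSFResult-class].
#' @name MSFResult-accessors
NULL

#' @rdname MSFResult-accessors
#' @export
setMethod("ensembleMSF", "MSFResult", function(x) x@ensemble)

#' @rdname MSFResult-accessors
#' @export
setMethod("perResidueMSF", "MSFResult", function(x) x@perResidue)

#' @rdname MSFResult-accessors
#' @export
setMethod("perAtomMSF", "MSFResult", function(x) x@perAtom)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d protein unit(s) x %d residues (%s), %d atoms\n",
              object@nProteins, nchar(object@sequence[1L]), object@sequence[1L],
              nrow(object@atoms)))
  cat(sprintf("  heavy: %d, H: %d (methyl-H: %d); waters: %d, ions: %d\n",
              sum(object@atoms$isHeavy), sum(!object@atoms$isHeavy),
              sum(object@atoms$isMethylHydrogen), object@waterCount,
              nrow(object@ions)))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms; t = %.6g..%.6g ps; box: %s\n",
              d[1L], d[2L], min(object@times), max(object@times),
              if (is.null(object@box)) "none" else "orthorhombic"))
})

setMethod("show", "TemperatureSeries", function(object) {
  cat(sprintf("TemperatureSeries '%s': %d points, T = %g..%g K\n",
              object@label, length(object@temperatures),
              min(object@temperatures), max(object@temperatures)))
})

setMethod("show", "MSFResult", function(object) {
  cat(sprintf("MSFResult [%s]: ensemble MSF = %.4g +/- %.2g A^2 (%d frames, %d protein unit(s))\n",
              object@selectionLabel, object@ensemble, object@ensembleSe,
              object@nFrames, length(object@perProtein)))
})

setMethod("show", "SegmentedFit", function(object) {
  cat(sprintf("SegmentedFit (%s space): breakpoint %.1f K, slopes %.4g / %.4g, p(two-regime) = %.3g\n",
              object@fitSpace, object@breakpoint, object@slopeLow,
              object@slopeHigh, object@pTwoRegime))
})

setMethod("show", "EnthalpyFit", function(object) {
  if (object@transitionDetected) {
    cat(sprintf("EnthalpyFit: T_D = %.1f K, delta_Cp = %.4g (p = %.3g)\n",
                object@tD, object@deltaCp, object@pTwoRegime))
  } else {
    cat(sprintf("EnthalpyFit: no transition (%s, p = %.3g); slope %.4g\n",
                object@diagnostic, object@pTwoRegime, object@cpLow))
  }
})

setMethod("show", "PowderConfig", function(object) {
  cat(sprintf("PowderConfig: %d protein unit(s), %d waters, %d ions; h = %.3f g/g; beta = %.4g mol/kJ\n",
              object@nProteins, nrow(object@waters), nrow(object@ions),
              hydrationLevel(object), object@beta))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: T = %g..%g K (%d pts), tLow = %g K, tD = %s, noise = %g%%, %s\n",
              min(object@tGrid), max(object@tGrid), length(object@tGrid),
              object@tLow, if (is.na(object@tD)) "none" else sprintf("%g K", object@tD),
              100 * object@noiseRel, object@hydrationMode))
})
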