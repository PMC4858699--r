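#' @include AllClasses.R
NULL

#' Hydration level of a system
#'
#' Mass of water per mass of protein (g water / g protein), computed from the
#' water count and the protein sequence with average molecular masses
#' (M_water = 18.015 Da; protein mass = sum of average residue masses plus one
#' water for the termini).
#'
#' @param x a [PowderConfig-class] or [Topology-class].
#' @param ... unused.
#' @return hydration level h in g/g.
#' @examples
#' cfg <- makePowderConfig(nProteins = 16, nWaters = 771, seed = 1)
#' round(hydrationLevel(cfg), 2)  # 0.4
#' @export
setGeneric("hydrationLevel", function(x, ...) standardGeneric("hydrationLevel"))

#' @rdname TemperatureSeries-accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))

#' @rdname TemperatureSeries-accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname TemperatureSeries-accessors
#' @export
setGeneric("seriesErrors", function(x) standardGeneric("seriesErrors"))

#' @rdname SegmentedFit-accessors
#' @export
setGeneric("breakpoint", function(x) standardGeneric("breakpoint"))

#' @rdname EnthalpyFit-accessors
#' @export
setGeneric("transitionTemperature", function(x) standardGeneric("transitionTemperature"))

#' @rdname EnthalpyFit-accessors
#' @export
setGeneric("deltaCp", function(x) standardGeneric("deltaCp"))

#' @rdname MSFResult-accessors
#' @export
setGeneric("ensembleMSF", function(x) standardGeneric("ensembleMSF"))

#' @rdname MSFResult-accessors
#' @export
setGeneric("perResidueMSF", function(x) standardGeneric("perResidueMSF"))

#' @rdname MSFResult-accessors
#' @export
setGeneric("perAtomMSF", function(x) standardGeneric("perAtomMSF"))

#' Build a per-residue MSF profile table
#'
#' Assembles the residue-level summary: one row per (residue, temperature)
#' with the residue's hydropathy class, MSF and standard error, sorted by
#' residue then temperature.
#'
#' @param x a named list keyed by temperature, each element an
#'   [MSFResult-class]; or a named list keyed by residue index, each element a
#'   [TemperatureSeries-class] (as produced by [makePerResidueDataset()]).
#' @param hydropathy a [HydropathyTable-class].
#' @param sequence one-letter protein sequence.
#' @param ... unused.
#' @return data.frame with columns \code{residueIndex}, \code{residueName},
#'   \code{class}, \code{temperature}, \code{msf}, \code{se}.
#' @export
setGeneric("residueProfileTable",
           function(x, hydropathy, sequence, ...) standardGeneric("residueProfileTable"))
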