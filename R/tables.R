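#' @include AllGenerics.R
NULL

.tableCache <- new.env(parent = emptyenv())

.readExtdata <- function(file) {
  path <- system.file("extdata", file, package = "powderdyn", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", quote = "")
}

#' Standard atomic masses
#'
#' Named vector of average atomic masses (Da) by element symbol (upper case).
#' @return named numeric vector.
#' @export
atomicMasses <- function() {
  if (is.null(.tableCache$atomic)) {
    tab <- .readExtdata("atomic_masses.tsv")
    .tableCache$atomic <- stats::setNames(tab$mass, toupper(tab$element))
  }
  .tableCache$atomic
}

#' Average amino-acid residue masses
#'
#' Average residue masses (Da, water of condensation removed) keyed by
#' one-letter code, with the three-letter mapping as attribute tables.
#' @return named numeric vector (one-letter codes); attributes \code{three}
#'   (one- to three-letter map) and \code{one} (three- to one-letter map).
#' @export
residueMasses <- function() {
  if (is.null(.tableCache$residue)) {
    tab <- .readExtdata("residue_masses.tsv")
    m <- stats::setNames(tab$mass, tab$one)
    attr(m, "three") <- stats::setNames(tab$three, tab$one)
    attr(m, "one") <- stats::setNames(tab$one, tab$three)
    .tableCache$residue <- m
  }
  .tableCache$residue
}

#' Eisenberg consensus hydropathy scale
#'
#' The Eisenberg consensus hydropathy values for the 20 standard residues,
#' with classification threshold 0 (value > 0 means hydrophobic). With this
#' threshold Q, K, D, S and R fall in the hydrophilic class and L, W and I in
#' the hydrophobic class, matching the classes used in residue-level powder
#' dynamics analyses.
#'
#' @param threshold classification threshold; default 0.
#' @return a [HydropathyTable-class].
#' @examples
#' classifyResidue("W", eisenbergHydropathy())  # hydrophobic
#' @export
eisenbergHydropathy <- function(threshold = 0) {
  tab <- .readExtdata("eisenberg_hydropathy.tsv")
  new("HydropathyTable",
      values = stats::setNames(tab$value, tab$one),
      threshold = threshold, name = "Eisenberg consensus")
}

#' Trp-cage sequence
#'
#' One-letter sequence of the Trp-cage miniprotein (20 residues, PDB 1L2Y),
#' the model protein of the powder systems this package targets.
#' @return character scalar.
#' @export
trpCageSequence <- function() "NLYIQWLKDGGPSSGRPPPS"
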