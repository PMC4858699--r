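#' @include synthetic-data.R
NULL

.oneFromThree <- function(three) {
  unname(attr(residueMasses(), "one")[toupper(three)])
}

#' @rdname residueProfileTable
#' @export
setMethod("residueProfileTable", "list", function(x, hydropathy, sequence, ...) {
  if (!length(x)) {
    return(data.frame(residueIndex = integer(0), residueName = character(0),
                      class = character(0), temperature = numeric(0),
                      msf = numeric(0), se = numeric(0)))
  }
  res <- .checkStandardSequence(sequence)
  cls <- classifyResidue(res, hydropathy)
  rows <- list()

  if (all(vapply(x, is, logical(1L), "TemperatureSeries"))) {
    # per-residue series keyed by residue index
    for (nm in names(x)) {
      r <- as.integer(nm)
      s <- x[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        residueIndex = r, residueName = res[r], class = unname(cls[r]),
        temperature = s@temperatures, msf = s@values, se = s@errors)
    }
  } else if (all(vapply(x, is, logical(1L), "MSFResult"))) {
    # MSF results keyed by temperature; average residues over protein units
    for (nm in names(x)) {
      temp <- as.numeric(nm)
      pr <- x[[nm]]@perResidue
      for (r in sort(unique(pr$residueIndex))) {
        sub <- pr[pr$residueIndex == r, , drop = FALSE]
        nP <- nrow(sub)
        se <- if (nP > 1L) stats::sd(sub$msf) / sqrt(nP) else sub$se[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          residueIndex = r, residueName = res[r], class = unname(cls[r]),
          temperature = temp, msf = mean(sub$msf), se = se)
      }
    }
  } else {
    .stopf("x must be a list of TemperatureSeries or of MSFResult objects")
  }

  out <- do.call(rbind, rows)
  allRes <- sort(unique(out$residueIndex))
  allT <- sort(unique(out$temperature))
  missing <- nrow(out) < length(allRes) * length(allT)
  if (missing) .warnf("some residues are missing temperatures; rows omitted")
  out <- out[order(out$residueIndex, out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Hydrophilic-to-hydrophobic MSF enhancement ratio
#'
#' Ratio of the class-mean MSF growth between a reference and a hot
#' temperature, hydrophilic over hydrophobic, with the terminal residues
#' excluded (their large MSF stems from bonding topology, not hydropathy).
#' A ratio above 1 is the hydrated-powder signature (hydrophilic residues
#' activate more); below 1 the dehydrated one.
#'
#' @param profile a profile table from [residueProfileTable()].
#' @param tRef,tHot the two temperatures (K); both must be present.
#' @return list with \code{ratio} and \code{status} ("ok", "infinite" when
#'   the hydrophobic growth is zero, "undefined" when tHot == tRef).
#' @export
enhancementRatio <- function(profile, tRef, tHot) {
  if (tHot == tRef) return(list(ratio = NA_real_, status = "undefined"))
  for (tt in c(tRef, tHot)) {
    if (!any(profile$temperature == tt)) .stopf("temperature %g K not in profile", tt)
  }
  resIdx <- sort(unique(profile$residueIndex))
  termini <- c(min(resIdx), max(resIdx))
  keep <- !(profile$residueIndex %in% termini)
  growth <- function(class_) {
    sub <- profile[keep & profile$class == class_, , drop = FALSE]
    ref <- sub$msf[sub$temperature == tRef][order(sub$residueIndex[sub$temperature == tRef])]
    hot <- sub$msf[sub$temperature == tHot][order(sub$residueIndex[sub$temperature == tHot])]
    mean(hot - ref)
  }
  gPhil <- growth("hydrophilic")
  gPhob <- growth("hydrophobic")
  if (abs(gPhob) < .Machine$double.eps) {
    return(list(ratio = Inf, status = "infinite"))
  }
  list(ratio = gPhil / gPhob, status = "ok")
}

#' Assemble the machine-readable analysis report
#'
#' Collects the transition temperatures, heat-capacity jump, per-residue
#' transition flags and class summaries into a versioned JSON report plus CSV
#' tables, written to a directory. The report records the provenance it is
#' given (seeds, parameters) and the package version; no timestamps, so
#' identical inputs give byte-identical output.
#'
#' @param outDir output directory (created if needed).
#' @param tLow lower transition temperature (K) or NA.
#' @param tDMsf T_D from the MSF deviation method (K) or NA.
#' @param enthalpyFit an [EnthalpyFit-class] or NULL.
#' @param residueReport data.frame from [detectResidueTransitions()] or NULL.
#' @param profile data.frame from [residueProfileTable()] or NULL.
#' @param provenance named list of seeds/parameters to record.
#' @return the report list, invisibly.
#' @export
fullReport <- function(outDir, tLow = NA_real_, tDMsf = NA_real_,
                       enthalpyFit = NULL, residueReport = NULL,
                       profile = NULL, provenance = list()) {
  if (is.null(enthalpyFit) && is.null(residueReport) && is.null(profile) &&
      is.na(tLow) && is.na(tDMsf)) {
    .stopf("at least one analysis product is required")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    schemaVersion = "1.0",
    package = list(name = "powderdyn",
                   version = as.character(utils::packageVersion("powderdyn"))),
    transitions = list(
      tLow = tLow,
      tDMsf = tDMsf,
      tDEnthalpy = if (is.null(enthalpyFit)) NA_real_ else enthalpyFit@tD,
      deltaCp = if (is.null(enthalpyFit)) NA_real_ else enthalpyFit@deltaCp,
      enthalpyTransitionDetected = if (is.null(enthalpyFit)) NA
                                   else enthalpyFit@transitionDetected,
      enthalpyPTwoRegime = if (is.null(enthalpyFit)) NA_real_
                           else enthalpyFit@pTwoRegime),
    residueSummary = if (is.null(residueReport)) NULL else list(
      nResidues = nrow(residueReport),
      nBothTransitions = sum(residueReport$hasTlowSlopeChange &
                               residueReport$hasTdDeviation)),
    classSummary = if (is.null(profile)) NULL else {
      tops <- stats::aggregate(msf ~ class, data = profile, FUN = mean)
      as.list(stats::setNames(tops$msf, paste0("mean_msf_", tops$class)))
    },
    provenance = provenance
  )
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(residueReport)) {
    utils::write.csv(residueReport, file.path(outDir, "residue_transitions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(profile)) {
    utils::write.csv(profile, file.path(outDir, "residue_profile.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
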