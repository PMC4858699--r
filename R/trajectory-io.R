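#' @include core-model.R
NULL

.waterResnames <- c("HOH", "SOL", "WAT")
.ionResnames <- c(CL = -1, CLA = -1, `CL-` = -1, NA. = 1, `NA+` = 1, SOD = 1, K = 1, POT = 1)
.methylResidues <- c("ALA", "ILE", "LEU", "MET", "THR", "VAL")

# Element from an atom name per PDB convention: strip leading digits and
# primes, first remaining letter. Ion residues map to their element directly.
.elementFromName <- function(name, resname) {
  nm <- toupper(gsub("^[0-9']+", "", name))
  if (toupper(resname) %in% c("CL", "CLA", "CL-")) return("CL")
  if (toupper(resname) %in% c("NA", "NA+", "SOD")) return("NA")
  el <- substr(nm, 1L, 1L)
  if (!el %in% c("H", "C", "N", "O", "S", "P")) {
    .stopf("cannot infer element for atom name '%s' in residue %s", name, resname)
  }
  el
}

# Methyl hydrogens by name convention: within a methyl-bearing residue
# (A, I, L, M, T, V), a carbon C<tail> with exactly three hydrogens named
# H<tail>1..H<tail>3 marks those hydrogens as methyl.
.flagMethylHydrogens <- function(names, elements, resname) {
  flag <- logical(length(names))
  if (!toupper(resname) %in% .methylResidues) return(flag)
  nm <- toupper(names)
  carbons <- nm[elements == "C" & nchar(nm) > 1L]
  for (cn in carbons) {
    tail <- substring(cn, 2L)
    hits <- which(elements == "H" & grepl(paste0("^H", tail, "[0-9]$"), nm))
    if (length(hits) == 3L) flag[hits] <- TRUE
  }
  flag
}

# Assemble a Topology from a raw atom table (one row per atom of the source
# file, file order) plus coordinates in Angstrom. Waters/ions are counted and
# removed; protein atoms keep their source-row index.
.buildTopology <- function(raw, coords) {
  stopifnot(nrow(raw) == nrow(coords))
  resUp <- toupper(raw$resname)
  isWater <- resUp %in% .waterResnames
  isIon <- resUp %in% names(.ionResnames)
  waterCount <- length(unique(paste(raw$chain[isWater], raw$resid[isWater])))
  ions <- data.frame(species = resUp[isIon],
                     charge = unname(.ionResnames[resUp[isIon]]),
                     stringsAsFactors = FALSE)
  keep <- which(!isWater & !isIon)
  if (!length(keep)) .stopf("no protein atoms found")
  raw <- raw[keep, , drop = FALSE]
  coords <- coords[keep, , drop = FALSE]

  # protein units: by chain when chains are informative, else by residue
  # numbering restarts
  chain <- raw$chain
  if (length(unique(chain)) > 1L) {
    unit <- as.integer(factor(chain, levels = unique(chain))) - 1L
  } else {
    restart <- c(FALSE, diff(raw$resid) < 0)
    unit <- cumsum(restart)
  }

  element <- mapply(.elementFromName, raw$name, raw$resname, USE.NAMES = FALSE)
  masses <- atomicMasses()
  mass <- unname(masses[element])
  if (anyNA(mass)) {
    .warnf("unknown element(s) %s; assigning hydrogen mass",
           paste(unique(element[is.na(mass)]), collapse = ", "))
    mass[is.na(mass)] <- masses[["H"]]
  }

  residueIndex <- integer(nrow(raw))
  isMethylH <- logical(nrow(raw))
  seqs <- character(0)
  threeToOne <- attr(residueMasses(), "one")
  for (k in unique(unit)) {
    rows <- which(unit == k)
    rid <- raw$resid[rows]
    dense <- as.integer(factor(rid, levels = unique(rid)))
    residueIndex[rows] <- dense
    rn3 <- toupper(raw$resname[rows][!duplicated(dense)])
    one <- threeToOne[rn3]
    if (anyNA(one)) {
      .stopf("unknown residue name(s): %s", paste(unique(rn3[is.na(one)]), collapse = ", "))
    }
    seqs <- c(seqs, paste(one, collapse = ""))
    for (r in unique(dense)) {
      rr <- rows[dense == r]
      isMethylH[rr] <- .flagMethylHydrogens(raw$name[rr], element[rr],
                                            raw$resname[rr][1L])
    }
  }
  if (length(unique(seqs)) != 1L) {
    .stopf("protein units do not share a common sequence")
  }

  atoms <- data.frame(
    atomId = seq_len(nrow(raw)),
    name = raw$name,
    element = element,
    mass = mass,
    residueIndex = residueIndex,
    residueName = toupper(raw$resname),
    proteinIndex = unit,
    isHeavy = element != "H",
    isMethylHydrogen = isMethylH,
    bfactor = if (!is.null(raw$bfactor)) raw$bfactor else 0,
    stringsAsFactors = FALSE
  )
  new("Topology",
      atoms = atoms, nProteins = length(unique(unit)), sequence = seqs[1L],
      waterCount = as.integer(waterCount), ions = ions,
      refCoords = unname(as.matrix(coords)),
      sourceIndices = as.integer(keep),
      sourceAtomCount = as.integer(length(isWater)))
}

# ---- GRO parsing -----------------------------------------------------------

.parseGroFrames <- function(lines) {
  frames <- list()
  i <- 1L
  nline <- length(lines)
  while (i <= nline) {
    if (!nzchar(trimws(lines[i])) && i == nline) break
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    if (is.na(natoms)) .stopf("malformed GRO frame at line %d", i)
    rows <- lines[(i + 2L):(i + 1L + natoms)]
    boxLine <- lines[i + 2L + natoms]
    time <- NA_real_
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm)) time <- as.numeric(sub("t=\\s*", "", tm))
    frames[[length(frames) + 1L]] <- list(
      resid = as.integer(substr(rows, 1L, 5L)),
      resname = trimws(substr(rows, 6L, 10L)),
      name = trimws(substr(rows, 11L, 15L)),
      # nm -> Angstrom
      coords = cbind(as.numeric(substr(rows, 21L, 28L)),
                     as.numeric(substr(rows, 29L, 36L)),
                     as.numeric(substr(rows, 37L, 44L))) * 10,
      box = as.numeric(strsplit(trimws(boxLine), "\\s+")[[1L]])[1:3] * 10,
      time = time
    )
    i <- i + 3L + natoms
    while (i <= nline && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  frames
}

.fileFormat <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) "pdb" else if (ext == "gro") "gro"
  else .stopf("unrecognised structure format: '%s' (expected .pdb or .gro)", ext)
}

# ---- exported readers ------------------------------------------------------

#' Read a topology from a PDB or GRO file
#'
#' Parses atom names, residues and chains; infers elements from atom names,
#' assigns masses from the bundled atomic-mass table, flags methyl-group
#' hydrogens by the name convention (a carbon with exactly three attached
#' H names within Ala/Ile/Leu/Met/Thr/Val), separates waters (HOH/SOL/WAT)
#' and chloride/sodium ions, and groups atoms into protein units by chain or
#' by residue-numbering restarts. GRO coordinates are converted from nm to
#' Angstrom on read.
#'
#' @param path path to a PDB (first model is used) or GRO file.
#' @return a [Topology-class].
#' @export
readTopology <- function(path) {
  fmt <- .fileFormat(path)
  if (fmt == "pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
    a <- pdb$atom
    raw <- data.frame(name = a$elety, resname = a$resid, resid = a$resno,
                      chain = ifelse(is.na(a$chain), "", a$chain),
                      bfactor = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
    coords <- cbind(a$x, a$y, a$z)
  } else {
    frames <- .parseGroFrames(readLines(path))
    if (!length(frames)) .stopf("no frames in GRO file")
    f <- frames[[1L]]
    raw <- data.frame(name = f$name, resname = f$resname, resid = f$resid,
                      chain = "", bfactor = 0, stringsAsFactors = FALSE)
    coords <- f$coords
  }
  .buildTopology(raw, coords)
}

#' Read a multi-frame trajectory
#'
#' Reads coordinate frames from a multi-model PDB (MODEL/ENDMDL delimited), a
#' concatenated GRO frame series, or a user-supplied frame iterator (the
#' adapter contract for binary formats: a function that returns
#' \code{list(coords = nAtoms x 3 Angstrom matrix, box = lengths or NULL,
#' time = ps or NA)} per call and \code{NULL} when exhausted). Only the
#' topology's protein atoms are retained; frames must match the source atom
#' count of the topology.
#'
#' @param x file path or frame-iterator function.
#' @param topology the [Topology-class] the frames belong to.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(x, topology) {
  stopifnot(is(topology, "Topology"))
  idx <- topology@sourceIndices
  nSrc <- topology@sourceAtomCount
  coordsList <- list(); boxList <- list(); times <- numeric(0)

  if (is.function(x)) {
    repeat {
      fr <- x()
      if (is.null(fr)) break
      if (nrow(fr$coords) != nSrc && nrow(fr$coords) != length(idx)) {
        .stopf("frame %d has %d atoms; topology expects %d (or %d protein atoms)",
               length(coordsList) + 1L, nrow(fr$coords), nSrc, length(idx))
      }
      xyz <- if (nrow(fr$coords) == nSrc) fr$coords[idx, , drop = FALSE] else fr$coords
      coordsList[[length(coordsList) + 1L]] <- xyz
      boxList[[length(boxList) + 1L]] <- if (is.null(fr$box)) NA_real_ else fr$box
      times <- c(times, if (is.null(fr$time)) NA_real_ else fr$time)
    }
  } else {
    fmt <- .fileFormat(x)
    if (fmt == "pdb") {
      pdb <- suppressWarnings(bio3d::read.pdb(x, multi = TRUE, verbose = FALSE))
      xyz <- pdb$xyz
      if (ncol(xyz) != 3L * nSrc) {
        .stopf("frame 1 has %d atoms; topology expects %d", ncol(xyz) / 3L, nSrc)
      }
      for (f in seq_len(nrow(xyz))) {
        m <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
        coordsList[[f]] <- m[idx, , drop = FALSE]
        boxList[[f]] <- NA_real_
        times <- c(times, NA_real_)
      }
    } else {
      frames <- .parseGroFrames(readLines(x))
      for (f in seq_along(frames)) {
        fr <- frames[[f]]
        if (nrow(fr$coords) != nSrc) {
          .stopf("frame %d has %d atoms; topology expects %d", f, nrow(fr$coords), nSrc)
        }
        coordsList[[f]] <- fr$coords[idx, , drop = FALSE]
        boxList[[f]] <- fr$box
        times <- c(times, fr$time)
      }
    }
  }

  nF <- length(coordsList)
  if (nF < 1L) .stopf("no frames read")
  nA <- length(idx)
  coords <- array(NA_real_, dim = c(nF, nA, 3L))
  for (f in seq_len(nF)) coords[f, , ] <- coordsList[[f]]
  haveBox <- vapply(boxList, function(b) length(b) == 3L && !anyNA(b), logical(1L))
  box <- if (all(haveBox)) do.call(rbind, boxList) else NULL
  if (anyNA(times)) times <- seq_len(nF) - 1
  new("Trajectory", topology = topology, coords = coords, box = box, times = times)
}

# ---- writers ---------------------------------------------------------------

.pdbAtomLine <- function(serial, name, resname, chain, resid, xyz, b, element) {
  nameField <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nameField, substr(resname, 1L, 3L), chain, resid,
          xyz[1L], xyz[2L], xyz[3L], 1.00, b, element)
}

.chainLetter <- function(proteinIndex) {
  LETTERS[(proteinIndex %% 26L) + 1L]
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Writes a single-model PDB using the topology's reference coordinates, with
#' each atom's B-factor set to the value of its residue (clamped to the fixed
#' PDB field width, two decimals). This is the standard vehicle for colouring
#' structures by residue-level MSF in molecular viewers.
#'
#' @param topology a [Topology-class].
#' @param values per-residue values: a named numeric (names = residue index,
#'   applied to every protein unit) or a data.frame with columns
#'   \code{residueIndex}, \code{value} and optionally \code{proteinIndex}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBfactorStructure <- function(topology, values, path) {
  a <- topology@atoms
  L <- nchar(topology@sequence[1L])
  if (is.data.frame(values)) {
    if (!all(c("residueIndex", "value") %in% names(values))) {
      .stopf("values data.frame needs columns residueIndex and value")
    }
    if (is.null(values$proteinIndex)) {
      lk <- stats::setNames(values$value, values$residueIndex)
      b <- lk[as.character(a$residueIndex)]
    } else {
      key <- paste(values$proteinIndex, values$residueIndex)
      lk <- stats::setNames(values$value, key)
      b <- lk[paste(a$proteinIndex, a$residueIndex)]
    }
  } else {
    lk <- stats::setNames(as.numeric(values), names(values))
    b <- lk[as.character(a$residueIndex)]
  }
  if (anyNA(b)) .stopf("values must cover every residue of every protein unit")
  b <- pmin(pmax(b, -99.99), 999.99)

  lines <- character(0)
  for (k in unique(a$proteinIndex)) {
    rows <- which(a$proteinIndex == k)
    lines <- c(lines, vapply(rows, function(i) {
      .pdbAtomLine(i, a$name[i], a$residueName[i], .chainLetter(k),
                   a$residueIndex[i], topology@refCoords[i, ], b[i], a$element[i])
    }, character(1L)), "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB
#'
#' MODEL/ENDMDL delimited frames over the topology's protein atoms; useful for
#' round-tripping synthetic trajectories through the text formats.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTrajectoryPDB <- function(traj, path) {
  a <- traj@topology@atoms
  nF <- dim(traj@coords)[1L]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nF)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (k in unique(a$proteinIndex)) {
      rows <- which(a$proteinIndex == k)
      writeLines(vapply(rows, function(i) {
        .pdbAtomLine(i, a$name[i], a$residueName[i], .chainLetter(k),
                     a$residueIndex[i], traj@coords[f, i, ], 0, a$element[i])
      }, character(1L)), con)
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
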