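#' @include trajectory-io.R
NULL

#' Kabsch rigid-body superposition
#'
#' Weighted least-squares rigid fit of a mobile point set onto a reference:
#' returns the proper rotation (det = +1) and translation minimising the
#' weighted sum of squared distances. Points are rows.
#'
#' @param mobile,reference numeric n x 3 matrices, n >= 3, non-collinear.
#' @param weights optional non-negative weights (default equal).
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   such that aligned = mobile \%*\% t(rotation) + translation, and
#'   \code{rmsd}, the post-fit weighted RMSD.
#' @export
kabschAlign <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n) {
    .stopf("need >= 3 points and equal counts (got %d and %d)", n, nrow(reference))
  }
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) {
    .stopf("weights must be non-negative with positive sum")
  }
  w <- w / sum(w)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  sv <- svd(Q)
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1e-12)) {
    .stopf("degenerate (collinear or coincident) point set")
  }
  H <- crossprod(P * w, Q)          # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - (cm %*% t(R))), rmsd = rmsd)
}

.applyTransform <- function(x, fit) {
  sweep(x %*% t(fit$rotation), 2L, fit$translation, "+")
}

# ---- atom selection --------------------------------------------------------

#' Select atoms of a topology
#'
#' Selection expressions combine tokens with \code{&} (intersection) and
#' \code{|} (union; \code{&} binds tighter). Tokens: \code{all}, \code{heavy},
#' \code{hydrogen} (or \code{all-h}), \code{methyl-h}, \code{non-methyl-h},
#' \code{residue(i)}, \code{protein(k)}. Methyl and non-methyl hydrogens
#' partition the hydrogens.
#'
#' @param topology a [Topology-class].
#' @param expression selection string, e.g. \code{"heavy & protein(0)"}.
#' @return sorted integer vector of atom indices.
#' @examples
#' top <- syntheticTopology(nProteins = 1)
#' length(selectAtoms(top, "methyl-h"))
#' @export
selectAtoms <- function(topology, expression) {
  a <- topology@atoms
  token <- function(tok) {
    tok <- tolower(trimws(tok))
    if (tok == "all") return(seq_len(nrow(a)))
    if (tok == "heavy") return(which(a$isHeavy))
    if (tok %in% c("hydrogen", "all-h")) return(which(!a$isHeavy))
    if (tok == "methyl-h") return(which(a$isMethylHydrogen))
    if (tok == "non-methyl-h") return(which(!a$isHeavy & !a$isMethylHydrogen))
    m <- regmatches(tok, regexec("^residue\\((\\d+)\\)$", tok))[[1L]]
    if (length(m)) return(which(a$residueIndex == as.integer(m[2L])))
    m <- regmatches(tok, regexec("^protein\\((\\d+)\\)$", tok))[[1L]]
    if (length(m)) return(which(a$proteinIndex == as.integer(m[2L])))
    .stopf("unknown selection token: '%s'", tok)
  }
  unionTerms <- strsplit(expression, "|", fixed = TRUE)[[1L]]
  out <- integer(0)
  for (term in unionTerms) {
    toks <- strsplit(term, "&", fixed = TRUE)[[1L]]
    idx <- Reduce(intersect, lapply(toks, token))
    out <- union(out, idx)
  }
  sort(out)
}

# ---- MSF -------------------------------------------------------------------

# Make each protein unit whole under an orthorhombic box: wrap every atom's
# displacement from the unit's first atom into [-L/2, L/2).
.unwrapUnit <- function(xyz, box) {
  anchor <- xyz[1L, ]
  dx <- sweep(xyz, 2L, anchor)
  dx <- dx - sweep(round(sweep(dx, 2L, box, "/")), 2L, box, "*")
  sweep(dx, 2L, anchor, "+")
}

# Align all frames of one protein unit to its frame-1 coordinates using the
# unit's alignment atoms; returns the aligned coordinates of the unit's atoms.
.alignUnitFrames <- function(coords, box, unitIdx, alignIdxLocal,
                             alignWeights = NULL) {
  nF <- dim(coords)[1L]
  out <- coords[, unitIdx, , drop = FALSE]
  if (!is.null(box)) {
    for (f in seq_len(nF)) out[f, , ] <- .unwrapUnit(out[f, , ], box[f, ])
  }
  if (is.null(alignIdxLocal)) return(out)
  ref <- out[1L, alignIdxLocal, ]
  for (f in seq_len(nF)) {
    fit <- kabschAlign(out[f, alignIdxLocal, ], ref, weights = alignWeights)
    out[f, , ] <- .applyTransform(out[f, , ], fit)
  }
  out
}

.massAverage <- function(values, masses) sum(values * masses) / sum(masses)

# Per-atom MSF of an aligned frames x atoms x 3 array over the given frames:
# variance of position about the window mean, summed over axes.
.msfFromAligned <- function(aligned, frames) {
  sub <- aligned[frames, , , drop = FALSE]
  mu <- colMeans(sub)                       # atoms x 3
  dev <- sweep(sub, c(2L, 3L), mu)
  rowSums(colSums(dev^2)) / length(frames)
}

#' Compute mean-square fluctuations
#'
#' For each protein unit independently, every frame is rigid-body fitted to
#' that unit's frame-1 (time 0) coordinates using the alignment selection
#' (default: the unit's heavy atoms), after making the unit whole under the
#' periodic box when one is present. The MSF of atom i is then the variance of
#' its aligned position about its mean aligned position,
#' MSF_i = (1/N_F) sum_t |x_i(t) - <x_i>|^2. Atomic values are mass-averaged
#' into per-residue and per-protein values, and the ensemble MSF is the
#' unweighted mean over protein units. With \code{nBlocks}, the trajectory is
#' split into contiguous equal-length blocks (remainder frames at the end are
#' dropped), the MSF recomputed per block against the same frame-1 reference,
#' and standard errors estimated as sd(blocks)/sqrt(nBlocks).
#'
#' @param traj a [Trajectory-class].
#' @param selection selection expression for the analysed atoms
#'   (default "heavy").
#' @param alignSelection selection for the rigid fit (default "heavy");
#'   "none" disables alignment.
#' @param nBlocks integer >= 2 for block-averaged errors, or NULL (no errors).
#' @param massWeightedAlign weight the rigid fit by atomic mass (default
#'   FALSE: mass enters only when MSF values are averaged).
#' @return an [MSFResult-class].
#' @seealso [blockErrors()], [selectAtoms()], [kabschAlign()]
#' @export
computeMSF <- function(traj, selection = "heavy", alignSelection = "heavy",
                       nBlocks = NULL, massWeightedAlign = FALSE) {
  top <- traj@topology
  a <- top@atoms
  nF <- dim(traj@coords)[1L]
  if (nF < 2L) .stopf("need at least 2 frames for a fluctuation computation")
  selIdx <- selectAtoms(top, selection)
  if (!length(selIdx)) .stopf("empty selection: '%s'", selection)
  doAlign <- !identical(tolower(alignSelection), "none")
  if (!is.null(nBlocks)) {
    nBlocks <- as.integer(nBlocks)
    if (nBlocks < 2L) .stopf("nBlocks must be >= 2")
    if (nF < nBlocks) .stopf("need at least nBlocks frames")
  }

  units <- sort(unique(a$proteinIndex))
  perAtom <- numeric(0); perAtomSe <- numeric(0); atomIndex <- integer(0)
  resRows <- list()
  perProtein <- numeric(0); perProteinSe <- numeric(0)
  blockEnsemble <- if (!is.null(nBlocks)) matrix(NA_real_, nBlocks, length(units))

  blockFrames <- NULL
  if (!is.null(nBlocks)) {
    len <- nF %/% nBlocks
    blockFrames <- lapply(seq_len(nBlocks), function(b) ((b - 1L) * len + 1L):(b * len))
  }

  for (ui in seq_along(units)) {
    k <- units[ui]
    unitIdx <- which(a$proteinIndex == k)
    selLocal <- match(intersect(selIdx, unitIdx), unitIdx)
    if (!length(selLocal)) next
    alignLocal <- NULL
    alignW <- NULL
    if (doAlign) {
      ai <- intersect(selectAtoms(top, alignSelection), unitIdx)
      if (length(ai) < 3L) .stopf("alignment selection has < 3 atoms in protein unit %d", k)
      alignLocal <- match(ai, unitIdx)
      if (massWeightedAlign) alignW <- a$mass[ai]
    }
    aligned <- .alignUnitFrames(traj@coords, traj@box, unitIdx, alignLocal, alignW)
    msfAll <- .msfFromAligned(aligned, seq_len(nF))
    msfSel <- msfAll[selLocal]
    masses <- a$mass[unitIdx][selLocal]

    blockAtom <- NULL
    if (!is.null(nBlocks)) {
      blockAtom <- vapply(blockFrames,
                          function(fr) .msfFromAligned(aligned, fr)[selLocal],
                          numeric(length(selLocal)))
      if (length(selLocal) == 1L) blockAtom <- matrix(blockAtom, nrow = 1L)
    }
    seOf <- function(v) stats::sd(v) / sqrt(length(v))

    atomIndex <- c(atomIndex, unitIdx[selLocal])
    perAtom <- c(perAtom, msfSel)
    perAtomSe <- c(perAtomSe, if (is.null(blockAtom)) rep(NA_real_, length(selLocal))
                              else apply(blockAtom, 1L, seOf))

    rid <- a$residueIndex[unitIdx][selLocal]
    for (r in sort(unique(rid))) {
      sub <- which(rid == r)
      resMsf <- .massAverage(msfSel[sub], masses[sub])
      resSe <- NA_real_
      if (!is.null(blockAtom)) {
        bv <- apply(blockAtom[sub, , drop = FALSE], 2L,
                    .massAverage, masses = masses[sub])
        resSe <- seOf(bv)
      }
      resRows[[length(resRows) + 1L]] <- data.frame(
        proteinIndex = k, residueIndex = r,
        residueName = a$residueName[unitIdx][selLocal][sub][1L],
        msf = resMsf, se = resSe)
    }

    perProtein <- c(perProtein, .massAverage(msfSel, masses))
    if (!is.null(blockAtom)) {
      bp <- apply(blockAtom, 2L, .massAverage, masses = masses)
      perProteinSe <- c(perProteinSe, seOf(bp))
      blockEnsemble[, ui] <- bp
    } else {
      perProteinSe <- c(perProteinSe, NA_real_)
    }
  }

  ensemble <- mean(perProtein)
  ensembleSe <- NA_real_
  if (!is.null(nBlocks)) {
    bv <- rowMeans(blockEnsemble, na.rm = TRUE)
    ensembleSe <- stats::sd(bv) / sqrt(nBlocks)
  }

  new("MSFResult",
      perAtom = stats::setNames(perAtom, atomIndex),
      perAtomSe = stats::setNames(perAtomSe, atomIndex),
      atomIndex = atomIndex,
      perResidue = do.call(rbind, resRows),
      perProtein = perProtein, perProteinSe = perProteinSe,
      ensemble = ensemble, ensembleSe = ensembleSe,
      selectionLabel = selection,
      nFrames = as.integer(nF),
      nBlocks = if (is.null(nBlocks)) NA_integer_ else nBlocks)
}

#' Block-averaged standard errors of the MSF
#'
#' Splits the trajectory into \code{nBlocks} contiguous equal-length blocks
#' (remainder frames at the end are dropped), computes the MSF independently
#' per block against the global frame-1 reference, and reports standard errors
#' sd(block values)/sqrt(nBlocks) at every aggregation level.
#'
#' @inheritParams computeMSF
#' @param nBlocks number of blocks (default 5).
#' @return list with \code{perAtomSe}, \code{perResidueSe} (data.frame),
#'   \code{perProteinSe}, \code{ensembleSe}.
#' @export
blockErrors <- function(traj, selection = "heavy", alignSelection = "heavy",
                        nBlocks = 5L) {
  res <- computeMSF(traj, selection, alignSelection, nBlocks = nBlocks)
  list(perAtomSe = res@perAtomSe,
       perResidueSe = res@perResidue[, c("proteinIndex", "residueIndex", "se")],
       perProteinSe = res@perProteinSe,
       ensembleSe = res@ensembleSe)
}
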