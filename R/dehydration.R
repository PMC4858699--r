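#' @include transition-detect.R
NULL

#' @rdname hydrationLevel
#' @export
setMethod("hydrationLevel", "PowderConfig", function(x, ...) {
  if (x@nProteins == 0L) .stopf("protein mass is zero")
  nrow(x@waters) * .waterMass / (x@nProteins * proteinMass(x@sequence))
})

#' @rdname hydrationLevel
#' @export
setMethod("hydrationLevel", "Topology", function(x, ...) {
  x@waterCount * .waterMass / (x@nProteins * proteinMass(x@sequence))
})

#' Water count needed for a target hydration level
#'
#' Inverts the hydration-level formula: N = round(h * nProteins * M_protein /
#' M_water), with masses from the bundled average-mass tables.
#'
#' @param h target hydration level, g water / g protein.
#' @param nProteins number of protein units.
#' @param sequence one-letter sequence of one unit.
#' @return integer water count.
#' @examples
#' watersForHydration(0.40, 16, trpCageSequence())  # 771
#' @export
watersForHydration <- function(h, nProteins, sequence = trpCageSequence()) {
  as.integer(round(h * nProteins * proteinMass(sequence) / .waterMass))
}

#' Metropolis acceptance probability for a water removal
#'
#' p = min(1, exp(-beta * deltaU)) with deltaU the configurational energy of
#' the system without the water minus the energy with it. Strongly bound
#' waters (deltaU > 0) are removed with low probability; downhill removals
#' (deltaU <= 0) are always accepted. Overflow for large negative deltaU is
#' guarded.
#'
#' @param deltaU energy change on removal, kJ/mol (vectorised).
#' @param beta inverse thermal energy 1/(k_B T), mol/kJ.
#' @return acceptance probability in [0, 1].
#' @export
removalAcceptance <- function(deltaU, beta) {
  if (beta <= 0) .stopf("beta must be positive")
  ifelse(deltaU <= 0, 1, exp(-beta * deltaU))
}

#' Inverse thermal energy
#'
#' beta = 1/(k_B T) in mol/kJ, with k_B = 0.0083144626 kJ/(mol K).
#' @param temperature K (default 300, the temperature at which dehydration
#'   cycles are run).
#' @return beta in mol/kJ.
#' @export
inverseBeta <- function(temperature = 300) 1 / (.kB * temperature)

#' Toy interaction energy of a powder configuration
#'
#' Pairwise Lennard-Jones plus Coulomb energy over water-protein and
#' water-water site pairs with a 10 Angstrom cutoff; a deliberately small,
#' deterministic desk-scale interaction model for exercising the dehydration
#' protocol (protein-protein terms are constant for rigid units and omitted).
#'
#' @param config a [PowderConfig-class].
#' @param cutoff pair cutoff in Angstrom (default 10).
#' @return energy in kJ/mol.
#' @export
toyEnergy <- function(config, cutoff = 10) {
  w <- config@waters
  if (nrow(w) == 0L) return(0)
  p <- config@proteinSites
  fCoul <- 1389.35  # kJ Angstrom / (mol e^2)
  pairEnergy <- function(xyz1, q1, e1, s1, xyz2, q2, e2, s2) {
    total <- 0
    for (i in seq_len(nrow(xyz1))) {
      d <- sqrt(rowSums(sweep(xyz2, 2L, xyz1[i, ])^2))
      if (any(d < 0.5)) .stopf("overlapping sites (< 0.5 Angstrom)")
      keep <- d <= cutoff
      if (!any(keep)) next
      eps <- sqrt(e1[i] * e2[keep]); sig <- (s1[i] + s2[keep]) / 2
      sr6 <- (sig / d[keep])^6
      total <- total + sum(4 * eps * (sr6^2 - sr6) + fCoul * q1[i] * q2[keep] / d[keep])
    }
    total
  }
  wxyz <- as.matrix(w[, c("x", "y", "z")])
  u <- 0
  if (nrow(p) > 0L) {
    u <- u + pairEnergy(wxyz, w$charge, w$eps, w$sigma,
                        as.matrix(p[, c("x", "y", "z")]), p$charge, p$eps, p$sigma)
  }
  if (nrow(w) > 1L) {
    for (i in seq_len(nrow(w) - 1L)) {
      rest <- (i + 1L):nrow(w)
      d <- sqrt(rowSums(sweep(wxyz[rest, , drop = FALSE], 2L, wxyz[i, ])^2))
      if (any(d < 0.5)) .stopf("overlapping sites (< 0.5 Angstrom)")
      keep <- d <= cutoff
      if (!any(keep)) next
      eps <- sqrt(w$eps[i] * w$eps[rest][keep])
      sig <- (w$sigma[i] + w$sigma[rest][keep]) / 2
      sr6 <- (sig / d[keep])^6
      u <- u + sum(4 * eps * (sr6^2 - sr6) +
                     fCoul * w$charge[i] * w$charge[rest][keep] / d[keep])
    }
  }
  u
}

#' Energy model from tagged water binding energies
#'
#' A simple configurational energy for toy powders built by
#' [makePowderConfig()]: U = -sum of the binding energies of the waters
#' present, so removing water w costs deltaU = +bindingEnergy(w).
#'
#' @param config a [PowderConfig-class].
#' @return energy in kJ/mol.
#' @export
waterBindingEnergy <- function(config) {
  -sum(config@waters$bindingEnergy)
}

#' Metropolis water-removal dehydration
#'
#' Prepares a lower-hydration powder from a hydrated configuration by cycles
#' of: pick a water uniformly at random, compute the configurational energy
#' change deltaU of removing it (energy without minus energy with), accept
#' with probability min(1, exp(-beta deltaU)), and on acceptance delete the
#' water and apply the relaxation hook. Rejected waters stay and may be
#' re-proposed later. The loop stops once the hydration level is at or below
#' the target. Strongly bound waters are thereby preferentially retained,
#' avoiding large perturbations of the protein structure. Protein and ion
#' records are never modified.
#'
#' @param config a [PowderConfig-class].
#' @param targetH target hydration level, g/g; must be below the current one.
#' @param energyFn configurational energy function, config -> kJ/mol
#'   (default [waterBindingEnergy()]).
#' @param relaxHook relaxation applied after each accepted removal,
#'   config -> config with unchanged water count semantics (default identity;
#'   in full molecular work this is an NPT relaxation).
#' @param seed RNG seed (default the config's).
#' @param maxAttempts safety cap on proposals (default 1e6).
#' @return list with \code{config} (the dehydrated [PowderConfig-class]) and
#'   \code{log}, a data.frame of every proposal: \code{attempt},
#'   \code{waterId}, \code{deltaU}, \code{accepted}.
#' @export
dehydrate <- function(config, targetH, energyFn = waterBindingEnergy,
                      relaxHook = identity, seed = config@rngSeed,
                      maxAttempts = 1e6) {
  h0 <- hydrationLevel(config)
  if (targetH > h0 + 1e-12) {
    .stopf("target hydration %.4f is above the current level %.4f", targetH, h0)
  }
  logRows <- list()
  withSeed(seed, {
    attempt <- 0L
    while (hydrationLevel(config) > targetH && nrow(config@waters) > 0L) {
      attempt <- attempt + 1L
      if (attempt > maxAttempts) .stopf("dehydration did not reach the target within %g attempts", maxAttempts)
      i <- sample.int(nrow(config@waters), 1L)
      wid <- config@waters$waterId[i]
      without <- config
      without@waters <- config@waters[-i, , drop = FALSE]
      uWith <- energyFn(config)
      uWithout <- energyFn(without)
      if (!is.finite(uWith) || !is.finite(uWithout)) {
        .stopf("energy function returned a non-finite value (partial log has %d entries)",
               length(logRows))
      }
      deltaU <- uWithout - uWith
      accepted <- stats::runif(1L) < removalAcceptance(deltaU, config@beta)
      logRows[[length(logRows) + 1L]] <- data.frame(
        attempt = attempt, waterId = wid, deltaU = deltaU, accepted = accepted)
      if (accepted) {
        config <- relaxHook(without)
      }
    }
  })
  list(config = config,
       log = if (length(logRows)) do.call(rbind, logRows)
             else data.frame(attempt = integer(0), waterId = integer(0),
                             deltaU = numeric(0), accepted = logical(0)))
}
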