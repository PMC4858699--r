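#' @include msf-engine.R
NULL

# Exhaustive two-segment breakpoint search. Candidates are midpoints between
# consecutive data temperatures with at least minSeg points on each side; at
# each candidate two independent OLS lines are fitted and the candidate with
# the smallest total SSE wins (ties toward the lowest candidate). The
# two-regime p-value is the 4-vs-2-parameter F test, Bonferroni-adjusted for
# the number of candidates scanned, so that the post-search test keeps its
# nominal size.
.segmentedSearch <- function(x, y, minSeg = 3L) {
  n <- length(x)
  cands <- (x[-n] + x[-1L]) / 2
  ok <- vapply(cands, function(cc) sum(x < cc) >= minSeg && sum(x > cc) >= minSeg,
               logical(1L))
  cands <- cands[ok]
  if (!length(cands)) .stopf("too few points for a two-segment fit")

  single <- .ols(x, y)
  best <- NULL
  for (cc in cands) {
    lo <- x < cc
    fl <- .ols(x[lo], y[lo])
    fh <- .ols(x[!lo], y[!lo])
    sse <- fl$sse + fh$sse
    if (is.null(best) || sse < best$sse - 1e-12 * max(1, best$sse)) {
      best <- list(cand = cc, low = fl, high = fh, sse = sse)
    }
  }
  scale <- max(sum(y^2), .Machine$double.eps)
  improvement <- single$sse - best$sse
  if (improvement <= 1e-10 * scale) {
    p <- 1
  } else if (best$sse <= 1e-10 * scale) {
    p <- 0
  } else {
    Fstat <- (improvement / 2) / (best$sse / (n - 4L))
    p <- min(1, length(cands) * stats::pf(Fstat, 2, n - 4L, lower.tail = FALSE))
  }
  list(best = best, pTwoRegime = p, single = single, nCandidates = length(cands))
}

.asSegmentedFit <- function(search, x, fitSpace) {
  b <- search$best
  new("SegmentedFit",
      breakpoint = b$cand,
      slopeLow = b$low$slope, interceptLow = b$low$intercept,
      slopeHigh = b$high$slope, interceptHigh = b$high$intercept,
      sse = b$sse, sseSingle = search$single$sse,
      pTwoRegime = search$pTwoRegime, fitSpace = fitSpace,
      residSigmaLow = b$low$sigma, residSigmaHigh = b$high$sigma,
      range = range(x), nCandidates = as.integer(search$nCandidates))
}

#' Fit the low-temperature harmonic line
#'
#' Ordinary least squares of the series values against temperature restricted
#' to the deep-harmonic window (default 100--150 K), where the MSF is linear
#' in T and independent of hydration level.
#'
#' @param series a [TemperatureSeries-class].
#' @param tMin,tMax window bounds in K (default 100 and 150).
#' @return list with \code{slope}, \code{intercept}, \code{sigma} (residual
#'   sd), \code{slopeSe}, \code{n}.
#' @export
fitHarmonicLow <- function(series, tMin = 100, tMax = 150) {
  keep <- series@temperatures >= tMin & series@temperatures <= tMax
  if (sum(keep) < 3L) .stopf("need >= 3 points in [%g, %g] K", tMin, tMax)
  f <- .ols(series@temperatures[keep], series@values[keep])
  list(slope = f$slope, intercept = f$intercept, sigma = f$sigma,
       slopeSe = f$slopeSe, n = f$n)
}

#' Detect the lower transition temperature T_low
#'
#' Two-segment fit of the harmonic region (T <= \code{tCap}): exhaustive
#' breakpoint search over midpoints between consecutive data temperatures,
#' two independent OLS lines per candidate (each segment keeps >= 3 points),
#' breakpoint = candidate minimising the total SSE. By default the fit runs
#' on log(MSF) vs T (the semi-log view in which both harmonic regimes appear
#' as straight lines); \code{fitSpace = "linear"} fits the values directly.
#'
#' @param series a [TemperatureSeries-class] of MSF vs T.
#' @param tCap upper end of the harmonic window, K (default 210).
#' @param fitSpace "log" (default) or "linear".
#' @return a [SegmentedFit-class]; its \code{pTwoRegime} is the scan-adjusted
#'   two-regime significance (not significant means no T_low).
#' @export
detectTlow <- function(series, tCap = 210, fitSpace = c("log", "linear")) {
  fitSpace <- match.arg(fitSpace)
  keep <- series@temperatures <= tCap
  x <- series@temperatures[keep]
  y <- series@values[keep]
  if (length(x) < 6L) .stopf("need >= 6 points with T <= %g K", tCap)
  if (fitSpace == "log") {
    if (any(y <= 0)) .stopf("log-space fit requires positive values")
    y <- log(y)
  }
  .asSegmentedFit(.segmentedSearch(x, y), x, fitSpace)
}

#' Detect the dynamical transition from the enthalpy series
#'
#' Fits two free lines to enthalpy vs temperature by the same exhaustive
#' breakpoint search (linear space) and reports T_D as the analytic
#' intersection of the two lines; the segment slopes are the heat capacities
#' and their difference is the heat-capacity jump delta_Cp. A transition is
#' declared only when the scan-adjusted two-regime F test is significant at
#' \code{alpha} and the intersection lies inside the data range; otherwise
#' the single-line result is returned with
#' \code{transitionDetected = FALSE} (the behaviour of dehydrated powders,
#' whose enthalpy is a single linear regime).
#'
#' @param hSeries a [TemperatureSeries-class] of enthalpy vs T (>= 8 points
#'   spanning >= 80 K).
#' @param alpha significance level (default 0.01).
#' @return an [EnthalpyFit-class].
#' @export
detectTdEnthalpy <- function(hSeries, alpha = 0.01) {
  x <- hSeries@temperatures
  y <- hSeries@values
  if (length(x) < 8L) .stopf("need >= 8 points")
  if (diff(range(x)) < 80) .stopf("need a temperature span of >= 80 K")
  s <- .segmentedSearch(x, y)
  b <- s$best
  slopeGap <- b$high$slope - b$low$slope
  scaleSlope <- max(abs(b$high$slope), abs(b$low$slope), .Machine$double.eps)
  noFit <- function(diag) {
    new("EnthalpyFit", tD = NA_real_,
        cpLow = s$single$slope, cpHigh = s$single$slope, deltaCp = NA_real_,
        transitionDetected = FALSE, pTwoRegime = s$pTwoRegime, diagnostic = diag)
  }
  if (s$pTwoRegime >= alpha) return(noFit("single-regime"))
  if (abs(slopeGap) < 1e-9 * scaleSlope) return(noFit("parallel-lines"))
  tD <- (b$low$intercept - b$high$intercept) / slopeGap
  if (tD <= min(x) || tD >= max(x)) return(noFit("intersection-outside-range"))
  new("EnthalpyFit", tD = tD,
      cpLow = b$low$slope, cpHigh = b$high$slope, deltaCp = slopeGap,
      transitionDetected = TRUE, pTwoRegime = s$pTwoRegime, diagnostic = "ok")
}

# Persistence-rule onset: first data temperature above tStart at which the
# observed values exceed prediction + band, with every higher temperature
# also exceeding it. Returns NA when never.
.persistentOnset <- function(x, obs, pred, band) {
  above <- obs > pred + band
  if (!length(above) || !any(above)) return(NA_real_)
  # last run of TRUEs reaching the end
  idx <- which(!rev(above))
  nTail <- if (!length(idx)) length(above) else idx[1L] - 1L
  if (nTail == 0L) return(NA_real_)
  x[length(x) - nTail + 1L]
}

#' Detect the dynamical transition from the MSF series
#'
#' Extrapolates the upper harmonic segment of a [SegmentedFit-class] (the
#' T_low..tCap line, in its own fit space) to higher temperatures and reports
#' T_D as the smallest data temperature whose value exceeds the extrapolation
#' by more than \code{kSigma} times max(fit residual sd, point error), with
#' every higher temperature also exceeding it (persistence rule, so a single
#' noisy point cannot declare a transition). Returns NA when the series never
#' leaves the harmonic line (no dynamical transition, as in strongly
#' dehydrated powders).
#'
#' @param series the full [TemperatureSeries-class] of MSF vs T.
#' @param seg the [SegmentedFit-class] from [detectTlow()] on the same series.
#' @param kSigma band width multiplier (default 3).
#' @return T_D in K, or NA when no onset is found.
#' @export
detectTdMsf <- function(series, seg, kSigma = 3) {
  tCap <- seg@range[2L]
  keep <- series@temperatures > tCap
  if (!any(keep)) return(NA_real_)
  x <- series@temperatures[keep]
  obs <- series@values[keep]
  err <- series@errors[keep]
  pred <- seg@interceptHigh + seg@slopeHigh * x
  if (seg@fitSpace == "log") {
    obs <- log(obs)
    err <- ifelse(series@values[keep] > 0, err / series@values[keep], 0)
  }
  # tiny floor guards exact (noise-free) data against roundoff
  band <- kSigma * pmax(seg@residSigmaHigh, err) + 1e-9 * max(abs(obs))
  .persistentOnset(x, obs, pred, band)
}

#' Per-residue transition report
#'
#' Given whole-protein transition temperatures, tests every residue's MSF(T)
#' series for the same two transitions: a slope change at T_low (two-sample
#' slope test between the below-T_low line and the T_low..T_D line, Welch
#' degrees of freedom) and an anharmonic deviation above T_D (persistence
#' rule against the extrapolated mid-segment line). The mean excess over the
#' extrapolation above T_D is reported as the anharmonic amplitude.
#'
#' @param perResidue named list keyed by residue index, each element a
#'   [TemperatureSeries-class].
#' @param tLow,tD whole-protein transition temperatures (K), determined
#'   independently.
#' @param alpha significance of the slope-change test (default 0.05).
#' @param kSigma deviation band multiplier (default 3).
#' @return data.frame with columns \code{residueIndex},
#'   \code{hasTlowSlopeChange}, \code{hasTdDeviation}, \code{slopeMid}
#'   (Angstrom^2/K on T_low <= T <= T_D), \code{amplitudeAboveTd}
#'   (Angstrom^2; NA unless a deviation is flagged).
#' @export
detectResidueTransitions <- function(perResidue, tLow, tD,
                                     alpha = 0.05, kSigma = 3) {
  rows <- list()
  for (nm in names(perResidue)) {
    s <- perResidue[[nm]]
    x <- s@temperatures; y <- s@values; err <- s@errors
    lowW <- x <= tLow
    midW <- x >= tLow & x <= tD
    if (sum(lowW) < 3L || sum(midW) < 3L) {
      .warnf("residue %s: too few temperatures in a fit window; skipped", nm)
      next
    }
    fLow <- .ols(x[lowW], y[lowW])
    fMid <- .ols(x[midW], y[midW])

    hasTlow <- FALSE
    seSum <- sqrt(fLow$slopeSe^2 + fMid$slopeSe^2)
    if (is.finite(seSum) && seSum > 0) {
      tStat <- (fMid$slope - fLow$slope) / seSum
      df <- seSum^4 / (fLow$slopeSe^4 / fLow$df + fMid$slopeSe^4 / fMid$df)
      hasTlow <- 2 * stats::pt(abs(tStat), df, lower.tail = FALSE) < alpha
    } else {
      # exact fits on both windows: any slope difference is real
      hasTlow <- abs(fMid$slope - fLow$slope) >
        1e-9 * max(abs(fMid$slope), abs(fLow$slope), .Machine$double.eps)
    }

    hi <- x > tD
    hasTd <- FALSE; amp <- NA_real_
    if (any(hi)) {
      pred <- fMid$intercept + fMid$slope * x[hi]
      band <- kSigma * pmax(fMid$sigma, err[hi]) + 1e-9 * max(abs(y))
      onset <- .persistentOnset(x[hi], y[hi], pred, band)
      hasTd <- !is.na(onset)
      if (hasTd) amp <- mean(y[hi] - pred)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      residueIndex = as.integer(nm),
      hasTlowSlopeChange = hasTlow, hasTdDeviation = hasTd,
      slopeMid = fMid$slope, amplitudeAboveTd = amp)
  }
  out <- do.call(rbind, rows)
  out[order(out$residueIndex), , drop = FALSE]
}

#' Fit the methyl-hydrogen MSF branches
#'
#' Below T_low the methyl-hydrogen MSF grows exponentially with temperature
#' (rotameric methyl jumps): an OLS of log(MSF) vs T yields the amplitude and
#' rate. At and above T_low the growth is linear: an OLS in linear space.
#'
#' @param series a [TemperatureSeries-class] of methyl-hydrogen MSF (values
#'   must be positive).
#' @param tLow the lower transition temperature (K).
#' @return list with \code{exponential} (logIntercept a, rate b so that
#'   value = exp(a + b T), residual sd sigma) and \code{linear} (slope,
#'   intercept, sigma) components.
#' @export
fitMethyl <- function(series, tLow) {
  x <- series@temperatures; y <- series@values
  if (any(y <= 0)) .stopf("methyl MSF values must be positive")
  lo <- x < tLow
  if (sum(lo) < 3L || sum(!lo) < 3L) .stopf("need >= 3 points on each side of tLow")
  fe <- .ols(x[lo], log(y[lo]))
  fl <- .ols(x[!lo], y[!lo])
  list(exponential = list(logIntercept = fe$intercept, rate = fe$slope,
                          sigma = fe$sigma, rateSe = fe$slopeSe),
       linear = list(slope = fl$slope, intercept = fl$intercept,
                     sigma = fl$sigma))
}
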