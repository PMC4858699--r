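# Internal helpers shared across modules.

# Boltzmann constant, kJ/(mol K)
.kB <- 0.0083144626

# Average molecular mass of water, Da
.waterMass <- 18.015

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps all generators pure functions of (arguments, seed).
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det forced to +1).
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Ordinary least squares of y on x; returns coefficients and diagnostics.
.ols <- function(x, y) {
  n <- length(x)
  fit <- stats::.lm.fit(cbind(1, x), y)
  cf <- fit$coefficients
  sse <- sum(fit$residuals^2)
  sxx <- sum((x - mean(x))^2)
  sigma <- if (n > 2L) sqrt(sse / (n - 2L)) else 0
  list(intercept = cf[1L], slope = cf[2L], sse = sse, sigma = sigma,
       slopeSe = if (sxx > 0) sigma / sqrt(sxx) else NA_real_, n = n, df = n - 2L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
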