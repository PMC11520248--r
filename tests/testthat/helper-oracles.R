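# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (no Levenberg-Marquardt, no transfer matrix).

# Exhaustive grid search for the three-state objective. The model is linear
# in a and b at fixed (c50, d), so for each (c50, d) cell the best grid a
# (and b) is found by evaluating the quadratic objective at the grid points
# bracketing its closed-form minimizer -- identical to scanning the whole
# a/b grid, at desk-scale cost.
gridSearchThreeState <- function(Fm, Dm, fN, urea,
                                 c50Grid = seq(1, 5, by = 0.01),
                                 dGrid = seq(0.1, 1.5, by = 0.01),
                                 abStep = 0.01) {
  abGrid <- seq(0, 1, by = abStep)
  bestAb <- function(num, den, sse0) {
    ## minimize sse0 - 2*x*num + x^2*den over the grid in x
    if (den <= 0) return(c(0, sse0))
    xs <- num / den
    cand <- unique(pmin(pmax(c(floor(xs / abStep), ceiling(xs / abStep)), 0),
                        length(abGrid) - 1L)) * abStep
    sse <- sse0 - 2 * cand * num + cand^2 * den
    i <- which.min(sse)
    c(cand[i], sse[i])
  }
  best <- list(ss = Inf)
  for (c50 in c50Grid) {
    for (d in dGrid) {
      K <- exp((urea - c50) / d)
      fI <- (1 - fN) / (1 + K)
      fU <- K * fI
      rF0 <- fN - Fm          # residual at a = 0
      rD0 <- fU - Dm          # residual at b = 0
      aFit <- bestAb(-sum(fI * rF0), sum(fI^2), sum(rF0^2))
      bFit <- bestAb(-sum(fI * rD0), sum(fI^2), sum(rD0^2))
      ss <- aFit[2] + bFit[2]
      if (ss < best$ss)
        best <- list(c50 = c50, d = d, a = aFit[1], b = bFit[1], ss = ss)
    }
  }
  best
}

# Brute-force helix-coil statistics by enumerating all 2^n configurations.
bruteForceHelicity <- function(n, s, sigmaNuc) {
  z <- 0; nh <- 0
  for (k in 0:(2^n - 1)) {
    st <- as.logical(bitwAnd(k, 2^(0:(n - 1))))
    runs <- sum(st & !c(FALSE, st[-n]))
    w <- s^sum(st) * sigmaNuc^runs
    z <- z + w
    nh <- nh + w * sum(st)
  }
  nh / z / n
}

# Literal per-residue triplet rule, written independently of the package's
# vectorized implementation.
bruteForceTriplet <- function(flags) {
  n <- length(flags)
  out <- rep(FALSE, n)
  if (n >= 3) for (i in 2:(n - 1))
    out[i] <- isTRUE(flags[i - 1]) && isTRUE(flags[i]) && isTRUE(flags[i + 1])
  out
}

# Roughly uniform points on the unit sphere (independent of the package's
# sampling scheme); used to build burial cages.
.spherePointsForTest <- function(n) {
  set.seed(4711)
  p <- matrix(rnorm(3 * n), ncol = 3)
  p / sqrt(rowSums(p^2))
}

# Convenience: full noisy-dataset -> three-state fit pipeline on the
# truth-normalized series.
fitSyntheticDataset <- function(seed, noiseSd = 0.03,
                                truth = ThreeStateParams(3.0, 0.45, 0.81, 0.24),
                                ...) {
  cfg <- GeneratorConfig(truth = truth, noiseSd = noiseSd,
                         seed = as.integer(seed), ...)
  ds <- generateDenaturationDataset(cfg)
  list(ds = ds, fit = fitThreeState(ds$fluorNorm, ds$cdNorm, ds$scatterNorm))
}
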