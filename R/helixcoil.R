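## Desk-scale cooperative helix-coil model: each residue is helical (h) or
## coil (c); a configuration's statistical weight is s^(#h) * sigma^(#h-runs).
## Exact expectations come from a transfer recursion; a Metropolis sampler
## provides the stochastic counterpart. This model is an explicitly
## simplified stand-in for force-field simulations: it reproduces trends of
## helicity versus H-bond strength, not quantitative propensities.

#' Exact mean helicity of the helix-coil model
#'
#' Expected fraction of helical residues, computed exactly by propagating the
#' partition function and its helix-count-weighted companion along the chain
#' (a transfer-matrix recursion). With `sigmaNuc = 1` residues are
#' independent and the result is s/(1+s) for any chain length.
#'
#' @param model a [HelixCoilModel-class].
#' @return expected helical fraction in \[0, 1\].
#' @export
meanHelicityExact <- function(model) {
  stopifnot(is(model, "HelixCoilModel"))
  s <- model@s; sg <- model@sigmaNuc; n <- model@n
  ## Z*: restricted partition sums by last-residue state; N*: companion sums
  ## weighted by the number of helical residues so far
  Zh <- sg * s; Zc <- 1
  Nh <- sg * s; Nc <- 0
  if (n > 1L) for (i in 2:n) {
    Zh2 <- s * (sg * Zc + Zh)
    Nh2 <- s * (sg * Nc + Nh) + Zh2   # current residue contributes 1 per config
    Zc2 <- Zc + Zh
    Nc2 <- Nc + Nh
    sc <- max(Zh2, Zc2)               # rescale to avoid overflow; ratios invariant
    Zh <- Zh2 / sc; Zc <- Zc2 / sc
    Nh <- Nh2 / sc; Nc <- Nc2 / sc
  }
  if (Zh + Zc == 0) return(0)
  (Nh + Nc) / (Zh + Zc) / n
}

# log statistical weight of a configuration (h = TRUE)
.hcLogWeight <- function(state, s, sigmaNuc) {
  runs <- sum(state & !c(FALSE, state[-length(state)]))
  sum(state) * log(s) + runs * log(sigmaNuc)
}

#' Metropolis estimate of the mean helicity
#'
#' Single-flip Metropolis sampling of the helix-coil weights. One sweep
#' attempts one flip per residue; the first 20% of sweeps are discarded as
#' burn-in and the standard error comes from 20 batch means.
#'
#' @param model a [HelixCoilModel-class].
#' @param nSweeps number of sweeps (>= 1).
#' @param seed integer RNG seed (caller's RNG state is preserved).
#' @return named numeric: `mean` and `se`.
#' @export
sampleHelicityMC <- function(model, nSweeps = 1e4, seed = 1L) {
  stopifnot(is(model, "HelixCoilModel"), nSweeps >= 1)
  n <- model@n; s <- model@s; sg <- model@sigmaNuc
  if (s == 0) return(c(mean = 0, se = 0))  # helical states carry zero weight
  logs <- log(s); logsg <- log(sg)
  withSeed(seed, {
    state <- rep(FALSE, n)
    burn <- ceiling(0.2 * nSweeps)
    keep <- nSweeps - burn
    fracs <- numeric(keep)
    for (sw in seq_len(nSweeps)) {
      ii <- sample.int(n, n, replace = TRUE)
      uu <- stats::runif(n)
      for (k in seq_len(n)) {
        i <- ii[k]
        left <- if (i > 1L) state[i - 1L] else FALSE
        right <- if (i < n) state[i + 1L] else FALSE
        ## change in (#h, #runs) when flipping residue i
        if (!state[i]) {
          dRuns <- 1L - (left + right)   # joins/extends/creates runs
          dLog <- logs + dRuns * logsg
        } else {
          dRuns <- (left + right) - 1L   # inverse move
          dLog <- -logs + dRuns * logsg
        }
        if (dLog >= 0 || uu[k] < exp(dLog)) state[i] <- !state[i]
      }
      if (sw > burn) fracs[sw - burn] <- mean(state)
    }
    est <- mean(fracs)
    nb <- min(20L, keep)
    bm <- vapply(split(fracs, cut(seq_len(keep), nb, labels = FALSE)),
                 mean, numeric(1))
    se <- stats::sd(bm) / sqrt(length(bm))
    c(mean = est, se = se)
  })
}

#' Map an H-bond prefactor to a helix propagation weight
#'
#' s(lambda) = exp(lambda * eps / kT - c0), with the single offset c0
#' calibrated so that s = 1 at `lambdaMid` for the reference energy `epsRef`:
#' c0 = lambdaMid * epsRef / kT. Regions with larger eps thus hold s > 1 down
#' to lower lambda (they melt later).
#'
#' @param lambda H-bond prefactor(s) in (0, 1].
#' @param eps per-residue H-bond energy (same units as `epsRef` and `kT`).
#' @param kT thermal energy (default 1: energies in kT units).
#' @param lambdaMid prefactor at which the reference region has s = 1.
#' @param epsRef reference H-bond energy defining the offset c0.
#' @return numeric propagation weight(s).
#' @export
propagationWeight <- function(lambda, eps, kT = 1, lambdaMid = 0.875,
                              epsRef = eps) {
  stopifnot(all(lambda > 0 & lambda <= 1))
  exp(lambda * eps / kT - lambdaMid * epsRef / kT)
}

#' Helicity versus H-bond strength, per region
#'
#' Evaluates the exact mean helicity of the helix-coil model over a
#' descending grid of H-bond prefactors for one or more regions that differ
#' in their per-residue H-bond energy. Output rows are labelled as coming
#' from the simplified stand-in model.
#'
#' @param baseModel a [HelixCoilModel-class] providing `n` and `sigmaNuc`;
#'   its `s` is ignored (recomputed from lambda).
#' @param lambdas numeric prefactors in (0, 1], sorted descending.
#' @param epsByRegion named numeric per-region H-bond energies (kT units).
#' @param kT,lambdaMid see [propagationWeight()]; the offset is calibrated
#'   with `epsRef = mean(epsByRegion)`.
#' @return data.frame with columns `lambda`, `region`, `meanHelicity`,
#'   `model` (constant `"helix-coil stand-in"`).
#' @export
lambdaScan <- function(baseModel, lambdas, epsByRegion, kT = 1,
                       lambdaMid = 0.875) {
  stopifnot(is(baseModel, "HelixCoilModel"), length(epsByRegion) >= 1)
  if (is.unsorted(rev(lambdas)))
    stop("lambdas must be sorted descending", call. = FALSE)
  if (is.null(names(epsByRegion)))
    names(epsByRegion) <- paste0("region", seq_along(epsByRegion))
  epsRef <- mean(epsByRegion)
  out <- expand.grid(lambda = lambdas, region = names(epsByRegion),
                     stringsAsFactors = FALSE)
  out$meanHelicity <- mapply(function(lam, reg) {
    s <- propagationWeight(lam, epsByRegion[[reg]], kT, lambdaMid, epsRef)
    meanHelicityExact(HelixCoilModel(baseModel@n, s, baseModel@sigmaNuc))
  }, out$lambda, out$region)
  out$model <- "helix-coil stand-in"
  out
}
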