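## Seeded synthetic denaturation data: scattering decay, three-state
## fluorescence/CD curves in raw signal units, and full emission/CD spectra.
## Stands in for the study's raw measurements so the whole pipeline is
## testable without any instrument data.

# run expr with a given seed, restoring the caller's RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# noiseless native-oligomer fraction: linear decay to 0 at the breakpoint
.fractionNativeTrue <- function(cfg, urea = cfg@ureaGrid) {
  pmax(0, 1 - urea / cfg@scatterBreakpoint)
}

# noiseless raw signal means for the three probes on the urea grid
.noiselessRaw <- function(cfg) {
  sg <- cfg@signals
  fN <- .fractionNativeTrue(cfg)
  pred <- predictThreeState(cfg@truth, fN, cfg@ureaGrid)
  list(
    fN = fN, Fnorm = pred$Fnorm, Dnorm = pred$Dnorm,
    S = sg@SIU + (sg@SN - sg@SIU) * fN,
    F = sg@FU + (sg@FN - sg@FU) * pred$Fnorm,
    D = sg@DN + (sg@DU - sg@DN) * pred$Dnorm
  )
}

# replicate table (urea, value) with additive Gaussian noise; noise SD is
# noiseSd[probe] times the probe's full signal amplitude
.replicateNoise <- function(cfg, means, amplitude, relSd) {
  u <- rep(cfg@ureaGrid, each = cfg@nRep)
  mu <- rep(means, each = cfg@nRep)
  data.frame(urea = u,
             value = mu + stats::rnorm(length(mu), 0, relSd * amplitude))
}

#' Synthetic static-light-scattering denaturation profile
#'
#' The noiseless mean decreases linearly from the native level `SN` at 0 M to
#' the common intermediate/unfolded level `SIU` at the scattering breakpoint
#' (default 3.5 M urea; `SN/SIU` defaults to 6) and is constant beyond it.
#' Seeded Gaussian replicate noise is added on the raw signal.
#'
#' @param cfg a [GeneratorConfig-class].
#' @return a raw-unit scattering [DenaturationSeries-class].
#' @export
generateScatteringProfile <- function(cfg) {
  stopifnot(is(cfg, "GeneratorConfig"))
  sg <- cfg@signals
  means <- sg@SIU + (sg@SN - sg@SIU) * .fractionNativeTrue(cfg)
  withSeed(cfg@seed, {
    pts <- .replicateNoise(cfg, means, sg@SN - sg@SIU, cfg@noiseSd[["scattering"]])
    buildDenaturationSeries(pts, probeLabel = "scatter300")
  })
}

#' Synthetic three-probe denaturation dataset
#'
#' Forward-simulates the three-state model on the urea grid: the native
#' fraction follows the noiseless scattering decay, the intermediate-unfolded
#' equilibrium follows the generating LEM parameters, and normalized signals
#' are rescaled into raw units via the per-species signal levels before
#' replicate noise is added.
#'
#' Both raw-unit series (as an instrument would deliver) and truth-normalized
#' series (normalized with the exact per-species levels, as used for model
#' round-trips) are returned; analysis of the raw series goes through
#' [buildDenaturationSeries()] and [normalizeSeries()].
#'
#' @param cfg a [GeneratorConfig-class].
#' @return list with raw [DenaturationSeries-class] elements `scatter`,
#'   `fluor`, `cd`; truth-normalized `scatterNorm`, `fluorNorm`, `cdNorm`;
#'   and `truth` (list with the generating parameters, signal levels and
#'   noiseless native fractions).
#' @examples
#' ds <- generateDenaturationDataset(GeneratorConfig(seed = 7L))
#' ds$fluorNorm
#' @export
generateDenaturationDataset <- function(cfg) {
  stopifnot(is(cfg, "GeneratorConfig"))
  sg <- cfg@signals
  nl <- .noiselessRaw(cfg)
  withSeed(cfg@seed, {
    ptsS <- .replicateNoise(cfg, nl$S, sg@SN - sg@SIU, cfg@noiseSd[["scattering"]])
    ptsF <- .replicateNoise(cfg, nl$F, sg@FN - sg@FU, cfg@noiseSd[["fluorescence"]])
    ptsD <- .replicateNoise(cfg, nl$D, abs(sg@DU - sg@DN), cfg@noiseSd[["cd"]])

    scatter <- buildDenaturationSeries(ptsS, "scatter300")
    fluor   <- buildDenaturationSeries(ptsF, "I335")
    cd      <- buildDenaturationSeries(ptsD, "CD222")

    normalizeWith <- function(series, zero, one, label) {
      initialize(series,
        mean = (series@mean - zero) / (one - zero),
        sd = series@sd / abs(one - zero),
        probeLabel = label, normalized = TRUE)
    }
    list(
      scatter = scatter, fluor = fluor, cd = cd,
      scatterNorm = normalizeWith(scatter, sg@SIU, sg@SN, "Snorm"),
      fluorNorm   = normalizeWith(fluor, sg@FU, sg@FN, "Fnorm"),
      cdNorm      = normalizeWith(cd, sg@DN, sg@DU, "Dnorm"),
      truth = list(params = cfg@truth, signals = sg, fN = nl$fN,
                   Fnorm = nl$Fnorm, Dnorm = nl$Dnorm, ureaGrid = cfg@ureaGrid)
    )
  })
}

# helix-like CD shape (negative bands at 208 and 222 nm plus a positive band
# near 193 nm) and coil-like shape (single negative band near 200 nm), both
# scaled to +1 at 222 nm so that multiplying by a (negative) per-species
# 222 nm level reproduces that level exactly at 222 nm
.cdShapeRaw <- function(wl) {
  0.9 * exp(-(wl - 193)^2 / (2 * 5^2)) -
    1.00 * exp(-(wl - 208)^2 / (2 * 5^2)) -
    0.98 * exp(-(wl - 222)^2 / (2 * 5.5^2))
}

.cdHelixShape <- function(wl) .cdShapeRaw(wl) / .cdShapeRaw(222)

.cdCoilShape <- function(wl) {
  exp(-(wl - 201)^2 / (2 * 10^2)) / exp(-(222 - 201)^2 / (2 * 10^2))
}

#' Synthetic emission and CD spectra across the urea titration
#'
#' Emission spectra are population-weighted mixtures of Gaussian bands
#' centred at `lambdaNative` (native and intermediate, whose Trp stays inside
#' the coiled-coil) and `lambdaUnfolded` (unfolded); band amplitudes are set
#' so that the signal at `lambdaNative` reproduces the per-species
#' fluorescence levels. CD spectra mix a helix-like basis (negative bands at
#' 208 and 222 nm) and a coil-like basis (single negative band near 200 nm),
#' scaled so the 222 nm value reproduces the per-species CD levels.
#'
#' @param cfg a [GeneratorConfig-class].
#' @param emissionGrid,cdGrid wavelength grids in nm.
#' @return list with elements `emission` and `cd`, each a list of
#'   [Spectrum-class] objects (one per urea concentration and replicate).
#' @export
generateSpectraSet <- function(cfg, emissionGrid = 300:450, cdGrid = 190:250) {
  stopifnot(is(cfg, "GeneratorConfig"))
  sg <- cfg@signals
  nl <- .noiselessRaw(cfg)
  fr <- fractionsThreeState(cfg@truth, nl$fN, cfg@ureaGrid)
  bandw <- 18  # nm, Gaussian SD of the emission bands

  gN <- exp(-(emissionGrid - cfg@lambdaNative)^2 / (2 * bandw^2))
  gU <- exp(-(emissionGrid - cfg@lambdaUnfolded)^2 / (2 * bandw^2))
  ## amplitude of the unfolded band chosen so its contribution AT lambdaNative
  ## equals FU, keeping the extracted I335 series consistent with the
  ## denaturation dataset
  att <- exp(-(cfg@lambdaNative - cfg@lambdaUnfolded)^2 / (2 * bandw^2))
  helixShape <- .cdHelixShape(cdGrid)
  coilShape <- .cdCoilShape(cdGrid)

  withSeed(cfg@seed + 1L, {
    emission <- list(); cd <- list(); k <- 0L
    for (i in seq_along(cfg@ureaGrid)) {
      u <- cfg@ureaGrid[i]
      emMean <- (fr@fN[i] * sg@FN + fr@fI[i] * sg@FI) * gN +
                fr@fU[i] * (sg@FU / att) * gU
      cdMean <- (fr@fN[i] * sg@DN + fr@fI[i] * sg@DI) * helixShape +
                fr@fU[i] * sg@DU * coilShape
      for (r in seq_len(cfg@nRep)) {
        k <- k + 1L
        emission[[k]] <- Spectrum(emissionGrid,
          emMean + stats::rnorm(length(emissionGrid), 0,
                                cfg@noiseSd[["fluorescence"]] * sg@FN),
          probe = "fluorescence", urea = u, replicate = r)
        cd[[k]] <- Spectrum(cdGrid,
          cdMean + stats::rnorm(length(cdGrid), 0,
                                cfg@noiseSd[["cd"]] * abs(sg@DN)),
          probe = "cd", urea = u, replicate = r)
      }
    }
    list(emission = emission, cd = cd)
  })
}

#' Simulated exponential-decay kinetic trace
#'
#' Minimal single-exponential helper for exercising [normalizeKinetics()]:
#' value(t) = plateau + amplitude * exp(-rate * t), sampled on a log-spaced
#' time grid.
#'
#' @param rate decay rate, 1/s.
#' @param amplitude,plateau signal amplitude and final level.
#' @param ureaFinal final urea concentration, mol/L.
#' @param tMin,tMax,n time grid specification (s).
#' @return a [KineticTrace-class].
#' @export
simulateKineticTrace <- function(rate = 0.1, amplitude = 40, plateau = 10,
                                 ureaFinal = 4, tMin = 0.001, tMax = 200,
                                 n = 400) {
  tt <- exp(seq(log(tMin), log(tMax), length.out = n))
  KineticTrace(tt, plateau + amplitude * exp(-rate * tt),
               probe = "fluorescence", ureaFinal = ureaFinal)
}
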