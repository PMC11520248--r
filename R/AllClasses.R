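#' @import methods
NULL

setClassUnion("integerOrNumeric", c("integer", "numeric"))

## ---------------------------------------------------------------------------
## Spectroscopy containers
## ---------------------------------------------------------------------------

#' Spectrum: one wavelength-resolved measurement at one urea concentration
#'
#' A single emission, CD or scattering spectrum recorded at a fixed urea
#' concentration. Wavelengths are a strictly increasing grid in nm; values are
#' in probe-native units (counts per second for fluorescence/scattering,
#' ellipticity for CD).
#'
#' @slot wavelengths numeric, nm, strictly increasing.
#' @slot values numeric, same length as `wavelengths`.
#' @slot probe character, one of `"fluorescence"`, `"cd"`, `"scattering"`.
#' @slot urea numeric scalar, mol/L, >= 0.
#' @slot replicate integer scalar replicate id.
#' @export
setClass("Spectrum",
  representation(
    wavelengths = "numeric",
    values      = "numeric",
    probe       = "character",
    urea        = "numeric",
    replicate   = "integer"
  ),
  prototype(probe = "fluorescence", urea = 0, replicate = 1L)
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@wavelengths) != length(object@values))
    msg <- c(msg, "wavelengths and values must have equal length")
  if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!object@probe %in% c("fluorescence", "cd", "scattering"))
    msg <- c(msg, "probe must be 'fluorescence', 'cd' or 'scattering'")
  if (length(object@urea) != 1L || is.na(object@urea) || object@urea < 0)
    msg <- c(msg, "urea must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param wavelengths numeric vector of wavelengths in nm.
#' @param values numeric vector of signal values.
#' @param probe `"fluorescence"`, `"cd"` or `"scattering"`.
#' @param urea urea concentration in mol/L.
#' @param replicate integer replicate id.
#' @return A [Spectrum-class] object; rows are sorted by wavelength.
#' @examples
#' sp <- Spectrum(300:450, dnorm(300:450, 335, 12), probe = "fluorescence")
#' lambdaMax(sp)
#' @export
Spectrum <- function(wavelengths, values, probe = c("fluorescence", "cd", "scattering"),
                     urea = 0, replicate = 1L) {
  probe <- match.arg(probe)
  ord <- order(wavelengths)
  new("Spectrum",
    wavelengths = as.numeric(wavelengths[ord]),
    values = as.numeric(values[ord]),
    probe = probe, urea = as.numeric(urea), replicate = as.integer(replicate))
}

#' DenaturationSeries: extracted scalar signal versus urea
#'
#' Per-concentration replicate mean, sample SD and replicate count of one
#' scalar probe (e.g. I335, CD222, scatter300) across a urea titration.
#'
#' @slot urea numeric, mol/L, sorted ascending, unique.
#' @slot mean numeric signal means.
#' @slot sd numeric sample standard deviations (>= 0).
#' @slot nRep integer replicate counts.
#' @slot probeLabel character label, e.g. `"I335"`.
#' @slot normalized logical scalar; `TRUE` after [normalizeSeries()].
#' @export
setClass("DenaturationSeries",
  representation(
    urea       = "numeric",
    mean       = "numeric",
    sd         = "numeric",
    nRep       = "integer",
    probeLabel = "character",
    normalized = "logical"
  ),
  prototype(probeLabel = "", normalized = FALSE)
)

setValidity("DenaturationSeries", function(object) {
  msg <- character()
  n <- length(object@urea)
  if (length(object@mean) != n || length(object@sd) != n || length(object@nRep) != n)
    msg <- c(msg, "urea, mean, sd and nRep must have equal length")
  if (n > 1L && any(diff(object@urea) <= 0))
    msg <- c(msg, "urea must be sorted ascending and unique")
  if (any(object@sd < 0, na.rm = TRUE))
    msg <- c(msg, "sd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a DenaturationSeries
#'
#' @param urea numeric urea concentrations, mol/L.
#' @param mean numeric signal means.
#' @param sd numeric standard deviations, default 0.
#' @param nRep integer replicate counts, default 1.
#' @param probeLabel character probe label.
#' @param normalized logical, whether the series is on the normalized scale.
#' @return A [DenaturationSeries-class] sorted by urea.
#' @export
DenaturationSeries <- function(urea, mean, sd = rep(0, length(urea)),
                               nRep = rep(1L, length(urea)),
                               probeLabel = "", normalized = FALSE) {
  ord <- order(urea)
  new("DenaturationSeries",
    urea = as.numeric(urea[ord]), mean = as.numeric(mean[ord]),
    sd = as.numeric(sd[ord]), nRep = as.integer(nRep[ord]),
    probeLabel = probeLabel, normalized = isTRUE(normalized))
}

#' KineticTrace: a stopped-flow style time course at one final urea concentration
#'
#' @slot time numeric, seconds, strictly increasing, all > 0.
#' @slot values numeric signal.
#' @slot probe character probe kind.
#' @slot ureaFinal numeric final urea concentration, mol/L.
#' @export
setClass("KineticTrace",
  representation(time = "numeric", values = "numeric",
                 probe = "character", ureaFinal = "numeric"),
  prototype(probe = "fluorescence", ureaFinal = 0)
)

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@values))
    msg <- c(msg, "time and values must have equal length")
  if (length(object@time) && (min(object@time) <= 0 || any(diff(object@time) <= 0)))
    msg <- c(msg, "time must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' @rdname KineticTrace-class
#' @param time numeric times in seconds.
#' @param values numeric signal values.
#' @param probe probe kind.
#' @param ureaFinal final urea concentration, mol/L.
#' @export
KineticTrace <- function(time, values, probe = "fluorescence", ureaFinal = 0) {
  new("KineticTrace", time = as.numeric(time), values = as.numeric(values),
      probe = probe, ureaFinal = as.numeric(ureaFinal))
}

## ---------------------------------------------------------------------------
## Equilibrium model parameters
## ---------------------------------------------------------------------------

#' Linear extrapolation model (LEM) parameters for the I-U equilibrium
#'
#' The denaturant dependence of the intermediate/unfolded equilibrium constant
#' is K(U) = exp(-(c50 - U)/d), where `c50` is the urea concentration at which
#' K = 1 (the transition midpoint) and `d = RT/m` is the reciprocal m-value in
#' concentration units.
#'
#' @slot c50 numeric, mol/L, >= 0.
#' @slot d numeric, mol/L, > 0.
#' @export
setClass("LEMParams", representation(c50 = "numeric", d = "numeric"))

setValidity("LEMParams", function(object) {
  msg <- character()
  if (length(object@c50) != 1L || is.na(object@c50) || object@c50 < 0)
    msg <- c(msg, "c50 must be a single non-negative number")
  if (length(object@d) != 1L || is.na(object@d) || object@d <= 0)
    msg <- c(msg, "d must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname LEMParams-class
#' @param c50 transition midpoint, mol/L.
#' @param d RT/m in mol/L.
#' @export
LEMParams <- function(c50, d) new("LEMParams", c50 = as.numeric(c50), d = as.numeric(d))

#' Three-state model parameters
#'
#' LEM parameters for the intermediate-unfolded step plus the two
#' signal-contrast constants: `a = (F_I - F_U)/(F_N - F_U)` for fluorescence
#' and `b = (D_I - D_N)/(D_U - D_N)` for CD.
#'
#' @slot lem a [LEMParams-class].
#' @slot a numeric fluorescence contrast constant.
#' @slot b numeric CD contrast constant.
#' @export
setClass("ThreeStateParams",
  representation(lem = "LEMParams", a = "numeric", b = "numeric"))

setValidity("ThreeStateParams", function(object) {
  msg <- character()
  if (length(object@a) != 1L || !is.finite(object@a))
    msg <- c(msg, "a must be a single finite number")
  if (length(object@b) != 1L || !is.finite(object@b))
    msg <- c(msg, "b must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @rdname ThreeStateParams-class
#' @param c50 transition midpoint, mol/L.
#' @param d RT/m, mol/L.
#' @param a fluorescence contrast constant.
#' @param b CD contrast constant.
#' @export
ThreeStateParams <- function(c50, d, a, b)
  new("ThreeStateParams", lem = LEMParams(c50, d), a = as.numeric(a), b = as.numeric(b))

#' Species fractions of the three-state system
#'
#' Fractions of total protein in the native oligomer (N), intermediate (I) and
#' unfolded (U) states. Vectors are allowed (one element per urea point);
#' elementwise fN + fI + fU = 1.
#'
#' @slot fN,fI,fU numeric fractions in \[0, 1\].
#' @export
setClass("SpeciesFractions",
  representation(fN = "numeric", fI = "numeric", fU = "numeric"))

setValidity("SpeciesFractions", function(object) {
  msg <- character()
  n <- length(object@fN)
  if (length(object@fI) != n || length(object@fU) != n)
    msg <- c(msg, "fN, fI, fU must have equal length")
  rng <- range(c(object@fN, object@fI, object@fU), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(abs(object@fN + object@fI + object@fU - 1) > 1e-9))
    msg <- c(msg, "fractions must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Thermodynamic context: temperature and gas constant
#'
#' @slot temperature numeric, K (default 293.15 K, the 20 degree C measurement
#'   temperature).
#' @slot R numeric gas constant, J/(mol K).
#' @export
setClass("ThermoContext",
  representation(temperature = "numeric", R = "numeric"),
  prototype(temperature = 293.15, R = 8.31446261815324))

setValidity("ThermoContext", function(object) {
  if (length(object@temperature) != 1L || object@temperature <= 0)
    "temperature must be a single positive number" else TRUE
})

#' @rdname ThermoContext-class
#' @param temperature temperature in K.
#' @param R gas constant in J/(mol K).
#' @export
ThermoContext <- function(temperature = 293.15, R = 8.31446261815324)
  new("ThermoContext", temperature = as.numeric(temperature), R = as.numeric(R))

## ---------------------------------------------------------------------------
## Fit results
## ---------------------------------------------------------------------------

#' Result of a global denaturation-curve fit
#'
#' @slot params a [ThreeStateParams-class] or [LEMParams-class] at the optimum.
#' @slot standardErrors named numeric, one per free parameter.
#' @slot covariance covariance matrix of the free parameters.
#' @slot residualSS residual sum of squares of the (weighted) objective.
#' @slot nObs number of residuals entering the objective.
#' @slot converged logical convergence flag.
#' @slot fixedBZero logical; `TRUE` if b was held at 0.
#' @slot model character, `"three_state"` or `"two_state"`.
#' @slot residuals list with per-probe residual vectors at the optimum.
#' @slot warnings character vector of diagnostic flags (e.g. midpoint outside
#'   the measured range).
#' @export
setClass("FitResult",
  representation(
    params         = "ANY",
    standardErrors = "numeric",
    covariance     = "matrix",
    residualSS     = "numeric",
    nObs           = "integer",
    converged      = "logical",
    fixedBZero     = "logical",
    model          = "character",
    residuals      = "list",
    warnings       = "character"
  ),
  prototype(fixedBZero = FALSE, warnings = character())
)

setValidity("FitResult", function(object) {
  msg <- character()
  if (any(object@standardErrors < 0, na.rm = TRUE))
    msg <- c(msg, "standard errors must be non-negative")
  if (nrow(object@covariance) != ncol(object@covariance))
    msg <- c(msg, "covariance must be square")
  if (isTRUE(object@converged)) {
    p <- object@params
    ok <- if (is(p, "ThreeStateParams"))
      all(is.finite(c(p@lem@c50, p@lem@d, p@a, p@b)))
    else all(is.finite(c(p@c50, p@d)))
    if (!ok) msg <- c(msg, "converged fits must carry finite parameters")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic-data generator configuration
## ---------------------------------------------------------------------------

#' Specific signal levels of the three species
#'
#' Raw-unit signal levels used by the synthetic generator: fluorescence
#' (`FN`, `FI`, `FU`), CD (`DN`, `DI`, `DU`), and scattering of the native
#' oligomer (`SN`) versus the common level of intermediate and unfolded
#' monomers (`SIU`). Defaults place the native scattering six-fold above the
#' dissociated plateau, and make the implied contrast constants
#' a = (FI-FU)/(FN-FU) = 0.81 and b = (DI-DN)/(DU-DN) = 0.24.
#'
#' @slot FN,FI,FU numeric fluorescence levels (counts/s).
#' @slot DN,DI,DU numeric CD levels (ellipticity; negative for helix).
#' @slot SN,SIU numeric scattering levels (counts/s).
#' @export
setClass("SpeciesSignals",
  representation(FN = "numeric", FI = "numeric", FU = "numeric",
                 DN = "numeric", DI = "numeric", DU = "numeric",
                 SN = "numeric", SIU = "numeric"))

setValidity("SpeciesSignals", function(object) {
  msg <- character()
  if (object@FN <= object@FU)
    msg <- c(msg, "FN must exceed FU (fluorescence drops on unfolding)")
  if (object@SN <= object@SIU)
    msg <- c(msg, "SN must exceed SIU (oligomers scatter more)")
  if (!is.finite((object@FI - object@FU) / (object@FN - object@FU)))
    msg <- c(msg, "derived a must be finite")
  if (!is.finite((object@DI - object@DN) / (object@DU - object@DN)))
    msg <- c(msg, "derived b must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname SpeciesSignals-class
#' @param FN,FI,FU fluorescence levels of N, I, U.
#' @param DN,DI,DU CD levels of N, I, U.
#' @param SN,SIU scattering levels of the oligomer and of I/U.
#' @export
SpeciesSignals <- function(FN = 1e6, FI = NULL, FU = 0.3e6,
                           DN = -20, DI = NULL, DU = -2,
                           SN = 6e5, SIU = 1e5) {
  ## defaults chosen so the implied contrasts match a = 0.81, b = 0.24
  if (is.null(FI)) FI <- FU + 0.81 * (FN - FU)
  if (is.null(DI)) DI <- DN + 0.24 * (DU - DN)
  new("SpeciesSignals", FN = FN, FI = FI, FU = FU,
      DN = DN, DI = DI, DU = DU, SN = SN, SIU = SIU)
}

#' Synthetic denaturation-experiment configuration
#'
#' Holds the generating ("truth") model, raw signal levels, the urea grid,
#' the scattering breakpoint, per-probe relative noise, replicate count, seed
#' and the emission-band centers.
#'
#' @slot truth a [ThreeStateParams-class] generating model.
#' @slot signals a [SpeciesSignals-class].
#' @slot ureaGrid numeric sorted urea grid, mol/L.
#' @slot scatterBreakpoint numeric, mol/L: scattering reaches its plateau here.
#' @slot noiseSd named numeric relative SDs for scattering/fluorescence/cd.
#' @slot nRep integer replicates per concentration.
#' @slot seed integer RNG seed.
#' @slot lambdaNative,lambdaUnfolded numeric emission-band centers, nm.
#' @export
setClass("GeneratorConfig",
  representation(
    truth             = "ThreeStateParams",
    signals           = "SpeciesSignals",
    ureaGrid          = "numeric",
    scatterBreakpoint = "numeric",
    noiseSd           = "numeric",
    nRep              = "integer",
    seed              = "integer",
    lambdaNative      = "numeric",
    lambdaUnfolded    = "numeric"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (any(diff(object@ureaGrid) <= 0))
    msg <- c(msg, "ureaGrid must be sorted ascending and unique")
  if (any(object@noiseSd < 0))
    msg <- c(msg, "noiseSd must be non-negative")
  if (object@nRep < 1L) msg <- c(msg, "nRep must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneratorConfig-class
#' @param truth generating [ThreeStateParams-class]; default
#'   `ThreeStateParams(3.0, 0.45, 0.81, 0.24)`.
#' @param signals a [SpeciesSignals-class].
#' @param ureaGrid urea grid, mol/L; default 0 to 7 M in 0.5 M steps.
#' @param scatterBreakpoint plateau onset of the scattering decay, mol/L.
#' @param noiseSd relative noise SD per probe; scalar or named vector with
#'   entries `scattering`, `fluorescence`, `cd`. Defaults 5%/3%/4%.
#' @param nRep replicates per concentration.
#' @param seed RNG seed.
#' @param lambdaNative,lambdaUnfolded emission band centers, nm.
#' @export
GeneratorConfig <- function(truth = ThreeStateParams(3.0, 0.45, 0.81, 0.24),
                            signals = SpeciesSignals(),
                            ureaGrid = seq(0, 7, by = 0.5),
                            scatterBreakpoint = 3.5,
                            noiseSd = c(scattering = 0.05, fluorescence = 0.03, cd = 0.04),
                            nRep = 3L, seed = 1L,
                            lambdaNative = 335, lambdaUnfolded = 344) {
  if (length(noiseSd) == 1L && is.null(names(noiseSd)))
    noiseSd <- c(scattering = unname(noiseSd), fluorescence = unname(noiseSd),
                 cd = unname(noiseSd))
  stopifnot(all(c("scattering", "fluorescence", "cd") %in% names(noiseSd)))
  new("GeneratorConfig", truth = truth, signals = signals,
      ureaGrid = as.numeric(ureaGrid), scatterBreakpoint = as.numeric(scatterBreakpoint),
      noiseSd = noiseSd[c("scattering", "fluorescence", "cd")],
      nRep = as.integer(nRep), seed = as.integer(seed),
      lambdaNative = as.numeric(lambdaNative), lambdaUnfolded = as.numeric(lambdaUnfolded))
}

## ---------------------------------------------------------------------------
## Trajectory helicity containers
## ---------------------------------------------------------------------------

#' Backbone dihedral angles over trajectory frames
#'
#' @slot phi,psi numeric matrices (frames x residues), degrees in (-180, 180];
#'   `NA` marks undefined angles (chain termini, missing atoms).
#' @slot residueIds integer residue labels (1-based).
#' @export
setClass("DihedralSeries",
  representation(phi = "matrix", psi = "matrix", residueIds = "integer"))

setValidity("DihedralSeries", function(object) {
  msg <- character()
  if (!all(dim(object@phi) == dim(object@psi)))
    msg <- c(msg, "phi and psi must have equal dimensions")
  if (ncol(object@phi) != length(object@residueIds))
    msg <- c(msg, "residueIds must match the number of residue columns")
  ang <- c(object@phi, object@psi)
  ang <- ang[!is.na(ang)]
  if (length(ang) && (any(ang <= -180) || any(ang > 180)))
    msg <- c(msg, "angles must lie in (-180, 180]")
  if (length(msg)) msg else TRUE
})

#' @rdname DihedralSeries-class
#' @param phi,psi frames x residues matrices of dihedral angles in degrees.
#' @param residueIds integer residue ids; default `1:ncol(phi)`.
#' @export
DihedralSeries <- function(phi, psi, residueIds = seq_len(ncol(phi))) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  new("DihedralSeries", phi = wrapAngle(phi), psi = wrapAngle(psi),
      residueIds = as.integer(residueIds))
}

#' Per-residue helical propensity profile
#'
#' Fraction of trajectory frames in which each residue is part of an
#' alpha-helix (helical dihedral window with both neighbours also helical).
#'
#' @slot propensity numeric per-residue fractions in \[0, 1\].
#' @slot nFrames integer number of frames averaged.
#' @slot residueIds integer residue labels.
#' @export
setClass("HelicityProfile",
  representation(propensity = "numeric", nFrames = "integer",
                 residueIds = "integer"))

setValidity("HelicityProfile", function(object) {
  if (any(object@propensity < 0 | object@propensity > 1, na.rm = TRUE))
    "propensities must lie in [0, 1]" else TRUE
})

#' Backbone hydrogen-bond potential parameters
#'
#' Parameters of the coarse-grained backbone H-bond potential
#' V(r) = lambda * eps * (5 (sigma/r)^12 - 6 (sigma/r)^10) cos^2(thetaN) cos^2(thetaC),
#' which vanishes when either angle magnitude reaches 90 degrees. `lambda` is
#' the denaturation prefactor (1 = full H-bond strength).
#'
#' @slot lambda numeric in (0, 1].
#' @slot epsilonHb numeric potential depth, > 0.
#' @slot sigmaHb numeric equilibrium distance, > 0.
#' @export
setClass("HBondParams",
  representation(lambda = "numeric", epsilonHb = "numeric", sigmaHb = "numeric"),
  prototype(lambda = 1))

setValidity("HBondParams", function(object) {
  msg <- character()
  if (object@lambda <= 0 || object@lambda > 1)
    msg <- c(msg, "lambda must lie in (0, 1]")
  if (object@epsilonHb <= 0) msg <- c(msg, "epsilonHb must be positive")
  if (object@sigmaHb <= 0) msg <- c(msg, "sigmaHb must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname HBondParams-class
#' @param lambda denaturation prefactor in (0, 1].
#' @param epsilonHb potential depth.
#' @param sigmaHb equilibrium distance.
#' @export
HBondParams <- function(lambda = 1, epsilonHb = 1, sigmaHb = 1)
  new("HBondParams", lambda = as.numeric(lambda),
      epsilonHb = as.numeric(epsilonHb), sigmaHb = as.numeric(sigmaHb))

## ---------------------------------------------------------------------------
## Helix-coil stand-in model
## ---------------------------------------------------------------------------

#' Cooperative two-state helix-coil model
#'
#' A Zimm-Bragg-style chain of `n` residues, each helical (h) or coil (c).
#' A configuration has statistical weight s^(number of h residues) *
#' sigmaNuc^(number of h-runs); `sigmaNuc < 1` penalizes helix nucleation.
#' This model is an explicitly simplified stand-in used to study trends of
#' helicity versus H-bond strength; it is not a molecular force field.
#'
#' @slot n integer residue count, >= 1.
#' @slot s numeric propagation weight per helical residue, >= 0.
#' @slot sigmaNuc numeric nucleation weight in (0, 1].
#' @export
setClass("HelixCoilModel",
  representation(n = "integer", s = "numeric", sigmaNuc = "numeric"))

setValidity("HelixCoilModel", function(object) {
  msg <- character()
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (object@s < 0) msg <- c(msg, "s must be non-negative")
  if (object@sigmaNuc <= 0 || object@sigmaNuc > 1)
    msg <- c(msg, "sigmaNuc must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname HelixCoilModel-class
#' @param n residue count.
#' @param s helix propagation weight.
#' @param sigmaNuc nucleation weight.
#' @export
HelixCoilModel <- function(n, s, sigmaNuc = 1)
  new("HelixCoilModel", n = as.integer(n), s = as.numeric(s),
      sigmaNuc = as.numeric(sigmaNuc))

## ---------------------------------------------------------------------------
## Atomic structures for SASA
## ---------------------------------------------------------------------------

#' Atom set for solvent-accessible surface area calculations
#'
#' A flat table of heavy atoms (element, atom name, residue id/name, chain,
#' Cartesian position in Angstrom) plus the per-element van der Waals radii
#' used by the Shrake-Rupley algorithm.
#'
#' @slot atoms data.frame with columns `element`, `name`, `resid`, `resname`,
#'   `chain`, `x`, `y`, `z`.
#' @slot radii named numeric van der Waals radii per element symbol, Angstrom.
#' @export
setClass("AtomSet", representation(atoms = "data.frame", radii = "numeric"))

setValidity("AtomSet", function(object) {
  msg <- character()
  need <- c("element", "name", "resid", "resname", "chain", "x", "y", "z")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(is.finite(object@atoms$x) & is.finite(object@atoms$y) &
             is.finite(object@atoms$z)))
      msg <- c(msg, "positions must be finite")
    if (!all(object@atoms$element %in% names(object@radii)))
      msg <- c(msg, "every element needs a van der Waals radius")
  }
  if (any(object@radii <= 0)) msg <- c(msg, "radii must be positive")
  if (length(msg)) msg else TRUE
})

#' Bondi-style van der Waals radii for common protein heavy atoms
#'
#' @return named numeric vector of radii in Angstrom.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, SE = 1.90)
}

#' @rdname AtomSet-class
#' @param atoms data.frame of atom records.
#' @param radii named vdW radii; defaults to [defaultVdwRadii()].
#' @export
AtomSet <- function(atoms, radii = defaultVdwRadii()) {
  atoms$element <- toupper(as.character(atoms$element))
  new("AtomSet", atoms = atoms, radii = radii)
}
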