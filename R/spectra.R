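## Spectral preprocessing: reading tables, smoothing, scalar-probe extraction,
## denaturation-series assembly and normalization.

#' Read a two-column spectral table
#'
#' Reads a delimited text file with two numeric columns (wavelength in nm,
#' signal) into a [Spectrum-class]. Header lines are allowed; rows are sorted
#' by wavelength; duplicated wavelengths are an error.
#'
#' @param path path to a delimited text file.
#' @param probe `"fluorescence"`, `"cd"` or `"scattering"`.
#' @param urea urea concentration of the measurement, mol/L.
#' @param replicate integer replicate id.
#' @param sep field separator; `""` (default) means any whitespace, use `","`
#'   for CSV.
#' @return A [Spectrum-class].
#' @export
readSpectrumTable <- function(path, probe = c("fluorescence", "cd", "scattering"),
                              urea = 0, replicate = 1L, sep = "") {
  probe <- match.arg(probe)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  split1 <- function(x) {
    if (nzchar(sep)) strsplit(x, sep, fixed = TRUE)[[1]]
    else strsplit(trimws(x), "[[:space:]]+")[[1]]
  }
  parsed <- lapply(lines, function(x) suppressWarnings(as.numeric(split1(x))))
  numericRow <- vapply(parsed, function(p) length(p) >= 2 && !anyNA(p[1:2]), logical(1))
  ## leading non-numeric lines are treated as headers; later ones are errors
  firstData <- match(TRUE, numericRow)
  if (is.na(firstData)) stop("no numeric rows in ", path, call. = FALSE)
  bad <- which(!numericRow & seq_along(numericRow) > firstData)
  if (length(bad))
    stop("non-numeric row at line ", bad[1], " of ", path, call. = FALSE)
  wl <- vapply(parsed[numericRow], `[`, numeric(1), 1L)
  vv <- vapply(parsed[numericRow], `[`, numeric(1), 2L)
  if (anyDuplicated(wl)) {
    dupLine <- which(numericRow)[which(duplicated(wl))[1]]
    stop("duplicated wavelength ", wl[duplicated(wl)][1], " nm at line ",
         dupLine, " of ", path, call. = FALSE)
  }
  Spectrum(wl, vv, probe = probe, urea = urea, replicate = replicate)
}

#' Moving-average smoothing of a spectrum
#'
#' Replaces each value by the mean of all points within `halfwidth` nm
#' (a +/- 5 nm window by default). At the spectrum edges the window is
#' truncated to the available points, so endpoints are preserved without
#' fabricating data. Requires a uniform wavelength grid.
#'
#' @param s a [Spectrum-class].
#' @param halfwidth window half-width in nm (>= 0).
#' @return the smoothed [Spectrum-class] on the same wavelength grid.
#' @export
movingAverage <- function(s, halfwidth = 5) {
  stopifnot(is(s, "Spectrum"), halfwidth >= 0)
  wl <- s@wavelengths
  n <- length(wl)
  if (n > 2L) {
    steps <- diff(wl)
    if (max(steps) - min(steps) > 1e-8 * mean(steps))
      stop("movingAverage requires a uniform wavelength grid", call. = FALSE)
  }
  if (n <= 1L || halfwidth == 0) return(s)
  step <- wl[2] - wl[1]
  k <- floor(halfwidth / step + 1e-9)
  v <- s@values
  ## truncated-window running mean via cumulative sums
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  initialize(s, values = sm)
}

#' Extract the signal at (nearest to) a given wavelength
#'
#' Returns the value at the grid point nearest to `wavelength`; the paper's
#' grids are 1 nm steps so no interpolation is performed.
#'
#' @param s a [Spectrum-class] (smooth first with [movingAverage()] if wanted).
#' @param wavelength query wavelength in nm; must be within the grid range.
#' @return numeric signal value.
#' @export
extractSignal <- function(s, wavelength) {
  stopifnot(is(s, "Spectrum"), length(s@wavelengths) >= 1L)
  wl <- s@wavelengths
  if (wavelength < min(wl) || wavelength > max(wl))
    stop(sprintf("wavelength %.4g nm outside grid range [%.4g, %.4g]",
                 wavelength, min(wl), max(wl)), call. = FALSE)
  s@values[which.min(abs(wl - wavelength))]
}

#' Wavelength of the emission maximum
#'
#' Global maximum of the spectrum; ties are broken toward the lowest
#' wavelength so that reported red shifts are deterministic.
#'
#' @param s a [Spectrum-class].
#' @return wavelength in nm.
#' @export
lambdaMax <- function(s) {
  stopifnot(is(s, "Spectrum"))
  if (!length(s@values)) stop("empty spectrum", call. = FALSE)
  s@wavelengths[which.max(s@values)]  # which.max returns the first maximum
}

#' Second-order Rayleigh scattering signal at 300 nm
#'
#' Arithmetic mean of the signal at all grid points within 300 +/- 5 nm,
#' the probe used to follow oligomer (barrel) disassembly.
#'
#' @param s a scattering [Spectrum-class] whose grid covers 295-305 nm.
#' @return mean signal over the window.
#' @export
rayleighScatter <- function(s) {
  stopifnot(is(s, "Spectrum"))
  wl <- s@wavelengths
  if (min(wl) > 295 || max(wl) < 305)
    stop("spectrum grid must cover 295-305 nm", call. = FALSE)
  inWin <- wl >= 295 & wl <= 305
  mean(s@values[inWin])
}

#' CD ellipticity ratio 222-to-208 nm
#'
#' Ratio of the (smoothed) ellipticities at 222 and 208 nm; values above 1
#' indicate interacting helices (coiled-coil). Ratios measured above
#' `flagAbove` M urea are reported but flagged unusable because the 208 nm
#' signal drowns in urea absorbance at high concentrations.
#'
#' @param s a CD [Spectrum-class] covering 208 and 222 nm.
#' @param flagAbove urea concentration above which the ratio is flagged
#'   (default 4.5 M); set `Inf` to disable.
#' @return numeric ratio with attribute `usable` (logical).
#' @export
cdRatio222208 <- function(s, flagAbove = 4.5) {
  v208 <- extractSignal(s, 208)
  v222 <- extractSignal(s, 222)
  if (v208 == 0)
    stop("ellipticity at 208 nm is zero: unusable point", call. = FALSE)
  r <- v222 / v208
  attr(r, "usable") <- s@urea <= flagAbove
  r
}

#' Assemble a denaturation series from replicate measurements
#'
#' @param points a data.frame (or list coercible to one) with columns `urea`
#'   and `value`, one row per replicate measurement.
#' @param probeLabel label for the extracted probe, e.g. `"I335"`.
#' @return a [DenaturationSeries-class] with per-concentration mean, sample SD
#'   (0 for single replicates) and replicate count, sorted by urea.
#' @export
buildDenaturationSeries <- function(points, probeLabel = "") {
  points <- as.data.frame(points)
  stopifnot(all(c("urea", "value") %in% names(points)))
  if (!nrow(points)) stop("no measurements supplied", call. = FALSE)
  sp <- split(points$value, points$urea)
  urea <- as.numeric(names(sp))
  m <- vapply(sp, mean, numeric(1))
  sdv <- vapply(sp, function(v) if (length(v) > 1L) stats::sd(v) else 0, numeric(1))
  nr <- vapply(sp, length, integer(1))
  DenaturationSeries(urea, m, sdv, nr, probeLabel = probeLabel)
}

#' Normalize a denaturation series between native and unfolded plateaus
#'
#' Maps the series affinely so the mean over the native plateau becomes ~1 and
#' the mean over the unfolded plateau becomes ~0:
#' `(x - unfolded_mean)/(native_mean - unfolded_mean)`. Noise can push points
#' outside \[0, 1\]; such points are kept and flagged via the `"outside01"`
#' attribute. SDs are scaled by the same factor.
#'
#' @param series a [DenaturationSeries-class].
#' @param nativeRange urea interval (length-2 numeric) defining the native
#'   plateau; default `c(0, 0.5)` M.
#' @param unfoldedRange urea interval for the unfolded plateau; default
#'   `c(6.5, 7)` M.
#' @return normalized [DenaturationSeries-class] with attribute `outside01`.
#' @export
normalizeSeries <- function(series, nativeRange = c(0, 0.5),
                            unfoldedRange = c(6.5, 7)) {
  stopifnot(is(series, "DenaturationSeries"))
  u <- series@urea
  inNat <- u >= nativeRange[1] & u <= nativeRange[2]
  inUnf <- u >= unfoldedRange[1] & u <= unfoldedRange[2]
  if (!any(inNat)) stop("no measured concentration in the native range", call. = FALSE)
  if (!any(inUnf)) stop("no measured concentration in the unfolded range", call. = FALSE)
  mNat <- mean(series@mean[inNat])
  mUnf <- mean(series@mean[inUnf])
  if (mNat == mUnf)
    stop("native and unfolded plateau means are equal: cannot normalize", call. = FALSE)
  scale <- mNat - mUnf
  out <- initialize(series,
    mean = (series@mean - mUnf) / scale,
    sd = series@sd / abs(scale),
    normalized = TRUE)
  attr(out, "outside01") <- which(out@mean < 0 | out@mean > 1)
  out
}

#' Normalize a kinetic trace between two anchor times
#'
#' Affine rescaling so the value at `tStart` (default 6 ms, past mixing
#' artifacts) maps to 1 and the value at `tEnd` (default 100 s, before
#' photobleaching matters) maps to 0. Anchor values are taken at the measured
#' time points nearest the anchors.
#'
#' @param trace a [KineticTrace-class] covering both anchors.
#' @param tStart,tEnd anchor times in seconds.
#' @return normalized [KineticTrace-class].
#' @export
normalizeKinetics <- function(trace, tStart = 0.006, tEnd = 100) {
  stopifnot(is(trace, "KineticTrace"))
  tt <- trace@time
  if (min(tt) > tStart || max(tt) < tEnd)
    stop("trace does not cover the anchor times", call. = FALSE)
  v0 <- trace@values[which.min(abs(tt - tStart))]
  v1 <- trace@values[which.min(abs(tt - tEnd))]
  if (v0 == v1) stop("anchor values are equal: cannot normalize", call. = FALSE)
  initialize(trace, values = (trace@values - v1) / (v0 - v1))
}

#' Convert instrument ellipticity to mean-residue molar ellipticity
#'
#' Optional helper using the mean-residue-weight convention:
#' `theta_MRE = theta_mdeg * MRW / (10 * pathlength_cm * conc_mg_ml)`.
#' All model fitting in this package operates on normalized signals; this
#' conversion only serves reporting in conventional units.
#'
#' @param thetaMdeg observed ellipticity in millidegrees.
#' @param mrw mean residue weight in Da (protein mass / number of residues).
#' @param pathlengthCm cuvette path length in cm.
#' @param concMgMl protein concentration in mg/mL.
#' @return molar ellipticity in deg cm^2 dmol^-1.
#' @export
molarEllipticity <- function(thetaMdeg, mrw, pathlengthCm = 0.1, concMgMl = 0.1) {
  thetaMdeg * mrw / (10 * pathlengthCm * concMgMl)
}
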