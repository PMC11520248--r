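## The three-state (N -> I -> U) equilibrium model with an LEM-parameterized
## I <-> U constant. The native-oligomer fraction fN is supplied externally
## (from normalized scattering); the model only describes the I/U equilibrium.

#' Urea-dependent I-U equilibrium constant
#'
#' K(U) = exp(-(c50 - U)/d): unity at the midpoint `c50`, strictly increasing
#' in urea. This is the linear extrapolation model rewritten so the fitted
#' parameters (c50, d = RT/m) are decorrelated.
#'
#' @param lem a [LEMParams-class].
#' @param urea urea concentration(s), mol/L, >= 0.
#' @return numeric K, same length as `urea`.
#' @export
equilibriumK <- function(lem, urea) {
  stopifnot(is(lem, "LEMParams"), all(urea >= 0))
  exp((urea - lem@c50) / lem@d)
}

#' Convert (c50, d) to the m-value and unfolding free energy in water
#'
#' m = RT/d and dG_H2O = m * c50, the conventional LEM reporting quantities.
#'
#' @param lem a [LEMParams-class].
#' @param ctx a [ThermoContext-class]; default 293.15 K.
#' @return named numeric: `m` (J mol^-1 M^-1) and `dG_H2O` (J mol^-1).
#' @export
deltaGWater <- function(lem, ctx = ThermoContext()) {
  stopifnot(is(lem, "LEMParams"), is(ctx, "ThermoContext"))
  m <- ctx@R * ctx@temperature / lem@d
  c(m = m, dG_H2O = m * lem@c50)
}

#' Species fractions of the three-state system
#'
#' Given the native-oligomer fraction `fN` (read from normalized scattering)
#' and the I-U equilibrium constant at the given urea concentration, the
#' non-native protein partitions as fI = (1 - fN)/(1 + K) and fU = K * fI.
#' Evaluated with stable logistic expressions so large K cannot overflow.
#'
#' @param params a [ThreeStateParams-class] (only the LEM part is used).
#' @param fN native fraction(s) in \[0, 1\].
#' @param urea urea concentration(s), mol/L; recycled against `fN`.
#' @return a [SpeciesFractions-class].
#' @export
fractionsThreeState <- function(params, fN, urea) {
  stopifnot(is(params, "ThreeStateParams"))
  if (any(fN < 0 | fN > 1))
    stop("fN must lie in [0, 1]; clip upstream if needed", call. = FALSE)
  n <- max(length(fN), length(urea))
  fN <- rep_len(fN, n); urea <- rep_len(urea, n)
  z <- (urea - params@lem@c50) / params@lem@d
  fI <- (1 - fN) * invOnePlusExp(z)
  fU <- (1 - fN) * expOverOnePlusExp(z)
  new("SpeciesFractions", fN = as.numeric(fN), fI = as.numeric(fI),
      fU = as.numeric(fU))
}

#' Predicted normalized fluorescence and CD signals (three-state)
#'
#' Fnorm = fN + a*fI and Dnorm = b*fI + fU, the globally fitted equations;
#' Fnorm is 1 and Dnorm 0 for pure native protein, and the conventions are
#' 1 = native for fluorescence, 1 = unfolded for CD.
#'
#' @inheritParams fractionsThreeState
#' @return list with numeric vectors `Fnorm` and `Dnorm`.
#' @export
predictThreeState <- function(params, fN, urea) {
  fr <- fractionsThreeState(params, fN, urea)
  list(Fnorm = fr@fN + params@a * fr@fI,
       Dnorm = params@b * fr@fI + fr@fU)
}

#' Predicted normalized signals for a two-state system
#'
#' For constructs without a native oligomer (monomeric/small-oligomer native
#' state), Fnorm = 1/(1 + K) and Dnorm = K/(1 + K).
#'
#' @param lem a [LEMParams-class].
#' @param urea urea concentration(s), mol/L, >= 0.
#' @return list with numeric vectors `Fnorm` and `Dnorm` (summing to 1).
#' @export
predictTwoState <- function(lem, urea) {
  stopifnot(is(lem, "LEMParams"), all(urea >= 0))
  z <- (urea - lem@c50) / lem@d
  list(Fnorm = invOnePlusExp(z), Dnorm = expOverOnePlusExp(z))
}
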