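## Global fitting of normalized denaturation curves: the native fraction is
## pinned to normalized scattering, and (c50, d, a, b) are shared between the
## fluorescence and CD residuals (Levenberg-Marquardt via minpack.lm).

#' Native fraction from normalized scattering
#'
#' Linear interpolation of a normalized scattering series at arbitrary urea
#' points, clipped to \[0, 1\] so the result is a valid fraction. Queries
#' outside the measured range are an error (no extrapolation).
#'
#' @param scatter a normalized scattering [DenaturationSeries-class].
#' @param ureaPoints numeric query concentrations, mol/L.
#' @return numeric fractions fN, one per query point.
#' @export
interpolateFractionNative <- function(scatter, ureaPoints) {
  stopifnot(is(scatter, "DenaturationSeries"))
  u <- scatter@urea
  if (any(ureaPoints < min(u) - 1e-12 | ureaPoints > max(u) + 1e-12))
    stop("query urea outside the measured scattering range", call. = FALSE)
  fn <- stats::approx(u, scatter@mean, xout = ureaPoints, rule = 1)$y
  pmin(pmax(fn, 0), 1)
}

## deterministic jitter table for multi-start initialization (no RNG use)
.multiStartOffsets <- rbind(
  c(0,     0,    0,    0),
  c(0.6,   0.25, -0.3,  0.3),
  c(-0.6, -0.2,   0.3, -0.15),
  c(1.2,   0.5,  -0.5,  0.5),
  c(-1.2,  0.1,   0.15, -0.1)
)

.lmControl <- function() minpack.lm::nls.lm.control(
  ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 1000, maxfev = 100000)

## covariance of the free parameters from a central-difference Jacobian,
## scaled by reduced chi-square (standard LM practice)
.lmCovariance <- function(residFun, par, rss) {
  p <- length(par)
  n <- length(residFun(par))
  J <- matrix(0, n, p)
  for (j in seq_len(p)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (residFun(up) - residFun(dn)) / (2 * h)
  }
  s2 <- rss / max(n - p, 1)
  cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cv) || any(!is.finite(cv)))
    cv <- matrix(NA_real_, p, p)
  dimnames(cv) <- list(names(par), names(par))
  cv
}

## delta-method covariance contribution from noise in the measured native
## fraction: cov += (J'J)^-1 J' G Sigma G' J (J'J)^-1, where G is the
## Jacobian of the residuals with respect to the scattering means and Sigma
## the variance of those means (replicate sd^2 / nRep)
.scatterNoiseCovariance <- function(residFun, par, scatter, ureaF, ureaD,
                                    wF, wD, est, fixBZero) {
  p <- length(par)
  zero <- matrix(0, p, p)
  varMean <- scatter@sd^2 / pmax(scatter@nRep, 1L)
  if (all(varMean == 0)) return(zero)
  residFromScatter <- function(sMeans) {
    sNorm <- initialize(scatter, mean = sMeans)
    pr <- ThreeStateParams(est["c50"], est["d"], est["a"],
                           if (fixBZero) 0 else est["b"])
    fNF <- interpolateFractionNative(sNorm, ureaF)
    fND <- interpolateFractionNative(sNorm, ureaD)
    c(wF * predictThreeState(pr, fNF, ureaF)$Fnorm,
      wD * predictThreeState(pr, fND, ureaD)$Dnorm)
  }
  m <- length(scatter@mean)
  r0 <- residFun(par)
  G <- matrix(0, length(r0), m)
  for (k in seq_len(m)) {
    h <- 1e-6
    up <- scatter@mean; up[k] <- up[k] + h
    dn <- scatter@mean; dn[k] <- dn[k] - h
    G[, k] <- (residFromScatter(up) - residFromScatter(dn)) / (2 * h)
  }
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (residFun(up) - residFun(dn)) / (2 * h)
  }
  A <- tryCatch(solve(crossprod(J), t(J) %*% G), error = function(e) NULL)
  if (is.null(A)) return(zero)
  out <- A %*% (varMean * t(A))
  (out + t(out)) / 2
}

.weightsFor <- function(series, weights) {
  if (weights == "none") return(rep(1, length(series@mean)))
  sdv <- series@sd
  if (all(sdv <= 0)) stop("inverse_sd weighting needs positive SDs", call. = FALSE)
  floorSd <- 0.1 * stats::median(sdv[sdv > 0])
  1 / pmax(sdv, floorSd)
}

#' Global three-state fit of fluorescence and CD denaturation curves
#'
#' Simultaneously fits Fnorm = fN + a*fI and Dnorm = b*fI + fU to normalized
#' fluorescence and CD series, with the native fraction fN interpolated from
#' the normalized scattering series and (c50, d, a, b) shared between both
#' probes. Five deterministic jittered initializations guard against local
#' minima; the best-residual solution is returned. Standard errors come from
#' the Jacobian-based covariance at the optimum scaled by reduced chi-square,
#' plus a delta-method term propagating the uncertainty of the scattering
#' means (fN is a measured regressor; ignoring its noise understates the
#' parameter uncertainty).
#'
#' @param fluor normalized fluorescence [DenaturationSeries-class].
#' @param cd normalized CD [DenaturationSeries-class].
#' @param scatter normalized scattering [DenaturationSeries-class]; its urea
#'   range must cover the fluorescence and CD grids.
#' @param init optional [ThreeStateParams-class] starting values; by default
#'   c50 starts at the CD half-amplitude concentration, d = 0.5 M, a = 0.8,
#'   b = 0.2.
#' @param fixBZero logical; hold b at 0 (test of an intermediate whose
#'   secondary structure equals the oligomer-embedded monomer).
#' @param weights `"none"` (equal weight, default) or `"inverse_sd"`.
#' @return a [FitResult-class].
#' @examples
#' cfg <- GeneratorConfig(noiseSd = 0)
#' ds <- generateDenaturationDataset(cfg)
#' fit <- fitThreeState(ds$fluorNorm, ds$cdNorm, ds$scatterNorm)
#' coef(fit)
#' @export
fitThreeState <- function(fluor, cd, scatter, init = NULL, fixBZero = FALSE,
                          weights = c("none", "inverse_sd")) {
  weights <- match.arg(weights)
  stopifnot(is(fluor, "DenaturationSeries"), is(cd, "DenaturationSeries"),
            is(scatter, "DenaturationSeries"))
  if (length(fluor@urea) < 6L || length(cd@urea) < 6L)
    stop("need at least 6 concentrations per probe", call. = FALSE)
  ampF <- diff(range(fluor@mean)); ampD <- diff(range(cd@mean))
  if (ampF < 1e-3 || ampD < 1e-3)
    stop("degenerate data: at least one curve is flat", call. = FALSE)

  fNF <- interpolateFractionNative(scatter, fluor@urea)
  fND <- interpolateFractionNative(scatter, cd@urea)
  wF <- .weightsFor(fluor, weights)
  wD <- .weightsFor(cd, weights)

  if (is.null(init)) {
    c50Init <- cd@urea[which.min(abs(cd@mean - 0.5))]
    init <- ThreeStateParams(max(c50Init, 0.5), 0.5, 0.8, 0.2)
  }
  p0 <- coef(init)
  uMax <- max(fluor@urea, cd@urea)
  lower <- c(c50 = 0, d = 1e-3, a = 0, b = 0)
  upper <- c(c50 = 2 * uMax + 5, d = 10, a = 1, b = 1)
  free <- if (fixBZero) c("c50", "d", "a") else c("c50", "d", "a", "b")

  residFun <- function(par) {
    full <- p0
    full[free] <- par
    if (fixBZero) full["b"] <- 0
    pr <- ThreeStateParams(full["c50"], full["d"], full["a"], full["b"])
    predF <- predictThreeState(pr, fNF, fluor@urea)$Fnorm
    predD <- predictThreeState(pr, fND, cd@urea)$Dnorm
    c(wF * (predF - fluor@mean), wD * (predD - cd@mean))
  }

  best <- NULL
  for (i in seq_len(nrow(.multiStartOffsets))) {
    st <- p0[free] + .multiStartOffsets[i, seq_along(free)]
    st <- pmin(pmax(st, lower[free]), upper[free])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower[free], upper = upper[free],
                         fn = residFun, control = .lmControl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("all Levenberg-Marquardt starts failed", call. = FALSE)

  est <- p0
  est[free] <- best$par
  if (fixBZero) est["b"] <- 0
  converged <- best$info %in% 1:4
  rss <- best$deviance
  cv <- .lmCovariance(residFun, best$par, rss)
  ## propagate the uncertainty of the measured native fraction (the
  ## scattering series is itself a noisy regressor) into the parameter
  ## covariance by the delta method; vanishes for noiseless scattering
  cv <- cv + .scatterNoiseCovariance(residFun, best$par, scatter,
                                     fluor@urea, cd@urea, wF, wD, est, fixBZero)
  se <- sqrt(pmax(diag(cv), 0))
  names(se) <- free

  warn <- character()
  if (est["c50"] < min(cd@urea) || est["c50"] > max(cd@urea))
    warn <- c(warn, "midpoint outside measured urea range")

  res <- residFun(best$par)
  nF <- length(fluor@urea)
  new("FitResult",
    params = ThreeStateParams(est["c50"], est["d"], est["a"], est["b"]),
    standardErrors = se, covariance = cv, residualSS = rss,
    nObs = as.integer(length(res)), converged = converged,
    fixedBZero = fixBZero, model = "three_state",
    residuals = list(fluorescence = res[seq_len(nF)] / wF,
                     cd = res[-seq_len(nF)] / wD),
    warnings = warn)
}

#' Two-state fit of a single normalized denaturation curve
#'
#' For constructs with no large native oligomer, fits Fnorm = 1/(1 + K)
#' (`direction = "native_referenced"`, a decreasing curve normalized to the
#' native state) or Dnorm = K/(1 + K) (`"unfolded_referenced"`, increasing).
#'
#' @param curve normalized [DenaturationSeries-class] with >= 4 concentrations
#'   spanning the transition.
#' @param direction normalization convention of the curve.
#' @param init optional [LEMParams-class] start; defaults to the
#'   half-amplitude concentration and d = 0.5 M.
#' @param weights `"none"` or `"inverse_sd"`.
#' @return a [FitResult-class] with a [LEMParams-class] in `fitParams()`.
#' @export
fitTwoState <- function(curve, direction = c("native_referenced", "unfolded_referenced"),
                        init = NULL, weights = c("none", "inverse_sd")) {
  direction <- match.arg(direction)
  weights <- match.arg(weights)
  stopifnot(is(curve, "DenaturationSeries"))
  if (length(curve@urea) < 4L)
    stop("need at least 4 concentrations", call. = FALSE)
  if (diff(range(curve@mean)) < 1e-3)
    stop("degenerate data: curve is flat", call. = FALSE)
  w <- .weightsFor(curve, weights)

  if (is.null(init)) {
    c50Init <- curve@urea[which.min(abs(curve@mean - 0.5))]
    init <- LEMParams(max(c50Init, 0.5), 0.5)
  }
  p0 <- coef(init)
  lower <- c(c50 = 0, d = 1e-3)
  upper <- c(c50 = 2 * max(curve@urea) + 5, d = 10)

  residFun <- function(par) {
    pred <- predictTwoState(LEMParams(par["c50"], par["d"]), curve@urea)
    yhat <- if (direction == "native_referenced") pred$Fnorm else pred$Dnorm
    w * (yhat - curve@mean)
  }

  best <- NULL
  for (i in seq_len(nrow(.multiStartOffsets))) {
    st <- pmin(pmax(p0 + .multiStartOffsets[i, 1:2], lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = residFun, control = .lmControl()),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all Levenberg-Marquardt starts failed", call. = FALSE)

  converged <- best$info %in% 1:4
  rss <- best$deviance
  cv <- .lmCovariance(residFun, best$par, rss)
  se <- sqrt(pmax(diag(cv), 0))
  names(se) <- names(best$par)

  warn <- character()
  if (best$par["c50"] < min(curve@urea) || best$par["c50"] > max(curve@urea)) {
    warn <- c(warn, "midpoint outside measured urea range")
    converged <- FALSE  # not identifiable from the measured window
  }

  new("FitResult",
    params = LEMParams(best$par["c50"], best$par["d"]),
    standardErrors = se, covariance = cv, residualSS = rss,
    nObs = as.integer(length(curve@urea)), converged = converged,
    fixedBZero = FALSE, model = "two_state",
    residuals = list(curve = residFun(best$par) / w),
    warnings = warn)
}

#' Species-fraction curves from a converged three-state fit
#'
#' Tabulates (urea, fN, fI, fU) over a urea grid, with fN interpolated from
#' the normalized scattering series and fI, fU from the fitted equilibrium.
#' The grid row with the largest intermediate fraction is marked.
#'
#' @param result a converged three-state [FitResult-class].
#' @param scatter normalized scattering [DenaturationSeries-class].
#' @param ureaGrid numeric urea grid within the scattering range.
#' @return data.frame with columns `urea`, `fN`, `fI`, `fU` and attribute
#'   `maxI` (list with `urea` and `fI` at the intermediate maximum).
#' @export
speciesFractionCurves <- function(result, scatter, ureaGrid) {
  stopifnot(is(result, "FitResult"), result@model == "three_state")
  if (!result@converged) stop("fit did not converge", call. = FALSE)
  fN <- interpolateFractionNative(scatter, ureaGrid)
  fr <- fractionsThreeState(result@params, fN, ureaGrid)
  out <- data.frame(urea = ureaGrid, fN = fr@fN, fI = fr@fI, fU = fr@fU)
  iMax <- which.max(out$fI)
  attr(out, "maxI") <- list(urea = out$urea[iMax], fI = out$fI[iMax])
  out
}
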