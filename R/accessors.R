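## Accessor generics and show methods

#' @name accessors
#' @title Accessors for im30unfold classes
#' @description Slot accessors for the spectroscopy, fit and helicity
#'   containers; user code should use these rather than `@`.
#' @param object an im30unfold S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setMethod("wavelengths", "Spectrum", function(object) object@wavelengths)

#' @rdname accessors
#' @export
setGeneric("signalValues", function(object) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setMethod("signalValues", "Spectrum", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("signalValues", "KineticTrace", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("ureaValues", function(object) standardGeneric("ureaValues"))
#' @rdname accessors
#' @export
setMethod("ureaValues", "DenaturationSeries", function(object) object@urea)
#' @rdname accessors
#' @export
setMethod("ureaValues", "Spectrum", function(object) object@urea)

#' @rdname accessors
#' @export
setGeneric("signalMeans", function(object) standardGeneric("signalMeans"))
#' @rdname accessors
#' @export
setMethod("signalMeans", "DenaturationSeries", function(object) object@mean)

#' @rdname accessors
#' @export
setGeneric("signalSds", function(object) standardGeneric("signalSds"))
#' @rdname accessors
#' @export
setMethod("signalSds", "DenaturationSeries", function(object) object@sd)

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setMethod("nReplicates", "DenaturationSeries", function(object) object@nRep)

#' @rdname accessors
#' @export
setGeneric("probeLabel", function(object) standardGeneric("probeLabel"))
#' @rdname accessors
#' @export
setMethod("probeLabel", "DenaturationSeries", function(object) object@probeLabel)

#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setMethod("isNormalized", "DenaturationSeries", function(object) object@normalized)

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))
#' @rdname accessors
#' @export
setMethod("fitParams", "FitResult", function(object) object@params)

#' @rdname accessors
#' @export
setGeneric("standardErrors", function(object) standardGeneric("standardErrors"))
#' @rdname accessors
#' @export
setMethod("standardErrors", "FitResult", function(object) object@standardErrors)

#' @rdname accessors
#' @export
setGeneric("residualSS", function(object) standardGeneric("residualSS"))
#' @rdname accessors
#' @export
setMethod("residualSS", "FitResult", function(object) object@residualSS)

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setMethod("isConverged", "FitResult", function(object) object@converged)

#' Extract fitted parameters as a named numeric vector
#'
#' @param object a [FitResult-class], [ThreeStateParams-class] or
#'   [LEMParams-class].
#' @param ... unused.
#' @return named numeric vector (`c50`, `d`, and for three-state fits `a`, `b`).
#' @export
setMethod("coef", "FitResult", function(object, ...) coef(object@params))

#' @rdname coef-FitResult-method
#' @export
setMethod("coef", "ThreeStateParams", function(object, ...)
  c(c50 = object@lem@c50, d = object@lem@d, a = object@a, b = object@b))

#' @rdname coef-FitResult-method
#' @export
setMethod("coef", "LEMParams", function(object, ...)
  c(c50 = object@c50, d = object@d))

#' @rdname accessors
#' @export
setGeneric("propensity", function(object) standardGeneric("propensity"))
#' @rdname accessors
#' @export
setMethod("propensity", "HelicityProfile", function(object) {
  stats::setNames(object@propensity, object@residueIds)
})

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "HelicityProfile", function(object) object@nFrames)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(object) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "AtomSet", function(object) object@atoms)

## show methods -------------------------------------------------------------

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum (%s): %d points, %.0f-%.0f nm, urea %.2f M, replicate %d\n",
    object@probe, length(object@wavelengths),
    min(object@wavelengths), max(object@wavelengths),
    object@urea, object@replicate))
})

setMethod("show", "DenaturationSeries", function(object) {
  cat(sprintf("DenaturationSeries '%s'%s: %d concentrations, %.2f-%.2f M urea\n",
    object@probeLabel, if (object@normalized) " (normalized)" else "",
    length(object@urea), min(object@urea), max(object@urea)))
})

setMethod("show", "LEMParams", function(object) {
  cat(sprintf("LEMParams: c50 = %.4g M, d = %.4g M\n", object@c50, object@d))
})

setMethod("show", "ThreeStateParams", function(object) {
  cat(sprintf("ThreeStateParams: c50 = %.4g M, d = %.4g M, a = %.4g, b = %.4g\n",
    object@lem@c50, object@lem@d, object@a, object@b))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (%s%s): %s\n", object@model,
    if (object@fixedBZero) ", b fixed at 0" else "",
    if (object@converged) "converged" else "NOT converged"))
  est <- coef(object)
  se <- object@standardErrors
  for (nm in names(est)) {
    if (nm %in% names(se))
      cat(sprintf("  %-4s %10.5g +/- %.3g\n", nm, est[[nm]], se[[nm]]))
    else
      cat(sprintf("  %-4s %10.5g (fixed)\n", nm, est[[nm]]))
  }
  cat(sprintf("  residual SS %.6g on %d observations\n",
    object@residualSS, object@nObs))
  if (length(object@warnings))
    cat("  flags:", paste(object@warnings, collapse = "; "), "\n")
})

setMethod("show", "HelicityProfile", function(object) {
  cat(sprintf("HelicityProfile: %d residues, %d frames, mean propensity %.3f\n",
    length(object@propensity), object@nFrames,
    mean(object@propensity, na.rm = TRUE)))
})

setMethod("show", "HelixCoilModel", function(object) {
  cat(sprintf("HelixCoilModel: n = %d, s = %.4g, sigmaNuc = %.4g\n",
    object@n, object@s, object@sigmaNuc))
})

setMethod("show", "AtomSet", function(object) {
  cat(sprintf("AtomSet: %d atoms, %d residues, chains: %s\n",
    nrow(object@atoms), length(unique(paste(object@atoms$chain, object@atoms$resid))),
    paste(unique(object@atoms$chain), collapse = ", ")))
})
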