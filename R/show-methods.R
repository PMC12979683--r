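# show() methods and accessors

#' Per-cell table of a scene or prediction grid
#'
#' @param x an [EstuaryScene-class] or [PredictionGrid-class].
#' @return data.frame of cells with habitat covariates.
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))

#' @rdname cellTable
#' @export
setMethod("cellTable", "EstuaryScene", function(x) x@zonal)

#' @rdname cellTable
#' @export
setMethod("cellTable", "PredictionGrid", function(x) x@cells)

setMethod("show", "EstuaryScene", function(object) {
  cat("EstuaryScene:", object@nx, "x", object@ny, "cells of",
      object@cellSize, "m\n")
  cat("  water cells:", sum(object@water),
      "| rivers:", paste(rownames(object@riverMouths), collapse = ", "),
      "\n")
  cat("  mangrove pixels:", sum(object@mangroveMask), "at",
      object@pixelSize, "m resolution\n")
  cat("  depth range (water):",
      sprintf("%.2f-%.2f m", min(object@depth[object@water]),
              max(object@depth[object@water])), "\n")
})

setMethod("show", "EnvFieldSeries", function(object) {
  cat("EnvFieldSeries:", format(min(object@dates)), "to",
      format(max(object@dates)), sprintf("(%d days)\n",
                                         length(object@dates)))
  cat("  variables: temp, do, salin, ph | noise amplitudes:",
      paste(sprintf("%s=%.2g", names(object@noiseAmp), object@noiseAmp),
            collapse = ", "), "\n")
})

setMethod("show", "TrueModel", function(object) {
  cat("TrueModel: intercept", object@intercept, "| Tweedie p =",
      object@p, ", phi =", object@phi, "\n")
})

setMethod("show", "SurveyDesign", function(object) {
  cat("SurveyDesign:", sum(object@setsPerMonth), "sets/month over",
      length(object@years), "years (",
      paste(range(object@years), collapse = "-"), ")\n")
  cat("  nets:", paste(object@netLengthsM, collapse = "/"), "m x",
      object@netHeightM, "m, soak", object@soakMinutes, "min\n")
})

setMethod("show", "ClassSignature", function(object) {
  cat("ClassSignature '", object@label, "': ", length(object@mean),
      " bands, n = ", object@n, "\n", sep = "")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec:",
      if (length(object@covariates)) paste(object@covariates,
                                           collapse = " + ")
      else "(intercept only)", "\n")
})

setMethod("show", "FitResult", function(object) {
  show(object@spec)
  if (!object@converged) {
    cat("  fit did not converge\n")
    return(invisible(NULL))
  }
  cat(sprintf("  Tweedie p = %.3f | scale = %.4f | AIC = %.2f\n",
              object@power, object@scale, object@aic))
  cat(sprintf("  deviance explained = %.1f%% | n = %d\n",
              object@devExpl, object@n))
})

setMethod("show", "ValidationReport", function(object) {
  if (length(object@foldRMSE)) {
    cat(sprintf("cross-validation (%d folds): RMSE = %.3f +/- %.3f",
                length(object@foldRMSE),
                mean(object@foldRMSE, na.rm = TRUE),
                stats::sd(object@foldRMSE, na.rm = TRUE)), "\n")
    cat(sprintf("  AUC = %.3f +/- %.3f\n",
                mean(object@foldAUC, na.rm = TRUE),
                stats::sd(object@foldAUC, na.rm = TRUE)))
  }
  if (length(object@external)) {
    e <- object@external
    cat(sprintf(
      "external: %.0f%% of scores above zero; t(%d) = %.2f, p = %.3g\n",
      100 * e$propAbove, e$df, e$t, e$p))
  }
})

setMethod("show", "PredictionGrid", function(object) {
  cat("PredictionGrid:", nrow(object@cells), "cells (",
      sum(object@cells$inUniverse), "in sampling universe )\n")
  cat(sprintf("  clip: <= %g m from shore, depth <= %g m\n",
              object@maxShoreDistM, object@maxDepthM))
})

setMethod("show", "AbundanceDraws", function(object) {
  cat("AbundanceDraws:", dim(object@draws)[1], "draws x",
      length(object@years), "years x", length(object@seasons),
      "seasons x", length(object@domains), "domains\n")
  cat(sprintf("  trimmed: %d of %d draw-cells (factor %g)\n",
              sum(!object@retained), length(object@retained),
              object@trimFactor))
})

setMethod("show", "DemographyConfig", function(object) {
  cat(sprintf("DemographyConfig: broods %g-%g, female fraction %g\n",
              object@broodMin, object@broodMax, object@femaleFraction))
  cat(sprintf("  juvenile females ~ TN(%g, %g) on [%g, %g]\n",
              object@tnMean, object@tnSD, object@tnA, object@tnB))
  cat(sprintf("  maturity ~ U{%d..%d}; %d realizations\n",
              object@maturityMin, object@maturityMax,
              object@nRealizations))
})
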