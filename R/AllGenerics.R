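#' Accessors for habitrans objects
#'
#' Small accessor generics used across the package's S4 containers.
#'
#' @param object a habitrans S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("habitats", function(object) standardGeneric("habitats"))

#' @rdname accessors
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("baselineHabitat", function(object) standardGeneric("baselineHabitat"))

#' @rdname accessors
#' @export
setGeneric("draws", function(object) standardGeneric("draws"))

#' @rdname accessors
#' @export
setGeneric("coefNames", function(object) standardGeneric("coefNames"))

#' @rdname accessors
#' @export
setGeneric("nDraws", function(object) standardGeneric("nDraws"))

#' @rdname accessors
#' @export
setGeneric("paramTable", function(object) standardGeneric("paramTable"))

#' @rdname accessors
#' @export
setGeneric("truthCoefficients", function(object) standardGeneric("truthCoefficients"))

#' @rdname accessors
#' @export
setGeneric("covariateMoments", function(object) standardGeneric("covariateMoments"))

#' @rdname accessors
#' @export
setGeneric("structuralZeros", function(object) standardGeneric("structuralZeros"))

setMethod("habitats", "TransitionModelSpec", function(object) object@habitats)
setMethod("habitats", "SimConfig", function(object) object@habitats)
setMethod("habitats", "TransitionCoefficients", function(object) object@habitats)
setMethod("habitats", "TransitionPosterior", function(object) object@spec@habitats)

setMethod("regions", "TransitionModelSpec", function(object) object@regions)
setMethod("regions", "SimConfig", function(object) object@regions)
setMethod("regions", "TransitionCoefficients", function(object) object@regions)
setMethod("regions", "TransitionPosterior", function(object) object@spec@regions)

setMethod("baselineHabitat", "TransitionModelSpec", function(object) object@baseline)
setMethod("baselineHabitat", "SimConfig", function(object) object@baselineHabitat)
setMethod("baselineHabitat", "TransitionCoefficients", function(object) object@baseline)
setMethod("baselineHabitat", "TransitionPosterior", function(object) object@spec@baseline)

setMethod("draws", "TransitionPosterior", function(object) object@draws)
setMethod("coefNames", "TransitionPosterior", function(object) colnames(object@draws))
setMethod("nDraws", "TransitionPosterior", function(object) nrow(object@draws))
setMethod("paramTable", "TransitionPosterior", function(object) object@paramTable)

setMethod("truthCoefficients", "SimTruth", function(object) object@coefficients)
setMethod("covariateMoments", "SimTruth", function(object) object@covariateMoments)

setMethod("structuralZeros", "TransitionModelSpec", function(object) !object@mask)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", length(object@habitats), "habitats,",
      length(object@regions), "regions\n")
  cat("  baseline habitat:", object@baselineHabitat, "\n")
  cat("  tracks:", object@nIndividuals, "individuals x", object@nSteps,
      "steps of", object@fixPeriodMin, "min (bursts every",
      object@burstPeriodMin, "min)\n")
  cat("  fix missingness:", object@pMissing, " seed:", object@seed, "\n")
})

setMethod("show", "TransitionModelSpec", function(object) {
  cat("TransitionModelSpec:", length(object@habitats), "habitats,",
      length(object@regions), "regions; baseline:", object@baseline, "\n")
  cat("  effects:", paste(c("intercept", object@effects), collapse = ", "), "\n")
  cat("  structural zeros:", sum(!object@mask), "of", length(object@mask),
      "(region, from, to) cells\n")
  cat("  MCMC:", object@nIter, "iterations,", object@burnIn, "burn-in,",
      object@nChains, "chain(s)\n")
})

setMethod("show", "TransitionCoefficients", function(object) {
  free <- sum(!is.na(object@intercepts)) + sum(!is.na(object@diel)) +
    sum(!is.na(object@time)) + sum(!is.na(object@forage)) +
    sum(!is.na(object@walk)) + sum(!is.na(object@stationary)) +
    sum(!is.na(object@temperature))
  cat("TransitionCoefficients over", length(object@habitats), "habitats /",
      length(object@regions), "regions (baseline:", object@baseline, ")\n")
  cat(" ", free, "non-missing entries (baseline entries fixed at 0)\n")
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth: generating coefficients +",
      sum(object@realizedTransitionCounts), "realized transitions\n")
  cat("  covariate moments:\n")
  print(object@covariateMoments, row.names = FALSE)
})

setMethod("show", "TransitionPosterior", function(object) {
  cat("TransitionPosterior:", nrow(object@draws), "kept draws x",
      ncol(object@draws), "coefficients\n")
  cat("  iterations:", object@meta$nIter, "burn-in:", object@meta$burnIn,
      " records:", object@meta$nRecords, "\n")
  if (!is.null(object@meta$runtimeSec))
    cat("  runtime:", round(object@meta$runtimeSec, 1), "s\n")
})

setMethod("show", "ClassifierReport", function(object) {
  cat("ClassifierReport: overall accuracy",
      sprintf("%.3f", object@accuracy), "\n")
  tab <- rbind(precision = object@precision, recall = object@recall)
  print(round(tab, 3))
  cat("confusion (rows true, cols predicted):\n")
  print(object@confusion)
})
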