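#' @import methods
NULL

#' Canonical behavior labels
#'
#' The four burst-level behavior categories used throughout the package, in
#' canonical order: forage, walk, stationary, flight. Behavior-proportion
#' covariates use the first three; flight is excluded from the design to
#' avoid the exact collinearity of proportions summing to one.
#'
#' @export
BEHAVIORS <- c("forage", "walk", "stationary", "flight")

#' Default habitat and region label sets
#'
#' Eight landcover categories and seven wintering regions used by default by
#' the synthetic-data generator, matching the classes used for midcontinent
#' greater white-fronted geese. The baseline (reference) habitat is
#' open water/unconsolidated shore.
#'
#' @rdname defaultLabels
#' @export
defaultHabitats <- function() {
  c("corn", "grass/winter wheat", "herbaceous wetlands", "other grains",
    "rice", "woody wetlands", "open water/unconsolidated shore", "other")
}

#' @rdname defaultLabels
#' @export
defaultRegions <- function() {
  c("MAV", "Chenier Plain", "Texas Mid-coast", "Lower Texas Coast",
    "South Texas Brushlands", "Rolling/High Plains", "Other")
}

#' @rdname defaultLabels
#' @export
defaultBaseline <- function() "open water/unconsolidated shore"

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Ground-truth transition coefficients
#'
#' Container for all coefficient blocks of the multinomial logistic
#' transition model on the standardized-covariate scale:
#' region-specific intercepts \code{b0[j|r]} and their hyper-means
#' \code{b0m[j]} (habitat-specific), harmonic time-of-day slopes
#' \code{b1[j]} (cos diel) and \code{b2[j]} (sin time), and
#' transition-specific behavior/temperature slopes \code{b3[i->j]} (forage),
#' \code{b4[i->j]} (walk), \code{b5[i->j]} (stationary), \code{b6[i->j]}
#' (temperature). All entries into the baseline habitat are structurally 0;
#' entries that are not parameterized (habitat unavailable in a region) are
#' \code{NA}.
#'
#' @slot habitats ordered habitat labels.
#' @slot baseline baseline (reference) habitat label.
#' @slot regions region labels.
#' @slot intercepts numeric matrix habitats x regions.
#' @slot hyperMeans named numeric vector over habitats.
#' @slot diel,time named numeric vectors over habitats (destination-specific).
#' @slot forage,walk,stationary,temperature numeric matrices from x to.
#' @export
setClass("TransitionCoefficients",
  representation(
    habitats = "character",
    baseline = "character",
    regions = "character",
    intercepts = "matrix",
    hyperMeans = "numeric",
    diel = "numeric",
    time = "numeric",
    forage = "matrix",
    walk = "matrix",
    stationary = "matrix",
    temperature = "matrix"
  )
)

setValidity("TransitionCoefficients", function(object) {
  H <- length(object@habitats)
  R <- length(object@regions)
  msg <- character()
  if (!(object@baseline %in% object@habitats))
    msg <- c(msg, "baseline must be one of the habitats")
  if (!identical(dim(object@intercepts), c(H, R)))
    msg <- c(msg, "intercepts must be habitats x regions")
  for (nm in c("forage", "walk", "stationary", "temperature")) {
    if (!identical(dim(slot(object, nm)), c(H, H)))
      msg <- c(msg, sprintf("%s must be a habitats x habitats matrix", nm))
  }
  if (length(object@hyperMeans) != H || length(object@diel) != H ||
      length(object@time) != H)
    msg <- c(msg, "hyperMeans, diel and time must have one entry per habitat")
  jb <- match(object@baseline, object@habitats)
  if (!is.na(jb) && identical(dim(object@intercepts), c(H, R))) {
    baseVals <- c(object@intercepts[jb, ], object@hyperMeans[jb],
                  object@diel[jb], object@time[jb],
                  object@forage[, jb], object@walk[, jb],
                  object@stationary[, jb], object@temperature[, jb])
    if (any(baseVals[!is.na(baseVals)] != 0))
      msg <- c(msg, "all coefficients into the baseline habitat must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic-data generator configuration
#'
#' Study-design parameters for the synthetic GPS/ACC generator: the habitat
#' and region label sets, per-region habitat availability, the baseline
#' habitat, ground-truth transition coefficients (standardized-covariate
#' scale), track dimensions, fix/burst cadences, per-fix missingness,
#' habitat-conditioned Dirichlet concentrations for behavior mixes, and the
#' diel AR(1) temperature process.
#'
#' @slot habitats,regions label sets.
#' @slot regionHabitats named list: region -> habitats available there.
#' @slot baselineHabitat baseline habitat label.
#' @slot trueCoefficients a [TransitionCoefficients-class] object.
#' @slot nIndividuals,nSteps track dimensions (steps are fix periods).
#' @slot pMissing per-fix i.i.d. missingness probability in [0,1).
#' @slot burstPeriodMin,fixPeriodMin cadences in minutes (defaults 6 and 30).
#' @slot behaviorAlpha named list: habitat -> Dirichlet concentrations over
#'   (forage, walk, stationary, flight), all strictly positive.
#' @slot tempParams named numeric: mean (deg C), amplitude (deg C),
#'   ar in (-1,1), sd (innovation sd, deg C, >= 0).
#' @slot startTime first fix timestamp (local clock time).
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig",
  representation(
    habitats = "character",
    regions = "character",
    regionHabitats = "list",
    baselineHabitat = "character",
    trueCoefficients = "TransitionCoefficients",
    nIndividuals = "integer",
    nSteps = "integer",
    pMissing = "numeric",
    burstPeriodMin = "numeric",
    fixPeriodMin = "numeric",
    behaviorAlpha = "list",
    tempParams = "numeric",
    startTime = "POSIXct",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!(object@baselineHabitat %in% object@habitats))
    msg <- c(msg, "baselineHabitat must be one of the habitats")
  if (!setequal(names(object@regionHabitats), object@regions))
    msg <- c(msg, "regionHabitats must be named by the regions")
  for (r in object@regions) {
    rh <- object@regionHabitats[[r]]
    if (!all(rh %in% object@habitats))
      msg <- c(msg, sprintf("regionHabitats[['%s']] contains unknown habitats", r))
    if (!(object@baselineHabitat %in% rh))
      msg <- c(msg, sprintf("baseline habitat missing from region '%s'", r))
    if (length(rh) < 2)
      msg <- c(msg, sprintf("region '%s' has fewer than 2 habitats; no transitions definable", r))
  }
  if (!setequal(names(object@behaviorAlpha), object@habitats))
    msg <- c(msg, "behaviorAlpha must be named by the habitats")
  for (h in names(object@behaviorAlpha)) {
    a <- object@behaviorAlpha[[h]]
    if (length(a) != 4L || any(!is.finite(a)) || any(a <= 0))
      msg <- c(msg, sprintf("behaviorAlpha[['%s']] must be 4 strictly positive values", h))
  }
  if (object@nSteps < 2L) msg <- c(msg, "nSteps must be >= 2")
  if (object@nIndividuals < 1L) msg <- c(msg, "nIndividuals must be >= 1")
  if (object@pMissing < 0 || object@pMissing >= 1)
    msg <- c(msg, "pMissing must be in [0, 1)")
  tp <- object@tempParams
  if (!all(c("mean", "amplitude", "ar", "sd") %in% names(tp)))
    msg <- c(msg, "tempParams must be named (mean, amplitude, ar, sd)")
  else {
    if (abs(tp[["ar"]]) >= 1) msg <- c(msg, "temperature AR coefficient must be in (-1, 1)")
    if (tp[["sd"]] < 0) msg <- c(msg, "temperature innovation sd must be >= 0")
  }
  if (object@fixPeriodMin %% object@burstPeriodMin != 0)
    msg <- c(msg, "fixPeriodMin must be a multiple of burstPeriodMin")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic simulation
#'
#' Records everything needed to score parameter recovery: the generating
#' coefficients, the covariate moments used to standardize during
#' generation, and the realized (region, from, to) transition counts.
#'
#' @slot coefficients generating [TransitionCoefficients-class].
#' @slot covariateMoments data.frame with columns covariate, mean, sd for
#'   forage, walk, stationary, temperature (sds strictly positive).
#' @slot realizedTransitionCounts integer array region x from x to.
#' @export
setClass("SimTruth",
  representation(
    coefficients = "TransitionCoefficients",
    covariateMoments = "data.frame",
    realizedTransitionCounts = "array"
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  cm <- object@covariateMoments
  if (!all(c("covariate", "mean", "sd") %in% names(cm)))
    msg <- c(msg, "covariateMoments needs columns covariate, mean, sd")
  else if (any(cm$sd <= 0))
    msg <- c(msg, "covariate sds must be strictly positive")
  if (any(object@realizedTransitionCounts < 0))
    msg <- c(msg, "transition counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Transition model specification
#'
#' The habitat set and baseline, regions and their habitat availability, the
#' structural-zero mask, which covariate blocks enter the linear predictor,
#' prior variances, and MCMC settings. Defaults mirror the study
#' configuration: vague Normal priors with variance 100 on every coefficient
#' block, hierarchical region intercepts \eqn{\beta_{0jr} \sim N(\beta_{0j},
#' 100)} with \eqn{\beta_{0j} \sim N(0, 100)}, and a single chain of 50,000
#' iterations with 10,000 burn-in.
#'
#' @slot habitats,baseline,regions label sets; baseline coefficients fixed 0.
#' @slot regionHabitats named list of per-region available habitats.
#' @slot mask logical array region x from x to; FALSE cells are structural
#'   zeros whose transition probability is exactly 0.
#' @slot effects subset of c("time", "behavior", "temperature"); intercepts
#'   are always included.
#' @slot priorInterceptVar,priorHyperVar,priorSlopeVar prior variances.
#' @slot nIter,burnIn,nChains MCMC settings.
#' @slot seed optional integer seed.
#' @export
setClass("TransitionModelSpec",
  representation(
    habitats = "character",
    baseline = "character",
    regions = "character",
    regionHabitats = "list",
    mask = "array",
    effects = "character",
    priorInterceptVar = "numeric",
    priorHyperVar = "numeric",
    priorSlopeVar = "numeric",
    nIter = "integer",
    burnIn = "integer",
    nChains = "integer",
    seed = "integerOrNULL"
  )
)

setValidity("TransitionModelSpec", function(object) {
  H <- length(object@habitats); R <- length(object@regions)
  msg <- character()
  if (!(object@baseline %in% object@habitats))
    msg <- c(msg, "baseline must be one of the habitats")
  if (!identical(dim(object@mask), c(R, H, H)))
    msg <- c(msg, "mask must be a region x from x to array")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  jb <- match(object@baseline, object@habitats)
  if (identical(dim(object@mask), c(R, H, H)) && !is.na(jb)) {
    for (ri in seq_len(R)) {
      avail <- object@habitats %in% object@regionHabitats[[object@regions[ri]]]
      # wherever any destination is allowed from i, the baseline must be too
      anyAllowed <- apply(object@mask[ri, , , drop = FALSE], 2, any)
      if (any(anyAllowed & !object@mask[ri, , jb]))
        msg <- c(msg, sprintf(
          "mask must allow the baseline habitat wherever it is available (region '%s')",
          object@regions[ri]))
      if (any(object@mask[ri, , !avail]))
        msg <- c(msg, sprintf(
          "mask allows a destination not available in region '%s'", object@regions[ri]))
    }
  }
  if (!all(object@effects %in% c("time", "behavior", "temperature")))
    msg <- c(msg, "effects must be a subset of time/behavior/temperature")
  if (object@priorInterceptVar <= 0 || object@priorHyperVar <= 0 ||
      object@priorSlopeVar <= 0)
    msg <- c(msg, "prior variances must be strictly positive")
  if (object@burnIn >= object@nIter) msg <- c(msg, "burnIn must be < nIter")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from the Gibbs sampler
#'
#' Post-burn-in MCMC samples of every free coefficient (one named column per
#' coefficient, e.g. \code{"b0[rice|MAV]"}, \code{"b3[corn->rice]"}), the
#' log-likelihood trace, the model specification, a parameter table with
#' per-coefficient metadata (effect family, indices, number of eligible
#' records), and run metadata.
#'
#' @slot draws numeric matrix, one row per kept iteration.
#' @slot logLik numeric log-likelihood trace (kept iterations).
#' @slot spec the [TransitionModelSpec-class] used for the fit.
#' @slot paramTable data.frame of coefficient metadata.
#' @slot meta list: seed, nIter, burnIn, nRecords, runtimeSec.
#' @export
setClass("TransitionPosterior",
  representation(
    draws = "matrix",
    logLik = "numeric",
    spec = "TransitionModelSpec",
    paramTable = "data.frame",
    meta = "list"
  )
)

setValidity("TransitionPosterior", function(object) {
  msg <- character()
  if (length(object@logLik) != nrow(object@draws))
    msg <- c(msg, "logLik trace length must equal the number of kept draws")
  if (nrow(object@paramTable) != ncol(object@draws))
    msg <- c(msg, "paramTable must have one row per draw column")
  if (any(!is.finite(object@draws)))
    msg <- c(msg, "draws must be finite")
  if (length(msg)) msg else TRUE
})

#' Classifier evaluation report
#'
#' Overall accuracy, per-class precision and recall, and the confusion
#' matrix (rows = true class, columns = predicted class).
#'
#' @slot accuracy overall proportion correct.
#' @slot precision,recall named numeric vectors per class.
#' @slot confusion integer matrix of counts, rows true, columns predicted.
#' @export
setClass("ClassifierReport",
  representation(
    accuracy = "numeric",
    precision = "numeric",
    recall = "numeric",
    confusion = "matrix"
  )
)

setValidity("ClassifierReport", function(object) {
  msg <- character()
  ok01 <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok01(object@accuracy) || !ok01(object@precision) || !ok01(object@recall))
    msg <- c(msg, "accuracy, precision and recall must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
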