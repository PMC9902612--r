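#' @useDynLib habitrans, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# C++ layout for each non-baseline destination: positions of the region
# intercepts, time slopes and per-origin transition slopes inside the
# destination's jointly-updated coefficient block.
.buildLayout <- function(spec) {
  H <- length(spec@habitats); R <- length(spec@regions)
  jb <- match(spec@baseline, spec@habitats)
  useTime <- "time" %in% spec@effects
  # 1-based columns of the covariate matrix (cos_diel, sin_time, forage,
  # walk, stationary, temperature)
  slopeCov <- c(if ("behavior" %in% spec@effects) 3:5,
                if ("temperature" %in% spec@effects) 6L)
  layout <- list()
  offset <- 0L
  for (j in seq_len(H)) {
    if (j == jb) next
    p <- 0L
    intPos <- rep(-1L, R)
    for (r in seq_len(R)) {
      if (spec@habitats[j] %in% spec@regionHabitats[[spec@regions[r]]]) {
        intPos[r] <- p; p <- p + 1L
      }
    }
    timePos <- integer(0); timeCov <- integer(0)
    if (useTime) { timePos <- c(p, p + 1L); timeCov <- c(0L, 1L); p <- p + 2L }
    slopePos <- rep(-1L, H)
    if (length(slopeCov)) {
      for (i in seq_len(H)) {
        if (any(spec@mask[, i, j])) {
          slopePos[i] <- p; p <- p + length(slopeCov)
        }
      }
    }
    layout[[length(layout) + 1L]] <- list(
      j = j - 1L, offset = offset, size = p, intPos = intPos,
      timePos = as.integer(timePos), timeCov = as.integer(timeCov),
      slopePos = slopePos, slopeCov = as.integer(slopeCov - 1L))
    offset <- offset + p
  }
  attr(layout, "P") <- offset
  layout
}

# eligible-record count per free coefficient, for identifying weakly
# informed parameters in recovery reports
.eligibleCounts <- function(pt, spec, records) {
  ri <- match(records$region, spec@regions)
  fi <- match(records$from, spec@habitats)
  n <- integer(nrow(pt))
  for (j in unique(pt$to)) {
    jIdx <- match(j, spec@habitats)
    el <- spec@mask[cbind(ri, fi, jIdx)]
    rows <- which(pt$to == j)
    for (q in rows) {
      n[q] <- switch(pt$family[q],
        intercept = sum(el & spec@regions[ri] == pt$region[q]),
        hyper = 0L,
        diel = sum(el), time = sum(el),
        sum(el & records$from == pt$from[q]))
    }
  }
  n
}

.validateRecords <- function(records, spec) {
  need <- c("from", "to", "region", "cos_diel", "sin_time", "forage",
            "walk", "stationary", "temperature")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  ri <- match(records$region, spec@regions)
  fi <- match(records$from, spec@habitats)
  ti <- match(records$to, spec@habitats)
  if (anyNA(ri) || anyNA(fi) || anyNA(ti))
    stop("records contain habitat/region labels outside the model spec")
  bad <- !spec@mask[cbind(ri, fi, ti)]
  if (any(bad))
    stop(sum(bad), " record(s) contradict the structural-zero mask")
  covs <- as.matrix(records[, c("cos_diel", "sin_time", "forage", "walk",
                                "stationary", "temperature")])
  if (any(!is.finite(covs))) stop("record covariates must be finite")
  invisible(TRUE)
}

#' Fit the transition model by Polya-Gamma Gibbs sampling
#'
#' One Gibbs sweep per iteration: destinations are visited in fixed habitat
#' order; for each non-baseline destination j, every eligible record (one
#' whose region/origin allows j) contributes a binary logistic term with
#' offset c = log sum of the competing allowed destinations' exponentiated
#' linear predictors; a latent Polya-Gamma(1, eta_j - c) variable is drawn
#' per eligible record, after which all coefficients feeding j (region
#' intercepts, time slopes and per-origin behavior/temperature slopes) are
#' drawn jointly from their conjugate Gaussian full conditional, followed by
#' the conjugate Normal update of the intercept hyper-mean. The first
#' `burnIn` sweeps are discarded.
#'
#' Covariates in `records` must already be standardized (see
#' [standardizeRecords()]). The sampler consumes R's RNG stream: the spec's
#' `seed` (when non-NULL) makes the draw sequence reproducible.
#'
#' @param records standardized transition-record data.frame.
#' @param spec a [TransitionModelSpec-class].
#' @param init optional [TransitionCoefficients-class] start (default
#'   all-zero, see [initializeCoefficients()]).
#' @return a [TransitionPosterior-class].
#' @export
gibbsFit <- function(records, spec, init = NULL) {
  validObject(spec)
  .validateRecords(records, spec)
  if (!is.null(spec@seed)) set.seed(spec@seed)
  if (is.null(init)) init <- initializeCoefficients(spec)
  pt <- buildParamTable(spec)
  pt$nEligible <- .eligibleCounts(pt, spec, records)
  layout <- .buildLayout(spec)
  theta0 <- coefficientsToVector(init, spec)
  isHyper <- pt$family == "hyper"
  hyper0 <- numeric(length(spec@habitats))
  hyper0[match(pt$to[isHyper], spec@habitats)] <- theta0[isHyper]
  destNames <- spec@habitats[spec@habitats != spec@baseline]
  t0 <- proc.time()[["elapsed"]]
  res <- pgGibbsCpp(
    from = match(records$from, spec@habitats) - 1L,
    to = match(records$to, spec@habitats) - 1L,
    region = match(records$region, spec@regions) - 1L,
    X = as.matrix(records[, c("cos_diel", "sin_time", "forage", "walk",
                              "stationary", "temperature")]),
    maskArr = as.logical(spec@mask),
    H = length(spec@habitats), R = length(spec@regions),
    jb = match(spec@baseline, spec@habitats) - 1L,
    layout = layout, thetaInit = unname(theta0[!isHyper]),
    hyperInit = hyper0, vInt = spec@priorInterceptVar,
    vHyper = spec@priorHyperVar, vSlope = spec@priorSlopeVar,
    nIter = spec@nIter, burnIn = spec@burnIn, destNames = destNames)
  runtime <- proc.time()[["elapsed"]] - t0
  nKeep <- spec@nIter - spec@burnIn
  drawsMat <- matrix(0, nKeep, nrow(pt), dimnames = list(NULL, pt$name))
  drawsMat[, !isHyper] <- res$theta
  hyperCols <- match(pt$to[isHyper], destNames)
  drawsMat[, which(isHyper)] <- res$hyper[, hyperCols, drop = FALSE]
  new("TransitionPosterior", draws = drawsMat, logLik = as.numeric(res$logLik),
      spec = spec, paramTable = pt,
      meta = list(seed = spec@seed, nIter = spec@nIter, burnIn = spec@burnIn,
                  nRecords = nrow(records), runtimeSec = runtime))
}

#' Conjugate full conditional of an intercept hyper-mean
#'
#' Given region intercepts b ~ N(hyper, priorVar) i.i.d. and hyper ~
#' N(0, hyperVar), returns the posterior mean and variance of hyper:
#' precision = n/priorVar + 1/hyperVar, mean = (sum(b)/priorVar)/precision.
#' This is the update the Gibbs sampler applies after each destination's
#' intercept block.
#'
#' @param values the current region-intercept values.
#' @param priorVar intercept prior variance (default 100).
#' @param hyperVar hyper-mean prior variance (default 100).
#' @return list with `mean` and `variance`.
#' @export
hyperMeanConditional <- function(values, priorVar = 100, hyperVar = 100) {
  prec <- length(values) / priorVar + 1 / hyperVar
  list(mean = sum(values) / priorVar / prec, variance = 1 / prec)
}
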