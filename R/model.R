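#' Linear predictors of the multinomial logit
#'
#' Computes, for each transition record and each destination habitat j, the
#' log-odds of moving to j relative to the baseline habitat J:
#' \deqn{\eta_j = \beta_{0jr} + \beta_{1j} \cos(Diel) + \beta_{2j} \sin(Time)
#'   + \beta_{3ij} Forage + \beta_{4ij} Walk + \beta_{5ij} Stationary
#'   + \beta_{6ij} Temperature,}
#' with r the record's region and i its origin habitat; \eqn{\eta_J \equiv 0}.
#' Covariates are expected on the standardized scale used for the fit.
#'
#' @param records transition-record data.frame (see
#'   [buildTransitionRecords()]): columns from, region, cos_diel, sin_time,
#'   forage, walk, stationary, temperature.
#' @param coeffs a [TransitionCoefficients-class].
#' @return numeric matrix, one row per record, one column per habitat.
#'   Entries are `NA` where a required coefficient is not parameterized.
#' @export
linearPredictor <- function(records, coeffs) {
  H <- length(coeffs@habitats)
  n <- nrow(records)
  ri <- match(records$region, coeffs@regions)
  fi <- match(records$from, coeffs@habitats)
  if (anyNA(ri)) stop("record with unknown region")
  if (anyNA(fi)) stop("record with unknown origin habitat")
  eta <- matrix(0, n, H, dimnames = list(NULL, coeffs@habitats))
  jb <- match(coeffs@baseline, coeffs@habitats)
  for (j in seq_len(H)) {
    if (j == jb) next
    eta[, j] <- coeffs@intercepts[j, ][ri] +
      coeffs@diel[j] * records$cos_diel + coeffs@time[j] * records$sin_time +
      coeffs@forage[cbind(fi, j)] * records$forage +
      coeffs@walk[cbind(fi, j)] * records$walk +
      coeffs@stationary[cbind(fi, j)] * records$stationary +
      coeffs@temperature[cbind(fi, j)] * records$temperature
  }
  eta
}

#' Transition probabilities
#'
#' Softmax of the linear predictors over each record's allowed destinations,
#' computed with max subtraction for overflow safety. Masked (structural
#' zero) destinations have probability exactly 0.
#'
#' @inheritParams linearPredictor
#' @param mask logical region x from x to array of allowed transitions.
#' @return numeric matrix, one row per record summing to 1 over habitats.
#' @export
transitionProbs <- function(records, coeffs, mask) {
  eta <- linearPredictor(records, coeffs)
  ri <- match(records$region, coeffs@regions)
  fi <- match(records$from, coeffs@habitats)
  H <- ncol(eta)
  allowed <- matrix(FALSE, nrow(eta), H)
  for (j in seq_len(H)) allowed[, j] <- mask[cbind(ri, fi, j)]
  if (any(rowSums(allowed) == 0)) stop("record with no allowed destination")
  if (any(is.na(eta[allowed]))) stop("unparameterized coefficient for an allowed destination")
  eta[!allowed] <- -Inf
  m <- apply(eta, 1, max)
  w <- exp(eta - m)
  w / rowSums(w)
}

#' Log-likelihood of transition records
#'
#' Sum over records of the log transition probability of the observed
#' destination. A record whose own (region, from, to) cell is masked has
#' probability 0 and signals a data/mask inconsistency.
#'
#' @inheritParams transitionProbs
#' @export
logLikelihood <- function(records, coeffs, mask) {
  p <- transitionProbs(records, coeffs, mask)
  ti <- match(records$to, coeffs@habitats)
  if (anyNA(ti)) stop("record with unknown destination habitat")
  pObs <- p[cbind(seq_len(nrow(p)), ti)]
  if (any(pObs == 0))
    stop("observed transition has probability 0 (masked destination observed); ",
         "data and mask are inconsistent")
  sum(log(pObs))
}
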