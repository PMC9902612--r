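#' Posterior effect summaries
#'
#' Posterior mean and equal-tailed credible interval for every coefficient,
#' grouped by effect family (region intercepts; hyper-means; cos-diel and
#' sin-time slopes; forage, walk, stationary and temperature
#' transition-specific slopes). Log-odds scale, relative to transitions
#' into the baseline habitat. The sign-significance flag marks intervals
#' excluding 0.
#'
#' @param post a [TransitionPosterior-class].
#' @param prob interval mass (default 0.95, i.e. 2.5-97.5% quantiles).
#' @return data.frame: name, family, from, to, region, mean, lower, upper,
#'   significant, nEligible.
#' @export
summarizeDraws <- function(post, prob = 0.95) {
  dr <- draws(post)
  if (nrow(dr) == 0L) stop("empty draws")
  a <- (1 - prob) / 2
  q <- t(apply(dr, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  out <- post@paramTable
  out$mean <- colMeans(dr)
  out$lower <- q[, 1]
  out$upper <- q[, 2]
  out$significant <- out$lower > 0 | out$upper < 0
  out
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the means of an early and a late segment of a chain,
#' each standard error estimated from the segment's spectral density at
#' frequency zero (autoregressive estimator, as in the coda package):
#' z = (mean_first - mean_last) / sqrt(se1^2 + se2^2).
#'
#' @param chain numeric vector (length >= 20).
#' @param first,last fractions of the chain used for the early and late
#'   segments (defaults 0.1 and 0.5; must sum to at most 1).
#' @return the z score.
#' @export
gewekeDiag <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  if (n < 20L) stop("chain too short for the Geweke diagnostic")
  if (first + last > 1) stop("first + last must be <= 1")
  x1 <- chain[seq_len(floor(first * n))]
  x2 <- chain[(n - floor(last * n) + 1L):n]
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("degenerate (zero-variance) chain segment")
  se2 <- function(x) .spectrum0ar(x) / length(x)
  (mean(x1) - mean(x2)) / sqrt(se2(x1) + se2(x2))
}

# spectral density at frequency zero via an AIC-selected AR fit
.spectrum0ar <- function(x) {
  fit <- stats::ar(x, aic = TRUE)
  if (length(fit$ar) == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke diagnostics for every coefficient
#'
#' @param post a [TransitionPosterior-class].
#' @inheritParams gewekeDiag
#' @return data.frame: name, z, firstFrac, lastFrac.
#' @export
gewekeReport <- function(post, first = 0.1, last = 0.5) {
  z <- apply(draws(post), 2, gewekeDiag, first = first, last = last)
  data.frame(name = coefNames(post), z = unname(z),
             firstFrac = first, lastFrac = last, stringsAsFactors = FALSE)
}

#' Sample autocorrelation function of a chain
#'
#' Standard sample ACF (lag 0 equals 1 by definition).
#'
#' @param chain numeric vector, longer than `maxLag`.
#' @param maxLag largest lag.
#' @return numeric vector of length maxLag + 1 (lags 0..maxLag).
#' @export
acfValues <- function(chain, maxLag) {
  if (length(chain) <= maxLag) stop("chain must be longer than maxLag")
  if (stats::var(chain) == 0) stop("degenerate (zero-variance) chain")
  as.numeric(stats::acf(chain, lag.max = maxLag, plot = FALSE)$acf)
}

#' Effective sample size and Monte-Carlo standard error
#'
#' Nonoverlapping batch-means estimators: `mcseMean` returns the MC
#' standard error of the chain mean; `essBasic` the implied effective
#' sample size.
#'
#' @param chain numeric vector.
#' @rdname mcse
#' @export
mcseMean <- function(chain) {
  n <- length(chain)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  bm <- colMeans(matrix(chain[seq_len(nb * b)], nrow = b))
  sqrt(stats::var(bm) / nb)
}

#' @rdname mcse
#' @export
essBasic <- function(chain) {
  stats::var(chain) / mcseMean(chain)^2
}

#' Posterior predicted transition matrix
#'
#' For one region and one covariate setting (standardized scale), averages
#' the per-draw softmax transition rows over the posterior. Masked cells
#' are exactly 0 in every draw, so rows sum to 1 over allowed destinations
#' draw by draw. Origin habitats with no allowed destination in the region
#' (unavailable there) yield NA rows.
#'
#' @param post a [TransitionPosterior-class].
#' @param region region label.
#' @param covariates named numeric vector on the standardized scale
#'   (cos_diel, sin_time, forage, walk, stationary, temperature); absent
#'   entries default to 0.
#' @param prob credible-interval mass (default 0.95).
#' @return list of from x to matrices: `mean`, `lower`, `upper`.
#' @export
predictedTransitionMatrix <- function(post, region, covariates = numeric(),
                                      prob = 0.95) {
  spec <- post@spec
  if (!(region %in% spec@regions)) stop("unknown region: ", region)
  r <- match(region, spec@regions)
  cv <- c(cos_diel = 0, sin_time = 0, forage = 0, walk = 0,
          stationary = 0, temperature = 0)
  stopifnot(all(names(covariates) %in% names(cv)))
  cv[names(covariates)] <- covariates
  dr <- draws(post)
  H <- length(spec@habitats)
  jb <- match(spec@baseline, spec@habitats)
  a <- (1 - prob) / 2
  col0 <- function(nm) if (nm %in% colnames(dr)) dr[, nm] else 0
  mkMat <- function() matrix(NA_real_, H, H,
                             dimnames = list(spec@habitats, spec@habitats))
  mMean <- mkMat(); mLo <- mkMat(); mHi <- mkMat()
  for (i in seq_len(H)) {
    allowed <- which(spec@mask[r, i, ])
    if (length(allowed) == 0L) next
    eta <- matrix(0, nrow(dr), length(allowed))
    for (a2 in seq_along(allowed)) {
      j <- allowed[a2]
      if (j == jb) next
      dest <- spec@habitats[j]
      eta[, a2] <- dr[, sprintf("b0[%s|%s]", dest, region)] +
        col0(sprintf("b1[%s]", dest)) * cv[["cos_diel"]] +
        col0(sprintf("b2[%s]", dest)) * cv[["sin_time"]] +
        col0(sprintf("b3[%s->%s]", spec@habitats[i], dest)) * cv[["forage"]] +
        col0(sprintf("b4[%s->%s]", spec@habitats[i], dest)) * cv[["walk"]] +
        col0(sprintf("b5[%s->%s]", spec@habitats[i], dest)) * cv[["stationary"]] +
        col0(sprintf("b6[%s->%s]", spec@habitats[i], dest)) * cv[["temperature"]]
    }
    m <- apply(eta, 1, max)
    w <- exp(eta - m)
    p <- w / rowSums(w)
    mMean[i, ] <- 0; mLo[i, ] <- 0; mHi[i, ] <- 0
    mMean[i, allowed] <- colMeans(p)
    qs <- apply(p, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    mLo[i, allowed] <- qs[1, ]
    mHi[i, allowed] <- qs[2, ]
  }
  list(mean = mMean, lower = mLo, upper = mHi)
}

#' Parameter-recovery report
#'
#' Scores a fit on synthetic data against the generating truth:
#' per-coefficient bias, credible-interval coverage indicator, and
#' aggregate coverage and truth-vs-posterior-mean correlation over
#' well-identified coefficients (at least `minEligible` eligible records;
#' intercept hyper-means are excluded as prior-identified). If the fit was
#' standardized on a different covariate scale than generation, pass the
#' fit's standardization: slope truths are rescaled by the sd ratio
#' (centering is assumed to match, as it does when the fit reuses the
#' generator's stored moments).
#'
#' @param post a [TransitionPosterior-class] fit on data generated with
#'   `truth`.
#' @param truth the [SimTruth-class] from [simulateTracks()].
#' @param standardization optional standardization spec of the fit.
#' @param prob interval mass (default 0.95).
#' @param minEligible well-identified threshold (default 30 records).
#' @return data.frame per coefficient (name, family, truth, mean, lower,
#'   upper, bias, covered, nEligible, wellIdentified) with attributes
#'   `coverage` and `correlation` computed over well-identified
#'   coefficients.
#' @export
recoveryReport <- function(post, truth, standardization = NULL, prob = 0.95,
                           minEligible = 30L) {
  summ <- summarizeDraws(post, prob = prob)
  tv <- coefficientsToVector(truth@coefficients, post@spec)
  if (!all(summ$name == names(tv)))
    stop("coefficient name mismatch between draws and truth")
  tvAdj <- unname(tv)
  if (!is.null(standardization)) {
    gen <- truth@covariateMoments
    fam2cov <- c(forage = "forage", walk = "walk", stationary = "stationary",
                 temperature = "temperature")
    for (fam in names(fam2cov)) {
      sel <- summ$family == fam
      sFit <- standardization$sd[match(fam2cov[[fam]], standardization$covariate)]
      sGen <- gen$sd[match(fam2cov[[fam]], gen$covariate)]
      tvAdj[sel] <- tvAdj[sel] * sFit / sGen
    }
  }
  out <- data.frame(name = summ$name, family = summ$family,
                    truth = tvAdj, mean = summ$mean,
                    lower = summ$lower, upper = summ$upper,
                    bias = summ$mean - tvAdj,
                    covered = summ$lower <= tvAdj & tvAdj <= summ$upper,
                    nEligible = summ$nEligible,
                    stringsAsFactors = FALSE)
  out$wellIdentified <- out$family != "hyper" & out$nEligible >= minEligible &
    !is.na(out$truth)
  wi <- out[out$wellIdentified, ]
  attr(out, "coverage") <- mean(wi$covered)
  attr(out, "correlation") <- stats::cor(wi$truth, wi$mean)
  out
}

#' Forest plot of posterior effects
#'
#' Point estimates with credible intervals, one panel per effect family,
#' echoing the usual presentation of habitat- and transition-specific
#' effects on the log-odds scale.
#'
#' @param summary output of [summarizeDraws()].
#' @param families effect families to include (default all).
#' @return a ggplot object.
#' @export
plotEffects <- function(summary, families = unique(summary$family)) {
  df <- summary[summary$family %in% families, ]
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = name)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = lower, xmax = upper),
                            height = 0) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(x = "effect on transition log-odds (vs baseline habitat)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
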