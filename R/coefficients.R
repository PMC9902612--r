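#' Construct a coefficient set
#'
#' Builds a [TransitionCoefficients-class] object. Entries into the baseline
#' habitat are forced to exactly 0; entries for (habitat, region) pairs where
#' the habitat is unavailable are `NA`. With no block arguments the object is
#' all-zero (the multinomial logit then reduces to a uniform distribution over
#' each region's allowed destinations).
#'
#' @param habitats ordered habitat labels.
#' @param baseline baseline habitat label (coefficients into it are 0).
#' @param regions region labels.
#' @param regionHabitats named list region -> available habitats; defaults to
#'   all habitats in every region.
#' @param intercepts habitats x regions matrix of `b0[j|r]` (or NULL for 0).
#' @param hyperMeans,diel,time numeric vectors over habitats.
#' @param forage,walk,stationary,temperature from x to matrices of
#'   transition-specific slopes.
#' @return a `TransitionCoefficients` object.
#' @export
transitionCoefficients <- function(habitats = defaultHabitats(),
                                   baseline = defaultBaseline(),
                                   regions = defaultRegions(),
                                   regionHabitats = NULL,
                                   intercepts = NULL, hyperMeans = NULL,
                                   diel = NULL, time = NULL,
                                   forage = NULL, walk = NULL,
                                   stationary = NULL, temperature = NULL) {
  H <- length(habitats); R <- length(regions)
  if (is.null(regionHabitats))
    regionHabitats <- stats::setNames(rep(list(habitats), R), regions)
  fillMat <- function(x, dims, dn) {
    if (is.null(x)) x <- matrix(0, dims[1], dims[2])
    stopifnot(identical(dim(x), as.integer(dims)))
    dimnames(x) <- dn
    x
  }
  fillVec <- function(x) {
    if (is.null(x)) x <- numeric(H)
    stopifnot(length(x) == H)
    stats::setNames(as.numeric(x), habitats)
  }
  int <- fillMat(intercepts, c(H, R), list(habitats, regions))
  # NA out intercepts where the destination is unavailable in the region
  for (r in regions) int[!(habitats %in% regionHabitats[[r]]), r] <- NA_real_
  jb <- match(baseline, habitats)
  int[jb, !is.na(int[jb, ])] <- 0
  hm <- fillVec(hyperMeans); dl <- fillVec(diel); tm <- fillVec(time)
  hm[jb] <- 0; dl[jb] <- 0; tm[jb] <- 0
  mats <- lapply(list(forage, walk, stationary, temperature), fillMat,
                 dims = c(H, H), dn = list(habitats, habitats))
  mats <- lapply(mats, function(m) { m[, jb] <- 0; m })
  new("TransitionCoefficients", habitats = habitats, baseline = baseline,
      regions = regions, intercepts = int, hyperMeans = hm, diel = dl,
      time = tm, forage = mats[[1]], walk = mats[[2]],
      stationary = mats[[3]], temperature = mats[[4]])
}

#' Draw a random coefficient set
#'
#' Convenience for simulation studies: fills every free entry with an
#' independent Uniform(-maxAbs, maxAbs) draw (baseline entries stay 0,
#' unavailable intercepts stay `NA`). Hyper-means are set to the per-habitat
#' mean of the drawn region intercepts.
#'
#' @param maxAbs maximum coefficient magnitude (default 1).
#' @param seed optional integer seed.
#' @inheritParams transitionCoefficients
#' @export
randomCoefficients <- function(habitats = defaultHabitats(),
                               baseline = defaultBaseline(),
                               regions = defaultRegions(),
                               regionHabitats = NULL,
                               maxAbs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- length(habitats); R <- length(regions)
  runifMat <- function(n1, n2) matrix(stats::runif(n1 * n2, -maxAbs, maxAbs), n1, n2)
  co <- transitionCoefficients(
    habitats, baseline, regions, regionHabitats,
    intercepts = runifMat(H, R),
    diel = stats::runif(H, -maxAbs, maxAbs),
    time = stats::runif(H, -maxAbs, maxAbs),
    forage = runifMat(H, H), walk = runifMat(H, H),
    stationary = runifMat(H, H), temperature = runifMat(H, H))
  hm <- rowMeans(co@intercepts, na.rm = TRUE)
  hm[match(baseline, habitats)] <- 0
  co@hyperMeans <- stats::setNames(hm, habitats)
  validObject(co)
  co
}

#' Availability-only structural mask
#'
#' Logical region x from x to array: a cell is allowed iff both habitats are
#' available in the region. This is the mask the generator uses; fitted
#' models typically tighten it with [structuralMask()] so that transitions
#' never observed are excluded from estimation.
#'
#' @param regionHabitats named list region -> available habitats.
#' @param habitats,regions full label sets (define array order).
#' @return logical array with dimnames (region, from, to).
#' @export
availabilityMask <- function(regionHabitats, habitats, regions) {
  H <- length(habitats); R <- length(regions)
  mask <- array(FALSE, c(R, H, H), dimnames = list(regions, habitats, habitats))
  for (r in seq_len(R)) {
    av <- habitats %in% regionHabitats[[regions[r]]]
    mask[r, , ] <- outer(av, av, `&`)
  }
  mask
}

#' Specify a transition model
#'
#' See [TransitionModelSpec-class] for the meaning of each component. If
#' `mask` is NULL the availability-only mask is used.
#'
#' @param habitats,baseline,regions,regionHabitats label structure.
#' @param mask logical region x from x to array of allowed transitions.
#' @param effects covariate blocks to include ("time", "behavior",
#'   "temperature"); intercepts are always included.
#' @param priorInterceptVar,priorHyperVar,priorSlopeVar Normal prior
#'   variances (all default 100).
#' @param nIter,burnIn,nChains MCMC settings (defaults 50000 / 10000 / 1).
#' @param seed optional integer seed for the sampler.
#' @export
transitionModelSpec <- function(habitats = defaultHabitats(),
                                baseline = defaultBaseline(),
                                regions = defaultRegions(),
                                regionHabitats = NULL,
                                mask = NULL,
                                effects = c("time", "behavior", "temperature"),
                                priorInterceptVar = 100,
                                priorHyperVar = 100,
                                priorSlopeVar = 100,
                                nIter = 50000L, burnIn = 10000L,
                                nChains = 1L, seed = NULL) {
  if (is.null(regionHabitats))
    regionHabitats <- stats::setNames(rep(list(habitats), length(regions)), regions)
  if (is.null(mask)) mask <- availabilityMask(regionHabitats, habitats, regions)
  new("TransitionModelSpec", habitats = habitats, baseline = baseline,
      regions = regions, regionHabitats = regionHabitats, mask = mask,
      effects = effects, priorInterceptVar = priorInterceptVar,
      priorHyperVar = priorHyperVar, priorSlopeVar = priorSlopeVar,
      nIter = as.integer(nIter), burnIn = as.integer(burnIn),
      nChains = as.integer(nChains),
      seed = if (is.null(seed)) NULL else as.integer(seed))
}

#' Initial coefficient values for the sampler
#'
#' Default all-zero start; optionally adds seeded Normal(0, jitterSd^2)
#' jitter on every free entry, used for multi-start convergence checks.
#'
#' @param spec a [TransitionModelSpec-class].
#' @param jitterSd standard deviation of the start jitter (default 0).
#' @param seed optional integer seed for the jitter.
#' @export
initializeCoefficients <- function(spec, jitterSd = 0, seed = NULL) {
  co <- transitionCoefficients(spec@habitats, spec@baseline, spec@regions,
                               spec@regionHabitats)
  if (jitterSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pt <- buildParamTable(spec)
    theta <- stats::rnorm(nrow(pt), 0, jitterSd)
    co <- vectorToCoefficients(stats::setNames(theta, pt$name), spec)
  }
  co
}

# -- parameter bookkeeping ---------------------------------------------------

# Effect-family prefixes follow the model equation's numbering:
# b0 region intercepts, b0m hyper-means, b1 cos(Diel), b2 sin(Time),
# b3 forage, b4 walk, b5 stationary, b6 temperature.
.slopeBlocks <- data.frame(
  prefix = c("b3", "b4", "b5", "b6"),
  slot = c("forage", "walk", "stationary", "temperature"),
  covariate = c("forage", "walk", "stationary", "temperature"),
  stringsAsFactors = FALSE)

#' Coefficient table for a model specification
#'
#' One row per free coefficient (in sampler update order): name, effect
#' family, destination habitat, origin habitat (transition-specific effects
#' only) and region (intercepts only). Destination-habitat blocks appear in
#' habitat order; the baseline habitat has no parameters. A transition-
#' specific slope `(i -> j)` is parameterized iff the mask allows `(i, j)`
#' in at least one region.
#'
#' @param spec a [TransitionModelSpec-class].
#' @export
buildParamTable <- function(spec) {
  H <- length(spec@habitats); R <- length(spec@regions)
  jb <- match(spec@baseline, spec@habitats)
  useTime <- "time" %in% spec@effects
  slopeUse <- c("behavior" %in% spec@effects, "behavior" %in% spec@effects,
                "behavior" %in% spec@effects, "temperature" %in% spec@effects)
  rows <- list()
  for (j in seq_len(H)) {
    if (j == jb) next
    dest <- spec@habitats[j]
    for (r in seq_len(R)) {
      if (dest %in% spec@regionHabitats[[spec@regions[r]]])
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("b0[%s|%s]", dest, spec@regions[r]),
          family = "intercept", to = dest, from = NA, region = spec@regions[r])
    }
    if (useTime) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("b1[%s]", dest), family = "diel",
        to = dest, from = NA, region = NA)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("b2[%s]", dest), family = "time",
        to = dest, from = NA, region = NA)
    }
    for (i in seq_len(H)) {
      if (!any(spec@mask[, i, j])) next
      for (k in seq_len(4)) {
        if (!slopeUse[k]) next
        rows[[length(rows) + 1L]] <- data.frame(
          name = sprintf("%s[%s->%s]", .slopeBlocks$prefix[k],
                         spec@habitats[i], dest),
          family = .slopeBlocks$slot[k], to = dest,
          from = spec@habitats[i], region = NA)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("b0m[%s]", dest), family = "hyper",
      to = dest, from = NA, region = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flatten coefficients to a named vector / rebuild from one
#'
#' `coefficientsToVector` extracts the free coefficients of `coeffs` in the
#' order of `buildParamTable(spec)`; `vectorToCoefficients` is its inverse
#' (entries absent from the vector are `NA` in the rebuilt object).
#'
#' @param coeffs a [TransitionCoefficients-class].
#' @param spec a [TransitionModelSpec-class].
#' @param theta named numeric vector of coefficients.
#' @rdname coefVector
#' @export
coefficientsToVector <- function(coeffs, spec) {
  pt <- buildParamTable(spec)
  out <- numeric(nrow(pt))
  for (q in seq_len(nrow(pt))) {
    fam <- pt$family[q]
    out[q] <- switch(fam,
      intercept = coeffs@intercepts[pt$to[q], pt$region[q]],
      hyper = coeffs@hyperMeans[pt$to[q]],
      diel = coeffs@diel[pt$to[q]],
      time = coeffs@time[pt$to[q]],
      slot(coeffs, fam)[pt$from[q], pt$to[q]])
  }
  stats::setNames(out, pt$name)
}

#' @rdname coefVector
#' @export
vectorToCoefficients <- function(theta, spec) {
  pt <- buildParamTable(spec)
  stopifnot(all(pt$name %in% names(theta)))
  co <- transitionCoefficients(spec@habitats, spec@baseline, spec@regions,
                               spec@regionHabitats)
  jb <- match(spec@baseline, spec@habitats)
  # entries of included effect families that are never parameterized become
  # NA; excluded families stay structurally 0
  slopeSlots <- c(if ("behavior" %in% spec@effects)
                    c("forage", "walk", "stationary"),
                  if ("temperature" %in% spec@effects) "temperature")
  for (s in slopeSlots) {
    m <- slot(co, s); m[] <- NA_real_; m[, jb] <- 0; slot(co, s) <- m
  }
  if ("time" %in% spec@effects) {
    co@diel[-jb] <- NA_real_; co@time[-jb] <- NA_real_
  }
  for (q in seq_len(nrow(pt))) {
    v <- unname(theta[pt$name[q]])
    fam <- pt$family[q]
    if (fam == "intercept") co@intercepts[pt$to[q], pt$region[q]] <- v
    else if (fam == "hyper") co@hyperMeans[pt$to[q]] <- v
    else if (fam == "diel") co@diel[pt$to[q]] <- v
    else if (fam == "time") co@time[pt$to[q]] <- v
    else { m <- slot(co, fam); m[pt$from[q], pt$to[q]] <- v; slot(co, fam) <- m }
  }
  co
}
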