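#' Synthetic-data generator configuration
#'
#' Builds a [SimConfig-class] with defaults that emulate the winter goose
#' tracking design: GPS fixes every 30 min with i.i.d. missingness, ACC
#' bursts every 6 min (3 s at 10 Hz, 30 samples per axis), 8 landcover
#' categories across 7 wintering regions with region-specific habitat
#' availability, habitat-conditioned behavior mixes, and a diel AR(1)
#' temperature process. Habitat sequences are generated from the package's
#' own transition model with the supplied ground-truth coefficients.
#'
#' Default region availability drops corn from the Chenier Plain and rice
#' from the Rolling/High Plains, giving the structural-zero machinery real
#' work on default settings. Default Dirichlet concentrations make crops
#' forage-heavy and open water / woody wetlands stationary-heavy (roosting),
#' with flight rare everywhere.
#'
#' @param habitats,regions,regionHabitats,baselineHabitat label structure.
#' @param trueCoefficients generating [TransitionCoefficients-class]
#'   (standardized-covariate scale); default all-zero.
#' @param nIndividuals,nSteps track dimensions (default 20 x 1500).
#' @param pMissing per-fix missingness probability (default 0.05).
#' @param burstPeriodMin,fixPeriodMin cadences in minutes.
#' @param behaviorAlpha named list habitat -> Dirichlet concentrations over
#'   (forage, walk, stationary, flight).
#' @param tempParams named numeric (mean, amplitude, ar, sd).
#' @param startTime first fix timestamp (local clock time).
#' @param seed integer RNG seed.
#' @export
simConfig <- function(habitats = defaultHabitats(),
                      regions = defaultRegions(),
                      regionHabitats = NULL,
                      baselineHabitat = defaultBaseline(),
                      trueCoefficients = NULL,
                      nIndividuals = 20L, nSteps = 1500L,
                      pMissing = 0.05,
                      burstPeriodMin = 6, fixPeriodMin = 30,
                      behaviorAlpha = NULL,
                      tempParams = c(mean = 10, amplitude = 4, ar = 0.7, sd = 1.5),
                      startTime = as.POSIXct("2017-01-05 00:00:00", tz = "UTC"),
                      seed = 1L) {
  if (is.null(regionHabitats)) {
    regionHabitats <- stats::setNames(rep(list(habitats), length(regions)), regions)
    if ("Chenier Plain" %in% regions)
      regionHabitats[["Chenier Plain"]] <-
        setdiff(regionHabitats[["Chenier Plain"]], "corn")
    if ("Rolling/High Plains" %in% regions)
      regionHabitats[["Rolling/High Plains"]] <-
        setdiff(regionHabitats[["Rolling/High Plains"]], "rice")
  }
  if (is.null(behaviorAlpha)) {
    crops <- c("corn", "grass/winter wheat", "other grains", "rice")
    behaviorAlpha <- lapply(habitats, function(h) {
      if (h %in% crops) c(forage = 6, walk = 2, stationary = 2, flight = 0.8)
      else if (h == baselineHabitat) c(forage = 1, walk = 1.5, stationary = 6, flight = 1)
      else if (h == "woody wetlands") c(forage = 1.5, walk = 1.5, stationary = 6, flight = 1)
      else if (h == "herbaceous wetlands") c(forage = 3, walk = 2, stationary = 4, flight = 1)
      else c(forage = 2, walk = 2, stationary = 3, flight = 1)
    })
    names(behaviorAlpha) <- habitats
  }
  if (is.null(trueCoefficients))
    trueCoefficients <- transitionCoefficients(habitats, baselineHabitat,
                                               regions, regionHabitats)
  new("SimConfig", habitats = habitats, regions = regions,
      regionHabitats = regionHabitats, baselineHabitat = baselineHabitat,
      trueCoefficients = trueCoefficients,
      nIndividuals = as.integer(nIndividuals), nSteps = as.integer(nSteps),
      pMissing = pMissing, burstPeriodMin = burstPeriodMin,
      fixPeriodMin = fixPeriodMin, behaviorAlpha = behaviorAlpha,
      tempParams = tempParams, startTime = startTime, seed = as.integer(seed))
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Closed-form covariate moments used for generation
#'
#' Mean and sd of the burst-count behavior proportions (forage, walk,
#' stationary) under a uniform mix over habitats of the habitat-conditioned
#' Dirichlet, with the extra multinomial variance from observing B bursts
#' per fix interval, and the stationary mean/sd of the diel AR(1)
#' temperature process (cosine variance amplitude^2/2 plus AR(1) stationary
#' variance). These are the moments the generator standardizes with; they
#' are stored in the returned [SimTruth-class] so that fits can be run on
#' exactly the generating covariate scale.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns covariate, mean, sd.
#' @export
generationMoments <- function(config) {
  B <- config@fixPeriodMin / config@burstPeriodMin
  al <- config@behaviorAlpha
  mom <- lapply(1:3, function(k) {
    mh <- vapply(al, function(a) a[k] / sum(a), 0)
    A <- vapply(al, sum, 0)
    vh <- mh * (1 - mh) * (A + B) / (B * (A + 1))
    m <- mean(mh)
    v <- mean(vh + mh^2) - m^2
    c(m, sqrt(v))
  })
  tp <- config@tempParams
  vT <- tp[["amplitude"]]^2 / 2 +
    if (tp[["sd"]] > 0) tp[["sd"]]^2 / (1 - tp[["ar"]]^2) else 0
  data.frame(
    covariate = c("forage", "walk", "stationary", "temperature"),
    mean = c(vapply(mom, `[`, 0, 1), tp[["mean"]]),
    sd = c(vapply(mom, `[`, 0, 2), if (vT > 0) sqrt(vT) else 1),
    stringsAsFactors = FALSE)
}

#' Simulate one behavior-proportion draw per row
#'
#' Draws Dirichlet(behaviorAlpha[habitat]) vectors over
#' (forage, walk, stationary, flight); each row sums to 1.
#'
#' @param habitat a habitat label present in the configuration.
#' @param config a [SimConfig-class].
#' @param n number of draws.
#' @return n x 4 matrix with columns named by [BEHAVIORS].
#' @export
simulateBehaviorProportions <- function(habitat, config, n = 1) {
  if (!habitat %in% config@habitats)
    stop("unknown habitat: ", habitat)
  a <- config@behaviorAlpha[[habitat]]
  out <- t(vapply(seq_len(n), function(i) .rdirichlet1(a), numeric(4)))
  colnames(out) <- BEHAVIORS
  out
}

#' Simulate a diel AR(1) temperature series
#'
#' temperature(t) = mean + amplitude * cos(2 pi hour(t) / 24 - pi) + e(t),
#' with e(t) a stationary AR(1) process. The cosine peaks at hour 12 and
#' bottoms at hour 0.
#'
#' @param nSteps number of fixes.
#' @param t0 timestamp of the first fix.
#' @param tempParams named numeric (mean, amplitude, ar, sd).
#' @param fixPeriodMin minutes between fixes (default 30).
#' @return numeric vector of length nSteps (degrees C).
#' @export
simulateTemperature <- function(nSteps, t0, tempParams, fixPeriodMin = 30) {
  ar <- tempParams[["ar"]]; sd <- tempParams[["sd"]]
  if (abs(ar) >= 1) stop("AR coefficient must be in (-1, 1)")
  if (sd < 0) stop("innovation sd must be nonnegative")
  times <- t0 + fixPeriodMin * 60 * (seq_len(nSteps) - 1)
  lt <- as.POSIXlt(times)
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  diel <- tempParams[["amplitude"]] * cos(2 * pi * hour / 24 - pi)
  e <- numeric(nSteps)
  if (sd > 0) {
    e[1] <- stats::rnorm(1, 0, sd / sqrt(1 - ar^2))
    innov <- stats::rnorm(nSteps - 1, 0, sd)
    for (t in seq_len(nSteps - 1)) e[t + 1] <- ar * e[t] + innov[t]
  }
  tempParams[["mean"]] + diel + e
}

#' Simulate GPS tracks from the transition model
#'
#' For each individual (region fixed per individual, assigned round-robin
#' over the configured regions), simulates a habitat sequence on the 30-min
#' fix grid step-by-step from the package's own multinomial logistic
#' transition model with the configured ground-truth coefficients,
#' restricted to the region's available habitats. At each fix a behavior mix
#' is drawn from the habitat-conditioned Dirichlet, burst labels for the
#' interval are drawn i.i.d. from it, and the resulting burst-count
#' proportions (standardized with [generationMoments()]) are the covariates
#' that drive the next transition, so covariates rebuilt downstream from
#' burst labels reproduce the generating covariates exactly. Fixes are then
#' dropped i.i.d. with probability `pMissing`.
#'
#' @param config a [SimConfig-class]; a region whose available-habitat set
#'   has fewer than 2 habitats is rejected.
#' @return list with elements `fixes` (retained-fix table: individual_id,
#'   timestamp, habitat, region, temperature_c), `truth` (a
#'   [SimTruth-class]), and `grid` (the full pre-missingness table including
#'   behavior proportions and the interval's burst labels, needed by
#'   [simulateBursts()]).
#' @export
simulateTracks <- function(config) {
  validObject(config)
  set.seed(config@seed)
  H <- length(config@habitats); R <- length(config@regions)
  co <- config@trueCoefficients
  mom <- generationMoments(config)
  mB <- mom$mean[1:3]; sB <- mom$sd[1:3]
  mT <- mom$mean[4]; sT <- mom$sd[4]
  B <- as.integer(config@fixPeriodMin / config@burstPeriodMin)
  jb <- match(config@baselineHabitat, config@habitats)
  counts <- array(0L, c(R, H, H),
                  dimnames = list(config@regions, config@habitats, config@habitats))
  alphaIdx <- config@behaviorAlpha[config@habitats]
  rows <- vector("list", config@nIndividuals)
  for (ind in seq_len(config@nIndividuals)) {
    rIdx <- (ind - 1L) %% R + 1L
    region <- config@regions[rIdx]
    availIdx <- which(config@habitats %in% config@regionHabitats[[region]])
    times <- config@startTime + config@fixPeriodMin * 60 * (seq_len(config@nSteps) - 1)
    temp <- simulateTemperature(config@nSteps, config@startTime,
                                config@tempParams, config@fixPeriodMin)
    lt <- as.POSIXlt(times)
    hour <- lt$hour + lt$min / 60 + lt$sec / 3600
    cosd <- cos(2 * pi * hour / 24)
    sint <- sin(2 * pi * hour / 24)
    hIdx <- integer(config@nSteps)
    hIdx[1] <- sample(availIdx, 1)
    phat <- matrix(0, config@nSteps, 4)
    labStr <- character(config@nSteps)
    for (t in seq_len(config@nSteps)) {
      p <- .rdirichlet1(alphaIdx[[hIdx[t]]])
      labs <- sample.int(4L, B, replace = TRUE, prob = p)
      phat[t, ] <- tabulate(labs, 4L) / B
      labStr[t] <- paste(BEHAVIORS[labs], collapse = ",")
      if (t < config@nSteps) {
        z <- (phat[t, 1:3] - mB) / sB
        zt <- (temp[t] - mT) / sT
        i <- hIdx[t]
        eta <- co@intercepts[availIdx, rIdx] +
          co@diel[availIdx] * cosd[t] + co@time[availIdx] * sint[t] +
          co@forage[i, availIdx] * z[1] + co@walk[i, availIdx] * z[2] +
          co@stationary[i, availIdx] * z[3] + co@temperature[i, availIdx] * zt
        eta <- eta - max(eta)
        w <- exp(eta)
        nxt <- availIdx[sample.int(length(availIdx), 1, prob = w)]
        counts[rIdx, i, nxt] <- counts[rIdx, i, nxt] + 1L
        hIdx[t + 1] <- nxt
      }
    }
    rows[[ind]] <- data.frame(
      individual_id = sprintf("bird_%02d", ind),
      timestamp = times,
      habitat = config@habitats[hIdx],
      region = region,
      temperature_c = temp,
      p_forage = phat[, 1], p_walk = phat[, 2],
      p_stationary = phat[, 3], p_flight = phat[, 4],
      burst_labels = labStr,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  keep <- stats::runif(nrow(grid)) >= config@pMissing
  fixes <- grid[keep, c("individual_id", "timestamp", "habitat", "region",
                        "temperature_c")]
  rownames(fixes) <- NULL
  truth <- new("SimTruth", coefficients = co, covariateMoments = mom,
               realizedTransitionCounts = counts)
  list(fixes = fixes, truth = truth, grid = grid)
}

# per-behavior signal templates (g units): per-axis mean and sd. Chosen so
# per-axis summary statistics separate the classes; stationary variance is
# below flight variance by construction.
.burstTemplates <- list(
  forage = list(mean = c(0.30, 0.05, 0.90), sd = c(0.25, 0.20, 0.25)),
  walk = list(mean = c(0.10, 0.10, 1.00), sd = c(0.10, 0.10, 0.12)),
  stationary = list(mean = c(0.00, 0.00, 1.00), sd = c(0.02, 0.02, 0.02)),
  flight = list(mean = c(0.00, 0.00, 1.20), sd = c(0.60, 0.50, 0.70))
)

.signalColumns <- function() {
  as.vector(vapply(c("ax", "ay", "az"),
                   function(a) sprintf("%s_%02d", a, 0:29), character(30)))
}

.makeSignals <- function(labels, nSamples = 30L) {
  n <- length(labels)
  out <- matrix(0, n, 3L * nSamples)
  colnames(out) <- as.vector(vapply(c("ax", "ay", "az"),
                                    function(a) sprintf("%s_%02d", a, seq_len(nSamples) - 1L),
                                    character(nSamples)))
  for (ax in 1:3) {
    mu <- vapply(labels, function(l) .burstTemplates[[l]]$mean[ax], 0)
    sdv <- vapply(labels, function(l) .burstTemplates[[l]]$sd[ax], 0)
    out[, (ax - 1L) * nSamples + seq_len(nSamples)] <-
      matrix(stats::rnorm(n * nSamples, mean = mu, sd = sdv), n, nSamples)
  }
  out
}

#' Simulate ACC bursts along simulated tracks
#'
#' Emits one burst every `burstPeriodMin` minutes per individual over the
#' full track (so `nIndividuals * nSteps * fixPeriodMin / burstPeriodMin`
#' bursts), whether or not the covering fix survived missingness — the
#' 60-min backward-assignment rule downstream is thereby exercised. Each
#' burst carries the behavior label drawn for its interval during
#' [simulateTracks()] and a 3 x 30 synthetic signal from per-behavior
#' mean/sd templates.
#'
#' @param grid the `grid` element returned by [simulateTracks()].
#' @param config the same [SimConfig-class].
#' @param seed RNG seed for the signals (default derived from the config
#'   seed, keeping full-dataset determinism).
#' @return burst table: individual_id, timestamp, behavior_label, then 90
#'   signal columns ax_00..az_29 (g units).
#' @export
simulateBursts <- function(grid, config,
                           seed = (config@seed + 1L) %% .Machine$integer.max) {
  if (nrow(grid) == 0) stop("empty grid")
  set.seed(as.integer(seed))
  B <- as.integer(config@fixPeriodMin / config@burstPeriodMin)
  labList <- strsplit(grid$burst_labels, ",", fixed = TRUE)
  n <- nrow(grid) * B
  ts <- rep(grid$timestamp, each = B) +
    config@burstPeriodMin * 60 * rep(seq_len(B) - 1L, nrow(grid))
  labels <- unlist(labList, use.names = FALSE)
  out <- data.frame(
    individual_id = rep(grid$individual_id, each = B),
    timestamp = ts,
    behavior_label = labels,
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(.makeSignals(labels)))
}

#' Simulate a balanced labeled training set of bursts
#'
#' Standalone generator for the behavior-classification harness: n bursts
#' per class from the same per-behavior signal templates as
#' [simulateBursts()], in randomized row order.
#'
#' @param nPerClass bursts per behavior class (default 150, the training-set
#'   cap used by [assembleTrainingSet()]).
#' @param seed integer seed.
#' @return data.frame: behavior_label plus 90 signal columns.
#' @export
simulateTrainingBursts <- function(nPerClass = 150L, seed = 1L) {
  set.seed(as.integer(seed))
  labels <- sample(rep(BEHAVIORS, each = nPerClass))
  data.frame(behavior_label = labels, as.data.frame(.makeSignals(labels)),
             stringsAsFactors = FALSE)
}
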