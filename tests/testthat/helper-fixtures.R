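# shared fixtures: small label sets, record builders, tiny simulations

hms <- function(...) as.POSIXct(paste("2017-01-10", c(...)), tz = "UTC")

# intercept-only records: every covariate 0, all transitions from `from`
interceptRecords <- function(to, habitats, region = "R1", from = habitats[1]) {
  if (length(to) == 0L)
    return(data.frame(individual_id = character(), sequence_id = character(),
                      t = integer(), from = character(), to = character(),
                      region = character(), cos_diel = numeric(),
                      sin_time = numeric(), forage = numeric(),
                      walk = numeric(), stationary = numeric(),
                      temperature = numeric(), stringsAsFactors = FALSE))
  data.frame(individual_id = "b1", sequence_id = "s1", t = seq_along(to),
             from = from, to = to, region = region,
             cos_diel = 0, sin_time = 0, forage = 0, walk = 0,
             stationary = 0, temperature = 0, stringsAsFactors = FALSE)
}

# three-habitat world with the baseline last, single region
tinyHabitats <- c("field", "marsh", "water")
tinyRegionHabitats <- list(R1 = tinyHabitats)

tinySpec <- function(nIter = 500L, burnIn = 100L, seed = 1L,
                     effects = character(0)) {
  transitionModelSpec(habitats = tinyHabitats, baseline = "water",
                      regions = "R1", regionHabitats = tinyRegionHabitats,
                      effects = effects, nIter = nIter, burnIn = burnIn,
                      seed = seed)
}

# small full-structure simulation used by several tests
smallSim <- function(seed = 5L, nIndividuals = 4L, nSteps = 250L,
                     pMissing = 0.05, maxAbs = 0.8, nRegions = 2L) {
  habs <- defaultHabitats()
  regs <- defaultRegions()[seq_len(nRegions)]
  rh <- stats::setNames(rep(list(habs), nRegions), regs)
  if ("Chenier Plain" %in% regs)
    rh[["Chenier Plain"]] <- setdiff(habs, "corn")
  co <- randomCoefficients(habs, defaultBaseline(), regs, rh,
                           maxAbs = maxAbs, seed = seed)
  cfg <- simConfig(habitats = habs, regions = regs, regionHabitats = rh,
                   trueCoefficients = co, nIndividuals = nIndividuals,
                   nSteps = nSteps, pMissing = pMissing, seed = seed + 1L)
  sim <- simulateTracks(cfg)
  list(cfg = cfg, sim = sim, habs = habs, regs = regs, rh = rh)
}

# a fix table on the 30-min grid from explicit timestamps
fixTable <- function(times, habitat = "field", region = "R1",
                     individual = "b1", temperature = 5) {
  data.frame(individual_id = individual, timestamp = times,
             habitat = rep_len(habitat, length(times)),
             region = region, temperature_c = temperature,
             stringsAsFactors = FALSE)
}

burstTable <- function(times, label = "forage", individual = "b1") {
  data.frame(individual_id = individual, timestamp = times,
             behavior_label = rep_len(label, length(times)),
             stringsAsFactors = FALSE)
}
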