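test_that("zero coefficients give uniform transitions over available habitats", {
  cfg <- simConfig(habitats = tinyHabitats, regions = "R1",
                   regionHabitats = tinyRegionHabitats,
                   baselineHabitat = "water",
                   trueCoefficients = transitionCoefficients(
                     tinyHabitats, "water", "R1", tinyRegionHabitats),
                   nIndividuals = 2L, nSteps = 5000L, pMissing = 0,
                   seed = 31L)
  sim <- simulateTracks(cfg)
  cnt <- apply(sim$truth@realizedTransitionCounts["R1", , ], 2, sum)
  n <- sum(cnt)
  # each destination frequency within 4 binomial sds of 1/3
  tol <- 4 * sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(cnt / n - 1 / 3) < tol))
})

test_that("pMissing = 0 yields exactly nSteps rows per individual", {
  s <- smallSim(seed = 7L, nIndividuals = 3L, nSteps = 40L, pMissing = 0)
  expect_equal(unname(table(s$sim$fixes$individual_id)),
               rep(40L, 3L), ignore_attr = TRUE)
})

test_that("a positive forage slope raises transitions into the target habitat", {
  # forage slope +1.2 into "marsh" from every origin
  fmat <- matrix(0, 3, 3); fmat[, 2] <- 1.2
  co <- transitionCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats,
                               forage = fmat)
  cfg <- simConfig(habitats = tinyHabitats, regions = "R1",
                   regionHabitats = tinyRegionHabitats,
                   baselineHabitat = "water", trueCoefficients = co,
                   nIndividuals = 2L, nSteps = 4000L, pMissing = 0, seed = 33L)
  sim <- simulateTracks(cfg)
  g <- sim$grid
  # per-step destination and forage covariate (last step has no destination)
  byInd <- split(seq_len(nrow(g)), g$individual_id)
  from <- unlist(lapply(byInd, function(i) i[-length(i)]))
  to <- unlist(lapply(byInd, function(i) i[-1]))
  forage <- g$p_forage[from]
  intoMarsh <- g$habitat[to] == "marsh"
  qs <- stats::quantile(forage, c(0.25, 0.75))
  hi <- mean(intoMarsh[forage >= qs[2]])
  lo <- mean(intoMarsh[forage <= qs[1]])
  expect_gt(hi, lo)
})

test_that("behavior-proportion draws have Dirichlet moments and sum to one", {
  cfg <- simConfig(nIndividuals = 2L, nSteps = 10L, seed = 2L,
                   behaviorAlpha = stats::setNames(
                     c(rep(list(c(forage = 1, walk = 1, stationary = 1, flight = 1)),
                           7),
                       list(c(forage = 10, walk = 0.5, stationary = 0.5, flight = 0.5))),
                     defaultHabitats()))
  set.seed(11)
  sym <- simulateBehaviorProportions("corn", cfg, n = 4000)
  expect_equal(rowSums(sym), rep(1, 4000), tolerance = 1e-12)
  expect_equal(unname(colMeans(sym)), rep(0.25, 4), tolerance = 0.02)
  skew <- simulateBehaviorProportions("other", cfg, n = 4000)
  expect_equal(unname(mean(skew[, "forage"])), 10 / 11.5, tolerance = 0.01)
  expect_error(simulateBehaviorProportions("tundra", cfg), "unknown habitat")
})

test_that("temperature process has the stated diel shape and AR(1) spread", {
  t0 <- as.POSIXct("2017-01-01 00:00:00", tz = "UTC")
  const <- simulateTemperature(100, t0, c(mean = 8, amplitude = 0, ar = 0, sd = 0))
  expect_equal(const, rep(8, 100))
  diel <- simulateTemperature(48, t0, c(mean = 0, amplitude = 5, ar = 0, sd = 0))
  hrs <- (0:47) / 2
  expect_equal(hrs[which.max(diel)], 12)
  expect_equal(hrs[which.min(diel)], 0)
  expect_equal(max(diel), 5)
  set.seed(4)
  ar <- simulateTemperature(20000, t0, c(mean = 0, amplitude = 0, ar = 0.8, sd = 1))
  expect_equal(stats::sd(ar), 1 / sqrt(1 - 0.64), tolerance = 0.05)
  expect_error(
    simulateTemperature(10, t0, c(mean = 0, amplitude = 0, ar = 0, sd = -1)),
    "nonnegative")
  expect_error(
    simulateTemperature(10, t0, c(mean = 0, amplitude = 0, ar = 1.2, sd = 1)),
    "AR coefficient")
})

test_that("burst schedule, labels and templates are as constructed", {
  s <- smallSim(seed = 3L, nIndividuals = 2L, nSteps = 30L, pMissing = 0.2)
  bs <- simulateBursts(s$sim$grid, s$cfg)
  # 5 bursts per fix interval regardless of missingness
  expect_equal(nrow(bs), 2L * 30L * 5L)
  one <- bs[bs$individual_id == "bird_01", ]
  expect_equal(diff(as.numeric(one$timestamp[1:6])), rep(360, 5))
  # label counts per interval reproduce the grid's burst-count proportions
  g1 <- s$sim$grid[s$sim$grid$individual_id == "bird_01", ][3, ]
  b1 <- one[one$timestamp >= g1$timestamp &
              one$timestamp < g1$timestamp + 1800, ]
  expect_equal(sum(b1$behavior_label == "forage") / 5, g1$p_forage)
  # stationary template variance below flight's
  sig <- grep("^a[xyz]_", names(bs), value = TRUE)
  vStat <- mean(apply(bs[bs$behavior_label == "stationary", sig, drop = FALSE], 1, var))
  vFly <- mean(apply(bs[bs$behavior_label == "flight", sig, drop = FALSE], 1, var))
  expect_lt(vStat, vFly)
})

test_that("simulation is deterministic in the config seed", {
  s1 <- smallSim(seed = 12L, nIndividuals = 2L, nSteps = 50L)
  s2 <- smallSim(seed = 12L, nIndividuals = 2L, nSteps = 50L)
  expect_identical(s1$sim$fixes, s2$sim$fixes)
  expect_identical(s1$sim$grid, s2$sim$grid)
  expect_identical(simulateBursts(s1$sim$grid, s1$cfg),
                   simulateBursts(s2$sim$grid, s2$cfg))
})

test_that("simulated transitions never leave the region's available habitats", {
  s <- smallSim(seed = 9L, nIndividuals = 4L, nSteps = 200L)
  cnt <- s$sim$truth@realizedTransitionCounts
  for (r in s$regs) {
    un <- setdiff(s$habs, s$rh[[r]])
    if (length(un)) {
      expect_true(all(cnt[r, , un] == 0))
      expect_true(all(cnt[r, un, ] == 0))
      expect_false(any(s$sim$fixes$habitat[s$sim$fixes$region == r] %in% un))
    }
  }
})

test_that("stored covariate moments match realized sample moments", {
  # near-uniform occupancy (zero coefficients) so the uniform-mix closed
  # form applies; agreement is within sampling error, tested at large n
  cfg <- simConfig(nIndividuals = 6L, nSteps = 2000L, pMissing = 0, seed = 44L)
  sim <- simulateTracks(cfg)
  mom <- covariateMoments(sim$truth)
  g <- sim$grid
  real <- c(mean(g$p_forage), mean(g$p_walk), mean(g$p_stationary),
            mean(g$temperature_c))
  expect_equal(real, mom$mean, tolerance = 0.05)
  realSd <- c(stats::sd(g$p_forage), stats::sd(g$p_walk),
              stats::sd(g$p_stationary), stats::sd(g$temperature_c))
  expect_equal(realSd, mom$sd, tolerance = 0.05)
})

test_that("configs with a single-habitat region are rejected", {
  expect_error(
    simConfig(habitats = tinyHabitats, regions = "R1",
              regionHabitats = list(R1 = "water"), baselineHabitat = "water",
              nIndividuals = 1L, nSteps = 10L),
    "fewer than 2")
})
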