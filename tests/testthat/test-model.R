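test_that("linear predictors follow the model equation with a zero baseline", {
  rec <- interceptRecords("marsh", tinyHabitats, from = "field")
  rec$cos_diel <- 1
  co0 <- transitionCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats)
  expect_equal(linearPredictor(rec, co0), matrix(0, 1, 3), ignore_attr = TRUE)
  # b0 = 0.5, b1 = -0.3, cos_diel = 1 -> eta = 0.2
  int <- matrix(0, 3, 1); int[2, 1] <- 0.5
  co <- transitionCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats,
                               intercepts = int, diel = c(0, -0.3, 0))
  eta <- linearPredictor(rec, co)
  expect_equal(eta[1, "marsh"], 0.2, ignore_attr = TRUE)
  # eta into the baseline is identically zero whatever the covariates
  set.seed(2)
  recR <- interceptRecords(rep("marsh", 20), tinyHabitats)
  for (k in c("cos_diel", "sin_time", "forage", "walk", "stationary",
              "temperature"))
    recR[[k]] <- rnorm(20)
  coR <- randomCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats,
                            seed = 3)
  expect_true(all(linearPredictor(recR, coR)[, "water"] == 0))
})

test_that("transition probabilities are a masked, overflow-safe softmax", {
  co0 <- transitionCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats)
  rec <- interceptRecords("marsh", tinyHabitats)
  mask <- availabilityMask(tinyRegionHabitats, tinyHabitats, "R1")
  expect_equal(as.numeric(transitionProbs(rec, co0, mask)), rep(1 / 3, 3))
  # eta = (0 baseline, ln 2) with two allowed destinations -> (1/3, 2/3)
  habs2 <- c("water", "marsh")
  int <- matrix(c(0, log(2)), 2, 1)
  co2 <- transitionCoefficients(habs2, "water", "R1", list(R1 = habs2),
                                intercepts = int)
  rec2 <- interceptRecords("marsh", habs2)
  mask2 <- availabilityMask(list(R1 = habs2), habs2, "R1")
  p2 <- transitionProbs(rec2, co2, mask2)
  expect_equal(as.numeric(p2), c(1 / 3, 2 / 3))
  # masking a destination zeroes it exactly and renormalizes the rest
  maskM <- mask; maskM["R1", "field", "marsh"] <- FALSE
  pM <- transitionProbs(rec, co0, maskM)
  expect_identical(unname(pM[1, "marsh"]), 0)
  expect_equal(sum(pM), 1, tolerance = 1e-12)
  expect_equal(as.numeric(pM[1, c("field", "water")]), c(0.5, 0.5))
  # overflow safety at extreme linear predictors
  intBig <- matrix(c(800, 0, 0), 3, 1)
  coBig <- transitionCoefficients(tinyHabitats, "water", "R1",
                                  tinyRegionHabitats, intercepts = intBig)
  pBig <- transitionProbs(rec, coBig, mask)
  expect_true(all(is.finite(pBig)))
  expect_equal(unname(pBig[1, "field"]), 1, tolerance = 1e-12)
})

test_that("log-likelihood is additive and flags masked observations", {
  habs4 <- c("a", "b", "c", "d")
  co <- transitionCoefficients(habs4, "a", "R1", list(R1 = habs4))
  mask <- availabilityMask(list(R1 = habs4), habs4, "R1")
  rec1 <- interceptRecords("b", habs4)
  expect_equal(logLikelihood(rec1, co, mask), log(1 / 4))
  recN <- interceptRecords(c("b", "c", "a", "d", "b"), habs4)
  expect_equal(logLikelihood(rbind(recN, recN), co, mask),
               2 * logLikelihood(recN, co, mask))
  maskM <- mask; maskM["R1", "a", "b"] <- FALSE
  expect_error(logLikelihood(rec1, co, maskM), "inconsistent")
})

test_that("the in-sample MLE beats a perturbed truth on large data", {
  set.seed(6)
  pv <- c(1, exp(0.5), exp(-0.4)); pv <- pv / sum(pv)
  to <- sample(c("water", "field", "marsh"), 3000, TRUE, pv[c(1, 2, 3)])
  rec <- interceptRecords(to, tinyHabitats)
  mask <- availabilityMask(tinyRegionHabitats, tinyHabitats, "R1")
  mkCo <- function(b) {
    transitionCoefficients(tinyHabitats, "water", "R1", tinyRegionHabitats,
                           intercepts = matrix(c(b[1], b[2], 0), 3, 1))
  }
  nll <- function(b) -logLikelihood(rec, mkCo(b), mask)
  opt <- stats::optim(c(0, 0), nll)
  truthPerturbed <- c(0.5 + 1, -0.4)
  expect_lt(nll(opt$par), nll(truthPerturbed))
})

test_that("the hyper-mean full conditional matches conjugate algebra", {
  hc <- hyperMeanConditional(c(1, 3), priorVar = 100, hyperVar = 100)
  expect_equal(hc$mean, 4 / 3)
  expect_equal(hc$variance, 100 / 3)
  # one intercept, tighter hyper prior
  hc2 <- hyperMeanConditional(2, priorVar = 4, hyperVar = 1)
  expect_equal(hc2$mean, (2 / 4) / (1 / 4 + 1))
  expect_equal(hc2$variance, 1 / (1 / 4 + 1))
})

test_that("the Gibbs sampler is deterministic given the spec seed", {
  set.seed(1)
  to <- sample(tinyHabitats, 300, TRUE)
  rec <- interceptRecords(to, tinyHabitats)
  p1 <- gibbsFit(rec, tinySpec(nIter = 150L, burnIn = 50L, seed = 77L))
  p2 <- gibbsFit(rec, tinySpec(nIter = 150L, burnIn = 50L, seed = 77L))
  expect_identical(draws(p1), draws(p2))
  expect_identical(p1@logLik, p2@logLik)
  p3 <- gibbsFit(rec, tinySpec(nIter = 150L, burnIn = 50L, seed = 78L))
  expect_false(identical(draws(p1), draws(p3)))
})

test_that("with no data the posterior reproduces the hierarchical prior", {
  rec <- interceptRecords(character(0), tinyHabitats)
  post <- gibbsFit(rec, tinySpec(nIter = 12000L, burnIn = 2000L, seed = 5L))
  b <- draws(post)[, "b0[field|R1]"]
  # marginally b0jr ~ N(0, 100 + 100)
  expect_equal(mean(b), 0, tolerance = 3 * mcseMean(b))
  expect_equal(stats::sd(b), sqrt(200), tolerance = 0.05)
  # slope posteriors collapse onto a point as their prior variance -> 0
  specTight <- transitionModelSpec(
    habitats = tinyHabitats, baseline = "water", regions = "R1",
    regionHabitats = tinyRegionHabitats, priorSlopeVar = 1e-8,
    nIter = 500L, burnIn = 100L, seed = 6L)
  rec2 <- interceptRecords(sample(tinyHabitats, 100, TRUE), tinyHabitats)
  rec2$forage <- rnorm(100)
  post2 <- gibbsFit(rec2, specTight)
  sl <- draws(post2)[, grep("^b3\\[", coefNames(post2))]
  expect_lt(max(abs(sl)), 1e-3)
})

test_that("an intercept-only fit recovers the empirical log-odds", {
  set.seed(8)
  p <- 0.35
  to <- ifelse(runif(2000) < p, "marsh", "water")
  rec <- interceptRecords(to, c("water", "marsh"))
  spec <- transitionModelSpec(habitats = c("water", "marsh"),
                              baseline = "water", regions = "R1",
                              regionHabitats = list(R1 = c("water", "marsh")),
                              effects = character(0),
                              nIter = 2500L, burnIn = 500L, seed = 9L)
  post <- gibbsFit(rec, spec)
  ch <- draws(post)[, "b0[marsh|R1]"]
  emp <- stats::qlogis(mean(to == "marsh"))
  expect_lt(abs(mean(ch) - emp), 4 * mcseMean(ch) + 0.01)
})

test_that("jittered starts converge to the same posterior", {
  set.seed(10)
  to <- sample(tinyHabitats, 500, TRUE, prob = c(0.5, 0.3, 0.2))
  rec <- interceptRecords(to, tinyHabitats)
  spec <- tinySpec(nIter = 3000L, burnIn = 1000L, seed = 11L)
  i1 <- initializeCoefficients(spec, jitterSd = 0.5, seed = 1)
  i2 <- initializeCoefficients(spec, jitterSd = 0.5, seed = 2)
  expect_identical(initializeCoefficients(spec, jitterSd = 0.5, seed = 1), i1)
  expect_true(all(coefficientsToVector(initializeCoefficients(spec), spec) == 0))
  p1 <- gibbsFit(rec, spec, init = i1)
  spec@seed <- 12L
  p2 <- gibbsFit(rec, spec, init = i2)
  m1 <- colMeans(draws(p1)); m2 <- colMeans(draws(p2))
  se <- sqrt(apply(draws(p1), 2, mcseMean)^2 + apply(draws(p2), 2, mcseMean)^2)
  expect_true(all(abs(m1 - m2) < 4 * se + 0.02))
})

test_that("records contradicting the mask or spec are rejected", {
  rec <- interceptRecords("marsh", tinyHabitats)
  spec <- tinySpec()
  m <- spec@mask; m["R1", "field", "marsh"] <- FALSE
  spec2 <- transitionModelSpec(habitats = tinyHabitats, baseline = "water",
                               regions = "R1",
                               regionHabitats = tinyRegionHabitats,
                               mask = m, nIter = 100L, burnIn = 10L)
  expect_error(gibbsFit(rec, spec2), "contradict")
  recBad <- rec; recBad$to <- "tundra"
  expect_error(gibbsFit(recBad, spec), "outside")
})
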