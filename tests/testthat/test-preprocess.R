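test_that("bursts assign backward with the 60-min cutoff", {
  fx <- fixTable(hms("10:00:00", "10:30:00"))
  bs <- burstTable(hms("10:12:00"))
  out <- assignBursts(fx, bs)
  expect_equal(out$fix_timestamp, hms("10:00:00"))
  # missing next fix: within 60 min kept, beyond dropped
  fx2 <- fixTable(hms("10:00:00", "12:00:00"))
  bs2 <- burstTable(hms("10:55:00", "11:05:00", "12:10:00"))
  out2 <- assignBursts(fx2, bs2)
  expect_equal(out2$fix_timestamp[1], hms("10:00:00"))
  expect_true(is.na(out2$fix_timestamp[2]))
  expect_equal(out2$fix_timestamp[3], hms("12:00:00"))
  # a burst exactly at a fix timestamp attaches to that fix (closed left)
  bs3 <- burstTable(hms("10:30:00"))
  out3 <- assignBursts(fx, bs3)
  expect_equal(out3$fix_timestamp, hms("10:30:00"))
  # bursts before the first fix are dropped
  out4 <- assignBursts(fx, burstTable(hms("09:50:00")))
  expect_true(is.na(out4$fix_timestamp))
  expect_error(assignBursts(fx[2:1, ], bs), "sorted")
})

test_that("sequences split at gaps strictly over 120 min", {
  fx <- fixTable(hms("00:00:00", "00:30:00", "01:00:00", "03:30:00"))
  seg <- segmentSequences(fx)
  expect_equal(unname(table(seg$sequence_id)), c(3L, 1L), ignore_attr = TRUE)
  # exactly 120 min stays in one sequence
  fx2 <- fixTable(hms("00:00:00", "02:00:00"))
  expect_equal(length(unique(segmentSequences(fx2)$sequence_id)), 1L)
  fx3 <- fixTable(hms("00:00:00", "02:00:01"))
  expect_equal(length(unique(segmentSequences(fx3)$sequence_id)), 2L)
})

test_that("behavior proportions count bursts and drop empty fixes", {
  fx <- fixTable(hms("10:00:00", "10:30:00", "11:00:00"))
  bs <- burstTable(hms("10:00:00", "10:06:00", "10:12:00", "10:18:00", "10:24:00"),
                   label = c("forage", "forage", "forage", "stationary", "flight"))
  iv <- behaviorProportions(assignBursts(fx, bs))
  expect_equal(nrow(iv), 1L)  # fixes without bursts contribute no interval
  expect_equal(iv$n_bursts, 5L)
  expect_equal(c(iv$p_forage, iv$p_walk, iv$p_stationary), c(0.6, 0.0, 0.2))
  expect_equal(iv$p_forage + iv$p_walk + iv$p_stationary + iv$p_flight, 1)
  # all-flight interval is retained (n_bursts > 0)
  bsF <- burstTable(hms("10:00:00", "10:06:00"), label = "flight")
  ivF <- behaviorProportions(assignBursts(fx, bsF))
  expect_equal(c(ivF$p_forage, ivF$p_walk, ivF$p_stationary), c(0, 0, 0))
  expect_error(
    behaviorProportions(assignBursts(fx, burstTable(hms("10:01:00"), label = "swim"))),
    "labeled")
})

test_that("harmonic clock covariates have the documented signs", {
  tc <- timeCovariates(hms("00:00:00", "06:00:00", "12:00:00", "18:00:00"))
  expect_equal(tc$cos_diel, c(1, 0, -1, 0), tolerance = 1e-12)
  expect_equal(tc$sin_time, c(0, 1, 0, -1), tolerance = 1e-12)
  # night positive / midday negative; morning positive / evening negative
  expect_gt(timeCovariates(hms("23:00:00"))$cos_diel, 0)
  expect_lt(timeCovariates(hms("13:00:00"))$cos_diel, 0)
  expect_gt(timeCovariates(hms("09:00:00"))$sin_time, 0)
  expect_lt(timeCovariates(hms("15:00:00"))$sin_time, 0)
})

test_that("standardization centers and scales with the sample sd", {
  rec <- interceptRecords(c("marsh", "water"), tinyHabitats)
  rec$forage <- c(0, 1); rec$walk <- c(2, 4); rec$stationary <- c(1, 3)
  rec$temperature <- c(-5, 5)
  std <- standardizeRecords(rec)
  expect_equal(std$records$forage, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(std$spec$sd[std$spec$covariate == "forage"], sqrt(0.5))
  # applying the stored spec reproduces the fresh fit
  std2 <- standardizeRecords(rec, spec = std$spec)
  expect_equal(std2$records, std$records)
  recC <- rec; recC$walk <- 1
  expect_error(standardizeRecords(recC), "zero-variance")
})

test_that("records form only across exact one-period steps within sequences", {
  fx <- fixTable(hms("10:00:00", "10:30:00", "11:00:00", "11:30:00"),
                 habitat = c("field", "field", "marsh", "marsh"))
  fx <- segmentSequences(fx)
  iv <- data.frame(individual_id = "b1",
                   timestamp = fx$timestamp,
                   n_bursts = 5L, p_forage = 0.4, p_walk = 0.2,
                   p_stationary = 0.2, p_flight = 0.2)
  rec <- buildTransitionRecords(fx, iv)
  expect_equal(nrow(rec), 3L)  # 4 consecutive fixes -> 3 records
  expect_equal(rec$from, c("field", "field", "marsh"))
  expect_equal(rec$to, c("field", "marsh", "marsh"))
  expect_true(any(rec$from == rec$to))  # self transitions allowed
  # a 60-min in-sequence gap produces no bridging record
  fx2 <- fixTable(hms("10:00:00", "11:00:00"), habitat = c("field", "marsh"))
  fx2 <- segmentSequences(fx2)
  iv2 <- iv[1:2, ]; iv2$timestamp <- fx2$timestamp
  expect_equal(nrow(buildTransitionRecords(fx2, iv2)), 0L)
  # single-fix sequences contribute nothing
  fx3 <- fixTable(hms("10:00:00"))
  fx3 <- segmentSequences(fx3)
  expect_equal(nrow(buildTransitionRecords(fx3, iv[1, ])), 0L)
  # an origin fix with no interval row produces no record
  rec2 <- buildTransitionRecords(fx, iv[-2, ])
  expect_equal(nrow(rec2), 2L)
})

test_that("record count equals sum over sequences of length minus one", {
  s <- smallSim(seed = 15L, nIndividuals = 3L, nSteps = 120L, pMissing = 0.1)
  bs <- simulateBursts(s$sim$grid, s$cfg)
  fx <- segmentSequences(s$sim$fixes)
  iv <- behaviorProportions(assignBursts(fx, bs))
  rec <- buildTransitionRecords(fx, iv)
  # with bursts every 6 min, every retained fix has an interval, and within
  # a sequence consecutive retained fixes 30 min apart pair up
  perSeq <- vapply(split(as.numeric(fx$timestamp), fx$sequence_id),
                   function(tt) sum(diff(tt) == 1800), 0L)
  expect_equal(nrow(rec), sum(perSeq))
  # proportions of the four behaviors sum to 1 on every interval
  expect_equal(iv$p_forage + iv$p_walk + iv$p_stationary + iv$p_flight,
               rep(1, nrow(iv)))
  # freshly standardized covariates have mean 0, sd 1
  std <- standardizeRecords(rec)
  for (k in c("forage", "walk", "stationary", "temperature")) {
    expect_equal(mean(std$records[[k]]), 0, tolerance = 1e-10)
    expect_equal(stats::sd(std$records[[k]]), 1, tolerance = 1e-10)
  }
})

test_that("structural masks exclude unavailable and unobserved transitions", {
  rec <- data.frame(
    individual_id = "b1", sequence_id = "s1", t = 1:4,
    from = c("field", "marsh", "field", "water"),
    to = c("marsh", "field", "water", "field"),
    region = "R1",
    cos_diel = 0, sin_time = 0, forage = 0, walk = 0, stationary = 0,
    temperature = 0, stringsAsFactors = FALSE)
  m <- structuralMask(rec, list(R1 = tinyHabitats), baseline = "water",
                      habitats = tinyHabitats, regions = "R1")
  expect_true(all(m["R1", , "water"]))              # baseline always allowed
  expect_true(m["R1", "field", "marsh"])
  expect_false(m["R1", "marsh", "water"] == FALSE)  # observed via baseline rule
  expect_false(m["R1", "marsh", "marsh"])           # never observed
  # all observed records are allowed
  ri <- match(rec$region, "R1"); fi <- match(rec$from, tinyHabitats)
  ti <- match(rec$to, tinyHabitats)
  expect_true(all(m[cbind(ri, fi, ti)]))
  # region availability: a habitat absent from the region is fully masked
  m2 <- structuralMask(rec, list(R1 = c("field", "marsh", "water"),
                                 R2 = c("marsh", "water")),
                       baseline = "water", habitats = tinyHabitats,
                       regions = c("R1", "R2"))
  expect_true(all(!m2["R2", , "field"]))
  expect_true(all(!m2["R2", "field", ]))
  # a dataset with every transition observed in a region is fully allowed
  allTrans <- expand.grid(from = tinyHabitats, to = tinyHabitats,
                          stringsAsFactors = FALSE)
  recAll <- data.frame(individual_id = "b1", sequence_id = "s1",
                       t = seq_len(nrow(allTrans)), from = allTrans$from,
                       to = allTrans$to, region = "R1", cos_diel = 0,
                       sin_time = 0, forage = 0, walk = 0, stationary = 0,
                       temperature = 0, stringsAsFactors = FALSE)
  m3 <- structuralMask(recAll, list(R1 = tinyHabitats), baseline = "water",
                       habitats = tinyHabitats, regions = "R1")
  expect_true(all(m3))
  # inconsistent inputs: a record landing on an unavailable habitat
  expect_error(
    structuralMask(rec, list(R1 = c("marsh", "water")), baseline = "water",
                   habitats = tinyHabitats, regions = "R1"),
    "masked")
  # global vs per-region scope
  rec2 <- rbind(rec,
                within(rec[1, ], region <- "R2"))
  rh <- list(R1 = tinyHabitats, R2 = tinyHabitats)
  mr <- structuralMask(rec2, rh, baseline = "water", habitats = tinyHabitats,
                       regions = c("R1", "R2"), scope = "region")
  mg <- structuralMask(rec2, rh, baseline = "water", habitats = tinyHabitats,
                       regions = c("R1", "R2"), scope = "global")
  expect_false(mr["R2", "marsh", "field"])  # unobserved within R2
  expect_true(mg["R2", "marsh", "field"])   # observed globally
})

test_that("burst assignment is stable and unique per burst", {
  s <- smallSim(seed = 18L, nIndividuals = 2L, nSteps = 60L, pMissing = 0.15)
  bs <- simulateBursts(s$sim$grid, s$cfg)
  a1 <- assignBursts(s$sim$fixes, bs)
  # each burst row maps to at most one fix, and re-assignment is identical
  a2 <- assignBursts(s$sim$fixes, bs)
  expect_identical(a1$fix_timestamp, a2$fix_timestamp)
  expect_equal(nrow(a1), nrow(bs))
})
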