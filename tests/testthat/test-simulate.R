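test_that("the generator is deterministic given its seed", {
  cfg <- simulationConfig(nSamples = 100, nProbes = 200, seed = 1)
  p1 <- simulateParticipants(cfg)
  p2 <- simulateParticipants(cfg)
  expect_identical(p1, p2)
  b1 <- simulateLifemethBundle(cfg)
  b2 <- simulateLifemethBundle(cfg)
  expect_identical(betaValues(b1$experiment), betaValues(b2$experiment))
  expect_identical(
    as.data.frame(SummarizedExperiment::colData(b1$experiment)),
    as.data.frame(SummarizedExperiment::colData(b2$experiment)))
  # a different seed changes the draw
  b3 <- simulateLifemethBundle(simulationConfig(nSamples = 100, nProbes = 200,
                                                seed = 2))
  expect_false(identical(betaValues(b1$experiment), betaValues(b3$experiment)))
})

test_that("lifestyle category frequencies and diet scores match the configured population", {
  cfg <- simulationConfig(nSamples = 10000, nProbes = 10, seed = 7,
                          nSpikedProbes = 0, nSpikedRegions = 0)
  ph <- simulateParticipants(cfg)
  expect_equal(mean(ph$Smoking == "never"), 632 / 713, tolerance = 0.025)
  expect_lt(abs(mean(ph$Smoking == "never") - 0.886), 0.02)
  expect_lt(abs(mean(ph$NeverDrinker) - 439 / 713), 0.02)
  expect_lt(abs(mean(ph$DQI) - 56), 0.3)
  expect_true(all(ph$DQI >= 0 & ph$DQI <= 100))
  # cell proportions are a simplex draw
  cells <- as.matrix(ph[grep("^Cell_", colnames(ph))])
  expect_equal(unname(rowSums(cells)), rep(1, nrow(ph)), tolerance = 1e-8)
})

test_that("invalid frequency vectors are rejected naming the factor", {
  expect_error(
    simulationConfig(categoryFrequencies = list(
      smoking = c(never = 0.5, former = 0.2, current = 0.2),
      alcohol = c(abstainer = 0.6, moderate = 0.3, heavy = 0.1),
      activity = c(high = 0.4, moderate = 0.3, low = 0.3))),
    "smoking")
  expect_error(simulationConfig(spikeDeltaBeta = 0.5), "spikeDeltaBeta")
  expect_error(simulationConfig(nProbes = 10, nSpikedProbes = 20),
               "exceed nProbes")
  expect_error(simulationConfig(regionNProbes = 2), "regionNProbes")
})

test_that("generated methylation respects range, uniqueness and coordinate invariants", {
  b <- tinyBundle(seed = 2)
  beta <- betaValues(b$experiment)
  expect_true(all(beta >= 0 & beta <= 1))
  expect_false(anyDuplicated(rownames(beta)) > 0)
  ann <- as.data.frame(probeAnnotation(b$experiment))
  for (chr in unique(ann$Chr)) {
    pos <- ann$Position[ann$Chr == chr]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("spiked probes carry the configured beta-scale shift", {
  cfg <- simulationConfig(nSamples = 400, nProbes = 1000, nSpikedProbes = 10,
                          spikeDeltaBeta = 0.05, nSpikedRegions = 0, seed = 3)
  b <- simulateLifemethBundle(cfg)
  cli <- b$scores$index
  dB <- computeDeltaBeta(betaValues(b$experiment)[spikedProbes(b$truth), ],
                         cli)
  expect_lt(abs(mean(dB) - 0.05), 0.01)

  # null spike: group difference indistinguishable from zero
  cfg0 <- simulationConfig(nSamples = 400, nProbes = 1000, nSpikedProbes = 10,
                           spikeDeltaBeta = 0, nSpikedRegions = 0, seed = 3)
  b0 <- simulateLifemethBundle(cfg0)
  beta0 <- betaValues(b0$experiment)[spikedProbes(b0$truth), ]
  cli0 <- b0$scores$index
  d0 <- computeDeltaBeta(beta0, cli0)
  se <- apply(beta0, 1, sd) * sqrt(1 / sum(cli0 == 1) + 1 / sum(cli0 == 0))
  expect_true(all(abs(d0) < 3 * se))
})

test_that("spiked regions are runs of consecutive annotated probes", {
  b <- tinyBundle(seed = 9, regionNProbes = 5)
  reg <- spikedRegions(b$truth)
  expect_equal(length(reg), 1L)
  ids <- unlist(S4Vectors::mcols(reg)$probeIds)
  expect_length(ids, 5L)
  ann <- as.data.frame(probeAnnotation(b$experiment))
  ann <- ann[order(ann$Chr, ann$Position), ]
  idx <- match(ids, ann$ProbeID)
  expect_equal(sort(idx), min(idx):max(idx))  # consecutive in genome order
  expect_true(all(ann$Chr[idx] == as.character(GenomicRanges::seqnames(reg))))
  expect_equal(min(ann$Position[idx]), GenomicRanges::start(reg))
  expect_equal(max(ann$Position[idx]), GenomicRanges::end(reg))
})

test_that("outcomes follow the configured link coefficients", {
  # null links: prevalence equals what the intercept implies, methylation slope ~ 0
  links0 <- c(t2dmIntercept = -0.4, t2dmCli = 0, t2dmMeth = 0,
              fbgIntercept = 5.3, fbgCli = 0, fbgMeth = 0,
              hba1cIntercept = 38, hba1cCli = 0, hba1cMeth = 0)
  cfg0 <- simulationConfig(nSamples = 4000, nProbes = 60, nSpikedProbes = 5,
                           nSpikedRegions = 0, outcomeLinks = links0,
                           seed = 21)
  b0 <- simulateLifemethBundle(cfg0)
  ph0 <- as.data.frame(SummarizedExperiment::colData(b0$experiment))
  expect_lt(abs(mean(ph0$T2DM) - plogis(-0.4)), 0.03)
  sig <- colMeans(betaValues(b0$experiment)[spikedProbes(b0$truth), ])
  slope <- coef(lm(ph0$FBG ~ sig))[2]
  expect_lt(abs(slope), 3 * summary(lm(ph0$FBG ~ sig))$coefficients[2, 2])

  # log-odds 0.69 on the binary index recovers an odds ratio near 2
  links2 <- links0
  links2["t2dmCli"] <- 0.69
  cfg2 <- simulationConfig(nSamples = 5000, nProbes = 20, nSpikedProbes = 0,
                           nSpikedRegions = 0, outcomeLinks = links2,
                           seed = 8)
  b2 <- simulateLifemethBundle(cfg2)
  ph2 <- as.data.frame(SummarizedExperiment::colData(b2$experiment))
  or <- exp(coef(glm(T2DM ~ CLI, data = ph2, family = binomial()))[2])
  expect_gt(or, 1.7)
  expect_lt(or, 2.3)

  # outcome columns are reproducible given the seed
  b2b <- simulateLifemethBundle(cfg2)
  ph2b <- as.data.frame(SummarizedExperiment::colData(b2b$experiment))
  expect_identical(ph2[c("T2DM", "FBG", "HbA1c")],
                   ph2b[c("T2DM", "FBG", "HbA1c")])
})

test_that("misaligned sample ids are rejected by the outcome stage", {
  cfg <- simulationConfig(nSamples = 30, nProbes = 50, nSpikedRegions = 0,
                          seed = 1)
  b <- simulateMethylation(cfg, simulateParticipants(cfg),
                           rep(0:1, length.out = 30))
  ph <- simulateParticipants(cfg)
  ph$SampleID <- rev(ph$SampleID)
  expect_error(simulateOutcomes(cfg, ph, b$experiment, b$truth),
               "misaligned")
})
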