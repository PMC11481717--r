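test_that("probe clustering applies the gap rule per chromosome", {
  ann <- data.frame(ProbeID = c("p1", "p2", "p3"),
                    Chr = "chr1", Position = c(100, 300, 1200))
  cl <- clusterProbes(ann, maxGap = 500)
  expect_equal(unname(cl), c(1L, 1L, 2L))
  # different chromosomes never share a cluster even at tiny distance
  ann2 <- data.frame(ProbeID = c("p1", "p2"),
                     Chr = c("chr1", "chr2"), Position = c(100, 150))
  expect_equal(length(unique(clusterProbes(ann2, maxGap = 1e6))), 2L)
  # degenerate gap: every probe its own cluster
  cl0 <- clusterProbes(ann, maxGap = 0)
  expect_equal(length(unique(cl0)), 3L)
  # ids are stable across calls and returned in input row order
  annR <- ann[c(3, 1, 2), ]
  clR <- clusterProbes(annR, maxGap = 500)
  expect_equal(unname(clR), c(2L, 1L, 1L))
  expect_error(clusterProbes(rbind(ann, ann[1, ]), 500), "duplicated")
})

test_that("within-cluster smoothing is the truncated running mean", {
  cl <- c(1L, 1L, 1L)
  expect_equal(smoothEffects(c(0, 0.3, 0), cl, window = 3),
               c(0.15, 0.1, 0.15))
  expect_equal(smoothEffects(c(0.2, 0.2, 0.2), cl, window = 3),
               rep(0.2, 3))
  expect_equal(smoothEffects(c(0.1, 0.5, 0.2), cl, window = 1),
               c(0.1, 0.5, 0.2))
  # clusters below 3 probes pass through unsmoothed
  expect_equal(smoothEffects(c(0.4, 0.1), c(1L, 2L), window = 3),
               c(0.4, 0.1))
  # five-probe cluster, window 5: hand-computed truncation at the edges
  x <- c(1, 2, 3, 4, 10)
  expect_equal(smoothEffects(x, rep(1L, 5), window = 5),
               c(mean(x[1:3]), mean(x[1:4]), mean(x), mean(x[2:5]),
                 mean(x[3:5])))
  expect_error(smoothEffects(x, rep(1L, 5), window = 4), "odd")
})

test_that("bump calling respects the cutoff, the sign and the probe floor", {
  ann <- data.frame(ProbeID = sprintf("p%02d", 1:10), Chr = "chr1",
                    Position = seq(100, by = 100, length.out = 10),
                    Gene = "G", Feature = "Body")
  cl <- rep(1L, 10)
  # everything under the cutoff: no calls
  low <- rep(0.005, 10)
  expect_equal(nrow(findBumps(low, low, cl, ann, cutoff = 0.01)), 0L)
  # a 5-probe run above the cutoff is one region of 5 probes
  eff <- c(rep(0, 3), rep(0.05, 5), rep(0, 2))
  res <- findBumps(eff, eff, cl, ann, cutoff = 0.01, minProbes = 3)
  expect_equal(nrow(res), 1L)
  expect_equal(res$nProbes, 5L)
  expect_equal(res$start, 400)
  expect_equal(res$end, 800)
  expect_equal(res$area, 5 * 0.05)
  expect_equal(res$avgDeltaBeta, 0.05)
  expect_true(is.na(res$fwer))
  # a 2-probe run is discarded at the 3-probe floor
  eff2 <- c(rep(0, 4), 0.05, 0.05, rep(0, 4))
  expect_equal(nrow(findBumps(eff2, eff2, cl, ann, 0.01, 3)), 0L)
  # sign changes break a run
  eff3 <- c(0.05, 0.05, 0.05, -0.05, -0.05, -0.05, rep(0, 4))
  res3 <- findBumps(eff3, eff3, cl, ann, 0.01, 3)
  expect_equal(nrow(res3), 2L)
  expect_equal(sign(res3$avgDeltaBeta), c(1, -1))
  # candidate regions are disjoint
  expect_true(res3$end[1] < res3$start[2])
})

test_that("permutation FWER is the add-one estimator and is seed-deterministic", {
  b <- tinyBundle(seed = 5, nSamples = 200, nProbes = 800,
                  nSpikedProbes = 0, regionNProbes = 5,
                  regionDeltaBeta = 0.12)
  r1 <- runDmrEwas(b$experiment, nPermutations = 100, seed = 42)
  r2 <- runDmrEwas(b$experiment, nPermutations = 100, seed = 42)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(nrow(r1) >= 1)
  # the strong spiked region dominates every permutation: fwer = 1/(B+1)
  expect_equal(min(r1$fwer), 1 / 101)
  # fwer is monotone non-increasing in area
  o <- order(r1$area, decreasing = TRUE)
  expect_true(all(diff(r1$fwer[o]) >= 0))
  # all fwer values are achievable add-one fractions
  expect_true(all(r1$fwer >= 1 / 101 & r1$fwer <= 1))
})

test_that("the spiked region is recovered with high probe overlap", {
  b <- tinyBundle(seed = 8, nSamples = 300, nProbes = 1500,
                  nSpikedProbes = 0, regionNProbes = 5,
                  regionDeltaBeta = 0.08)
  res <- runDmrEwas(b$experiment, nPermutations = 100, seed = 3)
  truthIds <- unlist(S4Vectors::mcols(spikedRegions(b$truth))$probeIds)
  top <- res[1, ]
  expect_lt(top$fwer, 0.05)
  overlap <- length(intersect(unlist(top$probeIds), truthIds)) /
    length(truthIds)
  expect_gte(overlap, 0.8)
  # probe positions all inside the reported span
  ann <- as.data.frame(probeAnnotation(b$experiment))
  pos <- ann$Position[match(unlist(top$probeIds), ann$ProbeID)]
  expect_true(all(pos >= top$start & pos <= top$end))
})

test_that("the permutation null is invariant to probe order", {
  b <- tinyBundle(seed = 11, nSamples = 120, nProbes = 600,
                  nSpikedProbes = 0, regionNProbes = 5,
                  regionDeltaBeta = 0.10)
  r1 <- runDmrEwas(b$experiment, nPermutations = 50, seed = 7)
  perm <- sample(nrow(b$experiment))
  r2 <- runDmrEwas(b$experiment[perm, ], nPermutations = 50, seed = 7)
  expect_equal(as.data.frame(r1[order(r1$Chr, r1$start), ]),
               as.data.frame(r2[order(r2$Chr, r2$start), ]),
               tolerance = 1e-12)
})

test_that("an empty candidate list short-circuits the permutations", {
  cand <- findBumps(rep(0, 5), rep(0, 5), rep(1L, 5),
                    data.frame(ProbeID = paste0("p", 1:5), Chr = "chr1",
                               Position = 1:5 * 100, Gene = "G",
                               Feature = "Body"))
  out <- assessFWER(matrix(runif(50), 5), rep(0:1, length.out = 10), NULL,
                    cand, rep(1L, 5), nPermutations = 10, seed = 1)
  expect_equal(nrow(out), 0L)
})
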