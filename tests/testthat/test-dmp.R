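test_that("beta/M transform is the clipped logit2", {
  expect_equal(betaToMvalue(0.5), 0)
  expect_equal(betaToMvalue(0.8), 2)
  expect_equal(betaToMvalue(0.2), -2)
  m0 <- betaToMvalue(0, epsilon = 1e-6)
  expect_true(is.finite(m0) && m0 < 0)
  expect_true(is.finite(betaToMvalue(1, epsilon = 1e-6)))
  expect_error(betaToMvalue(1.2), "\\[0, 1\\]")
  expect_error(betaToMvalue(0.5, epsilon = 0.7), "epsilon")
  # matrix shape is preserved
  m <- betaToMvalue(matrix(c(0.5, 0.8, 0.2, 0.5), 2))
  expect_equal(dim(m), c(2L, 2L))
})

test_that("per-probe least squares matches the normal-equations oracle", {
  set.seed(10)
  n <- 30
  X <- cbind(1, rep(0:1, each = n / 2), rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "CLI", "age", "batch")
  M <- matrix(rnorm(50 * n), nrow = 50)
  fit <- fitProbeModels(M, X)
  for (j in c(1, 17, 50)) {
    oracle <- normalEquationsFit(X, M[j, ])
    expect_equal(fit$coef[j], unname(oracle$coef[2]), tolerance = 1e-8)
    expect_equal(fit$se[j], unname(oracle$se[2]), tolerance = 1e-8)
    expect_equal(fit$sigma2[j], oracle$sigma2, tolerance = 1e-8)
  }
  # constant probe: zero coefficient, zero variance
  Mc <- rbind(rep(3, n))
  fitc <- fitProbeModels(Mc, X)
  expect_equal(fitc$coef, 0, tolerance = 1e-12)
  expect_equal(fitc$sigma2, 0, tolerance = 1e-12)
  # exact fit: M equals the exposure
  Xe <- cbind(1, c(0, 0, 1, 1))
  fite <- fitProbeModels(rbind(c(0, 0, 1, 1)), Xe)
  expect_equal(fite$coef, 1, tolerance = 1e-12)
  expect_equal(fite$sigma2, 0, tolerance = 1e-12)
  # collinear design is refused with the offending column named
  Xbad <- cbind(X, dup = X[, "age"])
  expect_error(fitProbeModels(M, Xbad), "dup")
})

test_that("probe results do not depend on probe order", {
  b <- tinyBundle(seed = 6)
  # few probes, so the empirical-null small-sample warning is expected
  r1 <- suppressWarnings(runDmpEwas(b$experiment))
  perm <- sample(nrow(b$experiment))
  r2 <- suppressWarnings(runDmpEwas(b$experiment[perm, ]))
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
})

test_that("variance moderation recovers the prior and has the right limits", {
  set.seed(77)
  d0 <- 4; s0 <- 2; df <- 20
  s2 <- s0^2 * df / rchisq(5000, df) * rchisq(5000, d0) / d0
  # equivalent scaled F draw: s2 ~ s0^2 F(df, d0)
  s2 <- s0^2 * rf(5000, df, d0)
  coefs <- rnorm(5000)
  mod <- moderateStatistics(s2, df, coefs, seUnit = 1)
  expect_gt(mod$d0, 3); expect_lt(mod$d0, 5)
  expect_gt(sqrt(mod$s02), 1.8); expect_lt(sqrt(mod$s02), 2.2)
  # no-shrinkage limit: ordinary t
  raw <- moderateStatistics(s2, df, coefs, seUnit = 1, d0 = 0)
  expect_equal(raw$t, coefs / sqrt(s2), tolerance = 1e-12)
  # full-shrinkage limit: common variance
  full <- moderateStatistics(s2, df, coefs, seUnit = 1, d0 = Inf)
  expect_equal(length(unique(round(full$s2Post, 12))), 1L)
  # shrinkage is monotone: extreme variances move toward s0^2
  expect_true(all(mod$s2Post[s2 > mod$s02] < s2[s2 > mod$s02]))
  expect_true(all(mod$s2Post[s2 < mod$s02] > s2[s2 < mod$s02]))
})

test_that("moderated statistics agree with the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(5)
  s2 <- rf(2000, 15, 6) * 1.3
  sq <- limma::squeezeVar(s2, df = 15)
  mod <- moderateStatistics(s2, 15, rnorm(2000), seUnit = 1)
  expect_equal(mod$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(mod$s02, sq$var.prior, tolerance = 0.01)
  expect_equal(mod$s2Post, sq$var.post, tolerance = 0.01)
})

test_that("BH adjustment matches brute force and the reference implementation", {
  expect_equal(adjustFDR(0.03), 0.03)
  expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
  expect_identical(adjustFDR(numeric(0)), numeric(0))
  set.seed(3)
  for (m in c(1, 7, 40, 100)) {
    p <- round(runif(m)^2, 3)  # with ties
    q <- adjustFDR(p)
    expect_equal(q, bruteForceBH(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(adjustFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("beta-scale effect sizes are group mean differences", {
  beta <- rbind(a = c(0.30, 0.30, 0.32, 0.32),
                b = c(0.5, 0.5, 0.5, 0.5))
  expect_equal(unname(computeDeltaBeta(beta, c(1, 1, 0, 0))),
               c(-0.02, 0))
  expect_equal(unname(computeDeltaBeta(beta, c(0, 0, 1, 1))), c(0.02, 0))
  expect_error(computeDeltaBeta(beta, c(1, 1, 1, 1)), "non-empty")
  expect_error(computeDeltaBeta(beta, c(1, 0, 2, 0)), "binary")
})

test_that("M-scale coefficients and beta-scale effects agree in sign at spiked probes", {
  cfg <- simulationConfig(nSamples = 300, nProbes = 2000, nSpikedProbes = 30,
                          spikeDeltaBeta = 0.05, nSpikedRegions = 0, seed = 13)
  b <- simulateLifemethBundle(cfg)
  dmp <- runDmpEwas(b$experiment)
  sub <- dmp[dmp$ProbeID %in% spikedProbes(b$truth), ]
  agree <- sign(sub$coefM) == sign(sub$deltaBeta)
  expect_gte(mean(agree), 0.99)
  # run metadata records the model and empirical-null parameters
  md <- S4Vectors::metadata(dmp)
  expect_equal(md$model, "base")
  expect_equal(md$n, 300)
  expect_true(is.finite(md$biasMu) && is.finite(md$inflationSigma))
})

test_that("the BMI-adjusted design gains exactly one column", {
  b <- tinyBundle(seed = 4)
  ph <- as.data.frame(SummarizedExperiment::colData(b$experiment))
  d1 <- buildDesign(ph, "base")
  d2 <- buildDesign(ph, "bmi")
  expect_equal(ncol(d2), ncol(d1) + 1L)
  expect_true("BMI" %in% colnames(d2))
  expect_equal(unname(d1[, 2]), ph$CLI)
})
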