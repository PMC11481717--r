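test_that("component scorers follow the risk-factor point allocation", {
  expect_identical(scoreSmoking(c("current", "former", "never")), c(0L, 1L, 2L))
  expect_error(scoreSmoking("pipe"), "unknown smoking category")

  expect_identical(scoreAlcohol(0, "female", neverDrinker = TRUE), 2L)
  expect_identical(scoreAlcohol(0, "male"), 2L)
  expect_equal(scoreAlcohol(1.0, "female"), 1L)
  expect_equal(scoreAlcohol(1.5, "female"), 0L)
  expect_equal(scoreAlcohol(2.0, "male"), 1L)
  expect_equal(scoreAlcohol(2.5, "male"), 0L)
  expect_error(scoreAlcohol(-1, "male"), "non-negative")
  expect_error(scoreAlcohol(1, "male", neverDrinker = TRUE), "zero units")

  expect_identical(scoreActivity(c("low", "moderate", "high")), c(0L, 1L, 2L))

  expect_equal(scoreDiet(56), 1L)
  expect_equal(scoreDiet(33.33), 0L)
  expect_equal(scoreDiet(66.66), 1L)
  expect_equal(scoreDiet(c(0, 33.34, 67, 100)), c(0L, 1L, 2L, 2L))
  expect_error(scoreDiet(101), "\\[0, 100\\]")
})

test_that("activity categorization applies the MET-minute rules with high before moderate", {
  expect_equal(categorizeActivity(vigorousDays = 3, totalMetMin = 1600), "high")
  expect_equal(categorizeActivity(vigorousDays = 3, totalMetMin = 1500), "high")
  expect_equal(categorizeActivity(vigorousDays = 2, moderateDays = 3,
                                  walkingDays = 2, totalMetMin = 3000), "high")
  expect_equal(categorizeActivity(vigorousDays = 3, vigorousMin = 25,
                                  totalMetMin = 500), "moderate")
  expect_equal(categorizeActivity(vigorousDays = 0, moderateDays = 3,
                                  moderateMin = 35, walkingDays = 2,
                                  walkingMin = 30, totalMetMin = 500),
               "moderate")
  expect_equal(categorizeActivity(vigorousDays = 1, moderateDays = 2,
                                  walkingDays = 2, totalMetMin = 700),
               "moderate")
  expect_equal(categorizeActivity(0), "low")
  expect_equal(categorizeActivity(vigorousDays = 2, totalMetMin = 1400), "low")
  # a record matching both rule sets must come out high, not moderate
  expect_equal(categorizeActivity(vigorousDays = 3, vigorousMin = 30,
                                  totalMetMin = 2000), "high")
  expect_error(categorizeActivity(8), "\\[0, 7\\]")
})

test_that("activity categorization is total over a grid of records", {
  set.seed(42)
  cats <- categorizeActivity(sample(0:7, 500, TRUE), sample(0:90, 500, TRUE),
                             sample(0:7, 500, TRUE), sample(0:90, 500, TRUE),
                             sample(0:7, 500, TRUE), sample(0:90, 500, TRUE),
                             runif(500, 0, 6000))
  expect_true(all(cats %in% c("high", "moderate", "low")))
})

test_that("index totals, the high-risk boundary at 4 and monotonicity hold over all 81 combinations", {
  grid <- expand.grid(s = 0:2, a = 0:2, act = 0:2, d = 0:2)
  res <- computeCLI(grid$s, grid$a, grid$act, grid$d)
  expect_equal(res$total, grid$s + grid$a + grid$act + grid$d)
  expect_equal(res$index, as.integer(res$total <= 4))
  expect_equal(res$riskLevel, ifelse(res$total <= 4, "high", "low"))
  # boundary: total 4 is high risk, 5 is low
  expect_equal(computeCLI(2, 2, 0, 0)$riskLevel, "high")
  expect_equal(computeCLI(2, 2, 1, 0)$riskLevel, "low")
  expect_equal(computeCLI(0, 0, 0, 0)$index, 1L)
  expect_equal(computeCLI(2, 2, 2, 2)$index, 0L)
  # raising any single component never moves low risk -> high risk
  for (comp in c("s", "a", "act", "d")) {
    g <- grid[grid[[comp]] < 2, ]
    g2 <- g
    g2[[comp]] <- g2[[comp]] + 1
    before <- computeCLI(g$s, g$a, g$act, g$d)$index
    after <- computeCLI(g2$s, g2$a, g2$act, g2$d)$index
    expect_true(all(after <= before))
  }
  expect_error(computeCLI(3, 0, 0, 0), "must be 0, 1 or 2")
})

test_that("component correlations match the direct Pearson formula and flag degenerate columns", {
  toy <- data.frame(a = c(1, 2, 3, 5, 4), b = c(2, 1, 4, 5, 3),
                    c = c(10, 8, 6, 2, 5))
  cc <- correlateComponents(toy)
  expect_equal(diag(cc$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$r, t(cc$r))
  manual <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(cc$r["a", "b"], manual(toy$a, toy$b), tolerance = 1e-12)
  expect_equal(cc$r["a", "c"], manual(toy$a, toy$c), tolerance = 1e-12)
  expect_equal(cc$p["a", "b"], cor.test(toy$a, toy$b)$p.value,
               tolerance = 1e-12)
  expect_warning(cc0 <- correlateComponents(cbind(toy, z = 1)),
                 "zero-variance")
  expect_true(all(is.na(cc0$r["z", ])))

  b <- tinyBundle(seed = 3)
  tab <- b$scores
  cc2 <- correlateComponents(tab[c("total", "smokingPoints", "alcoholPoints",
                                   "activityPoints", "dietPoints")])
  expect_true(cc2$r["total", "alcoholPoints"] > 0)
  expect_true(cc2$r["total", "activityPoints"] > 0)
})

test_that("phenotype scoring is complete-case and reproduces drawn categories", {
  b <- tinyBundle(seed = 5)
  ph <- as.data.frame(SummarizedExperiment::colData(b$experiment))
  sc <- scoreLifestyle(ph)
  expect_equal(nrow(sc), nrow(ph))
  expect_true(all(sc$total >= 0 & sc$total <= 8))
  # abstainers always earn the full alcohol points
  expect_true(all(sc$alcoholPoints[ph$NeverDrinker] == 2))
  ph$DQI[3] <- NA
  expect_error(scoreLifestyle(ph), "complete cases")
})
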