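#' Build a simulation configuration
#'
#' Returns a validated \linkS4class{SimulationConfig}. Defaults emulate the
#' cohort the pipeline targets: ~700 participants whose lifestyle category
#' frequencies match a West-African migrant study population (88.6% never
#' smokers, 61.6% alcohol abstainers, 41.7% high physical activity, diet
#' quality 56 +/- 6.1 points), a bimodal 450k-style beta landscape, spiked
#' probes at the 1-3% beta-difference scale of reported lifestyle DMPs, one
#' spiked 10-probe region with a 0.075 average shift, and outcome links on
#' the scale of the reported T2DM/FBG/HbA1c associations.
#'
#' @param nSamples,nProbes cohort and array size.
#' @param nSpikedProbes,spikeDeltaBeta isolated spiked probes and their
#'   beta-scale shift (must lie in [0, 0.2]).
#' @param nSpikedRegions,regionNProbes,regionDeltaBeta spiked contiguous
#'   regions (each \code{regionNProbes} >= 3 consecutive probes).
#' @param categoryFrequencies named list of probability vectors for
#'   \code{smoking}, \code{alcohol}, \code{activity} (see
#'   \linkS4class{SimulationConfig}).
#' @param dqiMean,dqiSd diet-quality distribution.
#' @param betaShapes,betaMixing,spikeShapes probe-mean Beta mixture
#'   \code{c(a1, b1, a2, b2)}, its low-component weight, and the Beta shapes
#'   of spiked-probe baseline means.
#' @param samplePrecision Beta precision of per-sample values around the
#'   probe mean; the default 200 gives a within-probe SD of ~3.5\% at
#'   mid-methylated probes.
#' @param outcomeLinks named coefficient vector (see
#'   \linkS4class{SimulationConfig}); defaults give ~40% T2DM prevalence, a
#'   CLI log-odds of 0.25, and FBG/HbA1c methylation slopes of 0.29 and
#'   -1.8 per 1% methylation.
#' @param noiseSdFbg,noiseSdHba1c outcome noise (mmol/L, mmol/mol).
#' @param seed integer master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 700L, nProbes = 20000L,
                             nSpikedProbes = 20L, spikeDeltaBeta = 0.02,
                             nSpikedRegions = 1L, regionNProbes = 10L,
                             regionDeltaBeta = 0.075,
                             categoryFrequencies = list(
                               smoking = c(never = 632, former = 65,
                                           current = 16) / 713,
                               alcohol = c(abstainer = 439, moderate = 253,
                                           heavy = 21) / 713,
                               activity = c(high = 297, moderate = 163,
                                            low = 253) / 713),
                             dqiMean = 56, dqiSd = 6.1,
                             betaShapes = c(2, 10, 10, 2), betaMixing = 0.5,
                             spikeShapes = c(8, 8), samplePrecision = 200,
                             outcomeLinks = c(t2dmIntercept = -0.55,
                                              t2dmCli = 0.25,
                                              t2dmMeth = -0.28,
                                              fbgIntercept = 5.3,
                                              fbgCli = 0.22, fbgMeth = 29,
                                              hba1cIntercept = 38,
                                              hba1cCli = 0.65,
                                              hba1cMeth = -180),
                             noiseSdFbg = 1.0, noiseSdHba1c = 8,
                             seed = 1L) {
  new("SimulationConfig",
      nSamples = as.integer(nSamples), nProbes = as.integer(nProbes),
      nSpikedProbes = as.integer(nSpikedProbes),
      spikeDeltaBeta = spikeDeltaBeta,
      nSpikedRegions = as.integer(nSpikedRegions),
      regionNProbes = as.integer(regionNProbes),
      regionDeltaBeta = regionDeltaBeta,
      categoryFrequencies = categoryFrequencies,
      dqiMean = dqiMean, dqiSd = dqiSd,
      betaShapes = betaShapes, betaMixing = betaMixing,
      spikeShapes = spikeShapes, samplePrecision = samplePrecision,
      outcomeLinks = outcomeLinks,
      noiseSdFbg = noiseSdFbg, noiseSdHba1c = noiseSdHba1c,
      seed = as.integer(seed))
}

# One master seed drives three documented sub-streams so each stage is
# reproducible on its own.
.subSeeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, 3L)
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

#' Simulate a participant phenotype table
#'
#' Draws demographics, the four lifestyle inputs, diet quality, estimated
#' blood-cell proportions (Dirichlet over six leukocyte types) and technical
#' covariates (hybridization batch, array position) for
#' \code{nSamples} participants. Activity records are constructed to be
#' internally consistent with the drawn IPAQ category, so
#' [categorizeActivity()] recovers it exactly. Deterministic given the
#' config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame, one row per participant.
#' @export
simulateParticipants <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nSamples
  set.seed(.subSeeds(config@seed)[1])
  freq <- config@categoryFrequencies
  smoking <- sample(names(freq$smoking), n, TRUE, prob = freq$smoking)
  alcoholCat <- sample(names(freq$alcohol), n, TRUE, prob = freq$alcohol)
  activityCat <- sample(names(freq$activity), n, TRUE, prob = freq$activity)
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.426, 0.574))

  cutoff <- ifelse(sex == "male", 2, 1)
  units <- numeric(n)
  mod <- alcoholCat == "moderate"; heavy <- alcoholCat == "heavy"
  units[mod] <- stats::runif(sum(mod), 0.1, cutoff[mod])
  units[heavy] <- cutoff[heavy] + stats::runif(sum(heavy), 0.5, 3)

  vd <- vm <- md <- mm <- wd <- wm <- tot <- numeric(n)
  hi <- activityCat == "high"; mo <- activityCat == "moderate"
  lo <- activityCat == "low"
  vd[hi] <- sample(3:6, sum(hi), TRUE)
  vm[hi] <- sample(30:60, sum(hi), TRUE)
  wd[hi] <- sample(0:3, sum(hi), TRUE)
  wm[hi] <- sample(10:40, sum(hi), TRUE)
  tot[hi] <- stats::runif(sum(hi), 1500, 4500)
  vd[mo] <- 3L
  vm[mo] <- sample(20:30, sum(mo), TRUE)
  md[mo] <- sample(0:2, sum(mo), TRUE)
  mm[mo] <- sample(10:25, sum(mo), TRUE)
  tot[mo] <- stats::runif(sum(mo), 600, 1450)
  wd[lo] <- sample(0:2, sum(lo), TRUE)
  wm[lo] <- sample(0:20, sum(lo), TRUE)
  tot[lo] <- stats::runif(sum(lo), 0, 400)

  # Dirichlet cell proportions around typical whole-blood composition
  alpha <- c(Gran = 33, CD4T = 10, CD8T = 7, Bcell = 4, Mono = 5, NK = 1.5)
  g <- matrix(stats::rgamma(n * 6, shape = rep(alpha, each = n)), nrow = n)
  cells <- g / rowSums(g)
  colnames(cells) <- paste0("Cell_", names(alpha))

  data.frame(
    SampleID = sprintf("S%05d", seq_len(n)),
    Age = round(.rtruncnorm(n, 51, 9.9, 18, 90)),
    Sex = sex,
    Site = sample(c("rural_ghana", "urban_ghana", "europe"), n, TRUE,
                  prob = c(104, 243, 366) / 713),
    BMI = round(.rtruncnorm(n, 27, 5.5, 16, 52), 1),
    Smoking = smoking,
    AlcoholUnitsPerDay = round(units, 2),
    NeverDrinker = alcoholCat == "abstainer",
    VigorousDays = vd, VigorousMin = vm,
    ModerateDays = md, ModerateMin = mm,
    WalkingDays = wd, WalkingMin = wm,
    TotalMetMin = round(tot),
    DQI = round(.rtruncnorm(n, config@dqiMean, config@dqiSd, 0, 100), 1),
    cells,
    Batch = sample(paste0("B", 1:6), n, TRUE),
    ArrayPosition = sample(paste0("P", 1:8), n, TRUE),
    stringsAsFactors = FALSE)
}

#' Simulate a methylation matrix with spiked signal
#'
#' Probe means are drawn from a two-component Beta mixture
#' (low/high-methylated), reproducing the bimodal beta landscape of
#' methylation arrays; per-sample values vary around each probe mean with a
#' common Beta precision. \code{nSpikedProbes} isolated probes and
#' \code{nSpikedRegions} runs of consecutive probes get mid-range baseline
#' means and an additive beta-scale shift in high-risk
#' (\code{cliIndex == 1}) participants; means are clipped to
#' [1e-3, 1 - 1e-3] and values to [1e-6, 1 - 1e-6]. Annotation positions increase
#' strictly within each chromosome; region probes are placed at small
#' (< 200 bp) gaps so they form one probe cluster downstream.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param participants phenotype table (row order defines sample order).
#' @param cliIndex binary high-risk index per participant.
#' @return list with elements \code{experiment}
#'   (\linkS4class{MethylationExperiment}) and \code{truth}
#'   (\linkS4class{GroundTruth}).
#' @export
simulateMethylation <- function(config, participants, cliIndex) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  n <- config@nSamples; p <- config@nProbes
  if (nrow(participants) != n)
    stop("participants does not match config nSamples")
  if (length(cliIndex) != n || !all(cliIndex %in% 0:1))
    stop("cliIndex must be binary with one value per participant")
  set.seed(.subSeeds(config@seed)[2])

  # annotation: probes spread over chr1..chr22, gap mixture so that some
  # background probes form small clusters and most are isolated
  chrom <- sort(sample(factor(paste0("chr", 1:22),
                              levels = paste0("chr", 1:22)), p, TRUE))
  gaps <- ifelse(stats::runif(p) < 0.3,
                 sample(50:400, p, TRUE), sample(2000L:20000L, p, TRUE))

  nregion <- config@nSpikedRegions
  regionIdx <- vector("list", nregion)
  if (nregion > 0) {
    w <- config@regionNProbes
    tab <- table(chrom)
    eligible <- names(tab)[tab >= w + 2]
    if (length(eligible) < nregion)
      stop("not enough probes per chromosome to place spiked regions")
    regChr <- sample(eligible, nregion)
    for (k in seq_len(nregion)) {
      onChr <- which(as.character(chrom) == regChr[k])
      startAt <- sample(seq_len(length(onChr) - w + 1), 1)
      idx <- onChr[startAt:(startAt + w - 1)]
      regionIdx[[k]] <- idx
      gaps[idx[-1]] <- sample(50:150, w - 1, TRUE)  # keep within one cluster
    }
  }
  pos <- unlist(lapply(split(gaps, chrom), function(g) 10000L + cumsum(g)),
                use.names = FALSE)
  probeIds <- sprintf("cg%08d", seq_len(p))
  genes <- ifelse(stats::runif(p) < 0.6, sprintf("GENE%04d",
                                                 sample.int(3000, p, TRUE)),
                  "Intergenic")
  features <- sample(c("TSS200", "TSS1500", "Body", "5'UTR", "3'UTR",
                       "1stExon", "IGR"), p, TRUE,
                     prob = c(.1, .1, .35, .08, .07, .05, .25))
  annotation <- data.frame(ProbeID = probeIds, Chr = as.character(chrom),
                           Position = pos, Gene = genes, Feature = features,
                           stringsAsFactors = FALSE)

  inRegion <- unlist(regionIdx)
  free <- setdiff(seq_len(p), inRegion)
  spikeIdx <- if (config@nSpikedProbes > 0)
    sort(sample(free, config@nSpikedProbes)) else integer(0)

  # probe-mean landscape: bimodal Beta mixture; per-sample values vary
  # around the probe mean with a common precision (array-realistic
  # within-probe SD of a few percent)
  sh <- config@betaShapes
  lowComp <- stats::runif(p) < config@betaMixing
  mu <- stats::rbeta(p, shape1 = ifelse(lowComp, sh[1], sh[3]),
                     shape2 = ifelse(lowComp, sh[2], sh[4]))
  shifted <- c(spikeIdx, inRegion)
  if (length(shifted)) {
    ss <- config@spikeShapes
    # mid-range baselines so the additive shift rarely clips
    mu[shifted] <- stats::rbeta(length(shifted), ss[1], ss[2])
  }
  muMat <- matrix(mu, nrow = p, ncol = n)
  if (length(shifted)) {
    delta <- c(rep(config@spikeDeltaBeta, length(spikeIdx)),
               rep(config@regionDeltaBeta, length(inRegion)))
    muMat[shifted, ] <- muMat[shifted, , drop = FALSE] +
      outer(delta, cliIndex)
  }
  muMat <- pmin(pmax(muMat, 1e-3), 1 - 1e-3)
  phi <- config@samplePrecision
  beta <- matrix(stats::rbeta(p * n, shape1 = muMat * phi,
                              shape2 = (1 - muMat) * phi), nrow = p)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(probeIds, participants$SampleID)

  regions <- if (nregion > 0) {
    GRanges(seqnames = vapply(regionIdx, function(i)
              annotation$Chr[i[1]], ""),
            ranges = IRanges(
              start = vapply(regionIdx, function(i) min(pos[i]), 0),
              end = vapply(regionIdx, function(i) max(pos[i]), 0)),
            probeIds = IRanges::CharacterList(
              lapply(regionIdx, function(i) probeIds[i])))
  } else GRanges()
  truth <- new("GroundTruth",
               spikedProbes = probeIds[spikeIdx],
               trueDeltaBeta = stats::setNames(
                 c(rep(config@spikeDeltaBeta, length(spikeIdx)),
                   rep(config@regionDeltaBeta, length(inRegion))),
                 probeIds[c(spikeIdx, inRegion)]),
               spikedRegions = regions,
               outcomeCoefficients = config@outcomeLinks)
  list(experiment = MethylationExperiment(beta, annotation, participants),
       truth = truth)
}

#' Simulate clinical outcomes
#'
#' Adds T2DM status (logistic link), fasting blood glucose and HbA1c
#' (linear links plus Gaussian noise) to the participant table. Predictors
#' are the binary lifestyle index (recomputed from the participant table via
#' [scoreLifestyle()]) and the centred mean beta over spiked probes.
#' Deterministic given the config seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param participants phenotype table.
#' @param experiment \linkS4class{MethylationExperiment} aligned with
#'   \code{participants}.
#' @param truth \linkS4class{GroundTruth} naming the spiked probes.
#' @return \code{participants} with added columns \code{T2DM}, \code{FBG},
#'   \code{HbA1c}.
#' @export
simulateOutcomes <- function(config, participants, experiment, truth) {
  stopifnot(is(config, "SimulationConfig"))
  if (!identical(colnames(experiment), participants$SampleID))
    stop("sample ids of methylation and participants are misaligned")
  set.seed(.subSeeds(config@seed)[3])
  n <- nrow(participants)
  cli <- scoreLifestyle(participants)$index
  spiked <- names(trueDeltaBeta(truth))
  sig <- if (length(spiked)) {
    m <- colMeans(betaValues(experiment)[spiked, , drop = FALSE])
    m - mean(m)
  } else rep(0, n)
  L <- config@outcomeLinks
  eta <- L["t2dmIntercept"] + L["t2dmCli"] * cli + L["t2dmMeth"] * sig
  participants$T2DM <- stats::rbinom(n, 1, stats::plogis(eta))
  participants$FBG <- round(
    L["fbgIntercept"] + L["fbgCli"] * cli + L["fbgMeth"] * sig +
      stats::rnorm(n, 0, config@noiseSdFbg), 2)
  participants$HbA1c <- round(
    L["hba1cIntercept"] + L["hba1cCli"] * cli + L["hba1cMeth"] * sig +
      stats::rnorm(n, 0, config@noiseSdHba1c), 1)
  participants
}

#' Simulate a complete study bundle
#'
#' Chains [simulateParticipants()], [scoreLifestyle()],
#' [simulateMethylation()] and [simulateOutcomes()] into one reproducible
#' bundle: the study conditions every downstream stage is exercised on.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{experiment} (phenotype incl. outcomes in
#'   \code{colData}), \code{truth}, \code{scores} (lifestyle score table)
#'   and \code{config}.
#' @examples
#' bundle <- simulateLifemethBundle(simulationConfig(nSamples = 50,
#'                                                   nProbes = 300, seed = 7))
#' table(bundle$scores$riskLevel)
#' @export
simulateLifemethBundle <- function(config) {
  participants <- simulateParticipants(config)
  scores <- scoreLifestyle(participants)
  sim <- simulateMethylation(config, participants, scores$index)
  pheno <- simulateOutcomes(config, participants, sim$experiment, sim$truth)
  pheno$CLI <- scores$index
  pheno$CLITotal <- scores$total
  experiment <- MethylationExperiment(betaValues(sim$experiment),
                                      as.data.frame(probeAnnotation(sim$experiment)),
                                      pheno)
  list(experiment = experiment, truth = sim$truth, scores = scores,
       config = config)
}
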