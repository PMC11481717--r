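#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList isEmpty
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData rowData
NULL

#' Container for a methylation study
#'
#' A \code{MethylationExperiment} is a
#' \linkS4class{RangedSummarizedExperiment} holding one assay named
#' \code{"beta"} (methylation fractions, probes x samples), probe annotation
#' as \code{rowRanges} (1-based manifest-style positions, with \code{gene}
#' and \code{feature} metadata columns) and the participant phenotype table
#' as \code{colData}.
#'
#' @slot ... see \linkS4class{RangedSummarizedExperiment}.
#' @seealso [MethylationExperiment()] for the validating constructor,
#'   [betaValues()], [mValues()], [probeAnnotation()].
#' @export
setClass("MethylationExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  msg <- NULL
  if (!"beta" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (anyNA(b) || any(b < 0) || any(b > 1))
      msg <- c(msg, "beta values must lie in [0, 1] with no missing entries")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (is.null(rownames(object)))
    msg <- c(msg, "probe ids (rownames) are required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Configuration of the synthetic-data generator
#'
#' Holds every knob of the simulator: cohort size, array size, the spiked
#' (truly differentially methylated) probes and regions, the lifestyle
#' category frequencies the phenotype table is drawn from, the diet-quality
#' distribution, the background beta mixture, and the coefficients linking
#' the lifestyle index and methylation to the clinical outcomes.
#'
#' @slot nSamples,nProbes cohort and array dimensions.
#' @slot nSpikedProbes number of isolated probes shifted between lifestyle
#'   groups; \code{spikeDeltaBeta} is the beta-scale shift, in (0, 0.2].
#' @slot nSpikedRegions,regionNProbes,regionDeltaBeta contiguous spiked
#'   regions: how many, how many consecutive probes each (>= 3), and the
#'   beta-scale shift applied to every probe in the region.
#' @slot categoryFrequencies named list of probability vectors for
#'   \code{smoking} (never/former/current), \code{alcohol}
#'   (abstainer/moderate/heavy) and \code{activity} (high/moderate/low).
#' @slot dqiMean,dqiSd diet-quality score distribution (points on 0-100,
#'   truncated normal).
#' @slot betaShapes shape parameters \code{(a1, b1, a2, b2)} of the
#'   two-component Beta mixture the probe means are drawn from;
#'   \code{betaMixing} is the weight of the low-methylated component;
#'   \code{spikeShapes} the Beta shapes of spiked-probe baseline means
#'   (kept mid-range so additive shifts rarely clip);
#'   \code{samplePrecision} the Beta precision of per-sample values around
#'   the probe mean (within-probe SD ~ sqrt(mu(1-mu)/(precision+1))).
#' @slot outcomeLinks named numeric vector of link coefficients:
#'   \code{t2dmIntercept} (log-odds), \code{t2dmCli}, \code{t2dmMeth},
#'   \code{fbgIntercept}, \code{fbgCli}, \code{fbgMeth},
#'   \code{hba1cIntercept}, \code{hba1cCli}, \code{hba1cMeth}. Methylation
#'   enters as the centred mean beta over spiked probes.
#' @slot noiseSdFbg,noiseSdHba1c residual noise of the continuous outcomes
#'   (mmol/L and mmol/mol).
#' @slot seed integer driving all three generator stages through derived
#'   sub-seeds.
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig", representation(
  nSamples = "integer", nProbes = "integer",
  nSpikedProbes = "integer", spikeDeltaBeta = "numeric",
  nSpikedRegions = "integer", regionNProbes = "integer",
  regionDeltaBeta = "numeric",
  categoryFrequencies = "list",
  dqiMean = "numeric", dqiSd = "numeric",
  betaShapes = "numeric", betaMixing = "numeric", spikeShapes = "numeric",
  samplePrecision = "numeric",
  outcomeLinks = "numeric",
  noiseSdFbg = "numeric", noiseSdHba1c = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  for (f in c("smoking", "alcohol", "activity")) {
    p <- object@categoryFrequencies[[f]]
    if (is.null(p))
      msg <- c(msg, sprintf("categoryFrequencies is missing factor '%s'", f))
    else if (anyNA(p) || any(p < 0) || any(p > 1) ||
             abs(sum(p) - 1) > 1e-6)
      msg <- c(msg, sprintf(
        "invalid frequency vector for factor '%s': probabilities must lie in [0,1] and sum to 1", f))
  }
  if (length(object@spikeDeltaBeta) != 1 || object@spikeDeltaBeta < 0 ||
      object@spikeDeltaBeta > 0.2)
    msg <- c(msg, "spikeDeltaBeta must lie in [0, 0.2]")
  if (object@nSpikedRegions > 0 && object@regionNProbes < 3)
    msg <- c(msg, "regionNProbes must be >= 3")
  if (object@nSpikedProbes + object@nSpikedRegions * object@regionNProbes >
      object@nProbes)
    msg <- c(msg, "spiked probes and regions exceed nProbes")
  if (object@dqiSd <= 0) msg <- c(msg, "dqiSd must be positive")
  if (object@samplePrecision <= 0)
    msg <- c(msg, "samplePrecision must be positive")
  need <- c("t2dmIntercept", "t2dmCli", "t2dmMeth", "fbgIntercept", "fbgCli",
            "fbgMeth", "hba1cIntercept", "hba1cCli", "hba1cMeth")
  if (!all(need %in% names(object@outcomeLinks)))
    msg <- c(msg, paste("outcomeLinks must contain:",
                        paste(setdiff(need, names(object@outcomeLinks)),
                              collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Ground truth of a simulated bundle
#'
#' Records which probes and regions were spiked, with what beta-scale effect,
#' and the outcome link coefficients actually used — the oracle against which
#' DMP/DMR recovery and mediation are judged.
#'
#' @slot spikedProbes character vector of isolated spiked probe ids.
#' @slot trueDeltaBeta named numeric, configured beta-scale shift per spiked
#'   probe (region probes included).
#' @slot spikedRegions \linkS4class{GRanges} of spiked spans (1-based,
#'   closed); metadata column \code{probeIds} is a CharacterList.
#' @slot outcomeCoefficients the link coefficients used by the outcome stage.
#' @export
setClass("GroundTruth", representation(
  spikedProbes = "character",
  trueDeltaBeta = "numeric",
  spikedRegions = "GRanges",
  outcomeCoefficients = "numeric"))

setValidity("GroundTruth", function(object) {
  msg <- NULL
  if (length(object@spikedRegions) > 0) {
    np <- lengths(S4Vectors::mcols(object@spikedRegions)$probeIds)
    if (any(np < 3))
      msg <- c(msg, "each spiked region must span at least 3 probes")
  }
  if (is.null(msg)) TRUE else msg
})

#' Per-probe differential-methylation results
#'
#' A \linkS4class{DFrame} with one row per probe: annotation, beta-scale
#' effect (high- minus low-risk group mean), M-scale coefficient, raw and
#' moderated t statistics, raw / empirical-null-corrected p-values and BH
#' FDR. \code{metadata()} carries the run record: model, sample size,
#' empirical-null bias and inflation, moderation hyperparameters and genomic
#' inflation factors before and after correction.
#'
#' @export
setClass("DMPResults", contains = "DFrame")

#' Differentially methylated regions
#'
#' A \linkS4class{DFrame} with one row per candidate region (chromosome,
#' 1-based start/end, probe count and ids, area of smoothed effects, average
#' raw beta difference, permutation FWER). \code{metadata()} records the
#' bump-hunting parameters, permutation count and seed.
#'
#' @export
setClass("DMRResults", contains = "DFrame")

#' Predictor-outcome association results
#'
#' A \linkS4class{DFrame}: one row per predictor x outcome x model cell with
#' the estimate (odds ratio for T2DM, slope otherwise), Wald 95\% confidence
#' interval and p-value.
#'
#' @export
setClass("AssociationResults", contains = "DFrame")

#' Result of one bootstrap mediation analysis
#'
#' Product-of-coefficients decomposition of an exposure effect through one
#' mediator: path a (exposure to mediator), path b (mediator to outcome,
#' exposure-adjusted), direct, indirect (= a x b) and total effects, with a
#' percentile bootstrap interval and two-sided p for the indirect effect.
#' For a binary outcome the b/direct/total paths are on the log-odds scale,
#' so the indirect product is scale-hybrid (see the vignette).
#'
#' @slot mediator mediator label.
#' @slot pathA,pathB,directEffect,indirectEffect,totalEffect path
#'   coefficients and effects.
#' @slot ciLow,ciHigh,pIndirect percentile bootstrap 95\% interval and
#'   add-one two-sided bootstrap p for the indirect effect.
#' @slot nBoot,nFailed,seed bootstrap bookkeeping.
#' @slot binaryOutcome whether the outcome was fitted by logistic regression.
#' @export
setClass("MediationResult", representation(
  mediator = "character",
  pathA = "numeric", pathB = "numeric",
  directEffect = "numeric", indirectEffect = "numeric",
  totalEffect = "numeric",
  ciLow = "numeric", ciHigh = "numeric", pIndirect = "numeric",
  nBoot = "integer", nFailed = "integer", seed = "integer",
  binaryOutcome = "logical"))

setValidity("MediationResult", function(object) {
  msg <- NULL
  if (abs(object@indirectEffect - object@pathA * object@pathB) >
      1e-12 * max(1, abs(object@indirectEffect)))
    msg <- c(msg, "indirectEffect must equal pathA * pathB")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    msg <- c(msg, "ciLow must not exceed ciHigh")
  if (is.null(msg)) TRUE else msg
})
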