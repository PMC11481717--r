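#' Construct a MethylationExperiment
#'
#' Assembles the three standard inputs — a beta-value matrix, an
#' Illumina-manifest-style probe annotation table and a phenotype table —
#' into a validated \linkS4class{MethylationExperiment}, cross-checking
#' probe and sample identifiers.
#'
#' @param beta numeric matrix of methylation fractions, probes x samples,
#'   with probe ids as rownames and sample ids as colnames.
#' @param annotation data.frame with columns \code{ProbeID}, \code{Chr},
#'   \code{Position} (1-based), \code{Gene}, \code{Feature}.
#' @param phenotype data.frame of participant records, one row per sample;
#'   must contain a \code{SampleID} column matching \code{colnames(beta)}.
#' @return a \linkS4class{MethylationExperiment}.
#' @examples
#' bundle <- simulateLifemethBundle(simulationConfig(nSamples = 40,
#'                                                   nProbes = 200, seed = 1))
#' bundle$experiment
#' @export
MethylationExperiment <- function(beta, annotation, phenotype) {
  beta <- as.matrix(beta)
  if (!is.numeric(beta))
    stop("beta matrix must be numeric")
  need <- c("ProbeID", "Chr", "Position", "Gene", "Feature")
  miss <- setdiff(need, colnames(annotation))
  if (length(miss))
    stop("annotation is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"SampleID" %in% colnames(phenotype))
    stop("phenotype is missing required column: SampleID")
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  if (anyDuplicated(annotation$ProbeID))
    stop("duplicated probe ids in annotation")
  if (anyDuplicated(phenotype$SampleID))
    stop("duplicated sample ids in phenotype")
  if (!setequal(rownames(beta), annotation$ProbeID))
    stop("probe ids differ between beta matrix and annotation; e.g. ",
         paste(utils::head(c(setdiff(rownames(beta), annotation$ProbeID),
                             setdiff(annotation$ProbeID, rownames(beta))), 5),
               collapse = ", "))
  if (!setequal(colnames(beta), phenotype$SampleID))
    stop("sample ids differ between beta matrix and phenotype; offenders: ",
         paste(utils::head(c(setdiff(colnames(beta), phenotype$SampleID),
                             setdiff(phenotype$SampleID, colnames(beta))), 5),
               collapse = ", "))
  annotation <- annotation[match(rownames(beta), annotation$ProbeID), ,
                           drop = FALSE]
  phenotype <- phenotype[match(colnames(beta), phenotype$SampleID), ,
                         drop = FALSE]
  rr <- GRanges(seqnames = annotation$Chr,
                ranges = IRanges(start = annotation$Position, width = 1L),
                gene = as.character(annotation$Gene),
                feature = as.character(annotation$Feature))
  names(rr) <- annotation$ProbeID
  se <- SummarizedExperiment(assays = list(beta = beta), rowRanges = rr,
                             colData = DataFrame(phenotype,
                                                 row.names = phenotype$SampleID))
  new("MethylationExperiment", se)
}

#' Accessors for MethylationExperiment
#'
#' \code{betaValues} returns the beta matrix; \code{mValues} its logit2
#' (M-value) transform via [betaToMvalue()]; \code{probeAnnotation} the
#' manifest-style annotation as a \linkS4class{DataFrame}.
#'
#' @param object a \linkS4class{MethylationExperiment}.
#' @param epsilon clipping constant passed to [betaToMvalue()].
#' @return matrix or DataFrame as described.
#' @name methylation-accessors
NULL

#' @rdname methylation-accessors
#' @export
setGeneric("betaValues", function(object) standardGeneric("betaValues"))

#' @rdname methylation-accessors
#' @export
setMethod("betaValues", "MethylationExperiment", function(object)
  SummarizedExperiment::assay(object, "beta"))

#' @rdname methylation-accessors
#' @export
setGeneric("mValues", function(object, epsilon = 1e-6)
  standardGeneric("mValues"))

#' @rdname methylation-accessors
#' @export
setMethod("mValues", "MethylationExperiment", function(object, epsilon = 1e-6)
  betaToMvalue(betaValues(object), epsilon = epsilon))

#' @rdname methylation-accessors
#' @export
setGeneric("probeAnnotation", function(object)
  standardGeneric("probeAnnotation"))

#' @rdname methylation-accessors
#' @export
setMethod("probeAnnotation", "MethylationExperiment", function(object) {
  rr <- rowRanges(object)
  DataFrame(ProbeID = names(rr),
            Chr = as.character(seqnames(rr)),
            Position = start(rr),
            Gene = S4Vectors::mcols(rr)$gene,
            Feature = S4Vectors::mcols(rr)$feature,
            row.names = names(rr))
})

setMethod("show", "MethylationExperiment", function(object) {
  cat("MethylationExperiment with", nrow(object), "probes and",
      ncol(object), "samples\n")
  b <- betaValues(object)
  cat(sprintf("beta range: [%.3f, %.3f]\n", min(b), max(b)))
  cat("chromosomes:",
      paste(utils::head(unique(as.character(seqnames(rowRanges(object)))), 8),
            collapse = ", "), "\n")
  cat("phenotype columns:",
      paste(utils::head(colnames(colData(object)), 10), collapse = ", "),
      if (ncol(colData(object)) > 10) "..." else "", "\n")
})

#' Accessors for simulation ground truth
#'
#' @param object a \linkS4class{GroundTruth}.
#' @return \code{spikedProbes}: ids of isolated spiked probes;
#'   \code{trueDeltaBeta}: named configured shifts for all spiked probes;
#'   \code{spikedRegions}: \linkS4class{GRanges} of spiked spans.
#' @name groundtruth-accessors
NULL

#' @rdname groundtruth-accessors
#' @export
setGeneric("spikedProbes", function(object) standardGeneric("spikedProbes"))

#' @rdname groundtruth-accessors
#' @export
setMethod("spikedProbes", "GroundTruth", function(object) object@spikedProbes)

#' @rdname groundtruth-accessors
#' @export
setGeneric("trueDeltaBeta", function(object) standardGeneric("trueDeltaBeta"))

#' @rdname groundtruth-accessors
#' @export
setMethod("trueDeltaBeta", "GroundTruth", function(object) object@trueDeltaBeta)

#' @rdname groundtruth-accessors
#' @export
setGeneric("spikedRegions", function(object) standardGeneric("spikedRegions"))

#' @rdname groundtruth-accessors
#' @export
setMethod("spikedRegions", "GroundTruth", function(object) object@spikedRegions)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@spikedProbes), "spiked probes,",
      length(object@spikedRegions), "spiked region(s)\n")
  if (length(object@trueDeltaBeta))
    cat(sprintf("beta-scale shifts: %s\n",
                paste(format(unique(object@trueDeltaBeta), digits = 3),
                      collapse = ", ")))
})

setMethod("show", "MediationResult", function(object) {
  cat("MediationResult —", object@mediator,
      if (object@binaryOutcome) "(logistic outcome)\n" else "(linear outcome)\n")
  cat(sprintf("  exposure -> mediator (a): %+.5f\n", object@pathA))
  cat(sprintf("  mediator -> outcome  (b): %+.5f\n", object@pathB))
  cat(sprintf("  indirect a*b: %+.5f  [%.5f, %.5f]  p = %.3f\n",
              object@indirectEffect, object@ciLow, object@ciHigh,
              object@pIndirect))
  cat(sprintf("  direct: %+.5f  total: %+.5f  (%d bootstraps, %d failed)\n",
              object@directEffect, object@totalEffect, object@nBoot,
              object@nFailed))
})
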