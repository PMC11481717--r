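#' Read the phenotype table
#'
#' Tab-separated, one row per participant; requires \code{SampleID} plus
#' the lifestyle, covariate and (if present) outcome columns documented in
#' [simulateParticipants()].
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenotype <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"SampleID" %in% colnames(ph))
    stop("phenotype file is missing required column: SampleID")
  if (anyDuplicated(ph$SampleID))
    stop("duplicated sample ids in phenotype: ",
         paste(unique(ph$SampleID[duplicated(ph$SampleID)]), collapse = ", "))
  ph
}

#' Read a beta-value matrix
#'
#' Tab-separated, probes in rows (first column = probe id), samples in
#' columns; every value must lie in [0, 1].
#'
#' @param path file path.
#' @return numeric matrix, probes x samples.
#' @export
readBetaMatrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  beta <- as.matrix(df)
  if (!is.numeric(beta)) stop("beta matrix contains non-numeric entries")
  bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0, 1] at probe '%s', sample '%s'",
                 rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  if (anyDuplicated(rownames(beta))) stop("duplicated probe ids")
  beta
}

#' Read a probe annotation table
#'
#' Comma-separated, Illumina-manifest style: \code{ProbeID}, \code{Chr},
#' \code{Position} (1-based), \code{Gene}, \code{Feature}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readAnnotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ProbeID", "Chr", "Position", "Gene", "Feature")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation file is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$ProbeID)) stop("duplicated probe ids in annotation")
  ann
}

#' Read a study bundle from disk
#'
#' Loads the three standard inputs and assembles a validated
#' \linkS4class{MethylationExperiment} (sample/probe ids cross-checked).
#'
#' @param dir directory containing \code{phenotype.tsv}, \code{beta.tsv}
#'   and \code{annotation.csv}.
#' @return a \linkS4class{MethylationExperiment}.
#' @export
readBundle <- function(dir) {
  MethylationExperiment(readBetaMatrix(file.path(dir, "beta.tsv")),
                        readAnnotation(file.path(dir, "annotation.csv")),
                        readPhenotype(file.path(dir, "phenotype.tsv")))
}

#' Write a simulated bundle to disk
#'
#' Writes \code{phenotype.tsv}, \code{beta.tsv}, \code{annotation.csv} and
#' \code{ground_truth.json} (spiked probes, spans and link coefficients).
#'
#' @param bundle result of [simulateLifemethBundle()].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- bundle$experiment
  utils::write.table(as.data.frame(colData(ex)),
                     file.path(dir, "phenotype.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  beta <- betaValues(ex)
  utils::write.table(data.frame(ProbeID = rownames(beta),
                                signif(beta, 6), check.names = FALSE),
                     file.path(dir, "beta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(as.data.frame(probeAnnotation(ex)),
                   file.path(dir, "annotation.csv"), row.names = FALSE)
  tr <- bundle$truth
  regions <- spikedRegions(tr)
  jsonlite::write_json(list(
    spikedProbes = spikedProbes(tr),
    trueDeltaBeta = as.list(trueDeltaBeta(tr)),
    spikedRegions = if (length(regions)) data.frame(
      Chr = as.character(seqnames(regions)),
      start = start(regions), end = end(regions),
      probeIds = vapply(S4Vectors::mcols(regions)$probeIds,
                        paste, "", collapse = ";")) else list(),
    outcomeCoefficients = as.list(tr@outcomeCoefficients)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write regions as a BED file
#'
#' BED6 with 0-based half-open intervals: \code{start} is the smallest
#' 1-based probe position minus one, \code{end} the largest. The name is
#' the region's annotated gene (or "NA"), the score
#' \code{floor(1000 * (1 - fwer))}, the strand ".". An empty result writes
#' a header-only file.
#'
#' @param dmrs a \linkS4class{DMRResults}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand", con)
  if (nrow(dmrs)) {
    score <- ifelse(is.na(dmrs$fwer), 0L,
                    as.integer(floor(1000 * (1 - dmrs$fwer))))
    nm <- ifelse(is.na(dmrs$gene) | dmrs$gene == "", "NA", dmrs$gene)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.", dmrs$Chr,
                       as.integer(dmrs$start) - 1L, as.integer(dmrs$end),
                       nm, score), con)
  }
  invisible(path)
}

# polynomial rolling hash of a deparsed object, for the metadata sidecar
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.writeResultTable <- function(x, path, seed = NA, config = NULL) {
  df <- as.data.frame(x)
  listCols <- vapply(df, is.list, TRUE)
  df[listCols] <- lapply(df[listCols], vapply, paste, "", collapse = ";")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    package = "lifemeth",
    version = as.character(utils::packageVersion("lifemeth")),
    seed = seed, configHash = .configHash(config), rows = nrow(df)),
    paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the analysis stages in order — lifestyle scoring, DMP
#' discovery, DMR discovery, outcome association of the top DMPs, mediation
#' through the top DMPs — writing one tab-separated table per stage (plus a
#' DMR BED file and a JSON metadata sidecar per table) to
#' \code{outDir}. Any stage failure aborts with a stage-named error.
#'
#' @param experiment a \linkS4class{MethylationExperiment} (e.g. from
#'   [readBundle()] or [simulateLifemethBundle()]).
#' @param outDir output directory.
#' @param model \code{"base"} or \code{"bmi"} for the EWAS stages.
#' @param cutoff,minProbes,maxGap,window,nPermutations DMR parameters
#'   ([runDmrEwas()]); \code{minProbes} below 3 is rejected, since a region
#'   is defined as 3 or more CpG sites.
#' @param nTopDmps how many top probes feed association and mediation.
#' @param nBoot mediation bootstrap replicates.
#' @param seed integer seed for the permutation and bootstrap stages.
#' @return invisibly, a list with the five stage results.
#' @export
runPipeline <- function(experiment, outDir, model = "base", cutoff = 0.01,
                        minProbes = 3L, maxGap = 500, window = 5L,
                        nPermutations = 500L, nTopDmps = 6L, nBoot = 1000L,
                        seed = 1L) {
  if (minProbes < 3)
    stop("minProbes must be >= 3: a region is defined as 3 or more CpG sites")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(model = model, cutoff = cutoff, minProbes = minProbes,
              maxGap = maxGap, window = window,
              nPermutations = nPermutations, nTopDmps = nTopDmps,
              nBoot = nBoot, seed = seed)
  stage <- function(name, expr) {
    message(sprintf("[lifemeth] stage %-10s n = %d, seed = %d", name,
                    ncol(experiment), seed))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  scores <- stage("score", scoreLifestyle(as.data.frame(colData(experiment))))
  .writeResultTable(scores, file.path(outDir, "lifestyle_scores.tsv"),
                    seed, cfg)
  dmps <- stage("ewas-dmp", runDmpEwas(experiment, model = model))
  md <- metadata(dmps)
  message(sprintf(
    "[lifemeth] empirical null: mu = %.4f sigma = %.4f; lambda %.3f -> %.3f",
    md$biasMu, md$inflationSigma, md$lambdaRaw, md$lambdaCorrected))
  .writeResultTable(dmps, file.path(outDir, "dmp_results.tsv"), seed, cfg)
  dmrs <- stage("ewas-dmr",
                runDmrEwas(experiment, model = model, cutoff = cutoff,
                           minProbes = minProbes, maxGap = maxGap,
                           window = window, nPermutations = nPermutations,
                           seed = seed))
  .writeResultTable(dmrs, file.path(outDir, "dmr_results.tsv"), seed, cfg)
  writeDmrBed(dmrs, file.path(outDir, "dmr_results.bed"))
  topIds <- utils::head(dmps$ProbeID, nTopDmps)
  assoc <- stage("associate",
                 associatePredictors(experiment, topIds, scores = scores))
  .writeResultTable(assoc, file.path(outDir, "association_results.tsv"),
                    seed, cfg)
  med <- stage("mediate",
               runMediation(experiment, topIds, nBoot = nBoot, seed = seed))
  .writeResultTable(med, file.path(outDir, "mediation_results.tsv"),
                    seed, cfg)
  invisible(list(scores = scores, dmps = dmps, dmrs = dmrs,
                 associations = assoc, mediation = med))
}
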