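#' Cluster probes along the genome
#'
#' Two consecutive probes (after sorting by chromosome and position) share a
#' cluster iff they sit on the same chromosome and at most \code{maxGap}
#' base pairs apart. Cluster ids are assigned in genome order and are stable
#' across runs.
#'
#' @param annotation probe annotation with columns \code{ProbeID},
#'   \code{Chr}, \code{Position}.
#' @param maxGap maximum intra-cluster gap in base pairs (default 500, the
#'   usual bump-hunting convention).
#' @return integer cluster id named by probe, in the input's row order.
#' @export
clusterProbes <- function(annotation, maxGap = 500) {
  annotation <- as.data.frame(annotation)
  if (anyDuplicated(annotation[c("Chr", "Position")]))
    stop("duplicated (chromosome, position) pairs in annotation")
  o <- order(annotation$Chr, annotation$Position)
  chr <- annotation$Chr[o]
  pos <- annotation$Position[o]
  newCluster <- c(TRUE, chr[-1] != chr[-length(chr)] |
                    diff(pos) > maxGap)
  id <- cumsum(newCluster)
  out <- integer(nrow(annotation))
  out[o] <- id
  names(out) <- annotation$ProbeID
  out
}

# truncated centered running mean along rows of a matrix, within cluster
# blocks; `index` rows must be sorted by (cluster, position)
.runningMeanByCluster <- function(x, clusters, window) {
  half <- (window - 1L) %/% 2L
  out <- x
  for (block in split(seq_along(clusters), clusters)) {
    L <- length(block)
    if (L < 3L || window == 1L) next
    xb <- x[block, , drop = FALSE]
    cs <- rbind(0, apply(xb, 2, cumsum))
    i <- seq_len(L)
    lo <- pmax(i - half, 1L)
    hi <- pmin(i + half, L)
    out[block, ] <- (cs[hi + 1L, , drop = FALSE] -
                       cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  out
}

#' Smooth per-probe effects within clusters
#'
#' Centered running mean of the beta-scale effects within each probe
#' cluster, with the window truncated at cluster edges. Clusters with fewer
#' than 3 probes pass through unsmoothed.
#'
#' @param effect numeric vector of per-probe effects, ordered by
#'   (chromosome, position).
#' @param clusters cluster ids from [clusterProbes()], same order.
#' @param window odd window size in probes (default 5); \code{window = 1}
#'   is the identity.
#' @return smoothed numeric vector, same length and order.
#' @export
smoothEffects <- function(effect, clusters, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  if (length(effect) != length(clusters))
    stop("effect and clusters must have the same length")
  drop(.runningMeanByCluster(cbind(effect), clusters, window))
}

#' Call candidate regions from smoothed effects
#'
#' Candidate differentially methylated regions are maximal runs of
#' consecutive probes of one cluster whose smoothed effect is uniformly
#' above \code{cutoff} or uniformly below \code{-cutoff}; runs with fewer
#' than \code{minProbes} probes are discarded. Per region, \code{area} is
#' the sum of absolute smoothed effects and \code{avgDeltaBeta} the mean of
#' the raw (unsmoothed) effects.
#'
#' @param smoothed,effect smoothed and raw per-probe beta-scale effects,
#'   ordered by (chromosome, position).
#' @param clusters cluster ids, same order.
#' @param annotation probe annotation in the same order.
#' @param cutoff beta-scale calling threshold (default 0.01, i.e. a 1.0%
#'   methylation difference).
#' @param minProbes minimum probes per region (default 3).
#' @return a \linkS4class{DMRResults} with \code{fwer} set to \code{NA}.
#' @export
findBumps <- function(smoothed, effect, clusters, annotation,
                      cutoff = 0.01, minProbes = 3L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (minProbes < 1) stop("minProbes must be >= 1")
  annotation <- as.data.frame(annotation)
  runs <- .bumpRuns(smoothed, clusters, cutoff, minProbes)
  if (!nrow(runs)) return(.emptyDmrResults())
  rows <- lapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$from[i]:runs$to[i]
    DataFrame(Chr = annotation$Chr[idx[1]],
              start = min(annotation$Position[idx]),
              end = max(annotation$Position[idx]),
              nProbes = length(idx),
              probeIds = IRanges::CharacterList(list(annotation$ProbeID[idx])),
              gene = annotation$Gene[idx[1]],
              area = sum(abs(smoothed[idx])),
              avgDeltaBeta = mean(effect[idx]),
              fwer = NA_real_)
  })
  new("DMRResults", do.call(rbind, rows))
}

.emptyDmrResults <- function()
  new("DMRResults", DataFrame(
    Chr = character(0), start = integer(0), end = integer(0),
    nProbes = integer(0), probeIds = IRanges::CharacterList(),
    gene = character(0), area = numeric(0), avgDeltaBeta = numeric(0),
    fwer = numeric(0)))

# run-length scan shared by candidate calling and the permutation null;
# returns data.frame(from, to) of qualifying runs
.bumpRuns <- function(smoothed, clusters, cutoff, minProbes) {
  state <- ifelse(smoothed > cutoff, 1L, ifelse(smoothed < -cutoff, -1L, 0L))
  # a run must stay within one cluster: encode (cluster, state) jointly
  key <- clusters * 3L + state
  r <- rle(key)
  to <- cumsum(r$lengths)
  from <- to - r$lengths + 1L
  keep <- (r$values %% 3L != 0L) & r$lengths >= minProbes
  data.frame(from = from[keep], to = to[keep])
}

# max area over qualifying runs (0 when none) — the permutation statistic
.maxBumpArea <- function(smoothed, clusters, cutoff, minProbes) {
  runs <- .bumpRuns(smoothed, clusters, cutoff, minProbes)
  if (!nrow(runs)) return(0)
  max(vapply(seq_len(nrow(runs)), function(i)
    sum(abs(smoothed[runs$from[i]:runs$to[i]])), numeric(1)))
}

# Frisch-Waugh residualization: exposure coefficients for many probes and
# many exposure vectors at once, covariates held fixed
.residualize <- function(x, covariates) {
  if (is.null(covariates)) return(as.matrix(x))
  qr.resid(qr(covariates), as.matrix(x))
}

.exposureEffects <- function(yResid, eResid) {
  # yResid: samples x probes, eResid: samples x B
  num <- crossprod(eResid, yResid)              # B x probes
  den <- colSums(eResid^2)
  num / den
}

#' Permutation familywise error rates for candidate regions
#'
#' Re-assigns the exposure labels at random (covariates held fixed), reruns
#' the full effect-smooth-call pipeline per permutation, and records the
#' maximum null region area. Each candidate's FWER is the add-one
#' permutation estimate \code{(1 + #\{null max area >= area\}) / (1 + B)}.
#'
#' @param betaMatrix probes x samples beta matrix, probes ordered by
#'   (chromosome, position).
#' @param exposure binary exposure vector.
#' @param covariates covariate matrix (samples x q) or \code{NULL}.
#' @param candidates \linkS4class{DMRResults} from the observed data.
#' @param clusters cluster ids in probe order.
#' @param nPermutations number of label permutations (default 500).
#' @param seed integer seed making the permutations reproducible.
#' @param cutoff,minProbes,window calling parameters; must match the
#'   observed-data call.
#' @return \code{candidates} with \code{fwer} filled in;
#'   \code{metadata()$nullMaxArea} holds the permutation null.
#' @export
assessFWER <- function(betaMatrix, exposure, covariates, candidates,
                       clusters, nPermutations = 500L, seed = 1L,
                       cutoff = 0.01, minProbes = 3L, window = 5L) {
  if (!nrow(candidates)) return(candidates)
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  set.seed(seed)
  n <- ncol(betaMatrix)
  perms <- vapply(seq_len(nPermutations), function(b) exposure[sample.int(n)],
                  numeric(n))
  yR <- .residualize(t(betaMatrix), covariates)
  eR <- .residualize(perms, covariates)
  eff <- .exposureEffects(yR, eR)               # B x probes
  smoothedNull <- .runningMeanByCluster(t(eff), clusters, window)
  nullMax <- vapply(seq_len(nPermutations), function(b)
    .maxBumpArea(smoothedNull[, b], clusters, cutoff, minProbes),
    numeric(1))
  fwer <- vapply(candidates$area, function(a)
    (1 + sum(nullMax >= a)) / (1 + nPermutations), numeric(1))
  out <- candidates
  out$fwer <- fwer
  metadata(out) <- c(metadata(candidates),
                     list(nullMaxArea = nullMax,
                          nPermutations = nPermutations, seed = seed))
  out
}

#' Epigenome-wide DMR analysis by bump hunting
#'
#' Computes per-probe beta-scale exposure effects (least squares with the
#' same covariate adjustment as the DMP stage, so the cutoff reads directly
#' as a methylation-fraction difference), clusters probes, smooths effects
#' within clusters, calls candidate regions of >= \code{minProbes} probes
#' beyond the cutoff, and attaches permutation familywise error rates.
#' Regions with FWER < 0.05 are the genome-wide significant calls.
#'
#' @param experiment a \linkS4class{MethylationExperiment}.
#' @param model \code{"base"} or \code{"bmi"} covariate set.
#' @param cutoff beta-scale calling cutoff (default 0.01).
#' @param minProbes minimum probes per region (default 3).
#' @param maxGap cluster gap in bp (default 500).
#' @param window smoothing window in probes (default 5, odd).
#' @param nPermutations label permutations for the FWER (default 500).
#' @param seed permutation seed.
#' @param exposure exposure column in \code{colData}.
#' @return a \linkS4class{DMRResults} sorted by FWER then area.
#' @export
runDmrEwas <- function(experiment, model = c("base", "bmi"), cutoff = 0.01,
                       minProbes = 3L, maxGap = 500, window = 5L,
                       nPermutations = 500L, seed = 1L, exposure = "CLI") {
  model <- match.arg(model)
  stopifnot(is(experiment, "MethylationExperiment"))
  ann <- as.data.frame(probeAnnotation(experiment))
  o <- order(ann$Chr, ann$Position)
  ann <- ann[o, ]
  beta <- betaValues(experiment)[o, , drop = FALSE]
  pheno <- as.data.frame(colData(experiment))
  design <- buildDesign(pheno, model = model, exposure = exposure)
  expo <- design[, 2]
  covs <- design[, -2, drop = FALSE]
  clusters <- clusterProbes(ann, maxGap = maxGap)
  eff <- drop(.exposureEffects(.residualize(t(beta), covs),
                               .residualize(cbind(expo), covs)))
  smoothed <- smoothEffects(eff, clusters, window = window)
  cand <- findBumps(smoothed, eff, clusters, ann, cutoff = cutoff,
                    minProbes = minProbes)
  cand <- assessFWER(beta, expo, covs, cand, clusters,
                     nPermutations = nPermutations, seed = seed,
                     cutoff = cutoff, minProbes = minProbes, window = window)
  if (nrow(cand)) cand <- cand[order(cand$fwer, -cand$area), ]
  metadata(cand) <- c(metadata(cand),
                      list(model = model, cutoff = cutoff,
                           minProbes = minProbes, maxGap = maxGap,
                           window = window, n = ncol(experiment)))
  new("DMRResults", cand)
}

setMethod("show", "DMRResults", function(object) {
  md <- metadata(object)
  cat(sprintf("DMRResults: %d candidate region(s)", nrow(object)))
  if (!is.null(md$nPermutations))
    cat(sprintf(", FWER from %d permutations", md$nPermutations))
  cat("\n")
  if (nrow(object)) {
    cat(sprintf("regions at FWER < 0.05: %d\n",
                sum(object$fwer < 0.05, na.rm = TRUE)))
    show(utils::head(as(object, "DFrame")[, setdiff(colnames(object),
                                                    "probeIds")], 5))
  }
})
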