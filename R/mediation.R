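#' Product-of-coefficients path estimates
#'
#' Three regressions decompose the exposure effect: (1) the total effect
#' from \code{outcome ~ exposure (+ covariates)}; (2) path a from
#' \code{mediator ~ exposure (+ covariates)} (linear); (3) path b and the
#' direct effect from \code{outcome ~ exposure + mediator (+ covariates)}.
#' A binary outcome is fitted by logistic regression, so b, direct and
#' total are then on the log-odds scale; in the all-linear case
#' total = direct + a*b holds exactly.
#'
#' @param exposure,mediator,outcome aligned numeric vectors; the exposure
#'   must vary.
#' @param covariates optional data.frame of adjustment covariates.
#' @param binaryOutcome logical; autodetected (outcome only 0/1) when
#'   \code{NULL}.
#' @return list with \code{pathA}, \code{pathB}, \code{directEffect},
#'   \code{totalEffect}, \code{indirectEffect}, \code{binaryOutcome}.
#' @export
estimatePaths <- function(exposure, mediator, outcome, covariates = NULL,
                          binaryOutcome = NULL) {
  if (stats::var(exposure) == 0) stop("exposure has zero variance")
  n <- length(exposure)
  if (length(mediator) != n || length(outcome) != n)
    stop("exposure, mediator and outcome must be aligned")
  if (is.null(binaryOutcome)) binaryOutcome <- all(outcome %in% 0:1)
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  dfA <- data.frame(mediator = mediator, exposure = exposure)
  dfOut <- data.frame(outcome = outcome, exposure = exposure,
                      mediator = mediator)
  dfTot <- data.frame(outcome = outcome, exposure = exposure)
  if (!is.null(cv)) {
    dfA <- cbind(dfA, cv); dfOut <- cbind(dfOut, cv)
    dfTot <- cbind(dfTot, cv)
  }
  aFit <- stats::lm(mediator ~ ., data = dfA)
  pathA <- unname(stats::coef(aFit)["exposure"])
  if (binaryOutcome) {
    oFit <- stats::glm(outcome ~ ., data = dfOut, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))
    tFit <- stats::glm(outcome ~ ., data = dfTot, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))
    if (!oFit$converged || !tFit$converged)
      stop("logistic outcome model did not converge")
  } else {
    oFit <- stats::lm(outcome ~ ., data = dfOut)
    tFit <- stats::lm(outcome ~ ., data = dfTot)
  }
  pathB <- unname(stats::coef(oFit)["mediator"])
  direct <- unname(stats::coef(oFit)["exposure"])
  total <- unname(stats::coef(tFit)["exposure"])
  list(pathA = pathA, pathB = pathB, directEffect = direct,
       totalEffect = total, indirectEffect = indirectEffect(pathA, pathB),
       binaryOutcome = binaryOutcome)
}

#' Indirect (mediated) effect
#'
#' The product-of-coefficients indirect effect a x b: the exposure-to-
#' mediator path times the exposure-adjusted mediator-to-outcome path.
#'
#' @param pathA,pathB finite path coefficients.
#' @return their product.
#' @examples
#' indirectEffect(-0.008, -0.28)   # 0.00224
#' @export
indirectEffect <- function(pathA, pathB) {
  if (!all(is.finite(pathA)) || !all(is.finite(pathB)))
    stop("path coefficients must be finite")
  pathA * pathB
}

#' Bootstrap mediation analysis
#'
#' Point estimates from [estimatePaths()] on the full data, then
#' participant-level resampling with replacement: the indirect effect
#' a x b is recomputed on each replicate, a percentile interval is taken at
#' levels alpha/2 and 1 - alpha/2, and a two-sided add-one bootstrap p
#' measures how often replicates cross zero. Replicates whose fits fail are
#' dropped and counted; more than 10\% failures aborts.
#'
#' @inheritParams estimatePaths
#' @param nBoot number of bootstrap replicates (>= 100; default 1000).
#' @param seed integer seed.
#' @param alpha interval level (default 0.05 for a 95\% CI).
#' @param mediatorName label for the result.
#' @return a \linkS4class{MediationResult}.
#' @export
bootstrapMediation <- function(exposure, mediator, outcome,
                               covariates = NULL, nBoot = 1000L, seed = 1L,
                               alpha = 0.05, binaryOutcome = NULL,
                               mediatorName = "mediator") {
  if (nBoot < 100) stop("nBoot must be >= 100")
  point <- estimatePaths(exposure, mediator, outcome, covariates,
                         binaryOutcome)
  n <- length(exposure)
  cv <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  set.seed(seed)
  ab <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      estimatePaths(exposure[idx], mediator[idx], outcome[idx],
                    if (is.null(cv)) NULL else cv[idx, , drop = FALSE],
                    binaryOutcome = point$binaryOutcome),
      error = function(e) NULL)
    if (!is.null(est)) ab[b] <- est$indirectEffect
  }
  failed <- sum(is.na(ab))
  if (failed > 0.1 * nBoot)
    stop(sprintf("bootstrap failed: %d of %d replicate fits unusable",
                 failed, nBoot))
  ab <- ab[!is.na(ab)]
  ci <- unname(stats::quantile(ab, c(alpha / 2, 1 - alpha / 2)))
  B <- length(ab)
  pInd <- min(1, 2 * min((1 + sum(ab <= 0)) / (B + 1),
                         (1 + sum(ab >= 0)) / (B + 1)))
  new("MediationResult", mediator = mediatorName,
      pathA = point$pathA, pathB = point$pathB,
      directEffect = point$directEffect,
      indirectEffect = point$indirectEffect,
      totalEffect = point$totalEffect,
      ciLow = ci[1], ciHigh = ci[2], pIndirect = pInd,
      nBoot = as.integer(nBoot), nFailed = as.integer(failed),
      seed = as.integer(seed), binaryOutcome = point$binaryOutcome)
}

#' Mediation of the lifestyle-T2DM association through methylation
#'
#' Runs [bootstrapMediation()] of the binary lifestyle index on T2DM
#' through each requested probe's beta values and through their mean beta
#' (the "mean of the top DMPs" mediator), returning one row per mediator:
#' |dmpIds| + 1 rows.
#'
#' @param experiment a \linkS4class{MethylationExperiment} with \code{CLI}
#'   and \code{T2DM} in \code{colData}.
#' @param dmpIds probe ids used as mediators.
#' @param covariates optional covariate data.frame.
#' @param nBoot,seed,alpha bootstrap settings.
#' @return \linkS4class{DFrame} with one row per
#'   \linkS4class{MediationResult}; the objects themselves are in
#'   \code{metadata()$results}.
#' @export
runMediation <- function(experiment, dmpIds, covariates = NULL,
                         nBoot = 1000L, seed = 1L, alpha = 0.05) {
  stopifnot(is(experiment, "MethylationExperiment"))
  pheno <- as.data.frame(colData(experiment))
  for (col in c("CLI", "T2DM"))
    if (!col %in% colnames(pheno))
      stop("phenotype is missing column: ", col)
  miss <- setdiff(dmpIds, rownames(experiment))
  if (length(miss))
    stop("probe id(s) not in methylation data: ",
         paste(miss, collapse = ", "))
  beta <- betaValues(experiment)
  mediators <- c(lapply(dmpIds, function(id) beta[id, ]),
                 list(colMeans(beta[dmpIds, , drop = FALSE])))
  names(mediators) <- c(dmpIds, "meanTopDMPs")
  results <- mapply(function(m, nm)
    bootstrapMediation(pheno$CLI, m, pheno$T2DM, covariates,
                       nBoot = nBoot, seed = seed, alpha = alpha,
                       mediatorName = nm),
    mediators, names(mediators), SIMPLIFY = FALSE)
  tab <- do.call(rbind, lapply(results, function(r)
    DataFrame(mediator = r@mediator, pathA = r@pathA, pathB = r@pathB,
              directEffect = r@directEffect,
              indirectEffect = r@indirectEffect,
              totalEffect = r@totalEffect, ciLow = r@ciLow,
              ciHigh = r@ciHigh, pIndirect = r@pIndirect,
              nBoot = r@nBoot, nFailed = r@nFailed)))
  metadata(tab) <- list(results = results, seed = seed, alpha = alpha)
  tab
}
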