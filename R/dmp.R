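#' Beta-value to M-value transform
#'
#' M = log2(beta / (1 - beta)), with beta clipped into
#' [epsilon, 1 - epsilon] first so the transform is finite at the
#' boundaries. Statistics are computed on M-values; effect sizes are
#' reported on the beta scale.
#'
#' @param beta numeric vector/matrix of methylation fractions in [0, 1].
#' @param epsilon clipping constant, in (0, 0.5).
#' @return M-values with the shape of \code{beta}.
#' @examples
#' betaToMvalue(c(0.5, 0.8))  # 0 and 2
#' @export
betaToMvalue <- function(beta, epsilon = 1e-6) {
  if (length(epsilon) != 1 || epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)")
  if (anyNA(beta) || any(beta < 0) || any(beta > 1))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Build the EWAS design matrix
#'
#' Intercept, the binary exposure (CLI index) and the adjustment covariates:
#' age, sex, study-site indicators, cell proportions, batch and
#' array-position indicators (one-hot, dropping the first level), optionally
#' BMI. Errors on rank deficiency, naming the collinear columns.
#'
#' @param phenotype participant table with an exposure column \code{CLI}
#'   plus the covariates above.
#' @param model \code{"base"} or \code{"bmi"} (additionally adjusts for
#'   BMI).
#' @param exposure name of the binary exposure column.
#' @return numeric design matrix, samples x coefficients, exposure in
#'   column 2.
#' @export
buildDesign <- function(phenotype, model = c("base", "bmi"),
                        exposure = "CLI") {
  model <- match.arg(model)
  if (!exposure %in% colnames(phenotype))
    stop("phenotype is missing exposure column: ", exposure)
  x <- phenotype[[exposure]]
  if (!all(x %in% 0:1)) stop("exposure must be binary 0/1")
  cellCols <- grep("^Cell_", colnames(phenotype), value = TRUE)
  # proportions sum to one, so one cell type is omitted as reference
  if (length(cellCols) > 1) cellCols <- cellCols[-1]
  covNames <- c("Age", "Sex", "Site", cellCols, "Batch", "ArrayPosition")
  if (model == "bmi") covNames <- c(covNames, "BMI")
  covNames <- intersect(covNames, colnames(phenotype))
  df <- data.frame(exposure = x, phenotype[covNames])
  X <- stats::model.matrix(~ ., data = df)
  colnames(X)[2] <- exposure
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]],
               collapse = ", "))
  X
}

#' Per-probe least-squares fits
#'
#' Ordinary least squares of every probe's M-values on a shared design
#' matrix, vectorized across probes. Returns the exposure coefficient, its
#' standard error, the residual variance and the residual degrees of
#' freedom.
#'
#' @param mMatrix numeric matrix, probes x samples.
#' @param design design matrix from [buildDesign()] (samples x
#'   coefficients).
#' @param coefIndex column of the design whose coefficient is of interest
#'   (default 2, the exposure).
#' @return list with \code{coef}, \code{se}, \code{sigma2} (per probe),
#'   \code{df} (scalar residual degrees of freedom) and \code{seUnit}
#'   (unscaled standard error sqrt[(X'X)^-1]_jj).
#' @export
fitProbeModels <- function(mMatrix, design, coefIndex = 2L) {
  mMatrix <- as.matrix(mMatrix)
  n <- ncol(mMatrix)
  if (nrow(design) != n)
    stop("design rows must match methylation samples")
  qx <- qr(design)
  if (qx$rank < ncol(design))
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]],
               collapse = ", "))
  df <- n - ncol(design)
  if (df < 1) stop("residual degrees of freedom must be >= 1")
  fit <- stats::lm.fit(design, t(mMatrix))
  cf <- fit$coefficients
  coefs <- if (is.matrix(cf)) cf[coefIndex, ] else cf[coefIndex]
  rss <- if (is.matrix(fit$residuals)) colSums(fit$residuals^2)
         else sum(fit$residuals^2)
  sigma2 <- rss / df
  xtxInv <- chol2inv(qr.R(qx))[coefIndex, coefIndex]
  seUnit <- sqrt(xtxInv)
  list(coef = unname(coefs), se = unname(seUnit * sqrt(sigma2)),
       sigma2 = unname(sigma2), df = df, seUnit = seUnit)
}

# Newton solve of trigamma(y) = x, vectorized (method-of-moments helper)
.trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of probe variances
#'
#' Shrinks per-probe residual variances toward a common prior by fitting a
#' scaled inverse-chi-square prior (d0, s0^2) to the observed variances by
#' method of moments on log variances, then forms posterior variances
#' s~^2 = (d0 s0^2 + df s^2) / (d0 + df) and moderated t statistics on
#' df + d0 degrees of freedom. With d0 = 0 the ordinary t is recovered; as
#' d0 grows all posterior variances approach s0^2 (if every variance is
#' identical, d0 is reported infinite and s~^2 = s0^2).
#'
#' @param sigma2 per-probe residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param coef per-probe coefficients.
#' @param seUnit unscaled standard error of the coefficient.
#' @param d0 optional fixed prior degrees of freedom (skips estimation).
#' @return list with \code{t} (moderated statistics), \code{dfTotal},
#'   \code{d0}, \code{s02} and \code{s2Post}.
#' @export
moderateStatistics <- function(sigma2, df, coef, seUnit, d0 = NULL) {
  ok <- sigma2 > 0
  if (is.null(d0)) {
    if (sum(ok) < 10)
      stop("need >= 10 probes with positive residual variance")
    z <- log(sigma2[ok])
    evar <- stats::var(z) - trigamma(df / 2)
    if (!is.finite(evar) || evar <= 1e-10) {
      d0 <- Inf
      s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
    } else {
      d0 <- 2 * .trigammaInverse(evar)
      s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    z <- log(sigma2[ok])
    s02 <- if (d0 > 0 && is.finite(d0))
      exp(mean(z) - digamma(df / 2) + log(df / 2) +
            digamma(d0 / 2) - log(d0 / 2))
    else exp(mean(z) - digamma(df / 2) + log(df / 2))
  }
  s2Post <- if (is.infinite(d0)) rep(s02, length(sigma2))
            else if (d0 == 0) sigma2
            else (d0 * s02 + df * sigma2) / (d0 + df)
  tmod <- coef / (seUnit * sqrt(s2Post))
  list(t = tmod, dfTotal = df + d0, d0 = d0, s02 = s02, s2Post = s2Post)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment: q_i = min over j with p_j >= p_i of
#' p_j * m / rank_j, clipped to [0, 1], returned in input order.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same length and order.
#' @export
adjustFDR <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

#' Beta-scale group difference per probe
#'
#' Mean beta in the high-risk group minus mean beta in the low-risk group —
#' the effect size reported alongside M-value statistics.
#'
#' @param betaMatrix probes x samples beta matrix.
#' @param cliIndex binary high-risk index per sample.
#' @return named numeric vector in [-1, 1].
#' @export
computeDeltaBeta <- function(betaMatrix, cliIndex) {
  if (length(cliIndex) != ncol(betaMatrix))
    stop("cliIndex length must match the number of samples")
  if (!all(cliIndex %in% 0:1)) stop("cliIndex must be binary 0/1")
  if (!any(cliIndex == 1) || !any(cliIndex == 0))
    stop("both exposure groups must be non-empty")
  rowMeans(betaMatrix[, cliIndex == 1, drop = FALSE]) -
    rowMeans(betaMatrix[, cliIndex == 0, drop = FALSE])
}

# genomic inflation factor: median chi-square ratio of z statistics
.genomicLambda <- function(z)
  stats::median(z^2) / stats::qchisq(0.5, df = 1)

# two-sided p from t without underflow, then matching z quantile
.tToZ <- function(tstat, df) {
  logp <- stats::pt(abs(tstat), df = df, lower.tail = FALSE, log.p = TRUE)
  sign(tstat) * stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
}

#' Epigenome-wide DMP analysis
#'
#' The full per-probe stage: M-value transform, per-probe least squares on
#' the exposure with covariate adjustment ([buildDesign()]),
#' empirical-Bayes variance moderation, conversion of moderated t to z,
#' empirical-null bias/inflation correction ([estimateEmpiricalNull()]),
#' Benjamini-Hochberg FDR and beta-scale effect sizes. Probes are returned
#' sorted by corrected p-value; an FDR below 0.05 is the genome-wide
#' significance convention.
#'
#' @param experiment a \linkS4class{MethylationExperiment} whose
#'   \code{colData} holds the exposure and covariates.
#' @param model \code{"base"} or \code{"bmi"}.
#' @param epsilon M-transform clipping constant.
#' @param exposure exposure column name in \code{colData}.
#' @return a \linkS4class{DMPResults}; \code{metadata()} holds \code{model},
#'   \code{n}, \code{biasMu}, \code{inflationSigma}, \code{nullProportion},
#'   \code{d0}, \code{s02}, \code{lambdaRaw}, \code{lambdaCorrected}.
#' @export
runDmpEwas <- function(experiment, model = c("base", "bmi"),
                       epsilon = 1e-6, exposure = "CLI") {
  model <- match.arg(model)
  stopifnot(is(experiment, "MethylationExperiment"))
  pheno <- as.data.frame(colData(experiment))
  design <- buildDesign(pheno, model = model, exposure = exposure)
  beta <- betaValues(experiment)
  m <- betaToMvalue(beta, epsilon = epsilon)
  fit <- fitProbeModels(m, design)
  mod <- moderateStatistics(fit$sigma2, fit$df, fit$coef, fit$seUnit)
  pRaw <- 2 * stats::pt(abs(mod$t), df = mod$dfTotal, lower.tail = FALSE)
  z <- .tToZ(mod$t, mod$dfTotal)
  nullFit <- estimateEmpiricalNull(z)
  zc <- (z - nullFit$mu) / nullFit$sigma
  pCorr <- 2 * stats::pnorm(abs(zc), lower.tail = FALSE)
  fdr <- adjustFDR(pCorr)
  deltaBeta <- computeDeltaBeta(beta, pheno[[exposure]])
  ann <- probeAnnotation(experiment)
  res <- DataFrame(ann[, c("ProbeID", "Chr", "Position", "Gene", "Feature")],
                   deltaBeta = unname(deltaBeta),
                   coefM = fit$coef,
                   tRaw = fit$coef / fit$se,
                   tModerated = mod$t,
                   z = z, zCorrected = zc,
                   pRaw = pRaw, pCorrected = pCorr, fdr = fdr)
  res <- res[order(res$pCorrected, res$pRaw), ]
  out <- new("DMPResults", res)
  metadata(out) <- list(model = model, n = ncol(experiment),
                        exposure = exposure, epsilon = epsilon,
                        df = fit$df, dfTotal = mod$dfTotal,
                        d0 = mod$d0, s02 = mod$s02,
                        biasMu = nullFit$mu,
                        inflationSigma = nullFit$sigma,
                        nullProportion = nullFit$nullProportion,
                        emConverged = nullFit$converged,
                        lambdaRaw = .genomicLambda(z),
                        lambdaCorrected = .genomicLambda(zc))
  out
}

setMethod("show", "DMPResults", function(object) {
  md <- metadata(object)
  cat(sprintf("DMPResults: %d probes, model '%s', n = %d\n",
              nrow(object), md$model, md$n))
  cat(sprintf("empirical null: mu = %.4f, sigma = %.4f (lambda %.3f -> %.3f)\n",
              md$biasMu, md$inflationSigma, md$lambdaRaw,
              md$lambdaCorrected))
  cat(sprintf("probes at FDR < 0.05: %d\n", sum(object$fdr < 0.05)))
  show(utils::head(as(object, "DFrame"), 5))
})
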