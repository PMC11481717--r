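#' Rank-based inverse-normal transform
#'
#' Blom-offset transform \code{qnorm((rank - 3/8) / (n + 1/4))} with average
#' ranks for ties; strictly monotone in the input ranks and invariant to
#' monotone rescaling of the input.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return transformed vector, approximately standard normal.
#' @export
inverseNormalTransform <- function(values) {
  if (anyNA(values)) stop("missing values are not supported")
  if (length(unique(values)) < 2)
    stop("inverse-normal transform undefined: all values identical")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(values) + 1 / 4))
}

.waldRow <- function(predictor, outcome, model, est, se, df = Inf,
                     logScale = FALSE) {
  q <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  stat <- est / se
  p <- if (is.finite(df)) 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  lo <- est - q * se; hi <- est + q * se
  if (logScale) { est <- exp(est); lo <- exp(lo); hi <- exp(hi) }
  DataFrame(predictor = predictor, outcome = outcome, model = model,
            estimate = est, ciLow = lo, ciHigh = hi, p = p)
}

#' Logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-8, at most 100 iterations) of
#' \code{outcome ~ predictor + covariates}. Reports the odds ratio per unit
#' predictor with a Wald 95\% interval and p-value. Grouped data are
#' supported through \code{weights} (counts per row). Perfect separation is
#' detected and raised as an error, as is non-convergence.
#'
#' @param outcome binary 0/1 vector (or success proportion with
#'   \code{weights}).
#' @param predictor numeric predictor.
#' @param covariates optional data.frame/matrix of adjustment covariates.
#' @param weights optional case weights (counts for grouped data).
#' @param predictorName,outcomeName,model labels for the result row.
#' @return one-row \linkS4class{AssociationResults} (estimate = odds
#'   ratio).
#' @examples
#' # 2x2 table a=20 b=80 / c=10 d=90: OR = (20*90)/(80*10) = 2.25
#' fitLogistic(outcome = c(1, 0, 1, 0), predictor = c(1, 1, 0, 0),
#'             weights = c(20, 80, 10, 90))
#' @export
fitLogistic <- function(outcome, predictor, covariates = NULL,
                        weights = NULL, predictorName = "predictor",
                        outcomeName = "T2DM", model = "base") {
  df <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  if (length(unique(stats::na.omit(outcome[outcome %in% 0:1]))) < 2 &&
      is.null(weights))
    stop("both outcome classes must be present")
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               weights = weights,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop("logistic regression did not converge after ", fit$iter,
         " iterations")
  co <- summary(fit)$coefficients
  if (abs(co[".x", "Estimate"]) > 15)
    stop("perfect separation: predictor coefficient diverges")
  out <- .waldRow(predictorName, outcomeName, model,
                  co[".x", "Estimate"], co[".x", "Std. Error"],
                  logScale = TRUE)
  new("AssociationResults", out)
}

#' Linear regression of a continuous outcome on one predictor
#'
#' Ordinary least squares of \code{outcome ~ predictor + covariates};
#' reports the predictor slope with a t-based 95\% interval and two-sided
#' p-value.
#'
#' @inheritParams fitLogistic
#' @param outcome continuous outcome vector.
#' @return one-row \linkS4class{AssociationResults} (estimate = slope in
#'   outcome units per predictor unit).
#' @export
fitLinear <- function(outcome, predictor, covariates = NULL,
                      predictorName = "predictor", outcomeName = "FBG",
                      model = "base") {
  df <- data.frame(.y = outcome, .x = predictor)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("collinear covariates: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  co <- summary(fit)$coefficients
  out <- .waldRow(predictorName, outcomeName, model, co[".x", "Estimate"],
                  co[".x", "Std. Error"], df = fit$df.residual)
  new("AssociationResults", out)
}

#' Associate top probes and lifestyle scores with clinical outcomes
#'
#' For every predictor (each requested probe's methylation, the binary CLI
#' and the four component scores) x outcome (T2DM logistic; FBG and HbA1c
#' linear) x model (base: unadjusted; adjusted: age, sex, study site, BMI),
#' fits the corresponding regression. Methylation predictors are scaled
#' "per 1%" (beta x 100) or rank inverse-normal transformed; lifestyle
#' scores enter untransformed.
#'
#' @param experiment a \linkS4class{MethylationExperiment} whose
#'   \code{colData} holds \code{T2DM}, \code{FBG}, \code{HbA1c}, \code{CLI}
#'   and the adjustment covariates.
#' @param dmpIds probe ids to use as methylation predictors.
#' @param scores optional [scoreLifestyle()] table supplying the component
#'   scores (matched on \code{SampleID}).
#' @param scale \code{"per_1pct"} (estimates read per 1\% methylation) or
#'   \code{"inverse_normal"}.
#' @return an \linkS4class{AssociationResults} with
#'   |predictors| x 3 outcomes x 2 models rows.
#' @export
associatePredictors <- function(experiment, dmpIds, scores = NULL,
                                scale = c("per_1pct", "inverse_normal")) {
  scale <- match.arg(scale)
  stopifnot(is(experiment, "MethylationExperiment"))
  pheno <- as.data.frame(colData(experiment))
  for (col in c("T2DM", "FBG", "HbA1c", "CLI"))
    if (!col %in% colnames(pheno))
      stop("phenotype is missing outcome/exposure column: ", col)
  miss <- setdiff(dmpIds, rownames(experiment))
  if (length(miss))
    stop("probe id(s) not in methylation data: ",
         paste(miss, collapse = ", "))
  beta <- betaValues(experiment)
  predictors <- lapply(dmpIds, function(id) {
    b <- beta[id, ]
    if (scale == "per_1pct") 100 * b else inverseNormalTransform(b)
  })
  names(predictors) <- dmpIds
  predictors$CLI <- pheno$CLI
  if (!is.null(scores)) {
    scores <- scores[match(pheno$SampleID, scores$SampleID), ]
    predictors$Smoking <- scores$smokingPoints
    predictors$Alcohol <- scores$alcoholPoints
    predictors$PhysicalActivity <- scores$activityPoints
    predictors$DQI <- scores$dietPoints
  }
  adjCovs <- data.frame(Age = pheno$Age, Sex = pheno$Sex, Site = pheno$Site,
                        BMI = pheno$BMI)
  rows <- list()
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    for (modelName in c("base", "adjusted")) {
      cv <- if (modelName == "adjusted") adjCovs else NULL
      rows[[length(rows) + 1]] <-
        fitLogistic(pheno$T2DM, x, cv, predictorName = nm,
                    outcomeName = "T2DM", model = modelName)
      rows[[length(rows) + 1]] <-
        fitLinear(pheno$FBG, x, cv, predictorName = nm,
                  outcomeName = "FBG", model = modelName)
      rows[[length(rows) + 1]] <-
        fitLinear(pheno$HbA1c, x, cv, predictorName = nm,
                  outcomeName = "HbA1c", model = modelName)
    }
  }
  out <- new("AssociationResults", do.call(rbind, lapply(rows, as, "DFrame")))
  metadata(out) <- list(scale = scale, n = nrow(pheno), dmpIds = dmpIds)
  out
}

#' Associate a region's mean methylation with the outcomes
#'
#' Runs the same outcome models on the mean beta across a region's probes —
#' the region-level follow-up of a DMR call.
#'
#' @param experiment a \linkS4class{MethylationExperiment}.
#' @param probeIds character vector of the region's probes.
#' @param scale as in [associatePredictors()].
#' @param name predictor label.
#' @return an \linkS4class{AssociationResults} with 6 rows.
#' @export
associateRegion <- function(experiment, probeIds,
                            scale = c("per_1pct", "inverse_normal"),
                            name = "DMR") {
  scale <- match.arg(scale)
  miss <- setdiff(probeIds, rownames(experiment))
  if (length(miss))
    stop("probe id(s) not in methylation data: ",
         paste(miss, collapse = ", "))
  pheno <- as.data.frame(colData(experiment))
  b <- colMeans(betaValues(experiment)[probeIds, , drop = FALSE])
  x <- if (scale == "per_1pct") 100 * b else inverseNormalTransform(b)
  adjCovs <- data.frame(Age = pheno$Age, Sex = pheno$Sex, Site = pheno$Site,
                        BMI = pheno$BMI)
  rows <- list()
  for (modelName in c("base", "adjusted")) {
    cv <- if (modelName == "adjusted") adjCovs else NULL
    rows[[length(rows) + 1]] <- fitLogistic(pheno$T2DM, x, cv,
                                            predictorName = name,
                                            outcomeName = "T2DM",
                                            model = modelName)
    rows[[length(rows) + 1]] <- fitLinear(pheno$FBG, x, cv,
                                          predictorName = name,
                                          outcomeName = "FBG",
                                          model = modelName)
    rows[[length(rows) + 1]] <- fitLinear(pheno$HbA1c, x, cv,
                                          predictorName = name,
                                          outcomeName = "HbA1c",
                                          model = modelName)
  }
  new("AssociationResults", do.call(rbind, lapply(rows, as, "DFrame")))
}

setMethod("show", "AssociationResults", function(object) {
  cat(sprintf("AssociationResults: %d rows (predictor x outcome x model)\n",
              nrow(object)))
  show(as(object, "DFrame"))
})
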