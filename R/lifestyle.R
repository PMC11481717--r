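#' Score smoking status
#'
#' Current smokers score 0, former smokers 1, never smokers 2 — the lowest
#' points go to the highest-risk category.
#'
#' @param status character vector with values \code{"current"},
#'   \code{"former"} or \code{"never"}.
#' @return integer points in \{0, 1, 2\}.
#' @export
scoreSmoking <- function(status) {
  status <- as.character(status)
  pts <- c(current = 0L, former = 1L, never = 2L)[status]
  if (anyNA(pts))
    stop("unknown smoking category: ",
         paste(unique(status[is.na(pts)]), collapse = ", "))
  unname(pts)
}

#' Score alcohol intake
#'
#' Sex-specific optimal-intake cut-offs: at most 1 unit/day for women and 2
#' for men (1 unit = 10 g alcohol). Abstainers (never drinkers, or zero
#' units) score 2, optimal drinkers 1, suboptimal drinkers 0.
#'
#' @param unitsPerDay non-negative daily alcohol units.
#' @param sex \code{"male"} or \code{"female"}.
#' @param neverDrinker logical; lifetime abstainer flag (implies zero units).
#' @return integer points in \{0, 1, 2\}.
#' @export
scoreAlcohol <- function(unitsPerDay, sex, neverDrinker = FALSE) {
  if (any(is.na(unitsPerDay)) || any(unitsPerDay < 0))
    stop("unitsPerDay must be non-negative")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  n <- max(length(unitsPerDay), length(sex), length(neverDrinker))
  unitsPerDay <- rep_len(unitsPerDay, n)
  sex <- rep_len(sex, n)
  neverDrinker <- rep_len(neverDrinker, n)
  if (any(neverDrinker & unitsPerDay > 0))
    stop("neverDrinker participants must report zero units")
  cutoff <- ifelse(sex == "male", 2, 1)
  ifelse(neverDrinker | unitsPerDay == 0, 2L,
         ifelse(unitsPerDay <= cutoff, 1L, 0L))
}

#' Categorize physical activity
#'
#' IPAQ-style three-level categorization from a weekly activity record.
#' "High": vigorous activity on >= 3 days with >= 1500 MET-min/week, or any
#' combination of walking/moderate/vigorous on >= 7 day-slots with >= 3000
#' MET-min/week. "Moderate": >= 3 days of vigorous activity of >= 20
#' min/day, or >= 5 days of moderate activity and/or walking of >= 30
#' min/day, or >= 5 combination day-slots reaching >= 600 MET-min/week.
#' Everything else is "low". High is checked before moderate. Day-slots sum
#' the per-type day counts, so a day with two activity types counts twice —
#' the usual IPAQ scoring convention.
#'
#' @param vigorousDays,vigorousMin days/week and minutes/day of vigorous
#'   activity.
#' @param moderateDays,moderateMin days/week and minutes/day of moderate
#'   activity.
#' @param walkingDays,walkingMin days/week and minutes/day of walking.
#' @param totalMetMin total physical activity in MET-minutes/week.
#' @return character vector: \code{"high"}, \code{"moderate"} or
#'   \code{"low"}.
#' @export
categorizeActivity <- function(vigorousDays, vigorousMin = 0,
                               moderateDays = 0, moderateMin = 0,
                               walkingDays = 0, walkingMin = 0,
                               totalMetMin = 0) {
  n <- max(lengths(list(vigorousDays, vigorousMin, moderateDays, moderateMin,
                        walkingDays, walkingMin, totalMetMin)))
  vd <- rep_len(vigorousDays, n); vm <- rep_len(vigorousMin, n)
  md <- rep_len(moderateDays, n); mm <- rep_len(moderateMin, n)
  wd <- rep_len(walkingDays, n); wm <- rep_len(walkingMin, n)
  tot <- rep_len(totalMetMin, n)
  if (any(c(vd, md, wd) < 0) || any(c(vd, md, wd) > 7))
    stop("activity days must lie in [0, 7]")
  if (any(c(vm, mm, wm, tot) < 0))
    stop("minutes and MET-minutes must be non-negative")
  slots <- vd + md + wd
  days30 <- md * (mm >= 30) + wd * (wm >= 30)
  high <- (vd >= 3 & tot >= 1500) | (slots >= 7 & tot >= 3000)
  moderate <- (vd >= 3 & vm >= 20) | (days30 >= 5) |
    (slots >= 5 & tot >= 600)
  ifelse(high, "high", ifelse(moderate, "moderate", "low"))
}

#' Score physical-activity level
#'
#' @param category \code{"low"}, \code{"moderate"} or \code{"high"}.
#' @return integer points 0/1/2.
#' @export
scoreActivity <- function(category) {
  category <- as.character(category)
  pts <- c(low = 0L, moderate = 1L, high = 2L)[category]
  if (anyNA(pts))
    stop("unknown activity category: ",
         paste(unique(category[is.na(pts)]), collapse = ", "))
  unname(pts)
}

#' Score diet quality
#'
#' The Diet Quality Index-International (0-100 points) is cut at fixed
#' thirds of its range: scores in [0, 33.33] earn 0 points, (33.33, 66.66]
#' earn 1 and (66.66, 100] earn 2.
#'
#' @param dqi numeric DQI-I score(s) in [0, 100].
#' @return integer points 0/1/2.
#' @export
scoreDiet <- function(dqi) {
  if (any(is.na(dqi)) || any(dqi < 0) || any(dqi > 100))
    stop("dqi must lie in [0, 100]")
  ifelse(dqi <= 33.33, 0L, ifelse(dqi <= 66.66, 1L, 2L))
}

#' Compute the comprehensive lifestyle index
#'
#' The comprehensive lifestyle index (CLI) is the unweighted sum of the four
#' component points (each 0/1/2), giving a total on 0-8. Totals of 4 or less
#' indicate a high-risk lifestyle (binary index 1); totals above 4 are low
#' risk (index 0).
#'
#' @param smokingPoints,alcoholPoints,activityPoints,dietPoints component
#'   points, each in \{0, 1, 2\} (vectors recycle to a common length).
#' @return data.frame with columns \code{smokingPoints},
#'   \code{alcoholPoints}, \code{activityPoints}, \code{dietPoints},
#'   \code{total}, \code{riskLevel} ("high"/"low") and binary \code{index}.
#' @examples
#' computeCLI(2, 2, 0, 0)  # total 4 sits on the high-risk boundary
#' @export
computeCLI <- function(smokingPoints, alcoholPoints, activityPoints,
                       dietPoints) {
  comp <- list(smokingPoints = smokingPoints, alcoholPoints = alcoholPoints,
               activityPoints = activityPoints, dietPoints = dietPoints)
  for (nm in names(comp))
    if (any(is.na(comp[[nm]])) || !all(comp[[nm]] %in% 0:2))
      stop(nm, " must be 0, 1 or 2")
  n <- max(lengths(comp))
  comp <- lapply(comp, function(x) as.integer(rep_len(x, n)))
  total <- comp$smokingPoints + comp$alcoholPoints + comp$activityPoints +
    comp$dietPoints
  data.frame(comp, total = total,
             riskLevel = ifelse(total <= 4L, "high", "low"),
             index = as.integer(total <= 4L))
}

#' Score a phenotype table
#'
#' Applies the four component scorers and [computeCLI()] to a participant
#' table (the schema produced by [simulateParticipants()] /
#' [readPhenotype()]), rejecting rows with missing lifestyle values.
#'
#' @param phenotype data.frame with columns \code{SampleID},
#'   \code{Smoking}, \code{AlcoholUnitsPerDay}, \code{NeverDrinker},
#'   \code{Sex}, the activity-record columns used by
#'   [categorizeActivity()] and \code{DQI}.
#' @return data.frame: \code{SampleID}, component points, \code{total},
#'   \code{riskLevel}, \code{index}.
#' @export
scoreLifestyle <- function(phenotype) {
  need <- c("SampleID", "Smoking", "AlcoholUnitsPerDay", "NeverDrinker",
            "Sex", "VigorousDays", "VigorousMin", "ModerateDays",
            "ModerateMin", "WalkingDays", "WalkingMin", "TotalMetMin", "DQI")
  miss <- setdiff(need, colnames(phenotype))
  if (length(miss))
    stop("phenotype is missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(phenotype[need]))
    stop("missing lifestyle values are not supported; complete cases only")
  act <- categorizeActivity(phenotype$VigorousDays, phenotype$VigorousMin,
                            phenotype$ModerateDays, phenotype$ModerateMin,
                            phenotype$WalkingDays, phenotype$WalkingMin,
                            phenotype$TotalMetMin)
  out <- computeCLI(scoreSmoking(phenotype$Smoking),
                    scoreAlcohol(phenotype$AlcoholUnitsPerDay, phenotype$Sex,
                                 phenotype$NeverDrinker),
                    scoreActivity(act),
                    scoreDiet(phenotype$DQI))
  cbind(SampleID = phenotype$SampleID, out)
}

#' Correlation matrix of the index and its components
#'
#' Pairwise Pearson correlations (with two-sided p-values) between the CLI
#' total, the four component scores and BMI, as used to inspect which
#' components drive index variation. Zero-variance columns yield \code{NA}
#' correlations and a warning naming the column.
#'
#' @param scoreTable data.frame/matrix of numeric columns, >= 3 rows, no
#'   missing values; typically the output of [scoreLifestyle()] joined with
#'   BMI.
#' @return list with matrices \code{r} (unit diagonal) and \code{p}.
#' @export
correlateComponents <- function(scoreTable) {
  x <- as.matrix(scoreTable)
  if (!is.numeric(x)) stop("scoreTable columns must all be numeric")
  if (nrow(x) < 3) stop("at least 3 rows are required")
  if (anyNA(x)) stop("missing values are not supported")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s), correlations undefined: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  k <- ncol(x); n <- nrow(x)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_; r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(r = r, p = p)
}
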