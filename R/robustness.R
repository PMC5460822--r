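## Coefficient-of-variation robustness protocol: per-subject CVs across
## configurations, aggregated over the cohort.

#' Coefficient of variation, in percent
#'
#' The ratio between the standard deviation and the absolute mean of a
#' series, times 100. The sample (n - 1) standard deviation is the
#' default; the population flavour is available because the series here
#' are short (3 or 4 values) and the choice matters.
#'
#' @param values Numeric vector of length >= 2.
#' @param sdType "sample" (n - 1, default) or "population" (n).
#' @param tol Means with absolute value below \code{tol} are rejected
#'   (the ratio is undefined at zero mean).
#' @return A single non-negative percentage.
#' @examples
#' coefficientOfVariation(c(1, 2, 3))  # 50
#' @export
coefficientOfVariation <- function(values,
                                   sdType = c("sample", "population"),
                                   tol = 1e-12) {
  sdType <- match.arg(sdType)
  if (length(values) < 2L)
    stop("coefficient of variation needs at least 2 values")
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite and non-missing")
  m <- mean(values)
  if (abs(m) <= tol)
    stop("coefficient of variation undefined: mean is (near) zero")
  s <- sd(values)
  if (sdType == "population")
    s <- s * sqrt((length(values) - 1) / length(values))
  100 * s / abs(m)
}

## Internal: CV without the input ceremony, for the experiment drivers.
.cv <- function(values, sdType) {
  coefficientOfVariation(values, sdType = sdType)
}

## Shared aggregation engine. `within` names the column whose values are
## pooled inside each CV series; `across` the column defining the table's
## groupings.
.cvExperiment <- function(features, within, across, sdType, experiment) {
  stopifnot(is.data.frame(features))
  need <- c("subject", "matrixSize", "sliceThickness", "nLevels",
            .featureNames)
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  features$spatial <- sprintf("m%d_st%gmm", features$matrixSize,
                              features$sliceThickness)
  subjects <- sort(unique(features$subject))
  groups <- sort(unique(features[[across]]))
  seriesVals <- sort(unique(features[[within]]))
  if (length(seriesVals) < 2L)
    stop(sprintf("need >= 2 distinct '%s' values to form a CV series",
                 within))

  ## completeness: every subject x grouping x series cell must exist once
  missing <- character(0)
  for (sub in subjects) for (g in groups) for (sv in seriesVals) {
    hit <- features$subject == sub & features[[across]] == g &
      features[[within]] == sv
    if (sum(hit) != 1L)
      missing <- c(missing, sprintf("%s / %s / %s", sub, g, sv))
  }
  if (length(missing))
    stop("incomplete feature table; missing or duplicated cells: ",
         paste(missing, collapse = "; "))

  mu <- matrix(NA_real_, length(.featureNames), length(groups),
               dimnames = list(.featureNames, as.character(groups)))
  sg <- mu
  for (f in .featureNames) {
    for (gi in seq_along(groups)) {
      cvs <- vapply(subjects, function(sub) {
        sel <- features$subject == sub & features[[across]] == groups[gi]
        block <- features[sel, ]
        block <- block[order(block[[within]]), ]
        .cv(block[[f]], sdType)
      }, numeric(1))
      mu[f, gi] <- mean(cvs)
      sg[f, gi] <- if (length(cvs) > 1L) sd(cvs) else 0
    }
  }
  new("RobustnessTable", meanCV = mu, sdCV = sg, experiment = experiment,
      nSubjects = length(subjects), threshold = 10)
}

#' Robustness under dynamic-range changes
#'
#' For each feature, subject and spatial configuration, the coefficient
#' of variation over the grey-level counts present in the table (16, 32
#' and 64 by default); then the mean and standard deviation of those CVs
#' across subjects. One table column per spatial configuration (4 by
#' default).
#'
#' @param features Cohort feature table from
#'   \code{\link{cohortFeatureTable}}; must contain every
#'   (subject, spatial, dynamic range) cell exactly once.
#' @param sdType Standard-deviation flavour for the CV, see
#'   \code{\link{coefficientOfVariation}}.
#' @return A \linkS4class{RobustnessTable}, features x spatial
#'   configurations.
#' @export
cvAcrossDynamicRange <- function(features, sdType = "sample") {
  .cvExperiment(features, within = "nLevels", across = "spatial",
                sdType = sdType, experiment = "dynamic-range")
}

#' Robustness under spatial-resolution changes
#'
#' For each feature, subject and dynamic range, the coefficient of
#' variation over the spatial configurations present in the table (the 4
#' matrix-size x slice-thickness combinations by default); then the mean
#' and standard deviation across subjects. One table column per dynamic
#' range (3 by default).
#'
#' @inheritParams cvAcrossDynamicRange
#' @return A \linkS4class{RobustnessTable}, features x dynamic ranges.
#' @export
cvAcrossResolution <- function(features, sdType = "sample") {
  .cvExperiment(features, within = "spatial", across = "nLevels",
                sdType = sdType, experiment = "spatial-resolution")
}

#' Apply (or change) the robustness threshold
#'
#' A cell is robust when its mean CV is strictly below the threshold;
#' a feature is robust overall when all its cells are.
#'
#' @param table A \linkS4class{RobustnessTable}.
#' @param threshold Percent; default 10.
#' @return The table with the threshold set; query the flags with
#'   \code{\link{robustFlags}} and \code{\link{overallRobust}}.
#' @examples
#' showMethods("robustFlags")
#' @export
classifyRobust <- function(table, threshold = 10) {
  stopifnot(is(table, "RobustnessTable"))
  table@threshold <- as.numeric(threshold)
  validObject(table)
  table
}

#' Normalize one subject's feature profiles to their per-feature maximum
#'
#' Divides each feature column by its maximum across the subject's
#' configurations, so every profile peaks at exactly 1; useful for
#' plotting configuration dependence of features with very different
#' scales on one axis. Features whose maximum is (near) zero are left
#' unnormalized and reported with a message.
#'
#' @param features One subject's rows of the cohort feature table.
#' @param tol Maxima below \code{tol} in absolute value are skipped.
#' @return The table with feature columns rescaled.
#' @export
normalizeProfiles <- function(features, tol = 1e-12) {
  stopifnot(is.data.frame(features), nrow(features) > 0L)
  for (f in intersect(.featureNames, names(features))) {
    mx <- max(features[[f]])
    if (!is.finite(mx) || abs(mx) <= tol) {
      message(sprintf("feature %s skipped: maximum is (near) zero", f))
      next
    }
    features[[f]] <- features[[f]] / mx
  }
  features
}

#' Write a RobustnessTable as CSV
#'
#' One row per feature (canonical order), one "mean (SD)" display column
#' per grouping, machine-readable mean/SD/robust columns alongside, and a
#' final overall-robust column.
#'
#' @param table A \linkS4class{RobustnessTable}.
#' @param path Output CSV path.
#' @return Invisibly, the data.frame written.
#' @export
writeRobustnessCSV <- function(table, path) {
  stopifnot(is(table, "RobustnessTable"))
  mc <- table@meanCV
  sc <- table@sdCV
  fl <- robustFlags(table)
  df <- data.frame(feature = rownames(mc), stringsAsFactors = FALSE)
  for (g in colnames(mc)) {
    df[[paste0(g, "_display")]] <- sprintf("%.2f (%.2f)", mc[, g], sc[, g])
    df[[paste0(g, "_mean_cv")]] <- mc[, g]
    df[[paste0(g, "_sd_cv")]] <- sc[, g]
    df[[paste0(g, "_robust")]] <- fl[, g]
  }
  df$overall_robust <- overallRobust(table)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
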