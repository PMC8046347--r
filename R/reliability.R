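#' Intraclass correlation ICC(1,1) from a subjects x sessions matrix
#'
#' One-way random-effects, single-rater, absolute-agreement ICC
#' (Shrout & Fleiss type 1,1; McGraw & Wong type 1):
#' \code{ICC = (BMS - WMS) / (BMS + (k - 1) WMS)} from the one-way ANOVA
#' mean squares.  Missing cells are handled by the unbalanced one-way ANOVA
#' over all available observations, with k replaced by
#' \code{k0 = (N - sum(k_i^2) / N) / (n - 1)}.  The 95\% confidence interval
#' is the exact F-based interval: with \code{F = BMS / WMS},
#' lower \code{(F/Fu - 1)/(F/Fu + k0 - 1)} and upper
#' \code{(F*Fl - 1)/(F*Fl + k0 - 1)} where Fu, Fl are the appropriate
#' F quantiles on (n-1, N-n) and (N-n, n-1) degrees of freedom.
#'
#' @param series numeric matrix, rows = subjects, columns = sessions; NA
#'   cells allowed.
#' @param alpha CI significance level (default 0.05).
#' @return List: \code{icc}, \code{ci} (length 2), \code{bms}, \code{wms},
#'   \code{k0}, \code{nSubjects}, \code{nObs}.
#' @export
icc11 <- function(series, alpha = 0.05) {
  m <- as.matrix(series)
  ki <- rowSums(!is.na(m))
  if (any(ki == 0L)) {
    warning(sum(ki == 0L), " subject(s) without observations dropped")
    m <- m[ki > 0L, , drop = FALSE]
    ki <- ki[ki > 0L]
  }
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 subjects with observations")
  N <- sum(ki)
  if (N <= n) stop("need replicate sessions to estimate within-subject variance")
  mi <- rowMeans(m, na.rm = TRUE)
  grand <- sum(m, na.rm = TRUE) / N
  bss <- sum(ki * (mi - grand)^2)
  wss <- sum((m - mi)^2, na.rm = TRUE)
  bms <- bss / (n - 1)
  wms <- wss / (N - n)
  k0 <- (N - sum(ki^2) / N) / (n - 1)
  if (wms == 0) {
    return(list(icc = 1, ci = c(if (bms > 0) 1 else NA_real_, 1), bms = bms,
                wms = wms, k0 = k0, nSubjects = n, nObs = N))
  }
  icc <- (bms - wms) / (bms + (k0 - 1) * wms)
  f <- bms / wms
  fl <- f / stats::qf(1 - alpha / 2, n - 1, N - n)
  fu <- f * stats::qf(1 - alpha / 2, N - n, n - 1)
  ci <- c((fl - 1) / (fl + k0 - 1), (fu - 1) / (fu + k0 - 1))
  list(icc = icc, ci = ci, bms = bms, wms = wms, k0 = k0,
       nSubjects = n, nObs = N)
}

#' Standard error of measurement from sample SD and ICC
#'
#' \code{SEM = SD * sqrt(1 - ICC)}, where SD is the standard deviation of
#' the sample scores (all observations pooled over subjects and sessions).
#' Negative ICC estimates are clamped to 0 inside the formula, with a
#' warning.
#'
#' @param sd pooled SD of the sample scores (ms).
#' @param icc intraclass correlation.
#' @return SEM in the units of \code{sd}.
#' @export
semFromSdIcc <- function(sd, icc) {
  if (sd < 0) stop("sd must be >= 0")
  if (icc > 1) stop("icc must be <= 1")
  if (icc < 0) {
    warning("negative ICC clamped to 0 in the SEM formula")
    icc <- 0
  }
  sd * sqrt(1 - icc)
}

#' Minimum detectable difference
#'
#' \code{MD = SEM * sqrt(2) * 1.96}: the smallest within-individual change
#' distinguishable from measurement error with 95\% confidence (also called
#' the minimum detectable change, MDC).
#'
#' @param sem standard error of measurement (ms).
#' @return MD in the units of \code{sem}.
#' @export
minimumDetectableDifference <- function(sem) {
  if (any(sem < 0)) stop("sem must be >= 0")
  sem * sqrt(2) * 1.96
}

#' Minimum detectable difference as a percentage of the mean
#' @param md minimum detectable difference (ms).
#' @param mean global mean of the measure (ms), must be > 0.
#' @return \code{100 * md / mean}.
#' @export
mdPercent <- function(md, mean) {
  if (mean <= 0) stop("mean must be > 0")
  100 * md / mean
}

#' Confidence intervals for SEM and MD propagated from the ICC interval
#'
#' \code{SEM CI = (sd * sqrt(1 - icc_high), sd * sqrt(1 - icc_low))} and
#' \code{MD CI = SEM CI * sqrt(2) * 1.96}.  ICC bounds above 1 are clamped.
#'
#' @param sd pooled SD of sample scores.
#' @param iccCi length-2 ICC confidence bounds (low, high).
#' @return List with \code{semCi} and \code{mdCi}.
#' @export
semMdConfidenceIntervals <- function(sd, iccCi) {
  lo <- sd * sqrt(max(0, 1 - iccCi[2]))
  hi <- sd * sqrt(max(0, 1 - iccCi[1]))
  semCi <- c(lo, hi)
  list(semCi = semCi, mdCi = semCi * sqrt(2) * 1.96)
}

#' Within-subject coefficient of variation with chi-square CI
#'
#' Per subject, the SD across that subject's sessions divided by the
#' subject mean; the reported CV is 100 times the root-mean-square of these
#' per-subject CVs.  The 95\% CI treats the squared CV as a pooled
#' within-subject variance on \code{sum(k_i - 1)} degrees of freedom:
#' \code{CV * sqrt(df / qchisq(1 -/+ alpha/2, df))}.
#'
#' @param series subjects x sessions matrix (all values must be > 0).
#' @param alpha CI level (default 0.05).
#' @return List: \code{cv} (percent), \code{ci}, \code{df},
#'   \code{nSubjects}.
#' @export
coefficientOfVariation <- function(series, alpha = 0.05) {
  m <- as.matrix(series)
  if (any(m[!is.na(m)] <= 0)) stop("CV requires strictly positive values")
  ki <- rowSums(!is.na(m))
  if (any(ki < 2L)) {
    warning(sum(ki < 2L), " subject(s) with < 2 sessions excluded from CV")
    m <- m[ki >= 2L, , drop = FALSE]
    ki <- ki[ki >= 2L]
  }
  if (!nrow(m)) stop("no subject has 2 or more sessions")
  cvi <- apply(m, 1L, function(v) stats::sd(v, na.rm = TRUE) /
                 mean(v, na.rm = TRUE))
  cv <- 100 * sqrt(mean(cvi^2))
  df <- sum(ki - 1L)
  ci <- cv * sqrt(df / stats::qchisq(c(1 - alpha / 2, alpha / 2), df))
  list(cv = cv, ci = ci, df = df, nSubjects = nrow(m))
}

#' Bland-Altman agreement against a reference session
#'
#' For each follow-up session versus the reference: paired differences on
#' the subjects present in both, mean difference, limits of agreement
#' (mean difference +/- 1.96 SD of the differences) and a formal linear-bias
#' test (OLS regression of the difference on the pair mean; slope p-value).
#' Slope p-values across comparisons can be adjusted with
#' \code{\link{fdrAdjust}}.
#'
#' @param series subjects x sessions matrix.
#' @param referenceSession column index of the reference (default 1).
#' @param fdr append Benjamini-Hochberg adjusted slope p-values.
#' @return List: \code{results} (one row per comparison: n, meanDiff,
#'   loaLower, loaUpper, slope, slopeP, slopePAdj, insufficient) and
#'   \code{pairs} (per-comparison data for plotting: mean, diff).
#' @export
blandAltman <- function(series, referenceSession = 1L, fdr = TRUE) {
  m <- as.matrix(series)
  if (referenceSession < 1L || referenceSession > ncol(m))
    stop("reference session not present")
  others <- setdiff(seq_len(ncol(m)), referenceSession)
  rows <- list(); pairs <- list()
  for (j in others) {
    ok <- !is.na(m[, referenceSession]) & !is.na(m[, j])
    d <- m[ok, j] - m[ok, referenceSession]
    mu <- (m[ok, j] + m[ok, referenceSession]) / 2
    n <- sum(ok)
    if (n < 3L) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0(referenceSession, " vs ", j), n = n,
        meanDiff = NA_real_, loaLower = NA_real_, loaUpper = NA_real_,
        slope = NA_real_, slopeP = NA_real_, insufficient = TRUE)
      pairs[[length(pairs) + 1L]] <- data.frame(mean = mu, diff = d)
      next
    }
    sdd <- stats::sd(d)
    slope <- NA_real_; slopeP <- NA_real_
    if (stats::var(mu) > 0) {
      fit <- stats::lm(d ~ mu)
      cf <- summary(fit)$coefficients
      slope <- cf["mu", "Estimate"]; slopeP <- cf["mu", "Pr(>|t|)"]
    } else if (sdd == 0) {
      slope <- 0; slopeP <- 1
    }
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste0(referenceSession, " vs ", j), n = n,
      meanDiff = mean(d), loaLower = mean(d) - 1.96 * sdd,
      loaUpper = mean(d) + 1.96 * sdd, slope = slope, slopeP = slopeP,
      insufficient = FALSE)
    pairs[[length(pairs) + 1L]] <- data.frame(mean = mu, diff = d)
  }
  res <- do.call(rbind, rows)
  if (fdr) {
    res$slopePAdj <- NA_real_
    ok <- !is.na(res$slopeP)
    if (any(ok)) res$slopePAdj[ok] <- fdrAdjust(res$slopeP[ok])
  }
  names(pairs) <- res$comparison
  list(results = res, pairs = pairs)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone non-decreasing in rank.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdrAdjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Pairwise Pearson correlation between sessions
#'
#' Pairwise-complete Pearson r for every session pair; cells with fewer
#' than 3 common subjects are set to NA.
#'
#' @param series subjects x sessions matrix.
#' @return Symmetric session x session correlation matrix (diagonal NA).
#' @export
correlationMatrix <- function(series) {
  m <- as.matrix(series)
  ns <- ncol(m)
  out <- matrix(NA_real_, ns, ns,
                dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) >= 3L)
      out[i, j] <- out[j, i] <- stats::cor(m[ok, i], m[ok, j])
  }
  out
}

#' Session correlation table with two measures in the two triangles
#'
#' Mirrors the customary presentation: the upper triangle holds the first
#' measure (e.g. whole-disc T2), the lower triangle the second
#' (e.g. nuclear T2).
#'
#' @param upperSeries,lowerSeries subjects x sessions matrices.
#' @return session x session matrix.
#' @export
sessionCorrelationTable <- function(upperSeries, lowerSeries) {
  up <- correlationMatrix(upperSeries)
  lo <- correlationMatrix(lowerSeries)
  out <- up
  out[lower.tri(out)] <- lo[lower.tri(lo)]
  out
}

#' Classify an ICC estimate
#'
#' Conventional bands: below 0.40 poor, 0.40 to below 0.60 moderate,
#' 0.60 to below 0.75 good, 0.75 and above excellent.
#'
#' @param icc numeric (vectorised).
#' @return Character vector of labels.
#' @export
classifyIcc <- function(icc) {
  if (any(!is.finite(icc))) stop("icc must be finite")
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' One reliability-table row for a measurement series
#'
#' Computes the full metric chain for a subjects x sessions series: global
#' mean and pooled SD of all observations, ICC(1,1) with CI, SEM with CI,
#' MD with CI, MD\%, CV with CI and the ICC classification.  The internal
#' identities \code{MD = SEM * sqrt(2) * 1.96} and
#' \code{MD\% = 100 * MD / mean} hold exactly by construction.
#'
#' @param series subjects x sessions matrix.
#' @param name measure name.
#' @return One-row data.frame.
#' @export
reliabilityMetrics <- function(series, name = "measure") {
  m <- as.matrix(series)
  vals <- m[!is.na(m)]
  mu <- mean(vals); sd <- stats::sd(vals)
  ic <- icc11(m)
  sem <- semFromSdIcc(sd, min(ic$icc, 1))
  md <- minimumDetectableDifference(sem)
  ci <- semMdConfidenceIntervals(sd, ic$ci)
  cv <- coefficientOfVariation(m)
  data.frame(
    measure = name, globalMean = mu, sd = sd,
    icc = ic$icc, iccLow = ic$ci[1], iccHigh = ic$ci[2],
    sem = sem, semLow = ci$semCi[1], semHigh = ci$semCi[2],
    md = md, mdLow = ci$mdCi[1], mdHigh = ci$mdCi[2],
    mdPct = mdPercent(md, mu),
    cv = cv$cv, cvLow = cv$ci[1], cvHigh = cv$ci[2],
    classification = classifyIcc(ic$icc),
    nSubjects = ic$nSubjects, nObs = ic$nObs)
}

#' Reliability table over many measurement series
#'
#' One row per series.  When \code{unitSeries} (rows = individual discs,
#' i.e. subject-level units) and \code{unitGrades} are supplied,
#' grade-stratified rows are appended: the discs of each degeneration grade
#' are analysed as their own series.
#'
#' @param seriesList named list of subjects x sessions matrices (typically
#'   per-level rows plus an averaged-levels "AvLx" row computed on
#'   per-subject level-averaged values).
#' @param unitSeries optional units x sessions matrix for grade
#'   stratification.
#' @param unitGrades optional per-unit grade labels (same row order).
#' @param gradePrefix label prefix for stratified rows.
#' @return data.frame, one row per measure (and per grade stratum).
#' @export
reliabilityTable <- function(seriesList, unitSeries = NULL,
                             unitGrades = NULL, gradePrefix = "grade ") {
  rows <- lapply(names(seriesList), function(nm)
    reliabilityMetrics(seriesList[[nm]], nm))
  if (!is.null(unitSeries) && !is.null(unitGrades)) {
    for (g in sort(unique(unitGrades))) {
      sub <- unitSeries[unitGrades == g, , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        reliabilityMetrics(sub, paste0(gradePrefix, g))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
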