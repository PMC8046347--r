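test_that("ICC(1,1) handles perfect agreement and absent subject variance", {
  m <- rbind(c(10, 10, 10), c(20, 20, 20), c(30, 30, 30))
  expect_equal(icc11(m)$icc, 1)

  m2 <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)  # identical rows
  expect_lte(icc11(m2)$icc, 0)
})

test_that("ICC(1,1) equals the from-scratch one-way ANOVA oracle", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(3:10, 1); k <- sample(2:8, 1)
    m <- simSeries(n, k, 100, stats::runif(1, 0, 10), stats::runif(1, 0.5, 5))
    if (i %% 2 == 0) m[sample(length(m), ceiling(length(m) / 6))] <- NA
    if (any(rowSums(!is.na(m)) == 0)) next
    expect_equal(icc11(m)$icc, iccOracle(m), tolerance = 1e-12)
  }
})

test_that("ICC confidence intervals cover the true value at nominal rate", {
  set.seed(4)
  hits <- 0; reps <- 300
  for (i in seq_len(reps)) {
    m <- simSeries(12, 9, 100, sqrt(0.8 / 0.2), 1)   # true ICC 0.8
    ci <- icc11(m)$ci
    if (ci[1] <= 0.8 && 0.8 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / reps, 0.91)
  expect_lt(hits / reps, 0.99)
})

test_that("SEM, MD and MD% reproduce the published worked-example rows", {
  # nuclear L5/S1: mean 120.1, SD 36.4, ICC 0.88
  sem <- semFromSdIcc(36.4, 0.88)
  expect_equal(sem, 12.609, tolerance = 1e-3)
  md <- minimumDetectableDifference(sem)
  expect_equal(md, 35.0, tolerance = 0.05 / 35)
  expect_equal(mdPercent(md, 120.1), 29.1, tolerance = 0.05 / 29.1)
  # anterior annulus L4/5: mean 89.2, SD 9.3, ICC 0.35
  sem2 <- semFromSdIcc(9.3, 0.35)
  expect_equal(sem2, 7.498, tolerance = 1e-3)
  expect_equal(minimumDetectableDifference(sem2), 20.78, tolerance = 1e-3)
  expect_equal(mdPercent(20.78, 89.2), 23.3, tolerance = 0.01)

  expect_equal(semFromSdIcc(10, 1), 0)
  expect_warning(s <- semFromSdIcc(10, -0.2), "clamped")
  expect_equal(s, 10)
  expect_error(semFromSdIcc(-1, 0.5), "sd")
  expect_equal(minimumDetectableDifference(0), 0)
  expect_error(mdPercent(10, 0), "mean")
})

test_that("SEM/MD intervals propagate from the ICC interval", {
  ci <- semMdConfidenceIntervals(13.4, c(0.95, 1.00))
  # printed bounds (0.9-2.9) lie inside the propagated interval
  expect_lte(ci$semCi[1], 0.9)
  expect_gte(ci$semCi[2], 2.9)
  expect_equal(ci$semCi[2], 13.4 * sqrt(0.05), tolerance = 1e-12)
  expect_equal(ci$mdCi, ci$semCi * sqrt(2) * 1.96)

  z <- semMdConfidenceIntervals(10, c(0.7, 0.7))
  expect_equal(diff(z$semCi), 0)
})

test_that("within-subject CV matches hand computation and recovers truth", {
  m <- rbind(c(100, 100, 100), c(50, 50, 50))
  expect_equal(coefficientOfVariation(m)$cv, 0)

  m2 <- rbind(c(90, 100, 110), c(45, 50, 55))
  byHand <- 100 * sqrt(mean(c(stats::sd(c(90, 100, 110)) / 100,
                              stats::sd(c(45, 50, 55)) / 50)^2))
  expect_equal(coefficientOfVariation(m2)$cv, byHand, tolerance = 1e-12)

  set.seed(8)
  base <- stats::rnorm(500, 100, 10)
  m3 <- vapply(1:9, function(j) base * (1 + stats::rnorm(500, 0, 0.03)),
               numeric(500))
  cv <- coefficientOfVariation(m3)
  expect_equal(cv$cv, 3.0, tolerance = 0.1 / 3)
  expect_true(cv$ci[1] < cv$cv && cv$cv < cv$ci[2])

  expect_error(coefficientOfVariation(rbind(c(1, -2), c(3, 4))), "positive")
})

test_that("Bland-Altman limits of agreement behave as normal theory predicts", {
  m <- cbind(a = c(10, 20, 30, 40), b = c(10, 20, 30, 40))
  ba <- blandAltman(m)
  expect_equal(ba$results$meanDiff, 0)
  expect_equal(ba$results$loaLower, 0)
  expect_equal(ba$results$loaUpper, 0)

  set.seed(14)
  m2 <- cbind(stats::rnorm(500, 100, 10), 0)
  m2[, 2] <- m2[, 1] + stats::rnorm(500)
  ba2 <- blandAltman(m2)$results
  expect_equal(ba2$loaLower, -1.96, tolerance = 0.15)
  expect_equal(ba2$loaUpper, 1.96, tolerance = 0.15)
  d <- m2[, 2] - m2[, 1]
  inside <- mean(d > ba2$loaLower & d < ba2$loaUpper)
  expect_gt(inside, 0.93); expect_lt(inside, 0.97)

  # proportional bias is detected in > 80% of n = 12 replicates
  set.seed(15)
  hits <- 0
  for (i in 1:200) {
    a <- stats::rnorm(12, 100, 15)
    b <- a + 0.1 * a + stats::rnorm(12, 0, 0.8)
    p <- blandAltman(cbind(a, b))$results$slopeP
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.8)

  # fewer than 3 complete pairs is flagged, not fatal
  m3 <- cbind(c(1, 2, NA, NA), c(1, NA, 3, 4))
  expect_true(blandAltman(m3)$results$insufficient)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(fdrAdjust(0.03), 0.03)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(c(0.001, 0.8)), c(0.002, 0.8))
  expect_error(fdrAdjust(c(0.1, 1.2)), "0, 1")
  set.seed(2)
  p <- stats::runif(10)
  expect_equal(fdrAdjust(p), bhOracle(p), tolerance = 1e-15)
})

test_that("session correlations respect affine invariance and layout", {
  a <- c(10, 12, 14, 16, 18)
  m <- cbind(s1 = a, s2 = a, s3 = 2 * a + 3)
  cm <- correlationMatrix(m)
  expect_equal(cm[1, 2], 1)
  expect_equal(cm[1, 3], 1)
  expect_true(is.na(cm[1, 1]))

  set.seed(19)
  m2 <- simSeries(60, 9, 100, sqrt(0.95), sqrt(0.05))  # ICC 0.95
  cm2 <- correlationMatrix(m2)
  expect_equal(mean(cm2[upper.tri(cm2)]), 0.95, tolerance = 0.03)

  tab <- sessionCorrelationTable(m, m2[1:5, 1:3])
  expect_equal(tab[1, 2], 1)                      # upper = first measure
  expect_equal(tab[2, 1], correlationMatrix(m2[1:5, 1:3])[2, 1])
})

test_that("ICC classification uses the conventional bands", {
  expect_identical(classifyIcc(c(0.88, 0.39, 0.40, 0.59, 0.60, 0.74, 0.75)),
                   c("excellent", "poor", "moderate", "moderate", "good",
                     "good", "excellent"))
})

test_that("reliability table rows satisfy the metric identities", {
  set.seed(23)
  series <- list(
    "whole L4/5" = simSeries(12, 9, 97, 16, 2.7),
    "nuclear L5/S1" = simSeries(12, 9, 120, 34, 12))
  tab <- reliabilityTable(series)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$md, tab$sem * sqrt(2) * 1.96)
  expect_equal(tab$mdPct, 100 * tab$md / tab$globalMean)
  expect_equal(tab$sem, tab$sd * sqrt(1 - pmin(tab$icc, 1)))
  expect_identical(tab$classification, classifyIcc(tab$icc))

  # grade stratification: a single stratum equals the unstratified row
  units <- simSeries(10, 5, 100, 10, 2)
  t1 <- reliabilityTable(list(all = units))
  t2 <- reliabilityTable(list(all = units), unitSeries = units,
                         unitGrades = rep(2, 10))
  expect_equal(t2[2, -1], t1[1, -1], ignore_attr = TRUE)
})

test_that("averaging exchangeable levels lowers the CV", {
  set.seed(27)
  better <- 0
  for (i in 1:60) {
    subj <- stats::rnorm(12, 100, 12)
    levels <- lapply(1:5, function(l)
      vapply(1:9, function(j) subj + stats::rnorm(12, 0, 2.5), numeric(12)))
    cvs <- vapply(levels, function(m) coefficientOfVariation(m)$cv, numeric(1))
    avg <- Reduce(`+`, levels) / 5
    if (coefficientOfVariation(avg)$cv <= min(cvs)) better <- better + 1
  }
  expect_gt(better / 60, 0.9)
})

test_that("the dropout pattern perturbs ICC within its CI width", {
  set.seed(35)
  for (i in 1:20) {
    m <- simSeries(12, 9, 100, 13.3, 1.9)
    full <- icc11(m)
    dropped <- icc11(applyDropout(m, c(12, 12, 12, 12, 11, 10, 10, 8, 8)))
    expect_lt(abs(full$icc - dropped$icc), diff(full$ci) / 2)
  }
})
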