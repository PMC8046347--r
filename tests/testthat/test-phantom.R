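test_that("noise-free forward model matches the closed form S0 exp(-TE/T2)", {
  spec <- noiselessSpec(discS0 = 1000,
                        regionT2 = matrix(100, 6, 5))
  r <- renderEchoStack(spec)
  discPix <- which(r$truth@tissueLabels[, , 1] == 3L)
  img1 <- r$stack@data[, , 1, 1]
  expect_equal(unique(round(img1[discPix], 6)),
               round(1000 * exp(-0.109), 6))
  # every echo, every tissue
  for (e in c(1, 8, 16)) {
    img <- r$stack@data[, , 1, e]
    te <- spec@echoTimes[e]
    expect_equal(img[discPix],
                 rep(1000 * exp(-te / 100), length(discPix)))
    bonePix <- which(r$truth@tissueLabels[, , 1] == 1L)
    expect_equal(img[bonePix],
                 rep(spec@boneS0 * exp(-te / spec@boneT2), length(bonePix)))
  }
})

test_that("noiseless rendering inverts exactly through the T2 fit", {
  spec <- noiselessSpec()
  r <- renderEchoStack(spec)
  mm <- regionMeanSignals(r$stack,
                          r$truth@discMasks * 10L + r$truth@regionLabels)
  fits <- fitRegionT2(mm, groupBy = c("slice", "region"))
  tru <- r$truth@regionTable
  key <- match(fits$region, tru$disc * 10 + tru$region)
  expect_true(all(abs(fits$t2 - tru$trueT2[key]) / tru$trueT2[key] < 1e-6))
})

test_that("Rician background magnitude has mean sigma*sqrt(pi/2)", {
  spec <- phantomSpec(noiseSigma = 20, seed = 101L, nSlices = 2L)
  r <- renderEchoStack(spec)
  bg <- r$stack@data[, , , 1][r$truth@tissueLabels == 0L]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), 20 * sqrt(pi / 2), tolerance = 0.02)
})

test_that("first-echo SNR in the disc matches the requested noise level", {
  spec <- phantomSpec(noiseSigma = 7, seed = 7L, nSlices = 2L,
                      regionT2 = matrix(100, 6, 5))
  r <- renderEchoStack(spec)
  disc <- r$stack@data[, , , 1][r$truth@tissueLabels == 3L]
  snr <- mean(disc) / 7
  expect_equal(snr, 400 * exp(-10.9 / 100) / 7, tolerance = 0.05)
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- phantomSpec(seed = 33L, nSlices = 1L)
  a <- renderEchoStack(spec)
  b <- renderEchoStack(spec)
  expect_identical(a$stack@data, b$stack@data)
  spec2 <- spec; spec2@seed <- 34L
  expect_false(identical(renderEchoStack(spec2)$stack@data, a$stack@data))
})

test_that("truth masks align pixel-for-pixel with the rendered stack", {
  spec <- noiselessSpec()
  r <- renderEchoStack(spec)
  e2 <- r$stack@data[, , 1, 2]
  expect_true(all(e2[r$truth@discMasks[, , 1] > 0] > 300))
  expect_true(all(e2[r$truth@tissueLabels[, , 1] == 0L] == 0))
  # region labels partition each disc mask
  expect_identical(r$truth@regionLabels > 0, r$truth@discMasks > 0)
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantomSpec(echoTimes = c(10, 5, 20)), "increasing")
  expect_error(phantomSpec(regionT2 = c(90, 100, -5, 100, 80)), "T2")
  expect_error(phantomSpec(discHalfWidth = 25), "margin")
  expect_error(
    renderEchoStack(phantomSpec(discTilt = c(40, -40, 40, -40, 40, -40),
                                gridHeight = 300)),
    "overlap|grid")
})

test_that("longitudinal truth follows mu + b_i + w_ij with dropout", {
  st <- studySpec(seed = 5L)
  ds <- generateLongitudinalDataset(st, phantomSpec(), render = FALSE)
  expect_equal(as.integer(table(ds$meta$session)),
               c(12L, 12L, 12L, 12L, 11L, 10L, 10L, 8L, 8L))
  # no returns after dropout
  expect_true(all(diff(colSums(!is.na(ds$offsets))) <= 0))

  # varW = 0: all sessions of a subject identical; ICC on truth = 1
  st0 <- studySpec(withinSD = 0, seed = 6L)
  ds0 <- generateLongitudinalDataset(st0, phantomSpec(), render = FALSE)
  expect_true(all(apply(ds0$offsets, 1,
                        function(v) diff(range(v, na.rm = TRUE)) == 0)))
  tr <- ds0$truth[ds0$truth$disc == 2 & ds0$truth$region == 3, ]
  m <- tapply(tr$trueT2, list(tr$subject, tr$session), mean)
  expect_equal(icc11(m)$icc, 1)
})

test_that("truth-table ICC recovers varB/(varB+varW) at large n", {
  st <- studySpec(nSubjects = 200L, nSessions = 9L,
                  dropout = rep(200L, 9L), betweenSD = 3, withinSD = 1,
                  seed = 77L)
  expect_equal(trueICC(st), 0.9)
  ds <- generateLongitudinalDataset(st, phantomSpec(), render = FALSE)
  expect_equal(icc11(ds$offsets)$icc, 0.90, tolerance = 0.025)
})
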