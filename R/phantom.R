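#' Construct a synthetic spine phantom specification
#'
#' Builds a \linkS4class{PhantomSpec} with defaults calibrated for the
#' segmentation thresholds used throughout the package (see the class
#' documentation).  Subregion T2 defaults follow published lumbar values:
#' high in the nucleus (130 ms) and lower in the annulus (81--106 ms), which
#' places whole-disc T2 near 100 ms.  The 16 default echo times are
#' 10.9, 21.8, ..., 174.4 ms.
#'
#' @param gridHeight,gridWidth image size in pixels; the default height is
#'   derived from the spine geometry.
#' @param nSlices number of sagittal slices (default 6).
#' @param echoTimes echo times in ms.
#' @param nDiscs number of discs (default 6, T12/L1 ... L5/S1).
#' @param discLabels level labels, cephalad to caudad.
#' @param vertebraHeight vertebral body height(s), pixels; recycled to
#'   \code{nDiscs + 1}.
#' @param vertebraWidth,discHalfWidth spine and disc lens widths, pixels.
#' @param discTilt per-disc tilt in degrees (recycled).
#' @param discHeight,endplateThickness gap geometry, pixels.
#' @param regionT2 length-5 vector or \code{nDiscs x 5} matrix of subregion
#'   T2 in ms (anterior annulus ... posterior annulus).
#' @param discS0,boneT2,boneS0,endplateT2,endplateS0 tissue signal model.
#' @param noiseSigma,noiseModel noise level (signal units) and model.
#' @param pixelSpacing in-plane spacing in mm (default 0.781).
#' @param jitter SD of a random perturbation applied to disc tilt (degrees),
#'   disc half-width (pixels, rounded), vertebral heights (pixels, rounded)
#'   and spine centre column (pixels, rounded); used to generate geometric
#'   variants of the same anatomy.  Requires a non-NA \code{seed}.
#' @param seed integer seed controlling noise (and jitter); NA uses the
#'   current RNG stream.
#' @return A validated \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec(noiseModel = "none")
#' st <- renderEchoStack(spec)
#' @export
phantomSpec <- function(gridHeight = NULL, gridWidth = 96L, nSlices = 6L,
                        echoTimes = 10.9 * (1:16), nDiscs = 6L,
                        discLabels = c("T12/L1", "L1/2", "L2/3", "L3/4",
                                       "L4/5", "L5/S1")[seq_len(nDiscs)],
                        vertebraHeight = 18L, vertebraWidth = 41L,
                        discHalfWidth = 15L,
                        discTilt = c(-9, -6, -3, 0, 5, 10),
                        discHeight = 7L, endplateThickness = 2L,
                        regionT2 = c(93, 100, 130, 106, 81),
                        discS0 = 400, boneT2 = 55, boneS0 = 175 / exp(-21.8 / 55),
                        endplateT2 = 45, endplateS0 = 100 / exp(-21.8 / 45),
                        noiseSigma = 7, noiseModel = "rician",
                        pixelSpacing = c(0.781, 0.781),
                        jitter = 0, seed = NA_integer_) {
  nDiscs <- as.integer(nDiscs)
  vh <- as.numeric(rep_len(vertebraHeight, nDiscs + 1L))
  tilt <- as.numeric(rep_len(discTilt, nDiscs))
  a <- as.numeric(rep_len(discHalfWidth, nDiscs))
  if (is.null(dim(regionT2))) {
    regionT2 <- matrix(rep(as.numeric(regionT2), each = nDiscs), nrow = nDiscs)
  }
  if (jitter > 0) {
    if (is.na(seed)) stop("geometry jitter needs a non-NA seed")
    jit <- withSeed(seed, list(
      tilt = stats::rnorm(nDiscs, 0, 3 * jitter),
      a = round(stats::rnorm(nDiscs, 0, 2 * jitter)),
      vh = round(stats::rnorm(nDiscs + 1L, 0, 2 * jitter)),
      cx = round(stats::rnorm(1, 0, 3 * jitter))
    ))
    tilt <- tilt + jit$tilt
    a <- pmax(10, pmin(a + jit$a, (vertebraWidth - 5) / 2))
    vh <- pmax(14, vh + jit$vh)
  } else {
    jit <- list(cx = 0)
  }
  gap <- as.integer(discHeight) + 2L * as.integer(endplateThickness)
  topMargin <- 8L
  if (is.null(gridHeight)) {
    gridHeight <- as.integer(topMargin + sum(vh) + nDiscs * gap +
      ceiling(max(abs(tan(tilt * pi / 180))) * vertebraWidth / 2) + 10L)
  }
  cx <- floor(gridWidth / 2) + jit$cx
  new("PhantomSpec",
    gridHeight = as.integer(gridHeight), gridWidth = as.integer(gridWidth),
    nSlices = as.integer(nSlices), echoTimes = as.numeric(echoTimes),
    nDiscs = nDiscs, discLabels = discLabels,
    spineCentreX = as.numeric(cx), vertebraWidth = as.numeric(vertebraWidth),
    vertebraHeights = vh, discHalfWidth = a, discTilt = tilt,
    discHeight = as.integer(discHeight),
    endplateThickness = as.integer(endplateThickness),
    regionT2 = regionT2, discS0 = as.numeric(discS0),
    boneT2 = as.numeric(boneT2), boneS0 = as.numeric(boneS0),
    endplateT2 = as.numeric(endplateT2), endplateS0 = as.numeric(endplateS0),
    noiseSigma = as.numeric(noiseSigma), noiseModel = noiseModel,
    pixelSpacing = as.numeric(pixelSpacing), topMargin = topMargin,
    seed = as.integer(seed))
}

# Rasterise the phantom geometry of one slice.  Returns tissue labels,
# disc indices, subregion labels, and per-pixel T2/S0 maps.  Geometry is
# identical across slices; only the noise differs.
phantomGeometry <- function(spec) {
  H <- spec@gridHeight; W <- spec@gridWidth
  tissue <- matrix(0L, H, W); discIdx <- matrix(0L, H, W)
  region <- matrix(0L, H, W)
  t2 <- matrix(Inf, H, W); s0 <- matrix(0, H, W)
  cx <- spec@spineCentreX
  halfW <- floor(spec@vertebraWidth / 2)
  et <- spec@endplateThickness
  dh <- spec@discHeight
  gap <- dh + 2L * et
  # first endplate row of each gap at the centre column
  gapTopC <- spec@topMargin + cumsum(spec@vertebraHeights[seq_len(spec@nDiscs)]) +
    (seq_len(spec@nDiscs) - 1L) * gap + 1L
  bottomRow <- spec@topMargin + sum(spec@vertebraHeights) + spec@nDiscs * gap
  xs <- (cx - halfW):(cx + halfW)
  tanTilt <- tan(spec@discTilt * pi / 180)
  for (x in xs) {
    dx <- x - cx
    colBone <- rep(TRUE, bottomRow)
    colBone[seq_len(spec@topMargin)] <- FALSE
    for (k in seq_len(spec@nDiscs)) {
      g0 <- round(gapTopC[k] + dx * tanTilt[k])
      rows <- g0:(g0 + gap - 1L)
      if (rows[1] < 1L || rows[gap] > H)
        stop("disc geometry leaves the image grid")
      if (k > 1L) {
        gPrev <- round(gapTopC[k - 1L] + dx * tanTilt[k - 1L]) + gap - 1L
        if (g0 - gPrev < 3L) stop("overlapping disc geometry")
      }
      colBone[rows[rows <= bottomRow]] <- FALSE
      epRows <- c(rows[seq_len(et)], rows[(gap - et + 1L):gap])
      tissue[epRows, x] <- 2L
      t2[epRows, x] <- spec@endplateT2; s0[epRows, x] <- spec@endplateS0
      a <- spec@discHalfWidth[k]
      if (abs(dx) <= a) {
        u <- dx / a
        halfH <- (dh / 2) * sqrt(max(0, 1 - u^2))
        centreRow <- g0 + et + (dh - 1L) %/% 2L
        dy <- (-(dh %/% 2)):(dh %/% 2)
        cover <- abs(dy) <= halfH - 0.5 + 1e-9
        if (any(cover)) {
          drows <- centreRow + dy[cover]
          b <- bandIndex(dx + a + 1L, 2L * a + 1L, 5L)
          tissue[drows, x] <- 3L
          discIdx[drows, x] <- k
          region[drows, x] <- b
          t2[drows, x] <- spec@regionT2[k, b]
          s0[drows, x] <- spec@discS0
        }
      }
    }
    boneRows <- which(colBone)
    boneRows <- boneRows[tissue[boneRows, x] == 0L]
    tissue[boneRows, x] <- 1L
    t2[boneRows, x] <- spec@boneT2; s0[boneRows, x] <- spec@boneS0
  }
  list(tissue = tissue, discIdx = discIdx, region = region, t2 = t2, s0 = s0)
}

# Magnitude-image noise models.  Rician: magnitude of a complex signal whose
# real/imaginary channels carry independent Gaussian noise of SD sigma.
applyNoise <- function(signal, sigma, model) {
  if (model == "none" || sigma == 0) return(signal)
  n <- length(signal)
  if (model == "gaussian") return(signal + stats::rnorm(n, 0, sigma))
  sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Render a multi-echo image stack from a phantom specification
#'
#' The noise-free pixel value at echo time TE is
#' \code{S0 * exp(-TE / T2)} for that pixel's tissue; noise is then applied
#' per \code{noiseModel}.  All slices share the same geometry and ground
#' truth; noise realisations are independent.  Rendering is deterministic
#' given \code{spec@seed}.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements \code{stack} (\linkS4class{EchoStack}) and
#'   \code{truth} (\linkS4class{PhantomTruth}), pixel-aligned.
#' @export
renderEchoStack <- function(spec) {
  validObject(spec)
  geo <- phantomGeometry(spec)
  H <- spec@gridHeight; W <- spec@gridWidth
  nE <- length(spec@echoTimes); nS <- spec@nSlices
  data <- array(0, dim = c(H, W, nS, nE))
  clean <- vapply(spec@echoTimes,
                  function(te) geo$s0 * exp(-te / geo$t2),
                  matrix(0, H, W))
  withSeed(spec@seed, {
    for (s in seq_len(nS)) {
      for (e in seq_len(nE)) {
        data[, , s, e] <- applyNoise(clean[, , e], spec@noiseSigma,
                                     spec@noiseModel)
      }
    }
  })
  stack <- new("EchoStack", data = data, echoTimes = spec@echoTimes,
               pixelSpacing = spec@pixelSpacing, sliceThickness = 3,
               interSliceDistance = 3)
  rep3 <- function(m) array(rep(m, nS), dim = c(H, W, nS))
  nPix <- tabulate(geo$region[geo$discIdx == 1L], 5L)
  regionTable <- do.call(rbind, lapply(seq_len(spec@nDiscs), function(k) {
    data.frame(disc = k, level = spec@discLabels[k], region = 1:5,
               trueT2 = spec@regionT2[k, ], S0 = spec@discS0,
               nPixelsPerSlice = tabulate(geo$region[geo$discIdx == k], 5L))
  }))
  t2m <- geo$t2; t2m[!is.finite(t2m)] <- 0
  truth <- new("PhantomTruth",
    tissueLabels = rep3(geo$tissue), discMasks = rep3(geo$discIdx),
    regionLabels = rep3(geo$region), t2Map = rep3(t2m), s0Map = rep3(geo$s0),
    regionTable = regionTable)
  list(stack = stack, truth = truth)
}

#' Construct a longitudinal study specification
#'
#' Defaults reproduce a 12-subject design measured at nine sessions over one
#' year with attrition: 12 subjects at the first four sessions, then 11, 10,
#' 10, 8 and 8.  Default variance components give a true ICC of about 0.98
#' and a true within-subject CV of about 1.9\% at a 102 ms mean.
#'
#' @param nSubjects,nSessions design size.
#' @param dropout subjects present per session (recycled/validated).
#' @param betweenSD,withinSD between-subject and within-subject session SD of
#'   true T2, ms.
#' @param seed integer seed; NA uses the current stream.
#' @return A validated \linkS4class{StudySpec}.
#' @export
studySpec <- function(nSubjects = 12L, nSessions = 9L,
                      dropout = c(12L, 12L, 12L, 12L, 11L, 10L, 10L, 8L, 8L),
                      betweenSD = 13.3, withinSD = 1.9, seed = NA_integer_) {
  new("StudySpec", nSubjects = as.integer(nSubjects),
      nSessions = as.integer(nSessions),
      dropout = as.integer(rep_len(dropout, nSessions)),
      betweenSD = as.numeric(betweenSD), withinSD = as.numeric(withinSD),
      seed = as.integer(seed))
}

#' True intraclass correlation implied by a study specification
#' @param study a \linkS4class{StudySpec}.
#' @return \code{betweenSD^2 / (betweenSD^2 + withinSD^2)}.
#' @export
trueICC <- function(study) {
  vb <- study@betweenSD^2; vw <- study@withinSD^2
  if (vb + vw == 0) return(1)
  vb / (vb + vw)
}

#' Generate a longitudinal multi-session phantom dataset
#'
#' Subject i, session j receives a true T2 offset \code{b_i + w_ij}
#' (\code{b_i ~ N(0, betweenSD^2)}, \code{w_ij ~ N(0, withinSD^2)}) added to
#' every subregion's T2.  The dropout pattern removes subjects from the end
#' of the roster; dropped subjects never return.  With \code{render = TRUE}
#' an \linkS4class{EchoStack} is rendered for every present subject-session
#' with an independently derived noise seed; with \code{render = FALSE} only
#' the ground-truth table is produced (useful for statistical simulations).
#'
#' @param study a \linkS4class{StudySpec}.
#' @param spec the per-session \linkS4class{PhantomSpec} template.
#' @param render render image stacks (TRUE) or truth tables only.
#' @return A list: \code{meta} (data.frame subject, session, stack index),
#'   \code{stacks} (list of render results, NULL if \code{render = FALSE}),
#'   \code{truth} (long data.frame subject, session, disc, level, region,
#'   trueT2), \code{offsets} (subject x session matrix of b_i + w_ij, NA
#'   where absent), and \code{geometryTruth} (one \linkS4class{PhantomTruth},
#'   valid for every rendered stack since geometry is fixed within subject).
#' @export
generateLongitudinalDataset <- function(study, spec = phantomSpec(),
                                        render = TRUE) {
  validObject(study)
  present <- outer(seq_len(study@nSubjects), study@dropout, `<=`)
  draws <- withSeed(study@seed, {
    b <- stats::rnorm(study@nSubjects, 0, study@betweenSD)
    w <- matrix(stats::rnorm(study@nSubjects * study@nSessions, 0,
                             study@withinSD),
                study@nSubjects, study@nSessions)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                               study@nSubjects * study@nSessions),
                    study@nSubjects, study@nSessions)
    list(b = b, w = w, seeds = seeds)
  })
  offsets <- draws$b + draws$w
  offsets[!present] <- NA_real_
  idx <- which(present, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  meta <- data.frame(subject = idx[, 1], session = idx[, 2],
                     stack = seq_len(nrow(idx)))
  truth <- do.call(rbind, lapply(seq_len(nrow(meta)), function(r) {
    i <- meta$subject[r]; j <- meta$session[r]
    data.frame(subject = i, session = j, disc = seq_len(spec@nDiscs),
               level = spec@discLabels,
               spec@regionT2 + offsets[i, j])
  }))
  names(truth)[5:9] <- paste0("r", 1:5)
  truth <- stats::reshape(truth, direction = "long",
                          varying = paste0("r", 1:5), v.names = "trueT2",
                          timevar = "region", idvar = c("subject", "session", "disc"))
  rownames(truth) <- NULL
  stacks <- NULL; geometryTruth <- NULL
  if (render) {
    stacks <- vector("list", nrow(meta))
    for (r in seq_len(nrow(meta))) {
      i <- meta$subject[r]; j <- meta$session[r]
      sp <- spec
      sp@regionT2 <- spec@regionT2 + offsets[i, j]
      sp@seed <- draws$seeds[i, j]
      res <- renderEchoStack(sp)
      stacks[[r]] <- res$stack
      if (is.null(geometryTruth)) geometryTruth <- res$truth
    }
  }
  list(meta = meta, stacks = stacks, truth = truth, offsets = offsets,
       geometryTruth = geometryTruth)
}
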