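#' Construct segmentation parameters
#'
#' All thresholds default to the published values of the semi-automated
#' procedure; constants the procedure leaves open are exposed with
#' documented defaults (see \linkS4class{SegmentationParams}).
#'
#' @param medianHeight,diffThresholdLocate,endplateIntensityThreshold
#'   vertical median window (rows), spine-locate difference (units),
#'   endplate darkness threshold (units).
#' @param neighborCountMin,apBorderThreshold contour-tracking neighbour rule
#'   and anterior/posterior border difference (units).
#' @param supportPointsPerDisc,costWeightGradient,costWeightGrey graph-search
#'   settings.
#' @param contourStepRows,minContourLength,maxDiscGap,propagationRadius,
#'   propagationLambda,gaussianSigma remaining tuning constants.
#' @return A validated \linkS4class{SegmentationParams}.
#' @export
segParams <- function(medianHeight = 15L, diffThresholdLocate = 100,
                      endplateIntensityThreshold = 150,
                      neighborCountMin = 3L, apBorderThreshold = 80,
                      supportPointsPerDisc = 8L, costWeightGradient = 0.5,
                      costWeightGrey = 0.5, contourStepRows = 2L,
                      minContourLength = 5L, maxDiscGap = 14L,
                      propagationRadius = 5L, propagationLambda = 1,
                      gaussianSigma = 1) {
  new("SegmentationParams",
    medianHeight = as.integer(medianHeight),
    diffThresholdLocate = as.numeric(diffThresholdLocate),
    endplateIntensityThreshold = as.numeric(endplateIntensityThreshold),
    neighborCountMin = as.integer(neighborCountMin),
    apBorderThreshold = as.numeric(apBorderThreshold),
    supportPointsPerDisc = as.integer(supportPointsPerDisc),
    costWeightGradient = as.numeric(costWeightGradient),
    costWeightGrey = as.numeric(costWeightGrey),
    contourStepRows = as.integer(contourStepRows),
    minContourLength = as.integer(minContourLength),
    maxDiscGap = as.integer(maxDiscGap),
    propagationRadius = as.integer(propagationRadius),
    propagationLambda = as.numeric(propagationLambda),
    gaussianSigma = as.numeric(gaussianSigma))
}

#' Vertical median filter (1 pixel wide, n rows tall)
#'
#' Each output pixel is the median of the vertical window of
#' \code{height} pixels centred on it, computed column by column.
#' Image borders are handled by reflection padding, which avoids artificial
#' signal-versus-zero differences at the image edge.
#'
#' @param image numeric matrix (rows = cephalocaudal).
#' @param height odd window height (default 15).
#' @return Filtered matrix of identical dimensions.
#' @export
verticalMedianFilter <- function(image, height = 15L) {
  height <- as.integer(height)
  if (height %% 2L == 0L) stop("median window height must be odd")
  if (nrow(image) < height)
    stop("image must have at least ", height, " rows")
  k <- (height - 1L) %/% 2L
  n <- nrow(image)
  pad <- c(k:1, 1:n, n:(n - k + 1L))
  out <- apply(image, 2L, function(col) {
    f <- stats::runmed(col[pad], height, endrule = "keep")
    f[(k + 1L):(k + n)]
  })
  dim(out) <- dim(image)
  out
}

#' Locate the spine centre column
#'
#' Returns the column with the highest count of pixels whose signal exceeds
#' the vertical-median image by at least \code{diffThresholdLocate} units
#' (signed difference: pixel brighter than its median).  Ties are broken by
#' the smallest column index.
#'
#' @param image the second-echo image.
#' @param medianImage its vertical-median filtered version.
#' @param params \linkS4class{SegmentationParams}.
#' @return The centre column index (1-based).
#' @export
locateSpineCentre <- function(image, medianImage, params = segParams()) {
  if (!all(dim(image) == dim(medianImage)))
    stop("image and medianImage must have identical dimensions")
  counts <- colSums((image - medianImage) >= params@diffThresholdLocate)
  if (all(counts == 0L)) stop("no spinal structure detected")
  which.max(counts)
}

#' Detect endplate seed rows along the spine centre column
#'
#' Strict local minima of the centre-column intensity profile with value
#' below \code{endplateIntensityThreshold}.  A constant run (plateau) counts
#' as one minimum when both flanking runs are higher; the reported row is the
#' plateau middle (lower row for even-length plateaus).  Runs touching the
#' profile ends are never minima.
#'
#' @param image the second-echo image.
#' @param centreColumn column to profile.
#' @param params \linkS4class{SegmentationParams}.
#' @return Increasing integer vector of seed rows (possibly empty).
#' @export
detectEndplateSeeds <- function(image, centreColumn, params = segParams()) {
  if (centreColumn < 1L || centreColumn > ncol(image))
    stop("centreColumn outside image")
  profile <- image[, centreColumn]
  r <- rle(profile)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- integer(0)
  if (length(r$values) >= 3L) {
    for (m in 2:(length(r$values) - 1L)) {
      if (r$values[m] < r$values[m - 1L] && r$values[m] < r$values[m + 1L] &&
          r$values[m] < params@endplateIntensityThreshold) {
        seeds <- c(seeds, starts[m] + (r$lengths[m] - 1L) %/% 2L)
      }
    }
  }
  seeds
}

# Count of 8-neighbours of (y, x) darker than `thr`; neighbours outside the
# image are ignored.
darkNeighbourCount <- function(image, y, x, thr) {
  ys <- max(1L, y - 1L):min(nrow(image), y + 1L)
  xs <- max(1L, x - 1L):min(ncol(image), x + 1L)
  sum(image[ys, xs] < thr) - (image[y, x] < thr)
}

#' Track an endplate contour anteriorly and posteriorly from a seed
#'
#' From each seed on the centre column the contour grows one column at a
#' time in both directions.  The next contour pixel is chosen among the
#' adjacent column's pixels within \code{contourStepRows} rows of the current
#' one, restricted to candidates with at least \code{neighborCountMin} of
#' their 8-neighbours below \code{endplateIntensityThreshold}; among those
#' the darkest pixel wins (ties: smallest row step, then the upper row).
#' Tracking stops when no candidate qualifies or when the column leaves
#' \code{xRange}.  Contours spanning fewer than \code{minContourLength}
#' columns are discarded with a warning.
#'
#' @param image the second-echo image.
#' @param seeds integer vector of seed rows.
#' @param centreColumn the column the seeds live on.
#' @param params \linkS4class{SegmentationParams}.
#' @param xRange optional inclusive column limits (anterior, posterior);
#'   defaults to the whole image width.
#' @return List (one element per seed) of two-column matrices
#'   \code{cbind(x, y)} ordered by increasing x, or NULL for discarded seeds.
#' @export
trackEndplateContours <- function(image, seeds, centreColumn,
                                  params = segParams(), xRange = NULL) {
  if (length(seeds) < 1L) stop("need at least one seed")
  if (is.null(xRange)) xRange <- c(1L, ncol(image))
  thr <- params@endplateIntensityThreshold
  step <- params@contourStepRows
  H <- nrow(image)
  trackDir <- function(y0, dir) {
    xs <- integer(0); ys <- integer(0)
    y <- y0; x <- centreColumn
    repeat {
      xn <- x + dir
      if (xn < xRange[1] || xn > xRange[2]) break
      cand <- clampInt((y - step):(y + step), 1L, H)
      cand <- unique(cand)
      ok <- vapply(cand, function(yy)
        darkNeighbourCount(image, yy, xn, thr) >= params@neighborCountMin,
        logical(1))
      if (!any(ok)) break
      cand <- cand[ok]
      vals <- image[cbind(cand, xn)]
      best <- cand[order(vals, abs(cand - y), cand)][1]
      x <- xn; y <- best
      xs <- c(xs, x); ys <- c(ys, y)
    }
    cbind(x = xs, y = ys)
  }
  lapply(seeds, function(y0) {
    ant <- trackDir(y0, -1L)
    post <- trackDir(y0, +1L)
    path <- rbind(ant[rev(seq_len(nrow(ant))), , drop = FALSE],
                  cbind(x = centreColumn, y = y0), post)
    if (nrow(path) < params@minContourLength) {
      warning("contour from seed row ", y0, " shorter than ",
              params@minContourLength, " px; discarded")
      return(NULL)
    }
    path
  })
}

#' Find anterior and posterior disc borders
#'
#' For each row of each disc row-span, scans outward from the spine centre
#' column and returns the first column on each side where the absolute
#' difference between the across-echo averaged image and the vertical-median
#' image reaches \code{apBorderThreshold} units.  If the difference already
#' reaches the threshold at the centre column itself the row is flagged
#' degenerate with both borders at the centre.  Rows without a hit on a side
#' inherit the nearest resolved row's border; a span with no resolved row at
#' all is an error.
#'
#' @param averagedImage mean image over all echoes.
#' @param medianImage vertical-median image (from the second echo).
#' @param centreColumn spine centre column.
#' @param discRowSpans list of integer row vectors, one per disc.
#' @param params \linkS4class{SegmentationParams}.
#' @return List (one per span) of data.frames with columns \code{row},
#'   \code{anterior}, \code{posterior}, \code{degenerate}.
#' @export
findApBorders <- function(averagedImage, medianImage, centreColumn,
                          discRowSpans, params = segParams()) {
  if (!all(dim(averagedImage) == dim(medianImage)))
    stop("image dimensions differ")
  W <- ncol(averagedImage)
  if (centreColumn < 1L || centreColumn > W) stop("centreColumn outside image")
  thr <- params@apBorderThreshold
  lapply(seq_along(discRowSpans), function(k) {
    rows <- discRowSpans[[k]]
    d <- abs(averagedImage[rows, , drop = FALSE] -
             medianImage[rows, , drop = FALSE])
    res <- data.frame(row = rows, anterior = NA_integer_,
                      posterior = NA_integer_, degenerate = FALSE)
    for (i in seq_along(rows)) {
      if (d[i, centreColumn] >= thr) {
        res$anterior[i] <- res$posterior[i] <- centreColumn
        res$degenerate[i] <- TRUE
        next
      }
      hitA <- which(d[i, seq_len(centreColumn - 1L)] >= thr)
      if (length(hitA)) res$anterior[i] <- max(hitA)
      hitP <- which(d[i, (centreColumn + 1L):W] >= thr)
      if (length(hitP)) res$posterior[i] <- centreColumn + min(hitP)
    }
    for (side in c("anterior", "posterior")) {
      miss <- which(is.na(res[[side]]))
      have <- which(!is.na(res[[side]]))
      if (!length(have))
        stop("disc span ", k, ": no ", side, " border resolved on any row")
      for (i in miss) {
        res[[side]][i] <- res[[side]][have[which.min(abs(have - i))]]
      }
    }
    res
  })
}

#' Build filled disc masks from contour pairs and borders
#'
#' A pixel belongs to disc k when its row lies strictly between the disc's
#' superior and inferior endplate contours at that column and its column
#' lies strictly between the anterior and posterior border of its row.
#' Overlap between filled discs indicates contour failure and is an error;
#' a disc with a missing contour yields no mask, with a warning.
#'
#' @param contourPairs list (one per disc) of lists with elements \code{sup}
#'   and \code{inf}, each a \code{cbind(x, y)} contour matrix or NULL.
#' @param borders list of border data.frames as returned by
#'   \code{\link{findApBorders}} (same order).
#' @param imageDim \code{c(rows, cols)} of the target mask.
#' @return Integer matrix: 0 outside, disc index inside.
#' @export
extractDiscMasks <- function(contourPairs, borders, imageDim) {
  mask <- matrix(0L, imageDim[1], imageDim[2])
  for (k in seq_along(contourPairs)) {
    cp <- contourPairs[[k]]
    if (is.null(cp$sup) || is.null(cp$inf)) {
      warning("disc ", k, ": missing contour; no mask produced")
      next
    }
    supY <- rep(NA_integer_, imageDim[2]); infY <- supY
    supY[cp$sup[, "x"]] <- cp$sup[, "y"]
    infY[cp$inf[, "x"]] <- cp$inf[, "y"]
    b <- borders[[k]]
    antAt <- rep(NA_integer_, imageDim[1]); postAt <- antAt
    antAt[b$row] <- b$anterior; postAt[b$row] <- b$posterior
    for (x in which(!is.na(supY) & !is.na(infY))) {
      if (infY[x] - supY[x] < 2L) next
      ys <- (supY[x] + 1L):(infY[x] - 1L)
      ys <- ys[!is.na(antAt[ys]) & antAt[ys] < x & x < postAt[ys]]
      if (!length(ys)) next
      if (any(mask[ys, x] != 0L))
        stop("overlapping filled discs at column ", x,
             " (contour failure between discs ",
             unique(mask[ys, x][mask[ys, x] != 0L])[1], " and ", k, ")")
      mask[ys, x] <- k
    }
  }
  mask
}

# Mean image across all echoes of one slice.
averagedImage <- function(stack, slice) {
  d <- dim(stack@data)
  a <- array(stack@data[, , slice, ], dim = c(d[1], d[2], d[4]))
  rowMeans(a, dims = 2L)
}

#' Segment the intervertebral discs of a multi-echo stack
#'
#' Runs the full per-slice delineation: vertical median filtering of the
#' second-echo image, spine-centre location on the localisation slice
#' (the third anatomical slice by default), endplate seed detection,
#' seed pairing into disc gaps, anterior/posterior border detection on the
#' averaged image, endplate contour tracking, optional graph-search contour
#' refinement through auto-placed support points, and mask extraction.
#'
#' Seeds are restricted to the vertical span of locate-qualifying pixels on
#' the centre column, and a candidate disc gap is kept only if the span
#' contains locate-qualifying pixels; both guards suppress spurious minima
#' in noisy background or bone.
#'
#' @param stack an \linkS4class{EchoStack}.
#' @param params \linkS4class{SegmentationParams}.
#' @param locSlice slice used to locate the spine centre (1-based; default
#'   the third slice, clamped to the available range).
#' @param refine refine tracked contours with \code{\link{dijkstraBoundary}}
#'   through \code{supportPointsPerDisc} auto-placed support points.
#' @param discLabels optional level labels, cephalad to caudad.
#' @return A \linkS4class{DiscSegmentation}.
#' @export
segmentDiscs <- function(stack, params = segParams(),
                         locSlice = min(3L, dim(stack@data)[3]),
                         refine = FALSE, discLabels = NULL) {
  d <- dim(stack@data)
  H <- d[1]; W <- d[2]; nS <- d[3]
  e2loc <- stack@data[, , locSlice, 2L]
  medLoc <- verticalMedianFilter(e2loc, params@medianHeight)
  centre <- locateSpineCentre(e2loc, medLoc, params)
  masks <- array(0L, dim = c(H, W, nS))
  allSeeds <- vector("list", nS)
  allContours <- vector("list", nS)
  allBorders <- vector("list", nS)
  nDiscsSeen <- NA_integer_
  for (s in seq_len(nS)) {
    e2 <- stack@data[, , s, 2L]
    med <- verticalMedianFilter(e2, params@medianHeight)
    avg <- averagedImage(stack, s)
    qual <- which((e2[, centre] - med[, centre]) >= params@diffThresholdLocate)
    if (!length(qual))
      stop("slice ", s, ": no locate-qualifying pixels on the centre column")
    seeds <- detectEndplateSeeds(e2, centre, params)
    seeds <- seeds[seeds >= min(qual) - params@maxDiscGap &
                   seeds <= max(qual) + params@maxDiscGap]
    if (length(seeds) < 2L) stop("slice ", s, ": fewer than two endplate seeds")
    gapOk <- diff(seeds) <= params@maxDiscGap
    pairs <- which(gapOk)
    # a genuine disc gap must contain locate-qualifying (bright disc) pixels
    pairs <- pairs[vapply(pairs, function(i)
      sum(qual > seeds[i] & qual < seeds[i + 1L]) >= 3L, logical(1))]
    if (!length(pairs)) stop("slice ", s, ": no disc gaps detected")
    spans <- lapply(pairs, function(i) (seeds[i] + 1L):(seeds[i + 1L] - 1L))
    borders <- findApBorders(avg, med, centre, spans, params)
    contourPairs <- vector("list", length(pairs))
    for (j in seq_along(pairs)) {
      xr <- c(min(borders[[j]]$anterior), max(borders[[j]]$posterior))
      tc <- trackEndplateContours(e2, seeds[c(pairs[j], pairs[j] + 1L)],
                                  centre, params, xRange = xr)
      if (refine) tc <- lapply(tc, function(path) {
        if (is.null(path)) return(NULL)
        sp <- placeSupportPoints(path, params@supportPointsPerDisc)
        refined <- dijkstraBoundary(avg, sp, params)
        refined$path
      })
      contourPairs[[j]] <- list(sup = tc[[1]], inf = tc[[2]])
    }
    masks[, , s] <- extractDiscMasks(contourPairs, borders, c(H, W))
    allSeeds[[s]] <- seeds
    allContours[[s]] <- contourPairs
    allBorders[[s]] <- borders
    if (is.na(nDiscsSeen)) nDiscsSeen <- length(pairs)
  }
  if (is.null(discLabels))
    discLabels <- paste0("disc", seq_len(max(nDiscsSeen, 1L)))
  new("DiscSegmentation", masks = masks, discLabels = discLabels,
      centreColumn = as.integer(centre), seeds = allSeeds,
      contours = allContours, borders = allBorders, params = params)
}

#' Place equally spaced support points along a contour
#'
#' Substitute for the operator's manual marking of roughly eight support
#' points per disc: points are taken at equal arc positions along a tracked
#' endplate contour (always including both endpoints).
#'
#' @param contour a \code{cbind(x, y)} contour matrix.
#' @param n number of points (default 8).
#' @return A \code{cbind(x, y)} matrix of support points.
#' @export
placeSupportPoints <- function(contour, n = 8L) {
  if (nrow(contour) < 2L) stop("contour too short for support points")
  idx <- unique(round(seq(1L, nrow(contour), length.out = max(2L, n))))
  contour[idx, , drop = FALSE]
}
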