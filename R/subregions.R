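#' Ellipse orientation and centroid of a disc mask
#'
#' Fits the image-moment ellipse: the centroid is the pixel mean and the
#' orientation is derived from the second central moments,
#' \code{0.5 * atan2(2 * mu11, mu20 - mu02)}, reported in degrees in
#' (-90, 90].  Rows count as y, columns as x (y grows caudally).  Degenerate
#' masks with no preferred axis (e.g. a circle) report 0 degrees.
#'
#' @param mask logical or 0/1 matrix.
#' @return List with \code{centroid} (c(x, y)) and \code{angle} (degrees).
#' @export
fitEllipseOrientation <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 10L) stop("mask has fewer than 10 pixels")
  y <- idx[, 1]; x <- idx[, 2]
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  if (abs(mu11) < 1e-9 && abs(mu20 - mu02) < 1e-9) {
    angle <- 0
  } else {
    angle <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  }
  if (angle <= -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  list(centroid = c(x = cx, y = cy), angle = angle)
}

# Rotation matrix acting on (x, y) column pairs, angle in degrees.
rotMat <- function(angleDeg) {
  a <- angleDeg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

#' Rotate a mask or grey image to the horizontal
#'
#' Rotates by \code{-angle} about the centroid so that a structure whose
#' fitted orientation is \code{angle} ends up horizontal.  Resampling is by
#' inverse mapping: nearest-neighbour for masks (label-safe), bilinear for
#' grey images.  The output grid equals the input grid.
#'
#' @param image matrix (mask or grey values).
#' @param angle orientation to remove, degrees.
#' @param centroid rotation centre c(x, y); defaults to the mask centroid
#'   (nonzero pixels) or the image centre for grey input.
#' @param interpolation \code{"nearest"} or \code{"bilinear"}.
#' @return Rotated matrix of identical dimensions.
#' @export
rotateToHorizontal <- function(image, angle, centroid = NULL,
                               interpolation = c("nearest", "bilinear")) {
  interpolation <- match.arg(interpolation)
  if (!is.finite(angle)) stop("angle must be finite")
  H <- nrow(image); W <- ncol(image)
  if (is.null(centroid)) {
    nz <- which(image != 0, arr.ind = TRUE)
    centroid <- if (nrow(nz) > 0) c(mean(nz[, 2]), mean(nz[, 1])) else
      c((W + 1) / 2, (H + 1) / 2)
  }
  if (angle == 0) return(image)
  # output pixel q samples input at p = c + R(angle) (q - c)
  R <- rotMat(angle)
  grid <- expand.grid(y = seq_len(H), x = seq_len(W))
  dx <- grid$x - centroid[1]; dy <- grid$y - centroid[2]
  sx <- centroid[1] + R[1, 1] * dx + R[1, 2] * dy
  sy <- centroid[2] + R[2, 1] * dx + R[2, 2] * dy
  out <- matrix(0, H, W)
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= W & iy >= 1 & iy <= H
    out[cbind(grid$y[ok], grid$x[ok])] <- image[cbind(iy[ok], ix[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= W & y0 >= 1 & y0 + 1 <= H
    v <- (1 - fx[ok]) * (1 - fy[ok]) * image[cbind(y0[ok], x0[ok])] +
      fx[ok] * (1 - fy[ok]) * image[cbind(y0[ok], x0[ok] + 1)] +
      (1 - fx[ok]) * fy[ok] * image[cbind(y0[ok] + 1, x0[ok])] +
      fx[ok] * fy[ok] * image[cbind(y0[ok] + 1, x0[ok] + 1)]
    out[cbind(grid$y[ok], grid$x[ok])] <- v
  }
  out
}

#' Partition a horizontal disc mask into five equidistant-width segments
#'
#' The x-extent of the mask is split into five contiguous column bands of
#' equal width; when the width is not divisible by five the remainder
#' columns are given, one each, to the anterior-most bands.  Labels run
#' 1 (anterior annulus) to 5 (posterior annulus).
#'
#' @param rotatedMask 0/1 matrix, already rotated to the horizontal.
#' @return Integer label matrix (0 outside the mask).
#' @export
partitionFive <- function(rotatedMask) {
  cols <- which(colSums(rotatedMask != 0) > 0)
  if (!length(cols)) stop("empty mask")
  x0 <- min(cols); x1 <- max(cols)
  width <- x1 - x0 + 1L
  if (width < 5L) stop("mask width (", width, ") must be at least 5 px")
  labels <- matrix(0L, nrow(rotatedMask), ncol(rotatedMask))
  idx <- which(rotatedMask != 0, arr.ind = TRUE)
  labels[idx] <- bandIndex(idx[, 2] - x0 + 1L, width, 5L)
  labels
}

#' Fit, rotate and partition one disc mask
#'
#' Combines \code{\link{fitEllipseOrientation}},
#' \code{\link{rotateToHorizontal}} and \code{\link{partitionFive}}, then
#' maps the band membership back onto the original (unrotated) mask pixels
#' by forward-rotating their coordinates.  Grey values are therefore always
#' extracted in the original frame; rotation never interpolates the signal
#' used for T2 estimation.
#'
#' @param mask 0/1 matrix of one disc in the original frame.
#' @param anteriorLeft is anterior at low x (default TRUE)?  When FALSE the
#'   band order is reversed so label 1 is still the anterior annulus.
#' @return List: \code{labels} (original-frame label matrix, 1..5),
#'   \code{rotated} (rotated mask), \code{rotatedLabels}, \code{angle},
#'   \code{centroid}, \code{width} (rotated-mask width in columns).
#' @export
partitionDisc <- function(mask, anteriorLeft = TRUE) {
  fit <- fitEllipseOrientation(mask)
  rot <- rotateToHorizontal(mask, fit$angle, fit$centroid, "nearest")
  rotLabels <- partitionFive(rot)
  cols <- which(colSums(rot != 0) > 0)
  x0 <- min(cols); width <- max(cols) - x0 + 1L
  # forward map original pixels into the rotated frame
  idx <- which(mask != 0, arr.ind = TRUE)
  R <- rotMat(-fit$angle)
  dx <- idx[, 2] - fit$centroid[1]; dy <- idx[, 1] - fit$centroid[2]
  rx <- fit$centroid[1] + R[1, 1] * dx + R[1, 2] * dy
  band <- bandIndex(clampInt(round(rx) - x0 + 1L, 1L, width), width, 5L)
  if (!anteriorLeft) band <- 6L - band
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[idx] <- band
  list(labels = labels, rotated = rot, rotatedLabels = rotLabels,
       angle = fit$angle, centroid = fit$centroid, width = width)
}

#' Partition every disc of a segmentation into five subregions
#'
#' @param segMasks integer array \code{[y, x, slice]} of disc indices (from
#'   \linkS4class{DiscSegmentation} or ground truth).
#' @param anteriorLeft see \code{\link{partitionDisc}}.
#' @return A \linkS4class{SubregionPartition}.
#' @export
partitionAllDiscs <- function(segMasks, anteriorLeft = TRUE) {
  d <- dim(segMasks)
  regions <- array(0L, d)
  geom <- list()
  for (s in seq_len(d[3])) {
    m <- segMasks[, , s]
    for (k in sort(unique(m[m > 0]))) {
      pd <- partitionDisc(m == k, anteriorLeft)
      sl <- regions[, , s]
      sl[pd$labels > 0] <- pd$labels[pd$labels > 0]
      regions[, , s] <- sl
      geom[[length(geom) + 1L]] <- data.frame(
        disc = k, slice = s, centroidX = pd$centroid[1],
        centroidY = pd$centroid[2], angle = pd$angle, width = pd$width)
    }
  }
  new("SubregionPartition", regionLabels = regions, discMasks = segMasks,
      geometry = do.call(rbind, geom))
}

#' Per-echo mean signal of labelled regions
#'
#' For every region label and every echo, the arithmetic mean of the
#' in-region pixel intensities.  The region coordinates come from one
#' segmentation per session and are applied unchanged to every echo.
#'
#' @param stack an \linkS4class{EchoStack}.
#' @param labels integer matrix (one slice) or \code{[y, x, slice]} array of
#'   region labels (0 = outside).
#' @param slice slice index when \code{labels} is a matrix.
#' @return Long data.frame: slice, region, echoTime, meanSignal, nPixels.
#' @export
regionMeanSignals <- function(stack, labels, slice = NULL) {
  d <- dim(stack@data)
  if (is.matrix(labels)) {
    if (is.null(slice)) stop("slice must be given for matrix labels")
    labs <- array(0L, c(d[1], d[2], d[3]))
    labs[, , slice] <- labels
    slices <- slice
  } else {
    labs <- labels
    slices <- seq_len(d[3])
  }
  out <- list()
  for (s in slices) {
    m <- labs[, , s]
    regs <- sort(unique(m[m > 0]))
    if (!length(regs)) next
    flat <- matrix(stack@data[, , s, ], d[1] * d[2], d[4])
    for (r in regs) {
      idx <- which(m == r)
      if (!length(idx)) stop("empty region ", r, " on slice ", s)
      mu <- colMeans(flat[idx, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        slice = s, region = r, echoTime = stack@echoTimes,
        meanSignal = mu, nPixels = length(idx))
    }
  }
  if (!length(out)) stop("no labelled pixels found")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
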