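# Gradient estimation: separable Gaussian pre-smoothing followed by central
# differences.  Returns list(gx, gy, mag).  sigma = 0 skips the smoothing.
imageGradients <- function(image, sigma = 1) {
  sm <- gaussianSmooth(image, sigma)
  H <- nrow(sm); W <- ncol(sm)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3L) gx[, 2:(W - 1L)] <- (sm[, 3:W] - sm[, 1:(W - 2L)]) / 2
  if (H >= 3L) gy[2:(H - 1L), ] <- (sm[3:H, ] - sm[1:(H - 2L), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

gaussianSmooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    vp <- v[c(rep(1L, r), 1:n, rep(n, r))]   # replicate padding
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1L):(r + n)]
  }
  tmp <- apply(image, 2L, smooth1)   # along columns
  t(apply(tmp, 1L, smooth1))         # along rows
}

#' Minimum-cost boundary path through ordered support points
#'
#' Connects consecutive support points by the minimum-cost 8-connected path
#' (Dijkstra's algorithm).  The cost of entering a pixel combines two terms,
#' each scaled to [0, 1] over the local search window before weighting:
#' the deviation of the pixel's gradient direction from the mean gradient
#' direction at the two flanking support points, as
#' \code{(1 - cos(theta)) / 2}, and the pixel's normalised grey value.
#' Dark pixels lying on edges whose gradient agrees with the boundary
#' orientation are therefore cheap, so the optimal path follows the object
#' edge through the support points.
#'
#' @param averagedImage image supplying grey values and gradients (the
#'   across-echo average in the segmentation pipeline).
#' @param supportPoints \code{cbind(x, y)} matrix of at least two points
#'   ordered along the intended boundary.
#' @param params \linkS4class{SegmentationParams} (cost weights, smoothing).
#' @param margin search-window padding around each point pair, pixels.
#' @return List with \code{path} (a \code{cbind(x, y)} matrix through all
#'   points) and \code{cost} (total accumulated cost, start pixels free).
#' @export
dijkstraBoundary <- function(averagedImage, supportPoints,
                             params = segParams(), margin = 5L) {
  sp <- as.matrix(supportPoints)
  if (nrow(sp) < 2L) stop("need at least two support points")
  H <- nrow(averagedImage); W <- ncol(averagedImage)
  if (any(sp[, 1] < 1L | sp[, 1] > W | sp[, 2] < 1L | sp[, 2] > H))
    stop("support points outside image")
  g <- imageGradients(averagedImage, params@gaussianSigma)
  fullPath <- sp[1, , drop = FALSE]
  totalCost <- 0
  for (i in seq_len(nrow(sp) - 1L)) {
    a <- sp[i, ]; b <- sp[i + 1L, ]
    x0 <- max(1L, min(a[1], b[1]) - margin); x1 <- min(W, max(a[1], b[1]) + margin)
    y0 <- max(1L, min(a[2], b[2]) - margin); y1 <- min(H, max(a[2], b[2]) + margin)
    sub <- averagedImage[y0:y1, x0:x1, drop = FALSE]
    rng <- range(sub)
    greyN <- if (diff(rng) > 0) (sub - rng[1]) / diff(rng) else sub * 0
    # reference direction: mean gradient at the two flanking support points
    refG <- c(g$gx[a[2], a[1]] + g$gx[b[2], b[1]],
              g$gy[a[2], a[1]] + g$gy[b[2], b[1]]) / 2
    refN <- sqrt(sum(refG^2))
    gxs <- g$gx[y0:y1, x0:x1, drop = FALSE]
    gys <- g$gy[y0:y1, x0:x1, drop = FALSE]
    mags <- sqrt(gxs^2 + gys^2)
    cosT <- matrix(1, nrow(sub), ncol(sub))
    ok <- mags > 0 & refN > 0
    cosT[ok] <- (gxs[ok] * refG[1] + gys[ok] * refG[2]) / (mags[ok] * refN)
    nodeCost <- params@costWeightGradient * (1 - cosT) / 2 +
      params@costWeightGrey * greyN
    res <- dijkstraGrid(nodeCost,
                        start = c(a[2] - y0 + 1L, a[1] - x0 + 1L),
                        goal = c(b[2] - y0 + 1L, b[1] - x0 + 1L))
    seg <- cbind(x = res$path[, 2] + x0 - 1L, y = res$path[, 1] + y0 - 1L)
    fullPath <- rbind(fullPath, seg[-1L, , drop = FALSE])
    totalCost <- totalCost + res$cost
  }
  list(path = fullPath, cost = totalCost)
}

# Dijkstra on an 8-connected pixel grid with node-entry costs.
# `nodeCost[r, c]` is paid when a path enters (r, c); the start node is free.
# An infinitesimal per-step cost breaks ties towards the shortest path, so a
# degenerate all-equal cost field yields the minimal 8-connected path; the
# reported cost is the pure node-cost sum along the chosen path.
dijkstraGrid <- function(nodeCost, start, goal, eps = 1e-9) {
  H <- nrow(nodeCost); W <- ncol(nodeCost)
  n <- H * W
  id <- function(r, c) (c - 1L) * H + r
  dist <- rep(Inf, n); done <- rep(FALSE, n); prev <- rep(NA_integer_, n)
  s <- id(start[1], start[2]); gl <- id(goal[1], goal[2])
  dist[s] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) stop("goal unreachable")
    if (u == gl) break
    done[u] <- TRUE
    r <- ((u - 1L) %% H) + 1L; c <- ((u - 1L) %/% H) + 1L
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1L || rr > H || cc < 1L || cc > W) next
      v <- id(rr, cc)
      if (done[v]) next
      alt <- dist[u] + nodeCost[rr, cc] + eps
      if (alt < dist[v] - 1e-15) {
        dist[v] <- alt; prev[v] <- u
      }
    }
  }
  path <- gl
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  cbindPath <- cbind(row = ((path - 1L) %% H) + 1L,
                     col = ((path - 1L) %/% H) + 1L)
  list(path = cbindPath,
       cost = sum(nodeCost[cbindPath[-1L, , drop = FALSE]]))
}

#' Propagate support points to an adjacent slice
#'
#' For each point, searches the adjacent slice within a Chebyshev radius for
#' the pixel most similar to the point's appearance in the source slice:
#' the score is \code{|d grey| + lambda * |d gradient magnitude| +
#' lambda * angle(d gradient direction)} (angle in radians; zero-magnitude
#' gradients contribute zero angle).  The original position is preferred on
#' ties; remaining ties resolve by row-major scan order.  If every candidate
#' scores identically the point is left in place with a warning.
#'
#' @param sourceImage averaged image of the slice the points live on.
#' @param adjacentImage averaged image of the neighbouring slice.
#' @param points \code{cbind(x, y)} support points.
#' @param searchRadius Chebyshev search radius, pixels (default 5).
#' @param params \linkS4class{SegmentationParams}.
#' @return Updated \code{cbind(x, y)} matrix.
#' @export
propagateSupportPoints <- function(sourceImage, adjacentImage, points,
                                   searchRadius = 5L, params = segParams()) {
  if (!all(dim(sourceImage) == dim(adjacentImage)))
    stop("slice dimensions differ")
  gS <- imageGradients(sourceImage, params@gaussianSigma)
  gA <- imageGradients(adjacentImage, params@gaussianSigma)
  lam <- params@propagationLambda
  H <- nrow(adjacentImage); W <- ncol(adjacentImage)
  out <- as.matrix(points)
  for (i in seq_len(nrow(out))) {
    x <- out[i, 1]; y <- out[i, 2]
    g0 <- sourceImage[y, x]; m0 <- gS$mag[y, x]
    d0 <- c(gS$gx[y, x], gS$gy[y, x])
    ys <- max(1L, y - searchRadius):min(H, y + searchRadius)
    xs <- max(1L, x - searchRadius):min(W, x + searchRadius)
    cand <- expand.grid(y = ys, x = xs)   # row-major scan order within radius
    score <- numeric(nrow(cand))
    for (j in seq_len(nrow(cand))) {
      yy <- cand$y[j]; xx <- cand$x[j]
      dg <- abs(adjacentImage[yy, xx] - g0)
      dm <- abs(gA$mag[yy, xx] - m0)
      dv <- c(gA$gx[yy, xx], gA$gy[yy, xx])
      ang <- 0
      if (m0 > 0 && gA$mag[yy, xx] > 0) {
        cosA <- sum(dv * d0) / (gA$mag[yy, xx] * m0)
        ang <- acos(pmin(1, pmax(-1, cosA)))
      }
      score[j] <- dg + lam * dm + lam * ang
    }
    if (diff(range(score)) < 1e-12) {
      warning("support point ", i, ": featureless neighbourhood, not moved")
      next
    }
    self <- which(cand$y == y & cand$x == x)
    if (length(self) && score[self] <= min(score) + 1e-12) next
    best <- which.min(score)
    out[i, ] <- c(cand$x[best], cand$y[best])
  }
  out
}
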