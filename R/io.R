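# NIfTI / CSV input-output.  Stacks travel as one 4-D NIfTI volume per
# session (y, x, slice, echo); echo times go in a JSON sidecar because the
# NIfTI header has no natural home for them.

#' Write an EchoStack as a 4-D NIfTI volume with a JSON sidecar
#'
#' @param stack an \linkS4class{EchoStack}.
#' @param path output path (".nii" or ".nii.gz").
#' @return The path, invisibly.
#' @export
writeEchoStack <- function(stack, path) {
  img <- RNifti::asNifti(stack@data,
    pixdim = c(stack@pixelSpacing, stack@interSliceDistance, 1))
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(echoTimes = stack@echoTimes,
                            pixelSpacing = stack@pixelSpacing,
                            sliceThickness = stack@sliceThickness,
                            interSliceDistance = stack@interSliceDistance),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read an EchoStack from a 4-D NIfTI volume
#'
#' @param path NIfTI path; echo times are taken from the JSON sidecar
#'   written by \code{\link{writeEchoStack}} unless given explicitly.
#' @param echoTimes optional echo times (ms), overriding the sidecar.
#' @return An \linkS4class{EchoStack}.
#' @export
readEchoStack <- function(path, echoTimes = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  meta <- list(pixelSpacing = c(1, 1), sliceThickness = 3,
               interSliceDistance = 3)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (file.exists(sidecar)) {
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE))
  }
  if (is.null(echoTimes)) echoTimes <- meta$echoTimes
  if (is.null(echoTimes))
    stop("echo times not found: pass echoTimes= or provide the JSON sidecar")
  new("EchoStack", data = arr, echoTimes = as.numeric(echoTimes),
      pixelSpacing = as.numeric(meta$pixelSpacing[1:2]),
      sliceThickness = meta$sliceThickness,
      interSliceDistance = meta$interSliceDistance)
}

#' Write label masks as a NIfTI volume
#' @param masks integer array \code{[y, x, slice]}.
#' @param path output path.
#' @export
writeLabelMasks <- function(masks, path) {
  RNifti::writeNifti(RNifti::asNifti(masks), path)
  invisible(path)
}

#' Read or write operator support points
#'
#' Support points travel as CSV with columns slice, disc, x, y, matching
#' the convention that an operator marks roughly eight points per disc.
#'
#' @param path CSV path.
#' @return data.frame(slice, disc, x, y).
#' @export
readSupportPoints <- function(path) {
  df <- utils::read.csv(path)
  need <- c("slice", "disc", "x", "y")
  if (!all(need %in% names(df)))
    stop("support-point file must have columns ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname readSupportPoints
#' @param points data.frame(slice, disc, x, y).
#' @export
writeSupportPoints <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Write a QC overlay PNG: second-echo image with disc mask boundaries
#'
#' @param stack an \linkS4class{EchoStack}.
#' @param masks integer mask array \code{[y, x, slice]}.
#' @param slice slice to draw.
#' @param path PNG output path.
#' @export
qcOverlayPng <- function(stack, masks, slice, path) {
  img <- stack@data[, , slice, 2L]
  m <- masks[, , slice]
  grDevices::png(path, width = ncol(img) * 4, height = nrow(img) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  # y reversed so row 1 (cephalad) sits on top
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, useRaster = TRUE)
  edge <- m != 0 &
    (rbind(m[-1, ], 0L) != m | rbind(0L, m[-nrow(m), ]) != m |
     cbind(m[, -1], 0L) != m | cbind(0L, m[, -ncol(m)]) != m)
  pts <- which(edge, arr.ind = TRUE)
  if (nrow(pts)) {
    graphics::points((pts[, 2] - 1) / (ncol(img) - 1),
                     1 - (pts[, 1] - 1) / (nrow(img) - 1),
                     pch = ".", col = "red", cex = 2)
  }
  invisible(path)
}
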