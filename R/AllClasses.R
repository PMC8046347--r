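#' @import methods
NULL

#' PhantomSpec: geometry and signal model of the synthetic spine phantom
#'
#' Describes a sagittal multi-echo spine phantom: stacked rectangular
#' vertebral bodies separated by tilted, lens-shaped intervertebral discs,
#' with thin dark endplate lines at each vertebra-disc interface.  Signal at
#' echo time TE is \code{S0 * exp(-TE / T2)} per tissue, optionally corrupted
#' by Rician or Gaussian noise.  Default intensities are calibrated so that
#' the segmentation thresholds (100-unit locate difference, 150-unit endplate
#' intensity, 80-unit anterior/posterior border difference) operate in their
#' intended regime: on the second echo discs are bright (roughly 300--340
#' units), vertebral bodies moderately bright (175 units), endplates dark
#' (100 units) and background zero.
#'
#' @slot gridHeight,gridWidth image dimensions in pixels (rows x columns);
#'   rows run cephalocaudally, columns anteroposteriorly.
#' @slot nSlices number of sagittal slices (default 6); slices share geometry
#'   and differ only in their noise realisation.
#' @slot echoTimes the echo times in ms, strictly increasing (default the 16
#'   values 10.9, 21.8, ..., 174.4).
#' @slot nDiscs number of rendered discs (default 6, labelled T12/L1 ... L5/S1).
#' @slot spineCentreX centre column of the spine.
#' @slot vertebraWidth,vertebraHeights vertebral body width and per-body
#'   heights in pixels (\code{nDiscs + 1} bodies).
#' @slot discHalfWidth per-disc lens semi-axis along the anteroposterior
#'   direction, pixels; must leave at least a 2-pixel corner margin inside the
#'   vertebral width so the border rule can fire outside the disc tip.
#' @slot discTilt per-disc tilt of the intervertebral gap, degrees.
#' @slot discHeight lens height at the disc centre, pixels (odd, <= 7 so the
#'   15-row vertical median stays dominated by non-disc tissue).
#' @slot endplateThickness endplate line thickness, pixels.
#' @slot regionT2 \code{nDiscs x 5} matrix of true subregion T2 (ms), columns
#'   anterior annulus ... posterior annulus.
#' @slot discS0,boneT2,boneS0,endplateT2,endplateS0 proton-density scalings
#'   (signal units) and T2 (ms) of the tissues.
#' @slot noiseSigma noise standard deviation, signal units.
#' @slot noiseModel one of \code{"rician"}, \code{"gaussian"}, \code{"none"}.
#' @slot pixelSpacing in-plane pixel spacing, mm.
#' @slot topMargin background rows above the first vertebra.
#' @slot seed integer RNG seed (NA = leave RNG state alone).
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    gridHeight = "integer", gridWidth = "integer", nSlices = "integer",
    echoTimes = "numeric", nDiscs = "integer", discLabels = "character",
    spineCentreX = "numeric", vertebraWidth = "numeric",
    vertebraHeights = "numeric", discHalfWidth = "numeric",
    discTilt = "numeric", discHeight = "integer",
    endplateThickness = "integer", regionT2 = "matrix",
    discS0 = "numeric", boneT2 = "numeric", boneS0 = "numeric",
    endplateT2 = "numeric", endplateS0 = "numeric",
    noiseSigma = "numeric", noiseModel = "character",
    pixelSpacing = "numeric", topMargin = "integer", seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  te <- object@echoTimes
  if (length(te) < 3L || any(te <= 0) || any(diff(te) <= 0))
    msg <- c(msg, "echoTimes must be positive and strictly increasing")
  if (any(object@regionT2 <= 0) || object@boneT2 <= 0 || object@endplateT2 <= 0)
    msg <- c(msg, "all T2 values must be > 0")
  if (nrow(object@regionT2) != object@nDiscs || ncol(object@regionT2) != 5L)
    msg <- c(msg, "regionT2 must be an nDiscs x 5 matrix")
  if (length(object@vertebraHeights) != object@nDiscs + 1L)
    msg <- c(msg, "need nDiscs + 1 vertebral body heights")
  if (length(object@discHalfWidth) != object@nDiscs ||
      length(object@discTilt) != object@nDiscs)
    msg <- c(msg, "discHalfWidth and discTilt must have one entry per disc")
  if (object@discHeight %% 2L == 0L)
    msg <- c(msg, "discHeight must be odd")
  # discs must sit inside the vertebral width with a corner margin
  if (any(2 * object@discHalfWidth + 1 > object@vertebraWidth - 4))
    msg <- c(msg, "disc width must leave a >=2 px corner margin inside the vertebral width")
  gap <- object@discHeight + 2L * object@endplateThickness
  # vertical extent: margins + bodies + gaps, plus room for the tilt excursion
  tiltDrop <- max(abs(tan(object@discTilt * pi / 180))) * object@vertebraWidth / 2
  need <- object@topMargin + sum(object@vertebraHeights) +
    object@nDiscs * gap + ceiling(tiltDrop) + 2L
  if (need > object@gridHeight)
    msg <- c(msg, sprintf("grid too small: need >= %d rows, have %d", need, object@gridHeight))
  halfW <- object@vertebraWidth / 2
  if (object@spineCentreX - halfW < 2 || object@spineCentreX + halfW > object@gridWidth - 1)
    msg <- c(msg, "spine does not fit inside the grid width")
  if (!object@noiseModel %in% c("rician", "gaussian", "none"))
    msg <- c(msg, "noiseModel must be 'rician', 'gaussian' or 'none'")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' EchoStack: one session's multi-echo image data
#'
#' A 4-D array of magnitude images, dimensions
#' \code{[row, column, slice, echo]}, with the echo times and voxel geometry
#' needed to interpret them.  Rows are cephalocaudal, columns
#' anteroposterior (sagittal convention).
#'
#' @slot data numeric 4-D array \code{[y, x, slice, echo]}.
#' @slot echoTimes echo times in ms, one per echo.
#' @slot pixelSpacing in-plane spacing, mm (row, column).
#' @slot sliceThickness,interSliceDistance slice geometry, mm.
#' @exportClass EchoStack
setClass("EchoStack",
  representation(
    data = "array", echoTimes = "numeric", pixelSpacing = "numeric",
    sliceThickness = "numeric", interSliceDistance = "numeric"
  )
)

setValidity("EchoStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be a 4-D array [y, x, slice, echo]")
  if (d[4] != length(object@echoTimes))
    return("fourth dimension must match length(echoTimes)")
  if (any(diff(object@echoTimes) <= 0))
    return("echoTimes must be strictly increasing")
  TRUE
})

#' PhantomTruth: pixel-aligned ground truth for a rendered phantom
#'
#' @slot tissueLabels integer array \code{[y, x, slice]}: 0 background,
#'   1 vertebral body, 2 endplate, 3 disc.
#' @slot discMasks integer array \code{[y, x, slice]}: 0 outside discs,
#'   otherwise the disc index (1 = most cephalad).
#' @slot regionLabels integer array \code{[y, x, slice]}: 0 or subregion
#'   1 (anterior annulus) ... 5 (posterior annulus).
#' @slot t2Map,s0Map numeric arrays \code{[y, x, slice]} of the true tissue
#'   parameters (0 in background).
#' @slot regionTable data.frame of true per-disc per-region T2 and S0.
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(
    tissueLabels = "array", discMasks = "array", regionLabels = "array",
    t2Map = "array", s0Map = "array", regionTable = "data.frame"
  )
)

#' StudySpec: layout and variance components of a longitudinal study
#'
#' Subject i, session j true T2 is \code{mu + b_i + w_ij} with
#' \code{b_i ~ N(0, betweenSD^2)} and \code{w_ij ~ N(0, withinSD^2)}, so the
#' implied true ICC is \code{betweenSD^2 / (betweenSD^2 + withinSD^2)}.
#' The default layout reproduces a 12-subject, 9-session design with
#' attrition to 8 subjects at the last two sessions.
#'
#' @slot nSubjects,nSessions design size.
#' @slot dropout integer vector, subjects present at each session
#'   (subjects drop out from the end of the roster, never return).
#' @slot betweenSD,withinSD between-subject and between-session
#'   (within-subject) SD of true T2, ms.
#' @slot seed integer RNG seed (NA = leave RNG state alone).
#' @exportClass StudySpec
setClass("StudySpec",
  representation(
    nSubjects = "integer", nSessions = "integer", dropout = "integer",
    betweenSD = "numeric", withinSD = "numeric", seed = "integer"
  )
)

setValidity("StudySpec", function(object) {
  msg <- character(0)
  if (object@nSubjects < 2L) msg <- c(msg, "need at least 2 subjects")
  if (object@nSessions < 2L) msg <- c(msg, "need at least 2 sessions")
  if (length(object@dropout) != object@nSessions)
    msg <- c(msg, "dropout must list the subject count at every session")
  if (any(object@dropout < 1L) || any(object@dropout > object@nSubjects))
    msg <- c(msg, "dropout counts must lie in [1, nSubjects]")
  if (object@betweenSD < 0 || object@withinSD < 0)
    msg <- c(msg, "variance components must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SegmentationParams: thresholds and tuning constants of the segmentation
#'
#' Defaults follow the published semi-automated procedure: a 1 x 15 vertical
#' median filter, a 100-unit original-minus-median difference for locating
#' the spine centre column, local minima below 150 units as endplate seeds,
#' contour tracking that requires at least 3 of the 8 neighbours below 150
#' units, and an 80-unit averaged-minus-median difference for the
#' anterior/posterior borders.  Constants the procedure leaves open
#' (cost weights, step neighbourhood, minimum contour length, propagation
#' radius) are explicit slots.
#'
#' @slot medianHeight vertical median window height, pixels (odd).
#' @slot diffThresholdLocate signed original-minus-median threshold, units.
#' @slot endplateIntensityThreshold endplate darkness threshold, units.
#' @slot neighborCountMin minimum dark 8-neighbours for contour tracking.
#' @slot apBorderThreshold absolute averaged-minus-median threshold, units.
#' @slot supportPointsPerDisc support points auto-placed per endplate contour.
#' @slot costWeightGradient,costWeightGrey graph-search cost weights (each
#'   term normalised to [0, 1] first).
#' @slot contourStepRows vertical freedom per column step when tracking.
#' @slot minContourLength contours shorter than this are discarded, pixels.
#' @slot maxDiscGap maximum seed-to-seed distance treated as one disc, rows.
#' @slot propagationRadius search radius when propagating support points to
#'   an adjacent slice, pixels.
#' @slot propagationLambda weight of the gradient terms in the propagation
#'   matching score.
#' @slot gaussianSigma pre-smoothing SD for gradient estimation, pixels.
#' @exportClass SegmentationParams
setClass("SegmentationParams",
  representation(
    medianHeight = "integer", diffThresholdLocate = "numeric",
    endplateIntensityThreshold = "numeric", neighborCountMin = "integer",
    apBorderThreshold = "numeric", supportPointsPerDisc = "integer",
    costWeightGradient = "numeric", costWeightGrey = "numeric",
    contourStepRows = "integer", minContourLength = "integer",
    maxDiscGap = "integer", propagationRadius = "integer",
    propagationLambda = "numeric", gaussianSigma = "numeric"
  )
)

setValidity("SegmentationParams", function(object) {
  msg <- character(0)
  if (object@medianHeight %% 2L == 0L || object@medianHeight < 3L)
    msg <- c(msg, "medianHeight must be odd and >= 3")
  for (s in c("diffThresholdLocate", "endplateIntensityThreshold",
              "apBorderThreshold"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@neighborCountMin < 1L || object@neighborCountMin > 8L)
    msg <- c(msg, "neighborCountMin must be in 1..8")
  if (object@costWeightGradient < 0 || object@costWeightGrey < 0)
    msg <- c(msg, "cost weights must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DiscSegmentation: the per-slice result of disc delineation
#'
#' @slot masks integer array \code{[y, x, slice]}: 0 outside, otherwise the
#'   disc index ordered cephalad to caudad.
#' @slot discLabels level labels for the mask indices.
#' @slot centreColumn detected spine-centre column.
#' @slot seeds per-slice list of endplate seed rows.
#' @slot contours per-slice, per-disc list of superior/inferior endplate
#'   contours (two-column x, y matrices).
#' @slot borders per-slice, per-disc list of per-row anterior/posterior
#'   border columns.
#' @slot params the \linkS4class{SegmentationParams} used.
#' @exportClass DiscSegmentation
setClass("DiscSegmentation",
  representation(
    masks = "array", discLabels = "character", centreColumn = "integer",
    seeds = "list", contours = "list", borders = "list",
    params = "SegmentationParams"
  )
)

#' SubregionPartition: five anterior-to-posterior subregions per disc
#'
#' @slot regionLabels integer array \code{[y, x, slice]}: 0 outside discs,
#'   otherwise subregion 1 (anterior annulus) ... 5 (posterior annulus).
#' @slot discMasks integer array \code{[y, x, slice]} of disc indices.
#' @slot geometry data.frame with one row per (disc, slice): centroid,
#'   fitted orientation angle (degrees) and rotated-mask width.
#' @exportClass SubregionPartition
setClass("SubregionPartition",
  representation(
    regionLabels = "array", discMasks = "array", geometry = "data.frame"
  )
)

#' RunConfig: everything needed for one end-to-end pipeline run
#'
#' @slot mode \code{"phantom"} (simulate, then analyse) or \code{"stacks"}
#'   (analyse a supplied list of \linkS4class{EchoStack} objects).
#' @slot phantom the \linkS4class{PhantomSpec} used in phantom mode.
#' @slot study the \linkS4class{StudySpec} defining the longitudinal layout.
#' @slot segParams segmentation thresholds.
#' @slot bypassSegmentation use ground-truth masks instead of running the
#'   segmentation (phantom mode only; for noiseless validation).
#' @slot refineWithGraphSearch refine tracked endplate contours by
#'   minimum-cost graph search through auto-placed support points.
#' @slot measures subset of \code{c("whole", "nuclear", "subregion")} to fit
#'   and tabulate.
#' @slot excludeMostCephalad drop the T12/L1 disc from reports (default TRUE,
#'   keeping the five lumbar levels).
#' @slot blindSessions analyse under randomised session labels and map back
#'   for reporting.
#' @slot seed master RNG seed for the run.
#' @slot outputDir optional directory for CSV/NIfTI/PNG output
#'   (length-0 character = keep everything in memory).
#' @exportClass RunConfig
setClass("RunConfig",
  representation(
    mode = "character", phantom = "PhantomSpec", study = "StudySpec",
    segParams = "SegmentationParams", bypassSegmentation = "logical",
    refineWithGraphSearch = "logical", measures = "character",
    excludeMostCephalad = "logical", blindSessions = "logical",
    seed = "integer", outputDir = "character"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("phantom", "stacks"))
    msg <- c(msg, "mode must be 'phantom' or 'stacks'")
  if (!all(object@measures %in% c("whole", "nuclear", "subregion")))
    msg <- c(msg, "measures must be a subset of whole/nuclear/subregion")
  if (length(msg)) msg else TRUE
})
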