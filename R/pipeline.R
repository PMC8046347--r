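#' Construct a pipeline run configuration
#'
#' @param mode \code{"phantom"} or \code{"stacks"}.
#' @param phantom a \linkS4class{PhantomSpec}.
#' @param study a \linkS4class{StudySpec}.
#' @param segParams a \linkS4class{SegmentationParams}.
#' @param bypassSegmentation use ground-truth masks (phantom mode only).
#' @param refineWithGraphSearch refine contours by graph search.
#' @param measures subset of \code{c("whole", "nuclear", "subregion")}.
#' @param excludeMostCephalad drop the most cephalad (T12/L1) disc from
#'   reports, keeping the five lumbar levels.
#' @param blindSessions analyse under randomised session labels.
#' @param seed master seed; NA leaves component seeds untouched.
#' @param outputDir optional output directory.
#' @return A validated \linkS4class{RunConfig}.
#' @export
runConfig <- function(mode = "phantom", phantom = phantomSpec(),
                      study = studySpec(), segParams = discT2::segParams(),
                      bypassSegmentation = FALSE,
                      refineWithGraphSearch = FALSE,
                      measures = c("whole", "nuclear", "subregion"),
                      excludeMostCephalad = TRUE, blindSessions = FALSE,
                      seed = NA_integer_, outputDir = character(0)) {
  new("RunConfig", mode = mode, phantom = phantom, study = study,
      segParams = segParams, bypassSegmentation = bypassSegmentation,
      refineWithGraphSearch = refineWithGraphSearch, measures = measures,
      excludeMostCephalad = excludeMostCephalad,
      blindSessions = blindSessions, seed = as.integer(seed),
      outputDir = outputDir)
}

#' Blind session labels with a stored key
#'
#' Assigns each session a random label (a bijection), emulating the
#' practice of giving every testing session a random number so the examiner
#' is blinded to measurement order.  Reliability statistics are invariant
#' under this relabelling; the key maps results back.
#'
#' @param sessions vector of session identifiers.
#' @param seed integer seed.
#' @return List: \code{blinded} (labels in input order) and \code{key}
#'   (data.frame session, blinded).
#' @export
randomizeSessionLabels <- function(sessions, seed = NA_integer_) {
  if (!length(sessions)) stop("need at least one session")
  perm <- withSeed(seed, sample(length(sessions)))
  key <- data.frame(session = sessions, blinded = perm)
  list(blinded = perm, key = key)
}

#' Dice overlap coefficient between two masks
#' @param a,b logical/0-1 arrays of identical shape.
#' @return \code{2|A n B| / (|A| + |B|)}.
#' @export
diceCoefficient <- function(a, b) {
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

# Fit all required regions of one session's stack.
# Returns a records data.frame: disc, slice, region, t2, s0, r2, converged,
# nPixels.  `truth` (a PhantomTruth) short-circuits the segmentation.
processStack <- function(stack, params = segParams(),
                         measures = c("whole", "nuclear", "subregion"),
                         truth = NULL, refine = FALSE, centralSlice = 3L,
                         anteriorLeft = TRUE) {
  if (!is.null(truth)) {
    masks <- truth@discMasks
    regions <- if (any(c("nuclear", "subregion") %in% measures))
      truth@regionLabels else NULL
  } else {
    seg <- segmentDiscs(stack, params, refine = refine)
    masks <- seg@masks
    regions <- if (any(c("nuclear", "subregion") %in% measures))
      regionLabels(partitionAllDiscs(masks, anteriorLeft)) else NULL
  }
  recs <- list()
  if ("whole" %in% measures) {
    mm <- regionMeanSignals(stack, masks)
    f <- fitRegionT2(mm, groupBy = c("slice", "region"))
    recs[[1L]] <- data.frame(disc = f$region, slice = f$slice,
                             region = "whole", t2 = f$t2, s0 = f$s0,
                             r2 = f$r2, converged = f$converged)
  }
  if (!is.null(regions)) {
    combo <- masks * 10L + regions
    combo[masks == 0L | regions == 0L] <- 0L
    needAll <- "subregion" %in% measures
    if (!needAll) {
      # nuclear only: subregion 3 on the central slice
      keep <- array(0L, dim(combo))
      keep[, , centralSlice] <- combo[, , centralSlice]
      keep[keep %% 10L != 3L] <- 0L
      combo <- keep
    }
    mm <- regionMeanSignals(stack, combo)
    f <- fitRegionT2(mm, groupBy = c("slice", "region"))
    recs[[length(recs) + 1L]] <- data.frame(
      disc = f$region %/% 10L, slice = f$slice,
      region = paste0("r", f$region %% 10L), t2 = f$t2, s0 = f$s0,
      r2 = f$r2, converged = f$converged)
  }
  out <- do.call(rbind, recs)
  out[order(out$disc, out$slice, out$region), ]
}

# Reshape long per-session records into subjects x sessions matrices, one
# per measure/level, plus the averaged-levels (AvLx) series.
buildSeries <- function(records, discLabels, measures, nSubjects, nSessions,
                        excludeMostCephalad = TRUE, centralSlice = 3L) {
  keepDiscs <- seq_along(discLabels)
  if (excludeMostCephalad && length(keepDiscs) > 1L)
    keepDiscs <- keepDiscs[-1L]
  asMatrix <- function(df) {
    m <- matrix(NA_real_, nSubjects, nSessions,
                dimnames = list(paste0("S", seq_len(nSubjects)),
                                paste0("sess", seq_len(nSessions))))
    t <- tapply(df$t2, list(df$subject, df$session), mean)
    m[cbind(as.integer(rownames(t)[row(t)]),
            as.integer(colnames(t)[col(t)]))] <- as.numeric(t)
    m
  }
  out <- list()
  addMeasure <- function(df, prefix) {
    perLevel <- lapply(keepDiscs, function(k) asMatrix(df[df$disc == k, ]))
    names(perLevel) <- paste(prefix, discLabels[keepDiscs])
    for (nm in names(perLevel)) out[[nm]] <<- perLevel[[nm]]
    avg <- Reduce(`+`, perLevel) / length(perLevel)
    out[[paste(prefix, "AvLx")]] <<- avg
  }
  if ("whole" %in% measures)
    addMeasure(records[records$region == "whole", ], "whole")
  if ("nuclear" %in% measures)
    addMeasure(records[records$region == "r3" &
                         records$slice == centralSlice, ], "nuclear")
  if ("subregion" %in% measures) {
    for (r in 1:5)
      addMeasure(records[records$region == paste0("r", r), ],
                 paste0("subregion", r))
  }
  out
}

#' Run the full phantom-to-reliability pipeline
#'
#' Simulates (or accepts) a longitudinal multi-session dataset, segments
#' every stack (or injects ground-truth masks), partitions discs into
#' subregions, fits T2, assembles subjects x sessions measurement series
#' per level plus the averaged-levels series, and computes the complete
#' reliability suite: the reliability table, Bland-Altman comparisons of
#' every follow-up against baseline with FDR-adjusted linear-bias tests,
#' and the whole/nuclear between-session correlation table.  Deterministic
#' given the seeds.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param stacks list of \linkS4class{EchoStack} plus a \code{meta}
#'   data.frame (subject, session) when \code{mode = "stacks"}.
#' @param meta companion metadata for \code{stacks} mode.
#' @param unitGrades optional per-unit degeneration grades for stratified
#'   rows; named by "subject:level" or a vector over the unit rows
#'   (subject-major) of the whole-disc unit series.
#' @return List: \code{records}, \code{series}, \code{table},
#'   \code{blandAltman}, \code{correlations}, \code{truth}, \code{meta},
#'   \code{manifest}, \code{sessionKey} (when blinded).
#' @export
runPipeline <- function(config, stacks = NULL, meta = NULL,
                        unitGrades = NULL) {
  validObject(config)
  t0 <- Sys.time()
  study <- config@study
  phantom <- config@phantom
  if (!is.na(config@seed)) {
    study@seed <- config@seed
  }
  truthTable <- NULL; geomTruth <- NULL
  if (config@mode == "phantom") {
    message("[simulate] rendering ", sum(study@dropout), " session stacks")
    ds <- generateLongitudinalDataset(study, phantom)
    stacks <- ds$stacks; meta <- ds$meta
    truthTable <- ds$truth; geomTruth <- ds$geometryTruth
  } else {
    if (is.null(stacks) || is.null(meta))
      stop("stacks mode needs stacks= and meta=")
  }
  sessionKey <- NULL
  if (config@blindSessions) {
    rl <- randomizeSessionLabels(sort(unique(meta$session)),
                                 if (is.na(config@seed)) NA_integer_ else
                                   config@seed + 1717L)
    sessionKey <- rl$key
    meta$analysisSession <- rl$blinded[match(meta$session,
                                             rl$key$session)]
  } else {
    meta$analysisSession <- meta$session
  }
  message("[segment+fit] processing ", length(stacks), " stacks")
  recs <- vector("list", length(stacks))
  for (r in seq_along(stacks)) {
    rec <- processStack(stacks[[r]], config@segParams, config@measures,
                        truth = if (config@bypassSegmentation) geomTruth,
                        refine = config@refineWithGraphSearch)
    rec$subject <- meta$subject[r]
    rec$session <- meta$analysisSession[r]
    recs[[r]] <- rec
  }
  records <- do.call(rbind, recs)
  # map blinded labels back for reporting
  if (config@blindSessions) {
    records$session <- sessionKey$session[match(records$session,
                                                sessionKey$blinded)]
  }
  discLabels <- if (config@mode == "phantom") phantom@discLabels else
    paste0("disc", sort(unique(records$disc)))
  message("[reliability] assembling series and tables")
  series <- buildSeries(records, discLabels, config@measures,
                        study@nSubjects, study@nSessions,
                        config@excludeMostCephalad)
  unitSeries <- NULL
  if (!is.null(unitGrades) && "whole" %in% measuresOf(config)) {
    unitSeries <- unitSeriesFromRecords(records, discLabels,
                                        study@nSubjects, study@nSessions,
                                        config@excludeMostCephalad)
    if (length(unitGrades) != nrow(unitSeries))
      stop("unitGrades must have one entry per subject-level unit (",
           nrow(unitSeries), ")")
  }
  tab <- reliabilityTable(series, unitSeries = unitSeries,
                          unitGrades = unitGrades)
  primary <- grep("^(whole|nuclear) ", names(series), value = TRUE)
  ba <- lapply(series[primary], blandAltman)
  corr <- NULL
  if (all(c("whole AvLx", "nuclear AvLx") %in% names(series))) {
    corr <- sessionCorrelationTable(series[["whole AvLx"]],
                                    series[["nuclear AvLx"]])
  }
  manifest <- list(
    package = "discT2",
    version = as.character(utils::packageVersion("discT2")),
    rVersion = R.version.string,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = config@seed, mode = config@mode,
    measures = config@measures,
    nStacks = length(stacks),
    configHash = hashObject(config))
  out <- list(records = records, series = series, table = tab,
              blandAltman = ba, correlations = corr, truth = truthTable,
              meta = meta, manifest = manifest, sessionKey = sessionKey)
  if (length(config@outputDir)) writeRunOutputs(out, config, stacks)
  out
}

measuresOf <- function(config) config@measures

# units = subject x level rows (subject-major), whole-disc T2 per session
unitSeriesFromRecords <- function(records, discLabels, nSubjects, nSessions,
                                  excludeMostCephalad = TRUE) {
  keep <- seq_along(discLabels)
  if (excludeMostCephalad && length(keep) > 1L) keep <- keep[-1L]
  w <- records[records$region == "whole" & records$disc %in% keep, ]
  units <- expand.grid(level = keep, subject = seq_len(nSubjects))
  m <- matrix(NA_real_, nrow(units), nSessions,
              dimnames = list(paste0("S", units$subject, ":",
                                     discLabels[units$level]), NULL))
  agg <- stats::aggregate(t2 ~ subject + session + disc, w, mean)
  rowIdx <- match(paste0("S", agg$subject, ":", discLabels[agg$disc]),
                  rownames(m))
  m[cbind(rowIdx, agg$session)] <- agg$t2
  m
}

hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

# Serialise a completed run into CSV / NIfTI / PNG files.
writeRunOutputs <- function(run, config, stacks) {
  dir <- config@outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$records, file.path(dir, "region_t2_records.csv"),
                   row.names = FALSE)
  utils::write.csv(run$table, file.path(dir, "reliability_table.csv"),
                   row.names = FALSE)
  baRows <- do.call(rbind, lapply(names(run$blandAltman), function(nm)
    cbind(measure = nm, run$blandAltman[[nm]]$results)))
  utils::write.csv(baRows, file.path(dir, "bland_altman.csv"),
                   row.names = FALSE)
  if (!is.null(run$correlations))
    utils::write.csv(run$correlations,
                     file.path(dir, "session_correlations.csv"))
  if (!is.null(run$truth))
    utils::write.csv(run$truth, file.path(dir, "truth_table.csv"),
                     row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  # QC overlay of the first stack's central slice
  if (length(stacks)) {
    st <- stacks[[1]]
    seg <- tryCatch(segmentDiscs(st, config@segParams), error = function(e) NULL)
    if (!is.null(seg)) {
      qcOverlayPng(st, seg@masks, min(3L, dim(st@data)[3]),
                   file.path(dir, "qc_overlay.png"))
    }
  }
  invisible(dir)
}
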