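#' Fit a mono-exponential T2 decay
#'
#' Least-squares fit of \code{S(TE) = S0 * exp(-TE / T2)} to a measured
#' multi-echo decay.  Starting values come from a log-linear regression on
#' the positive signals; the nonlinear refinement uses
#' Levenberg-Marquardt least squares with T2 bounded to [1, 2000] ms for
#' physical plausibility.  If the refinement fails to converge the
#' log-linear estimate is returned with \code{converged = FALSE}.
#'
#' @param echoTimes strictly increasing echo times (ms).
#' @param signals measured signal at each echo.
#' @param excludeFirstEcho drop the first echo before fitting (off by
#'   default; all echoes enter the fit).
#' @param offset include an additive noise-floor constant in the model
#'   (off by default; the reference model is pure mono-exponential).
#' @param t2Bounds lower/upper T2 bounds, ms.
#' @return An object of class \code{DecayFit}: list with \code{S0},
#'   \code{T2} (ms), \code{offset}, \code{residualRMS}, \code{r2},
#'   \code{converged}, \code{n}.
#' @examples
#' te <- 10.9 * (1:16)
#' f <- fitMonoexponential(te, 1000 * exp(-te / 100))
#' c(f$S0, f$T2)
#' @export
fitMonoexponential <- function(echoTimes, signals, excludeFirstEcho = FALSE,
                               offset = FALSE, t2Bounds = c(1, 2000)) {
  if (length(echoTimes) != length(signals))
    stop("echoTimes and signals must have equal length")
  if (any(diff(echoTimes) <= 0)) stop("echoTimes must be strictly increasing")
  if (excludeFirstEcho) {
    echoTimes <- echoTimes[-1]; signals <- signals[-1]
  }
  pos <- signals > 0
  if (sum(pos) < 3L) stop("need at least 3 positive signal values")
  # log-linear initialisation
  ll <- stats::lm.fit(cbind(1, echoTimes[pos]), log(signals[pos]))
  slope <- ll$coefficients[2]
  t2Init <- if (slope < 0) min(max(-1 / slope, t2Bounds[1]), t2Bounds[2]) else
    t2Bounds[2]
  s0Init <- exp(ll$coefficients[1])
  llFit <- list(S0 = unname(s0Init), T2 = unname(t2Init), offset = 0)
  df <- data.frame(te = echoTimes, s = signals)
  fit <- tryCatch({
    if (offset) {
      minpack.lm::nlsLM(s ~ S0 * exp(-te / T2) + C, data = df,
        start = list(S0 = llFit$S0, T2 = llFit$T2, C = 0),
        lower = c(1e-12, t2Bounds[1], -Inf),
        upper = c(Inf, t2Bounds[2], Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(s ~ S0 * exp(-te / T2), data = df,
        start = list(S0 = llFit$S0, T2 = llFit$T2),
        lower = c(1e-12, t2Bounds[1]), upper = c(Inf, t2Bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    pred <- llFit$S0 * exp(-echoTimes / llFit$T2)
    res <- signals - pred
    out <- c(llFit, list(
      residualRMS = sqrt(mean(res^2)),
      r2 = 1 - sum(res^2) / sum((signals - mean(signals))^2),
      converged = FALSE, n = length(signals)))
    class(out) <- "DecayFit"
    return(out)
  }
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  out <- list(S0 = unname(cf["S0"]), T2 = unname(cf["T2"]),
              offset = if (offset) unname(cf["C"]) else 0,
              residualRMS = sqrt(mean(res^2)),
              r2 = 1 - sum(res^2) / sum((signals - mean(signals))^2),
              converged = TRUE, n = length(signals))
  class(out) <- "DecayFit"
  out
}

#' @export
print.DecayFit <- function(x, ...) {
  cat(sprintf("DecayFit: S0 = %.4g, T2 = %.4g ms (RMS %.3g, R2 %.4f%s)\n",
              x$S0, x$T2, x$residualRMS, x$r2,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Fit T2 for every region-mean decay in a table
#'
#' @param means long data.frame with columns \code{echoTime},
#'   \code{meanSignal} and any grouping columns (e.g. disc, slice, region).
#' @param groupBy names of the grouping columns.
#' @param ... passed to \code{\link{fitMonoexponential}}.
#' @return data.frame: one row per group with T2, S0, r2, converged.
#' @export
fitRegionT2 <- function(means, groupBy = c("disc", "slice", "region"), ...) {
  key <- interaction(means[groupBy], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(means)), key), function(i) {
    g <- means[i, , drop = FALSE]
    g <- g[order(g$echoTime), ]
    f <- fitMonoexponential(g$echoTime, g$meanSignal, ...)
    cbind(g[1, groupBy, drop = FALSE],
          data.frame(t2 = f$T2, s0 = f$S0, r2 = f$r2,
                     converged = f$converged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-disc T2: unweighted mean of the whole-disc fit across slices
#'
#' @param records data.frame with columns \code{disc}, \code{slice},
#'   \code{region}, \code{t2}; the whole-disc region is labelled
#'   \code{"whole"}.
#' @return data.frame disc, t2 (ms).
#' @export
wholeDiscT2 <- function(records) {
  r <- records[records$region == "whole", ]
  if (!nrow(r)) stop("no whole-disc fits in records")
  out <- aggregate(t2 ~ disc, r, mean)
  out[order(out$disc), ]
}

#' Nuclear T2: the central subregion on the central slice
#'
#' Returns, per disc, exactly the T2 of subregion 3 on the central
#' anatomical slice (slice 3 of 6 by default): the geometric nucleus.
#'
#' @param records as in \code{\link{wholeDiscT2}}, regions \code{"r1"} ...
#'   \code{"r5"}.
#' @param centralSlice the central slice index (default 3).
#' @return data.frame disc, t2 (ms).
#' @export
nuclearT2 <- function(records, centralSlice = 3L) {
  r <- records[records$region == "r3" & records$slice == centralSlice, ]
  if (!nrow(r)) stop("no central-slice subregion-3 fit available")
  r <- r[order(r$disc), c("disc", "t2")]
  rownames(r) <- NULL
  r
}

#' Subregion T2 averaged across slices
#'
#' Per disc and subregion, the unweighted mean of that subregion's T2 over
#' all slices.
#'
#' @param records as in \code{\link{nuclearT2}}.
#' @return data.frame disc, region, t2.
#' @export
subregionT2Averaged <- function(records) {
  r <- records[records$region %in% paste0("r", 1:5), ]
  if (!nrow(r)) stop("no subregion fits in records")
  out <- aggregate(t2 ~ disc + region, r, mean)
  out[order(out$disc, out$region), ]
}
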