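# Widefield fluorescence (%dF/F) quantification pipeline:
# trial QC -> averaging -> spatial smoothing -> %dF/F normalization ->
# response-window detection -> half-maximum map segmentation -> intensity,
# temporal-phase, and surround metrics.

#' Reject trials that deviate from the mean response profile
#'
#' Computes the spatial mean gray value of every frame of every trial, then
#' the across-trial mean profile `m(t)`, and rejects trial `i` iff
#' `max_t |a_i(t) - m(t)| / m(t) >= deviationFrac`. The comparison profile is
#' computed once from all input trials (single pass; it is not recomputed
#' after rejection).
#'
#' @param trials list of [TrialStack-class] with identical geometry (>= 2).
#' @param deviationFrac rejection boundary as a fraction (default 0.10; the
#'   rule is "greater than or equal").
#' @return list with `kept`, `rejected` (lists of trials), `keptIdx`,
#'   `rejectedIdx`, and `deviations` (per-trial maximum relative deviation).
#' @export
rejectArtifactTrials <- function(trials, deviationFrac = 0.10) {
  stopifnot(length(trials) >= 2)
  dims <- lapply(trials, function(tr) dim(tr@frames))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("trials have mismatched shapes")
  npix <- prod(dims[[1]][1:2])
  a <- vapply(trials,
              function(tr) colMeans(matrix(tr@frames, npix)),
              numeric(dims[[1]][3]))              # [frame, trial]
  m <- rowMeans(a)
  if (any(m == 0)) stop("degenerate stack: mean gray value is zero")
  deviations <- apply(abs(a - m) / m, 2, max)
  rej <- deviations >= deviationFrac
  list(kept = trials[!rej], rejected = trials[rej],
       keptIdx = which(!rej), rejectedIdx = which(rej),
       deviations = deviations)
}

#' Average trials into a mean time series
#'
#' Pixel-wise, frame-wise arithmetic mean of the kept trials.
#'
#' @param kept non-empty list of [TrialStack-class].
#' @return a [TrialStack-class] holding the mean series.
#' @export
averageTrials <- function(kept) {
  if (length(kept) == 0) stop("no trials to average")
  acc <- kept[[1]]@frames
  for (i in seq_along(kept)[-1]) acc <- acc + kept[[i]]@frames
  new("TrialStack", frames = acc / length(kept), trialId = "mean")
}

#' Normalize a mean series to percent dF/F
#'
#' The baseline image is the pixel-wise mean of the pre-stimulus frames
#' (`1 .. stimOnsetFrame - 1`); every frame is converted to
#' `(F - baseline) / baseline * 100`.
#'
#' @param meanStack a [TrialStack-class] (typically the trial average, after
#'   smoothing).
#' @param config the session's [SessionConfig-class].
#' @return a [DFFSeries-class].
#' @export
computeDFF <- function(meanStack, config) {
  stopifnot(is(meanStack, "TrialStack"), is(config, "SessionConfig"))
  f <- meanStack@frames
  if (dim(f)[3] != config@nFrames)
    stop("frame count does not match the session config")
  pre <- seq_len(config@stimOnsetFrame - 1L)
  baseline <- rowMeans(f[, , pre, drop = FALSE], dims = 2)
  nBad <- sum(baseline <= 0)
  if (nBad > 0)
    stop(sprintf("baseline not strictly positive at %d pixel(s)", nBad))
  dff <- array(0, dim(f))
  for (t in seq_len(dim(f)[3]))
    dff[, , t] <- (f[, , t] - baseline) / baseline * 100
  new("DFFSeries", frames = dff, baselineImage = baseline, config = config)
}

#' Detect the evoked response window of a session trace
#'
#' The peak is the argmax of the trace over the post-stimulus frames
#' (earliest on ties). The onset is the earliest frame between stimulus onset
#' and the peak whose value exceeds `mu_b + kSd * sigma_b` (baseline mean and
#' SD from the pre-stimulus frames; if `sigma_b == 0` an absolute floor of
#' `floorPct` is used) and that is non-decreasing into the next frame; if no
#' frame crosses, the peak frame is used. The offset is the first frame after
#' the peak at which the trace is <= 0; if the trace never returns to zero
#' the last frame is used and the window is flagged censored. A trace whose
#' post-stimulus maximum is not positive yields a no-response window.
#'
#' @param trace numeric vector of length `config@nFrames` (ROI-mean percent
#'   dF/F per frame).
#' @param config the session's [SessionConfig-class].
#' @param kSd baseline-SD multiplier for the onset threshold (default 2).
#' @param floorPct absolute onset floor in percent when the baseline SD is
#'   zero (default 0.1).
#' @return a [ResponseWindow-class].
#' @export
detectResponseWindow <- function(trace, config, kSd = 2.0, floorPct = 0.1) {
  stopifnot(length(trace) == config@nFrames)
  stim <- config@stimOnsetFrame
  post <- stim:config@nFrames
  peak <- post[which.max(trace[post])]
  if (trace[peak] <= 0)
    return(new("ResponseWindow", onsetFrame = NA_integer_,
               peakFrame = NA_integer_, offsetFrame = NA_integer_,
               censored = FALSE, noResponse = TRUE))
  pre <- trace[seq_len(stim - 1L)]
  muB <- mean(pre)
  sdB <- if (length(pre) > 1) stats::sd(pre) else 0
  thr <- if (sdB == 0) muB + floorPct else muB + kSd * sdB
  onset <- peak
  for (k in stim:peak) {
    rising <- k == peak || trace[k + 1L] >= trace[k]
    if (trace[k] > thr && rising) { onset <- k; break }
  }
  censored <- FALSE
  after <- if (peak < config@nFrames) (peak + 1L):config@nFrames else integer()
  zc <- after[trace[after] <= 0]
  if (length(zc)) {
    offset <- zc[1]
  } else {
    offset <- config@nFrames
    censored <- TRUE
  }
  new("ResponseWindow", onsetFrame = as.integer(onset),
      peakFrame = as.integer(peak), offsetFrame = as.integer(offset),
      censored = censored, noResponse = FALSE)
}

#' Segment the cortical map at half the maximal response
#'
#' Projects the percent dF/F frames of the response window to their pixel-wise
#' mean `M`, thresholds at half of `max(M)` (strictly greater), and returns
#' the 8-connected component containing the global maximum. The threshold is
#' relative, so the map is invariant under positive rescaling of `M`.
#'
#' @param dff a [DFFSeries-class].
#' @param window a valid [ResponseWindow-class].
#' @return list with `mask` (logical matrix), `areaPx`, `areaUm2` (`NA`
#'   without a pixel size), `projection` (`M`), and `threshold`.
#' @export
segmentMap <- function(dff, window) {
  stopifnot(is(dff, "DFFSeries"), is(window, "ResponseWindow"))
  if (window@noResponse) stop("no positive response: cannot segment a map")
  idx <- window@onsetFrame:window@offsetFrame
  M <- rowMeans(dff@frames[, , idx, drop = FALSE], dims = 2)
  mx <- max(M)
  if (mx <= 0) stop("no positive response in the projected window")
  theta <- 0.5 * mx
  candidate <- M > theta
  amax <- which(M == mx, arr.ind = TRUE)[1, ]
  mask <- floodFill(candidate, amax, connectivity = 8)
  areaPx <- sum(mask)
  px <- dff@config@pixelSizeUm
  list(mask = mask, areaPx = areaPx,
       areaUm2 = if (is.na(px)) NA_real_ else areaPx * px^2,
       projection = M, threshold = theta)
}

roiMeanTrace <- function(dff, mask) {
  m <- matrix(dff@frames, prod(dim(dff@frames)[1:2]))
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Measure intensity and temporal metrics over the map ROI
#'
#' Plots (conceptually) the map-ROI mean percent dF/F against time and
#' measures the peak intensity and the phase durations on that same trace:
#' the response window is re-derived from the ROI trace with
#' [detectResponseWindow()], so the windowing trace and the intensity trace
#' are the same object.
#'
#' @param dff a [DFFSeries-class].
#' @param mask logical map mask (non-empty).
#' @param config the session's [SessionConfig-class].
#' @param kSd,floorPct forwarded to [detectResponseWindow()].
#' @return list with `trace`, `window` (the re-derived
#'   [ResponseWindow-class]), `peakIntensityPct`, and the durations
#'   `onsetTimeS`, `timeToPeakS`, `attackS`, `decayS`, `totalDurationS`
#'   (seconds; `attackS + decayS == totalDurationS`).
#' @export
measureMapMetrics <- function(dff, mask, config = dff@config, kSd = 2.0,
                              floorPct = 0.1) {
  if (!any(mask)) stop("empty map mask")
  trace <- roiMeanTrace(dff, mask)
  w <- detectResponseWindow(trace, config, kSd = kSd, floorPct = floorPct)
  if (w@noResponse) {
    return(list(trace = trace, window = w, peakIntensityPct = NA_real_,
                onsetTimeS = NA_real_, timeToPeakS = NA_real_,
                attackS = NA_real_, decayS = NA_real_,
                totalDurationS = NA_real_))
  }
  rate <- config@frameRateHz
  list(trace = trace, window = w,
       peakIntensityPct = trace[w@peakFrame],
       onsetTimeS = (w@onsetFrame - config@stimOnsetFrame) / rate,
       timeToPeakS = (w@peakFrame - config@stimOnsetFrame) / rate,
       attackS = (w@peakFrame - w@onsetFrame) / rate,
       decayS = (w@offsetFrame - w@peakFrame) / rate,
       totalDurationS = (w@offsetFrame - w@onsetFrame) / rate)
}

#' Measure the surround (negative) signal adjacent to the map
#'
#' The surround ROI is the morphological dilation of the map mask by a disk
#' of `ringWidthPx`, minus the map itself — an automated stand-in for the
#' manually drawn surround ROI. The reported value is the minimum of the
#' surround ROI-mean trace over the frames from stimulus onset to the window
#' offset, clipped at zero from above (a surround that never goes negative
#' reports 0).
#'
#' @param dff a [DFFSeries-class].
#' @param mask logical map mask.
#' @param window the session's [ResponseWindow-class].
#' @param ringWidthPx dilation radius in pixels (>= 1; default 10).
#' @return `surroundMinPct` (a single number <= 0).
#' @export
measureSurround <- function(dff, mask, window, ringWidthPx = 10) {
  stopifnot(ringWidthPx >= 1)
  surround <- diskDilate(mask, ringWidthPx) & !mask
  if (!any(surround)) stop("surround ROI empty: map fills the image")
  trace <- roiMeanTrace(dff, surround)
  idx <- dff@config@stimOnsetFrame:window@offsetFrame
  min(min(trace[idx]), 0)
}

#' Run the full FAI quantification for one session / limb
#'
#' Composes the pipeline in acquisition order: artifact-trial rejection,
#' trial averaging, spatial Gaussian smoothing, percent dF/F normalization
#' against the pre-stimulus baseline, response-window detection on the
#' global-mean trace, half-maximum map segmentation, map-ROI intensity and
#' temporal metrics, and the surround minimum.
#'
#' @param trials list of [TrialStack-class] (one session/limb).
#' @param config the session's [SessionConfig-class].
#' @param deviationFrac trial-rejection boundary (default 0.10).
#' @param smoothRadiusPx Gaussian SD in pixels (default 1.0).
#' @param kSd,floorPct onset-rule parameters.
#' @param ringWidthPx surround-ring width (default 10).
#' @return list with `metrics` (a [FAIMetrics-class]), `dff`, `window`,
#'   `map` (the [segmentMap()] result or `NULL`), and `rejection`.
#' @export
runFAISession <- function(trials, config, deviationFrac = 0.10,
                          smoothRadiusPx = 1.0, kSd = 2.0, floorPct = 0.1,
                          ringWidthPx = 10) {
  rejection <- if (length(trials) >= 2) {
    rejectArtifactTrials(trials, deviationFrac)
  } else {
    list(kept = trials, rejected = list(), keptIdx = seq_along(trials),
         rejectedIdx = integer(), deviations = rep(0, length(trials)))
  }
  if (length(rejection$kept) == 0)
    stop("stage reject_artifact_trials: all trials rejected")
  meanStack <- averageTrials(rejection$kept)
  smoothed <- gaussianSmooth(meanStack, smoothRadiusPx)
  dff <- computeDFF(smoothed, config)

  # initial window from the global-mean trace
  globalTrace <- colMeans(matrix(dff@frames, prod(dim(dff@frames)[1:2])))
  window <- detectResponseWindow(globalTrace, config, kSd, floorPct)
  nk <- length(rejection$kept); nr <- length(rejection$rejected)

  noResp <- new("FAIMetrics",
    peakIntensityPct = NA_real_, mapAreaPx = NA_real_, mapAreaUm2 = NA_real_,
    onsetTimeS = NA_real_, timeToPeakS = NA_real_, attackS = NA_real_,
    decayS = NA_real_, totalDurationS = NA_real_, surroundMinPct = NA_real_,
    nTrialsKept = as.integer(nk), nTrialsRejected = as.integer(nr),
    censored = FALSE, noResponse = TRUE)
  if (window@noResponse)
    return(list(metrics = noResp, dff = dff, window = window, map = NULL,
                rejection = rejection))

  map <- tryCatch(segmentMap(dff, window),
                  error = function(e)
                    stop("stage segment_map: ", conditionMessage(e)))
  mm <- measureMapMetrics(dff, map$mask, config, kSd, floorPct)
  if (mm$window@noResponse)
    return(list(metrics = noResp, dff = dff, window = window, map = map,
                rejection = rejection))
  surround <- measureSurround(dff, map$mask, mm$window, ringWidthPx)

  metrics <- new("FAIMetrics",
    peakIntensityPct = mm$peakIntensityPct,
    mapAreaPx = as.numeric(map$areaPx), mapAreaUm2 = map$areaUm2,
    onsetTimeS = mm$onsetTimeS, timeToPeakS = mm$timeToPeakS,
    attackS = mm$attackS, decayS = mm$decayS,
    totalDurationS = mm$totalDurationS, surroundMinPct = surround,
    nTrialsKept = as.integer(nk), nTrialsRejected = as.integer(nr),
    censored = mm$window@censored, noResponse = FALSE)
  list(metrics = metrics, dff = dff, window = mm$window, map = map,
       rejection = rejection)
}
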