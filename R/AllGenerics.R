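#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return `frames()` the `[row, col, frame]` array; `nFrames()` the frame
#'   count; `frameTimes()` frame times in seconds (frame 1 at t = 0);
#'   `baselineImage()` the pre-stimulus mean image; `coreArea()` the soma
#'   cross-sectional pixel count; `controlImage()` the watershed-closed
#'   control image; `combinedThreshold()` the combined (two-paw mean)
#'   withdrawal threshold in grams.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("baselineImage", function(x) standardGeneric("baselineImage"))

#' @rdname accessors
#' @export
setGeneric("coreArea", function(x) standardGeneric("coreArea"))

#' @rdname accessors
#' @export
setGeneric("controlImage", function(x) standardGeneric("controlImage"))

#' @rdname accessors
#' @export
setGeneric("combinedThreshold",
           function(x) standardGeneric("combinedThreshold"))

#' @rdname accessors
#' @export
setMethod("frames", "TrialStack", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("frames", "DFFSeries", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "TrialStack", function(x) dim(x@frames)[3])

#' @rdname accessors
#' @export
setMethod("nFrames", "DFFSeries", function(x) dim(x@frames)[3])

#' @rdname accessors
#' @export
setMethod("nFrames", "SessionConfig", function(x) as.integer(x@nFrames))

#' @rdname accessors
#' @export
setMethod("frameTimes", "SessionConfig", function(x)
  (seq_len(x@nFrames) - 1) / x@frameRateHz)

#' @rdname accessors
#' @export
setMethod("baselineImage", "DFFSeries", function(x) x@baselineImage)

#' @rdname accessors
#' @export
setMethod("coreArea", "ShadowROI", function(x) x@coreAreaPx)

#' @rdname accessors
#' @export
setMethod("controlImage", "CompressedStack", function(x) x@controlImage)

#' @rdname accessors
#' @export
setMethod("combinedThreshold", "VonFreySession", function(x) x@combinedG)

setMethod("show", "SessionConfig", function(object) {
  cat(sprintf(
    "SessionConfig: %d frames @ %g Hz, stimulus at frame %d (%.2f s), %g s stimulus\n",
    object@nFrames, object@frameRateHz, object@stimOnsetFrame,
    (object@stimOnsetFrame - 1) / object@frameRateHz, object@stimDurationS))
})

setMethod("show", "TrialStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TrialStack '%s': %d x %d px, %d frames, range [%g, %g]\n",
              object@trialId, d[1], d[2], d[3],
              min(object@frames), max(object@frames)))
})

setMethod("show", "DFFSeries", function(object) {
  d <- dim(object@frames)
  cat(sprintf("DFFSeries: %d x %d px, %d frames (%%dF/F), peak %.3f%%\n",
              d[1], d[2], d[3], max(object@frames)))
})

setMethod("show", "ResponseWindow", function(object) {
  if (object@noResponse) {
    cat("ResponseWindow: no positive evoked response\n")
  } else {
    cat(sprintf("ResponseWindow: onset %d, peak %d, offset %d%s\n",
                object@onsetFrame, object@peakFrame, object@offsetFrame,
                if (object@censored) " (censored at last frame)" else ""))
  }
})

setMethod("show", "FAIMetrics", function(object) {
  cat("FAIMetrics\n")
  if (object@noResponse) {
    cat("  no positive evoked response\n")
  } else {
    cat(sprintf("  peak intensity: %.3f %%dF/F over %g px map\n",
                object@peakIntensityPct, object@mapAreaPx))
    cat(sprintf("  onset %.2f s, time-to-peak %.2f s, attack %.2f s, decay %.2f s, total %.2f s%s\n",
                object@onsetTimeS, object@timeToPeakS, object@attackS,
                object@decayS, object@totalDurationS,
                if (object@censored) " (censored)" else ""))
    cat(sprintf("  surround minimum: %.3f %%dF/F\n", object@surroundMinPct))
  }
  cat(sprintf("  trials kept/rejected: %d/%d\n",
              object@nTrialsKept, object@nTrialsRejected))
})

setMethod("show", "CompressedStack", function(object) {
  d <- dim(object@slices)
  cat(sprintf("CompressedStack: %d x %d px, %d quantification slices + control image\n",
              d[1], d[2], d[3]))
})

setMethod("show", "ShadowROI", function(object) {
  cat(sprintf("ShadowROI at (%d, %d): core %d px, dilated %d px%s\n",
              object@seedXY[1], object@seedXY[2], object@coreAreaPx,
              sum(object@dilatedMask),
              if (object@flagged) paste0(" [flagged: ", object@flagReason, "]")
              else ""))
})

setMethod("show", "PerisomaticResult", function(object) {
  cat(sprintf(
    "PerisomaticResult: density %.4f (core %d px, %d slices, %d stained px)\n",
    object@normalizedDensity, object@coreAreaPx, object@nSlices,
    sum(object@stainedPxPerSlice)))
})

setMethod("show", "VonFreySession", function(object) {
  cat(sprintf("VonFreySession: %d filaments (%g-%g g), thresholds L %.2f g / R %.2f g, combined %.2f g\n",
              length(object@ladderG), min(object@ladderG), max(object@ladderG),
              object@thresholdsG[1], object@thresholdsG[2], object@combinedG))
})

#' Convert session metrics to a one-row data frame
#'
#' @param x a `FAIMetrics` object.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a one-row `data.frame` with the documented metrics columns.
#' @export
as.data.frame.FAIMetrics <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(
    peak_intensity_pct = x@peakIntensityPct,
    map_area_px = x@mapAreaPx,
    map_area_um2 = x@mapAreaUm2,
    onset_time_s = x@onsetTimeS,
    time_to_peak_s = x@timeToPeakS,
    attack_s = x@attackS,
    decay_s = x@decayS,
    total_duration_s = x@totalDurationS,
    surround_min_pct = x@surroundMinPct,
    n_trials_kept = x@nTrialsKept,
    n_trials_rejected = x@nTrialsRejected,
    censored = x@censored,
    no_response = x@noResponse)
}
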