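#' @import methods
NULL

# All pixel and frame indices in this package are 1-based (R convention).
# Times are seconds; intensities are raw camera counts until dF/F
# normalization, after which they are percent (%dF/F).

#' Acquisition geometry and stimulus timing of one imaging session
#'
#' Describes a widefield fluorescence imaging session: frame rate, number of
#' frames per trial, the index of the first post-stimulus frame, the stimulus
#' duration, and (optionally) the physical pixel size. Frames
#' `1 .. stimOnsetFrame - 1` are the pre-stimulus baseline.
#'
#' @slot frameRateHz frames per second (> 0).
#' @slot nFrames frames per trial (>= 4).
#' @slot stimOnsetFrame 1-based index of the first post-stimulus frame;
#'   must leave at least one baseline frame and be strictly inside the series.
#' @slot stimDurationS stimulus duration in seconds.
#' @slot pixelSizeUm physical pixel edge in micrometres, or `NA` if unknown.
#'
#' @examples
#' cfg <- SessionConfig(frameRateHz = 5, nFrames = 31, stimOnsetFrame = 6)
#' frameTimes(cfg)[1:5]
#' @export
setClass("SessionConfig",
  representation(
    frameRateHz = "numeric",
    nFrames = "integer",
    stimOnsetFrame = "integer",
    stimDurationS = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (length(object@frameRateHz) != 1 || !is.finite(object@frameRateHz) ||
      object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be a single positive number")
  if (length(object@nFrames) != 1 || object@nFrames < 4L)
    msg <- c(msg, "nFrames must be >= 4")
  if (length(object@stimOnsetFrame) != 1 ||
      object@stimOnsetFrame < 2L || object@stimOnsetFrame >= object@nFrames)
    msg <- c(msg, paste(
      "stimOnsetFrame must leave >= 1 baseline frame",
      "and be strictly inside the series"))
  if (length(object@stimDurationS) != 1 || object@stimDurationS < 0)
    msg <- c(msg, "stimDurationS must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SessionConfig-class
#' @param frameRateHz frames per second.
#' @param nFrames frames per trial.
#' @param stimOnsetFrame 1-based index of the first post-stimulus frame.
#' @param stimDurationS stimulus duration (seconds).
#' @param pixelSizeUm optional physical pixel size (micrometres).
#' @return A `SessionConfig` object.
#' @export
SessionConfig <- function(frameRateHz = 5, nFrames = 31L, stimOnsetFrame = 6L,
                          stimDurationS = 1, pixelSizeUm = NA_real_) {
  new("SessionConfig",
      frameRateHz = as.numeric(frameRateHz),
      nFrames = as.integer(nFrames),
      stimOnsetFrame = as.integer(stimOnsetFrame),
      stimDurationS = as.numeric(stimDurationS),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' One stimulus trial: an ordered stack of grayscale frames
#'
#' @slot frames numeric array `[row, col, frame]`, all values finite and >= 0.
#' @slot trialId character identifier.
#' @export
setClass("TrialStack",
  representation(frames = "array", trialId = "character"))

setValidity("TrialStack", function(object) {
  f <- object@frames
  if (length(dim(f)) != 3) return("frames must be a [row, col, frame] array")
  if (dim(f)[3] < 1) return("at least one frame required")
  if (!all(is.finite(f))) return("frames must be finite")
  if (min(f) < 0) return("intensities must be >= 0")
  TRUE
})

#' @rdname TrialStack-class
#' @param frames numeric array `[row, col, frame]`.
#' @param trialId identifier string.
#' @return A `TrialStack`.
#' @export
TrialStack <- function(frames, trialId = "trial") {
  new("TrialStack", frames = frames, trialId = as.character(trialId))
}

#' Per-frame percent dF/F image series
#'
#' Produced by [computeDFF()]. `frames` hold percent change in fluorescence
#' relative to `baselineImage`, the pixel-wise mean of the pre-stimulus
#' frames; the pre-stimulus frames of the series therefore average to exactly
#' zero at every pixel.
#'
#' @slot frames numeric array `[row, col, frame]` in percent.
#' @slot baselineImage strictly positive numeric matrix.
#' @slot config the [SessionConfig-class] of the session.
#' @export
setClass("DFFSeries",
  representation(frames = "array", baselineImage = "matrix",
                 config = "SessionConfig"))

setValidity("DFFSeries", function(object) {
  if (length(dim(object@frames)) != 3)
    return("frames must be a [row, col, frame] array")
  if (!all(dim(object@frames)[1:2] == dim(object@baselineImage)))
    return("baselineImage shape must match frames")
  if (min(object@baselineImage) <= 0)
    return("baselineImage must be strictly positive")
  TRUE
})

#' Detected evoked-response window of a session trace
#'
#' Frame indices (1-based, relative to trial start) of the signal onset, the
#' peak, and the offset (first zero crossing after the peak). `censored` marks
#' traces that never return to zero before the last frame; `noResponse` marks
#' traces whose post-stimulus maximum is not positive (all index slots are
#' then `NA`).
#'
#' @slot onsetFrame,peakFrame,offsetFrame integer frame indices.
#' @slot censored logical; offset clipped at the last frame.
#' @slot noResponse logical; no positive evoked signal.
#' @export
setClass("ResponseWindow",
  representation(onsetFrame = "integer", peakFrame = "integer",
                 offsetFrame = "integer", censored = "logical",
                 noResponse = "logical"))

setValidity("ResponseWindow", function(object) {
  if (object@noResponse) return(TRUE)
  if (anyNA(c(object@onsetFrame, object@peakFrame, object@offsetFrame)))
    return("window indices must be set unless noResponse")
  if (!(object@onsetFrame <= object@peakFrame &&
        object@peakFrame <= object@offsetFrame))
    return("need onsetFrame <= peakFrame <= offsetFrame")
  TRUE
})

#' Scalar outputs of one imaging session / limb
#'
#' @slot peakIntensityPct map-ROI mean percent dF/F at peak response.
#' @slot mapAreaPx map area in pixels.
#' @slot mapAreaUm2 map area in square micrometres (`NA` without pixel size).
#' @slot onsetTimeS,timeToPeakS,attackS,decayS,totalDurationS phase timings in
#'   seconds, measured from stimulus onset (onset/time-to-peak) or between
#'   window frames (attack/decay/total). `attackS + decayS == totalDurationS`.
#' @slot surroundMinPct most negative surround-ROI mean percent dF/F
#'   (reported as <= 0).
#' @slot nTrialsKept,nTrialsRejected trial QC bookkeeping.
#' @slot censored,noResponse flags propagated from the response window.
#' @export
setClass("FAIMetrics",
  representation(
    peakIntensityPct = "numeric", mapAreaPx = "numeric", mapAreaUm2 = "numeric",
    onsetTimeS = "numeric", timeToPeakS = "numeric", attackS = "numeric",
    decayS = "numeric", totalDurationS = "numeric", surroundMinPct = "numeric",
    nTrialsKept = "integer", nTrialsRejected = "integer",
    censored = "logical", noResponse = "logical"))

#' Binarized compressed z-stack for perisomatic quantification
#'
#' Quantification slices are boolean images after median filtering, grouped
#' maximum projection, in-plane selection, and Bernsen binarization. The
#' control image carries watershed-closed shadow boundaries and is used only
#' to seed region growing; it is excluded from all density sums.
#'
#' @slot slices logical array `[row, col, slice]` (quantification slices).
#' @slot provenance integer indices of the projected source slices.
#' @slot controlImage logical matrix, same shape as one slice.
#' @export
setClass("CompressedStack",
  representation(slices = "array", provenance = "integer",
                 controlImage = "matrix"))

setValidity("CompressedStack", function(object) {
  if (!is.logical(object@slices) || length(dim(object@slices)) != 3)
    return("slices must be a logical [row, col, slice] array")
  if (dim(object@slices)[3] < 1) return("need >= 1 quantification slice")
  if (!is.logical(object@controlImage) ||
      !all(dim(object@controlImage) == dim(object@slices)[1:2]))
    return("controlImage must be a logical matrix matching slice shape")
  TRUE
})

#' Region-grown soma shadow and its perisomatic ring
#'
#' @slot seedXY integer `(row, col)` seed coordinate.
#' @slot coreMask logical matrix; the region-grown soma cross-section.
#' @slot coreAreaPx pixel count of `coreMask`.
#' @slot dilatedMask core after disk dilation (defines the perisomatic ROI).
#' @slot ringMask `dilatedMask & !coreMask`.
#' @slot flagged logical; soma area outside the configured sanity bounds.
#' @slot flagReason character; why the ROI was flagged ("" if not).
#' @export
setClass("ShadowROI",
  representation(seedXY = "integer", coreMask = "matrix",
                 coreAreaPx = "integer", dilatedMask = "matrix",
                 ringMask = "matrix", flagged = "logical",
                 flagReason = "character"))

setValidity("ShadowROI", function(object) {
  if (!is.logical(object@coreMask)) return("coreMask must be logical")
  if (!object@coreMask[object@seedXY[1], object@seedXY[2]])
    return("seed must lie inside coreMask")
  if (any(object@coreMask & !object@dilatedMask))
    return("coreMask must be a subset of dilatedMask")
  TRUE
})

#' Normalized perisomatic stained-volume ratio for one neuron
#'
#' `normalizedDensity` is the sum over quantification slices of foreground
#' pixels inside the dilated ROI, divided by the soma cross-sectional area and
#' by the number of quantification slices (control image excluded).
#'
#' @slot normalizedDensity dimensionless ratio (>= 0).
#' @slot stainedPxPerSlice integer vector of foreground counts per slice.
#' @slot coreAreaPx soma cross-sectional area (pixels).
#' @slot nSlices number of quantification slices.
#' @export
setClass("PerisomaticResult",
  representation(normalizedDensity = "numeric", stainedPxPerSlice = "integer",
                 coreAreaPx = "integer", nSlices = "integer"))

#' Von Frey test session: filament ladder, responses, thresholds
#'
#' @slot ladderG ascending filament weights in grams, within `[0.04, 2]`.
#' @slot responses integer matrix `[filament, paw]` of noxious-response counts
#'   out of `nStim`.
#' @slot nStim stimulations per filament (default 5).
#' @slot thresholdsG per-paw withdrawal threshold (grams).
#' @slot combinedG mean of the two paw thresholds.
#' @export
setClass("VonFreySession",
  representation(ladderG = "numeric", responses = "matrix", nStim = "integer",
                 thresholdsG = "numeric", combinedG = "numeric"))

setValidity("VonFreySession", function(object) {
  l <- object@ladderG
  if (any(l < 0.04 - 1e-12) || any(l > 2 + 1e-12) || any(diff(l) <= 0))
    return("ladder must be strictly increasing within [0.04, 2.0] g")
  r <- object@responses
  if (nrow(r) != length(l)) return("one response row per filament")
  if (any(r < 0 | r > object@nStim, na.rm = TRUE))
    return("counts must lie in [0, nStim]")
  TRUE
})

# ---- ground-truth classes for the synthetic generators ----

#' Ground truth of a synthetic FAI session
#'
#' Holds the quantities the analysis pipeline estimates: the response
#' centroid, true peak percent dF/F, spatial spread, temporal kernel
#' parameters, surround amplitude, injected-artifact trial indices, and the
#' RNG seed.
#'
#' @slot centerXY integer `(row, col)` of the response centroid.
#' @slot amplitudePct true peak percent dF/F (> 0).
#' @slot sigmaPx spatial Gaussian SD in pixels (> 0).
#' @slot onsetS,riseS,decayTauS temporal kernel parameters in seconds.
#' @slot surroundAmplitudePct true surround amplitude (<= 0).
#' @slot artifactTrials 1-based indices of trials that receive an artifact.
#' @slot seed RNG seed.
#' @export
setClass("FAIGroundTruth",
  representation(centerXY = "integer", amplitudePct = "numeric",
                 sigmaPx = "numeric", onsetS = "numeric", riseS = "numeric",
                 decayTauS = "numeric", surroundAmplitudePct = "numeric",
                 artifactTrials = "integer", seed = "integer"))

setValidity("FAIGroundTruth", function(object) {
  msg <- character()
  if (object@amplitudePct < 0) msg <- c(msg, "amplitudePct must be >= 0")
  if (object@sigmaPx <= 0) msg <- c(msg, "sigmaPx must be > 0")
  if (object@decayTauS <= 0) msg <- c(msg, "decayTauS must be > 0")
  if (object@riseS <= 0) msg <- c(msg, "riseS must be > 0")
  if (object@surroundAmplitudePct > 0)
    msg <- c(msg, "surroundAmplitudePct must be <= 0")
  if (length(object@artifactTrials) && min(object@artifactTrials) < 1L)
    msg <- c(msg, "artifactTrials must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname FAIGroundTruth-class
#' @param centerXY,amplitudePct,sigmaPx,onsetS,riseS,decayTauS,surroundAmplitudePct,artifactTrials,seed
#'   see the class slots.
#' @return A `FAIGroundTruth`.
#' @export
FAIGroundTruth <- function(centerXY = c(64L, 64L), amplitudePct = 10,
                           sigmaPx = 5, onsetS = 0.2, riseS = 0.6,
                           decayTauS = 1.0, surroundAmplitudePct = -1,
                           artifactTrials = integer(), seed = 1L) {
  new("FAIGroundTruth", centerXY = as.integer(centerXY),
      amplitudePct = amplitudePct, sigmaPx = sigmaPx, onsetS = onsetS,
      riseS = riseS, decayTauS = decayTauS,
      surroundAmplitudePct = surroundAmplitudePct,
      artifactTrials = as.integer(artifactTrials), seed = as.integer(seed))
}

#' Ground truth of a synthetic perisomatic PV stack
#'
#' @slot somaCenters integer matrix `[n, 2]` of `(row, col)` soma centres.
#' @slot somaRadiusPx soma radius in pixels (cross-sectional area is
#'   the disk of this radius).
#' @slot ringCoverage fraction of each perisomatic annulus covered by
#'   puncta, in `[0, 1]`.
#' @slot punctaDensityBg background punctum rate per pixel.
#' @slot nSlices stack depth (quantification slices).
#' @slot seed RNG seed.
#' @export
setClass("PVGroundTruth",
  representation(somaCenters = "matrix", somaRadiusPx = "numeric",
                 ringCoverage = "numeric", punctaDensityBg = "numeric",
                 nSlices = "integer", seed = "integer"))

setValidity("PVGroundTruth", function(object) {
  msg <- character()
  if (object@ringCoverage < 0 || object@ringCoverage > 1)
    msg <- c(msg, "ringCoverage must be in [0, 1]")
  if (object@somaRadiusPx <= 0) msg <- c(msg, "somaRadiusPx must be > 0")
  if (object@punctaDensityBg < 0) msg <- c(msg, "punctaDensityBg must be >= 0")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname PVGroundTruth-class
#' @param somaCenters,somaRadiusPx,ringCoverage,punctaDensityBg,nSlices,seed
#'   see the class slots.
#' @return A `PVGroundTruth`.
#' @export
PVGroundTruth <- function(somaCenters, somaRadiusPx = 11, ringCoverage = 0.8,
                          punctaDensityBg = 0.02, nSlices = 3L, seed = 1L) {
  somaCenters <- matrix(as.integer(somaCenters), ncol = 2)
  new("PVGroundTruth", somaCenters = somaCenters,
      somaRadiusPx = somaRadiusPx, ringCoverage = ringCoverage,
      punctaDensityBg = punctaDensityBg, nSlices = as.integer(nSlices),
      seed = as.integer(seed))
}

#' Ground truth of a synthetic von Frey subject
#'
#' @slot trueThresholdG true withdrawal threshold in grams, within the assay
#'   ladder range `[0.04, 2.0]`.
#' @slot slope psychometric steepness per log-gram (`Inf` for a step).
#' @slot seed RNG seed.
#' @export
setClass("VFGroundTruth",
  representation(trueThresholdG = "numeric", slope = "numeric",
                 seed = "integer"))

setValidity("VFGroundTruth", function(object) {
  if (object@trueThresholdG < 0.04 || object@trueThresholdG > 2.0)
    return("trueThresholdG must lie in [0.04, 2.0] g")
  if (object@slope <= 0) return("slope must be > 0")
  TRUE
})

#' @rdname VFGroundTruth-class
#' @param trueThresholdG,slope,seed see the class slots.
#' @return A `VFGroundTruth`.
#' @export
VFGroundTruth <- function(trueThresholdG = 0.6, slope = 8, seed = 1L) {
  new("VFGroundTruth", trueThresholdG = trueThresholdG, slope = slope,
      seed = as.integer(seed))
}
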