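# Perisomatic parvalbumin density quantification: pre-processing (disk median
# filter, grouped max projection, in-plane slice selection, Bernsen local
# binarization), a watershed-closed control image, seeded region growing with
# disk dilation, and the normalized stained-volume ratio.

#' Bernsen local adaptive thresholding
#'
#' For each pixel the local minimum `L` and maximum `H` over the circular
#' neighbourhood of `radiusPx` (symmetric-reflection borders) give the local
#' contrast `H - L` and midpoint `(H + L) / 2`. If the contrast is at least
#' `contrastThreshold`, the pixel is foreground iff its value exceeds the
#' midpoint; otherwise the whole neighbourhood is taken as one class:
#' foreground iff the midpoint is at or above mid-gray of the bit depth (the
#' standard low-contrast rule). Inputs with values above the 8-bit range are
#' min-max rescaled to 0-255 first (the low-contrast rule needs a defined
#' bit depth).
#'
#' @param img numeric grayscale matrix.
#' @param radiusPx neighbourhood radius in pixels (>= 1; default 15).
#' @param contrastThreshold minimum local contrast on the 8-bit scale
#'   (default 15).
#' @param bitDepth bit depth defining mid-gray (default 8; mid-gray is
#'   `(2^bitDepth - 1) / 2`).
#' @return logical matrix (TRUE = foreground).
#' @export
bernsenBinarize <- function(img, radiusPx = 15, contrastThreshold = 15,
                            bitDepth = 8) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("input must be a numeric grayscale matrix")
  stopifnot(radiusPx >= 1)
  maxVal <- 2^bitDepth - 1
  if (max(img) > maxVal) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) * maxVal
           else matrix(0, nrow(img), ncol(img))
  }
  H <- grayDilate(img, radiusPx)
  L <- grayErode(img, radiusPx)
  mid <- (H + L) / 2
  ifelse(H - L >= contrastThreshold, img > mid, mid >= maxVal / 2)
}

#' Pre-process a confocal z-stack into a binarized compressed stack
#'
#' Applies a disk median filter to every slice, max-projects non-overlapping
#' groups of `group` consecutive slices (a trailing remainder is projected as
#' its own slice), keeps the `selected` projected slices in order (the
#' "in-plane" selection, an explicit input here), binarizes each kept slice
#' with [bernsenBinarize()], and appends a watershed-closed control image
#' built from the `guide`-th selected slice.
#'
#' @param raw numeric array `[row, col, slice]`, depth >= `group`.
#' @param group slices per projection group (default 5).
#' @param selected indices into the projected stack to keep (>= 1 of them).
#' @param guide index into `selected` of the slice used for the control image
#'   (default 1).
#' @param medianRadiusPx median filter radius (default 1).
#' @param radiusPx,contrastThreshold,bitDepth Bernsen parameters.
#' @return a [CompressedStack-class]; the grayscale intermediate (median
#'   filtered, projected, selected) is attached as attribute `"grayscale"`.
#' @export
preprocessStack <- function(raw, group = 5, selected, guide = 1,
                            medianRadiusPx = 1, radiusPx = 15,
                            contrastThreshold = 15, bitDepth = 8) {
  stopifnot(length(dim(raw)) == 3, dim(raw)[3] >= group)
  if (missing(selected) || length(selected) == 0)
    stop("empty in-plane selection")
  filt <- raw
  for (s in seq_len(dim(raw)[3]))
    filt[, , s] <- medianFilterDisk(raw[, , s], medianRadiusPx)
  proj <- maxProjectGroups(filt, group)
  if (any(selected < 1) || any(selected > dim(proj$projected)[3]))
    stop("selected slice indices out of range for the projected stack")
  gray <- proj$projected[, , selected, drop = FALSE]
  bin <- array(FALSE, dim(gray))
  for (s in seq_len(dim(gray)[3]))
    bin[, , s] <- bernsenBinarize(gray[, , s], radiusPx, contrastThreshold,
                                  bitDepth)
  stopifnot(guide >= 1, guide <= dim(bin)[3])
  ctrl <- makeControlImage(bin[, , guide])
  out <- new("CompressedStack", slices = bin,
             provenance = as.integer(selected), controlImage = ctrl)
  attr(out, "grayscale") <- gray
  out
}

#' Close shadow boundaries with a watershed transform
#'
#' The guide foreground is first sealed by a binary closing (disk dilation
#' followed by erosion, radius `closingRadiusPx`), which bridges pixel-scale
#' holes and short gaps between adjacent stained structures so the shadow
#' boundary is a contiguous wall. The background (shadow) regions of the
#' closed guide are then split into basins by a watershed of their distance
#' transform (distance to the nearest foreground pixel, flooded from its
#' local maxima), and ridge pixels — background pixels bordering a different
#' basin — are added to the foreground. Every shadow thereby becomes a closed
#' region that a seeded region-growing step cannot leak out of.
#'
#' @param guide logical matrix (binarized image; TRUE = stained foreground).
#' @param closingRadiusPx disk radius of the pre-watershed binary closing
#'   (default 2; 0 disables closing).
#' @return logical control image: the closed guide plus watershed ridge
#'   lines.
#' @export
makeControlImage <- function(guide, closingRadiusPx = 2) {
  if (!is.logical(guide)) stop("guide must be a binarized (logical) image")
  if (all(guide)) stop("no shadows: guide image is all foreground")
  if (closingRadiusPx > 0) {
    # closing = erosion of the complement's dilation; grayDilate/grayErode on
    # 0/1 matrices implement both with reflective borders
    g <- grayDilate(matrix(as.numeric(guide), nrow(guide)), closingRadiusPx)
    guide <- grayErode(g, closingRadiusPx) > 0.5
  }
  shadow <- !guide
  if (all(shadow)) return(guide)   # nothing to close against
  if (all(guide)) stop("no shadows survive closing: guide too dense")
  d <- EBImage::distmap(matrix(as.numeric(shadow), nrow(guide), ncol(guide)))
  w <- matrix(as.integer(EBImage::watershed(d)), nrow(guide), ncol(guide))
  # ridge: background pixel with an 8-neighbour carrying a different basin label
  ridge <- matrix(FALSE, nrow(guide), ncol(guide))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shiftMatrix(w, dr, dc, fill = 0L)
    ridge <- ridge | (w > 0L & nb > 0L & nb != w)
  }
  guide | (ridge & shadow)
}

#' Grow a soma shadow from a seed and build its perisomatic ROI
#'
#' 4-connected flood fill of the control image's background from the seed
#' (bounded by foreground and watershed ridge pixels), followed by disk
#' dilation. ROIs whose core area falls outside the configured sanity bounds
#' are flagged (they emulate the operator's rejection of tissue artifacts)
#' and are excluded from batch statistics, not errors.
#'
#' @param control logical control image from [makeControlImage()].
#' @param seedXY integer `(row, col)`; must be on a background pixel.
#' @param dilationRadiusPx disk radius for the perisomatic dilation
#'   (default 2; 0 gives an empty ring).
#' @param minSomaAreaPx,maxSomaAreaPx core-area sanity bounds (defaults
#'   30 and 5000 pixels).
#' @return a [ShadowROI-class].
#' @export
growShadowROI <- function(control, seedXY, dilationRadiusPx = 2,
                          minSomaAreaPx = 30, maxSomaAreaPx = 5000) {
  stopifnot(is.logical(control))
  seedXY <- as.integer(seedXY)
  if (control[seedXY[1], seedXY[2]])
    stop("seed lies on a foreground/ridge pixel of the control image")
  core <- floodFill(!control, seedXY, connectivity = 4)
  areaPx <- sum(core)
  dil <- diskDilate(core, dilationRadiusPx)
  flagged <- areaPx < minSomaAreaPx || areaPx > maxSomaAreaPx
  reason <- if (!flagged) "" else if (areaPx < minSomaAreaPx)
    sprintf("core area %d px below minimum %d", areaPx, minSomaAreaPx)
  else sprintf("core area %d px above maximum %d", areaPx, maxSomaAreaPx)
  new("ShadowROI", seedXY = seedXY, coreMask = core,
      coreAreaPx = as.integer(areaPx), dilatedMask = dil,
      ringMask = dil & !core, flagged = flagged, flagReason = reason)
}

#' Normalized perisomatic stained-volume ratio for one neuron
#'
#' Sums the foreground pixels inside the dilated ROI over every
#' quantification slice, then normalizes by the soma cross-sectional area
#' (the undilated core) and by the number of quantification slices. The
#' control image is excluded from both the sum and the slice count.
#'
#' @param stack a [CompressedStack-class].
#' @param roi a [ShadowROI-class] within the stack bounds.
#' @return a [PerisomaticResult-class].
#' @export
perisomaticDensity <- function(stack, roi) {
  stopifnot(is(stack, "CompressedStack"), is(roi, "ShadowROI"))
  if (!all(dim(roi@coreMask) == dim(stack@slices)[1:2]))
    stop("ROI masks do not match the stack geometry")
  if (roi@coreAreaPx == 0) stop("empty core")
  ns <- dim(stack@slices)[3]
  stained <- vapply(seq_len(ns),
                    function(s) sum(stack@slices[, , s] & roi@dilatedMask),
                    integer(1))
  new("PerisomaticResult",
      normalizedDensity = sum(stained) / roi@coreAreaPx / ns,
      stainedPxPerSlice = stained, coreAreaPx = roi@coreAreaPx,
      nSlices = as.integer(ns))
}

#' Quantify perisomatic density for a list of seed points
#'
#' Applies [growShadowROI()] and [perisomaticDensity()] to every seed.
#' Flagged ROIs are reported but excluded from the per-stack mean. Seeds
#' falling inside an already-grown core produce duplicate rows and a warning
#' (deduplication is the caller's responsibility). Results are independent of
#' seed order up to row order.
#'
#' @param stack a [CompressedStack-class].
#' @param seeds integer matrix `[n, 2]` of `(row, col)` seed points (>= 1).
#' @param dilationRadiusPx,minSomaAreaPx,maxSomaAreaPx forwarded to
#'   [growShadowROI()].
#' @return list with `perNeuron` (data frame: seed coordinates, core area,
#'   density, flag) and `meanDensity` (mean over unflagged neurons).
#' @export
batchQuantify <- function(stack, seeds, dilationRadiusPx = 2,
                          minSomaAreaPx = 30, maxSomaAreaPx = 5000) {
  seeds <- matrix(as.integer(seeds), ncol = 2)
  if (nrow(seeds) < 1) stop("need at least one seed")
  rows <- vector("list", nrow(seeds))
  coreIds <- character(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    roi <- tryCatch(
      growShadowROI(stack@controlImage, seeds[i, ], dilationRadiusPx,
                    minSomaAreaPx, maxSomaAreaPx),
      error = function(e) e)
    if (inherits(roi, "error")) {
      rows[[i]] <- data.frame(seed_row = seeds[i, 1], seed_col = seeds[i, 2],
                              core_area_px = NA_integer_,
                              density = NA_real_, flagged = TRUE,
                              flag_reason = conditionMessage(roi))
      coreIds[i] <- NA_character_
      next
    }
    res <- perisomaticDensity(stack, roi)
    coreIds[i] <- paste(range(which(roi@coreMask)), roi@coreAreaPx,
                        collapse = ":")
    rows[[i]] <- data.frame(seed_row = seeds[i, 1], seed_col = seeds[i, 2],
                            core_area_px = roi@coreAreaPx,
                            density = res@normalizedDensity,
                            flagged = roi@flagged,
                            flag_reason = roi@flagReason)
  }
  perNeuron <- do.call(rbind, rows)
  ok <- stats::complete.cases(perNeuron$density) & !perNeuron$flagged
  if (!any(ok)) stop("all seeds invalid or flagged")
  dup <- !is.na(coreIds) & duplicated(coreIds)
  if (any(dup))
    warning(sprintf("%d seed(s) fell inside an already-analyzed shadow",
                    sum(dup)))
  list(perNeuron = perNeuron, meanDensity = mean(perNeuron$density[ok]))
}
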