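# Behavioral and ancillary histology metrics: von Frey withdrawal threshold,
# dendritic spine density with branch-class grouping, ROI integrated density,
# and a generic labeled-cell counter.

#' Von Frey withdrawal threshold from per-filament response counts
#'
#' The threshold is the lowest filament whose response rate reaches the
#' criterion (`count / nStim >= criterion`; with the assay standard of 5
#' stimulations and a 60 percent criterion this means >= 3 responses). If no
#' filament reaches it, the assay ceiling (2.0 g) is returned. Counts beyond
#' the first supra-criterion filament are ignored (testing stops there);
#' counts may be shorter than the ladder when testing stopped early. An
#' all-`NA` count vector (untestable paw) returns `NA`.
#'
#' @param counts integer vector of noxious-response counts, in ladder order.
#' @param ladder ascending filament weights in grams (default the standard
#'   Semmes-Weinstein set, [vfLadderDefault()]).
#' @param nStim stimulations per filament (default 5).
#' @param criterion response-rate criterion (default 0.60).
#' @param ceilingG value returned when the criterion is never met
#'   (default 2.0 g, the assay maximum).
#' @return withdrawal threshold in grams.
#' @examples
#' vfThreshold(c(0, 1, 2, 3), ladder = c(0.04, 0.07, 0.16, 0.4))
#' @export
vfThreshold <- function(counts, ladder = vfLadderDefault(), nStim = 5,
                        criterion = 0.60, ceilingG = 2.0) {
  if (length(counts) > length(ladder))
    stop("more response counts than ladder filaments")
  if (all(is.na(counts))) return(NA_real_)
  hit <- which(!is.na(counts) & counts / nStim >= criterion)
  if (length(hit)) ladder[hit[1]] else ceilingG
}

#' Combine left and right paw thresholds
#'
#' Arithmetic mean of the two paw thresholds; `NA` propagates (an untestable
#' paw is not imputed).
#'
#' @param leftG,rightG per-paw thresholds in grams.
#' @return combined threshold in grams.
#' @export
combinePaws <- function(leftG, rightG) (leftG + rightG) / 2

#' Build a [VonFreySession-class] from generated or recorded counts
#'
#' @param ladder ascending filament weights (grams).
#' @param responses integer matrix `[filament, paw]` (2 columns).
#' @param nStim stimulations per filament.
#' @param criterion,ceilingG forwarded to [vfThreshold()].
#' @return a [VonFreySession-class] with per-paw and combined thresholds.
#' @export
vonFreySession <- function(ladder, responses, nStim = 5, criterion = 0.60,
                           ceilingG = 2.0) {
  thr <- apply(responses, 2, vfThreshold, ladder = ladder, nStim = nStim,
               criterion = criterion, ceilingG = ceilingG)
  new("VonFreySession", ladderG = ladder,
      responses = matrix(as.integer(responses), ncol = 2),
      nStim = as.integer(nStim), thresholdsG = as.numeric(thr),
      combinedG = unname(combinePaws(thr[1], thr[2])))
}

#' Dendritic spine density per segment with branch-class grouping
#'
#' Per-segment density is the spine count divided by the segment length
#' (spines per micrometre). Grouped means are reported for every level of the
#' `groupBy` columns (e.g. apical/basilar by branch order) and for all
#' branches pooled.
#'
#' @param records data frame with at least `length_um` (> 0) and `spines`
#'   columns; typically also `neuron`, `layer`, `class`
#'   (apical/basilar), and `order` (1-3).
#' @param groupBy character vector of grouping column names
#'   (default `c("class", "order")`).
#' @return list with `perSegment` (the input plus a `density` column) and
#'   `grouped` (data frame of group means, with an `all branches` row).
#' @export
spineDensity <- function(records, groupBy = c("class", "order")) {
  stopifnot(is.data.frame(records),
            all(c("length_um", "spines") %in% names(records)))
  if (any(records$length_um <= 0)) stop("segment lengths must be > 0")
  records$density <- records$spines / records$length_um
  groupBy <- intersect(groupBy, names(records))
  grouped <- if (length(groupBy)) {
    ag <- stats::aggregate(records["density"], records[groupBy], mean)
    ag$n_segments <- stats::aggregate(records["density"], records[groupBy],
                                      length)$density
    ag
  } else NULL
  allRow <- data.frame(matrix("all branches", nrow = 1,
                              ncol = length(groupBy),
                              dimnames = list(NULL, groupBy)),
                       density = mean(records$density),
                       n_segments = nrow(records))
  grouped <- if (is.null(grouped)) allRow else {
    for (g in groupBy) grouped[[g]] <- as.character(grouped[[g]])
    rbind(grouped, allRow)
  }
  list(perSegment = records, grouped = grouped)
}

#' Integrated density within a rectangular ROI
#'
#' Sum of pixel intensities inside the ROI. Across a batch the ROI dimensions
#' must be identical (use [integratedDensityBatch()]), emulating an ROI of
#' consistent size applied to every image.
#'
#' @param image numeric matrix.
#' @param roi integer vector `c(row, col, height, width)`: top-left corner
#'   and extent.
#' @return sum of intensities inside the ROI.
#' @export
integratedDensity <- function(image, roi) {
  stopifnot(is.matrix(image), length(roi) == 4)
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (r0 < 1 || c0 < 1 || h < 1 || w < 1 ||
      r0 + h - 1 > nrow(image) || c0 + w - 1 > ncol(image))
    stop("ROI out of image bounds")
  sum(image[r0:(r0 + h - 1), c0:(c0 + w - 1)])
}

#' @rdname integratedDensity
#' @param images list of numeric matrices.
#' @param rois list of ROIs (`c(row, col, height, width)`), all with
#'   identical height and width (enforced).
#' @return numeric vector of integrated densities.
#' @export
integratedDensityBatch <- function(images, rois) {
  stopifnot(length(images) == length(rois))
  dims <- vapply(rois, function(r) r[3:4], numeric(2))
  if (length(rois) > 1 && !all(dims == dims[, 1]))
    stop("ROI dimensions must be identical across the batch")
  mapply(integratedDensity, images, rois)
}

#' Count labeled cells in an image
#'
#' Generic threshold-and-count: thresholds the image, labels 8-connected
#' components, and counts components of at least `minBlobPx` pixels. This is
#' an explicit generic substitute for template-correlation cell counters, and
#' is labeled as such in all outputs.
#'
#' @param image numeric matrix.
#' @param intensityThreshold pixels strictly above this are foreground.
#' @param minBlobPx minimum component size in pixels (default 1).
#' @return integer count of qualifying components.
#' @export
countLabeledCells <- function(image, intensityThreshold, minBlobPx = 1) {
  cc <- connectedComponents(image > intensityThreshold, connectivity = 8)
  sum(cc$sizes >= minBlobPx)
}
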