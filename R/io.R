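# Stack readers/writers (multi-page grayscale TIFF), metrics CSV with a
# stable column order, and run manifests for bit-reproducible reruns.

#' Read a multi-page grayscale TIFF stack
#'
#' Frames are returned in page order as raw integer counts (no rescaling).
#' RGB/multi-channel pages are refused with a clear error; truncated files
#' fail closed (no partial data).
#'
#' @param path path to a multi-page grayscale TIFF (8/12-in-16/16 bit).
#' @return numeric array `[row, col, frame]` with attribute `bitsPerSample`.
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!length(pages)) stop("no pages in TIFF: ", path)
  first <- pages[[1]]
  if (length(dim(first)) == 3)
    stop("RGB/multi-channel TIFF not supported (grayscale stacks only): ",
         path)
  bits <- attr(first, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  arr <- array(0, c(dim(first), length(pages)))
  for (i in seq_along(pages)) {
    if (!all(dim(pages[[i]]) == dim(first)))
      stop("inconsistent page geometry in ", path)
    arr[, , i] <- pages[[i]]
  }
  attr(arr, "bitsPerSample") <- as.integer(bits)
  arr
}

#' Write an image stack as a multi-page TIFF
#'
#' Values are rounded, clipped to the sample range, and written uncompressed.
#' Stacks are written as 16-bit by default (carrying a 12-bit range when the
#' data come from the session simulator); masks should be written at 8 bits
#' as 0/255.
#'
#' @param stack numeric array `[row, col, frame]`, a matrix (single page), or
#'   a [TrialStack-class].
#' @param path output path.
#' @param bitsPerSample 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, bitsPerSample = 16) {
  if (is(stack, "TrialStack")) stack <- stack@frames
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  if (is.logical(stack)) stack <- stack * 255
  stopifnot(bitsPerSample %in% c(8, 16))
  top <- 2^bitsPerSample - 1
  pages <- lapply(seq_len(dim(stack)[3]), function(i) {
    v <- round(pmin(pmax(stack[, , i], 0), top))
    v / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bitsPerSample,
                  compression = "none")
  invisible(path)
}

# canonical metrics column order; unknown columns follow alphabetically
metricsColumnOrder <- function() c(
  "session", "limb", "peak_intensity_pct", "map_area_px", "map_area_um2",
  "onset_time_s", "time_to_peak_s", "attack_s", "decay_s",
  "total_duration_s", "surround_min_pct", "n_trials_kept",
  "n_trials_rejected", "censored", "no_response",
  "seed_row", "seed_col", "core_area_px", "density", "flagged", "flag_reason")

#' Write metrics rows to CSV with a stable column order
#'
#' Columns known to the package's metrics schema come first in their
#' documented order; any remaining columns follow alphabetically, so output
#' is independent of insertion order. Floats are written at fixed precision.
#'
#' @param rows a data frame (possibly 0 rows: header-only output).
#' @param path output CSV path.
#' @param digits significant digits for floating-point columns (default 10).
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(rows, path, digits = 10) {
  stopifnot(is.data.frame(rows))
  known <- intersect(metricsColumnOrder(), names(rows))
  rest <- sort(setdiff(names(rows), known))
  rows <- rows[, c(known, rest), drop = FALSE]
  for (j in seq_along(rows)) {
    if (is.double(rows[[j]])) rows[[j]] <- signif(rows[[j]], digits)
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records tool version, seed, parameter echo, and input-file digests so a
#' rerun with an identical manifest reproduces identical outputs for the
#' deterministic stages.
#'
#' @param path output JSON path.
#' @param seed the run's RNG seed.
#' @param params named list of parameters (echoed verbatim).
#' @param inputs character vector of input file paths (MD5-digested).
#' @return the manifest list, invisibly.
#' @export
writeManifest <- function(path, seed, params = list(), inputs = character()) {
  manifest <- list(
    tool = "cortexmap",
    version = as.character(utils::packageVersion("cortexmap")),
    seed = seed,
    params = params,
    inputs = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
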