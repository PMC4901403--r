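# File-level entry points behind the command-line interface: each reads
# standard formats (TIFF stacks, YAML configs, CSV tables), runs the
# corresponding pipeline, and writes CSV/JSON outputs plus a run manifest.

sessionConfigFromList <- function(p) {
  SessionConfig(
    frameRateHz = p$frame_rate_hz %||% 5,
    nFrames = p$n_frames %||% 31L,
    stimOnsetFrame = p$stim_onset_frame %||% 6L,
    stimDurationS = p$stim_duration_s %||% 1,
    pixelSizeUm = p$pixel_size_um %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze one FAI session from files
#'
#' Reads every multi-page TIFF in `trialsDir` (one trial per file, sorted by
#' name), runs [runFAISession()] with the parameters of the session YAML, and
#' writes `metrics.csv`, `rejected_trials.json`, and `manifest.json` into
#' `outDir`.
#'
#' @param sessionYaml path to a YAML file with keys `frame_rate_hz`,
#'   `n_frames`, `stim_onset_frame` and optional `stim_duration_s`,
#'   `pixel_size_um`, `deviation_frac`, `smooth_radius_px`, `k_sd`,
#'   `ring_width_px`, `session`, `limb`.
#' @param trialsDir directory of per-trial TIFF stacks.
#' @param outDir output directory (created if needed).
#' @return the [FAIMetrics-class] of the session, invisibly.
#' @export
faiAnalyzeFiles <- function(sessionYaml, trialsDir, outDir) {
  p <- yaml::read_yaml(sessionYaml)
  config <- sessionConfigFromList(p)
  files <- sort(list.files(trialsDir, pattern = "\\.tiff?$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stop("no TIFF trials found in ", trialsDir)
  trials <- lapply(seq_along(files), function(i) {
    arr <- readStack(files[i])
    TrialStack(array(as.numeric(arr), dim(arr)), trialId = basename(files[i]))
  })
  res <- runFAISession(trials, config,
                       deviationFrac = p$deviation_frac %||% 0.10,
                       smoothRadiusPx = p$smooth_radius_px %||% 1.0,
                       kSd = p$k_sd %||% 2.0,
                       ringWidthPx = p$ring_width_px %||% 10)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  row <- cbind(data.frame(session = p$session %||% "session",
                          limb = p$limb %||% "limb"),
               as.data.frame(res$metrics))
  writeMetrics(row, file.path(outDir, "metrics.csv"))
  jsonlite::write_json(
    list(rejected = basename(files)[res$rejection$rejectedIdx],
         deviations = res$rejection$deviations),
    file.path(outDir, "rejected_trials.json"), auto_unbox = TRUE, digits = NA)
  writeManifest(file.path(outDir, "manifest.json"), seed = p$seed %||% NA,
                params = p, inputs = c(sessionYaml, files))
  invisible(res$metrics)
}

#' Quantify perisomatic density from files
#'
#' Reads a confocal z-stack TIFF and a CSV of seed points (columns `row`,
#' `col`), runs pre-processing and [batchQuantify()], and writes
#' `per_neuron.csv`, `summary.json`, and `manifest.json` into `outDir`.
#'
#' @param stackPath multi-page TIFF z-stack.
#' @param seedsCsv CSV with columns `row`, `col` (1-based pixel coordinates).
#' @param paramsYaml optional YAML with keys `group`, `selected`, `guide`,
#'   `radius_px`, `contrast_threshold`, `dilation_radius_px`,
#'   `min_soma_area_px`, `max_soma_area_px`.
#' @param outDir output directory.
#' @return the [batchQuantify()] result, invisibly.
#' @export
pvQuantifyFiles <- function(stackPath, seedsCsv, paramsYaml = NULL, outDir) {
  p <- if (!is.null(paramsYaml)) yaml::read_yaml(paramsYaml) else list()
  raw <- readStack(stackPath)
  arr <- array(as.numeric(raw), dim(raw))
  selected <- p$selected %||% seq_len(ceiling(dim(arr)[3] / (p$group %||% 5)))
  cstack <- preprocessStack(arr, group = p$group %||% 5,
                            selected = as.integer(selected),
                            guide = p$guide %||% 1,
                            radiusPx = p$radius_px %||% 15,
                            contrastThreshold = p$contrast_threshold %||% 15)
  seeds <- utils::read.csv(seedsCsv)
  res <- batchQuantify(cstack, as.matrix(seeds[, c("row", "col")]),
                       dilationRadiusPx = p$dilation_radius_px %||% 2,
                       minSomaAreaPx = p$min_soma_area_px %||% 30,
                       maxSomaAreaPx = p$max_soma_area_px %||% 5000)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeMetrics(res$perNeuron, file.path(outDir, "per_neuron.csv"))
  jsonlite::write_json(
    list(mean_density = res$meanDensity,
         n_neurons = sum(!res$perNeuron$flagged),
         n_flagged = sum(res$perNeuron$flagged),
         params = p),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeManifest(file.path(outDir, "manifest.json"), seed = p$seed %||% NA,
                params = p, inputs = c(stackPath, seedsCsv))
  invisible(res)
}

#' Compute von Frey thresholds from a behavior CSV
#'
#' Input schema: columns `animal`, `day`, `paw`, `filament_g`,
#' `n_responses`. One threshold per animal/day/paw, then the two paws are
#' averaged into a combined threshold per animal/day.
#'
#' @param behaviorCsv input CSV.
#' @param outCsv output CSV path (optional).
#' @param nStim,criterion,ceilingG forwarded to [vfThreshold()].
#' @return data frame with per-animal/day combined thresholds.
#' @export
vfThresholdFiles <- function(behaviorCsv, outCsv = NULL, nStim = 5,
                             criterion = 0.60, ceilingG = 2.0) {
  d <- utils::read.csv(behaviorCsv)
  need <- c("animal", "day", "paw", "filament_g", "n_responses")
  if (!all(need %in% names(d)))
    stop("behavior CSV must have columns: ", paste(need, collapse = ", "))
  keys <- unique(d[, c("animal", "day", "paw")])
  keys$threshold_g <- vapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$animal == keys$animal[i] & d$day == keys$day[i] &
             d$paw == keys$paw[i], ]
    sub <- sub[order(sub$filament_g), ]
    vfThreshold(sub$n_responses, ladder = sub$filament_g, nStim = nStim,
                criterion = criterion, ceilingG = ceilingG)
  }, numeric(1))
  wide <- stats::reshape(keys, idvar = c("animal", "day"),
                         timevar = "paw", direction = "wide")
  thrCols <- grep("^threshold_g", names(wide), value = TRUE)
  wide$combined_g <- rowMeans(wide[, thrCols, drop = FALSE])
  if (!is.null(outCsv)) utils::write.csv(wide, outCsv, row.names = FALSE)
  wide
}
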