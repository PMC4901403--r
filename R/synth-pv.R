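# Synthetic confocal-like parvalbumin stacks: dark elliptical soma "shadows"
# on mid-gray neuropil, bright puncta on each soma's perisomatic annulus
# covering a controlled fraction of its arc, background puncta throughout the
# neuropil, a few bright filled ellipses standing in for PV+ interneuron
# somata, and Poisson-like (intensity-scaled) noise. Gray levels are 8-bit.

paintDisks <- function(img, centers, radius, value) {
  if (nrow(centers) == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  r <- ceiling(radius)
  for (k in seq_len(nrow(centers))) {
    cy <- centers[k, 1]; cx <- centers[k, 2]
    ri <- max(1, floor(cy - r)):min(n, ceiling(cy + r))
    ci <- max(1, floor(cx - r)):min(m, ceiling(cx + r))
    d2 <- outer((ri - cy)^2, (ci - cx)^2, "+")
    sub <- img[ri, ci, drop = FALSE]
    sub[d2 <= radius^2] <- value
    img[ri, ci] <- sub
  }
  img
}

#' Generate a synthetic perisomatic PV confocal stack
#'
#' @param truth a [PVGroundTruth-class].
#' @param shape image dimensions `(rows, cols)`; default `c(256, 256)`.
#' @param neuropilLevel,somaLevel,punctumLevel,pvSomaLevel gray levels
#'   (8-bit scale) of the stained neuropil, the unstained soma shadows, the
#'   perisomatic/background puncta, and the PV+ somata.
#' @param punctumRadiusPx punctum disk radius in pixels.
#' @param noiseSdFrac Poisson-like noise: per-pixel Gaussian SD is
#'   `noiseSdFrac * sqrt(value)` (default 0.15; 0 disables noise).
#' @param nPvSomata number of bright PV+ soma ellipses added away from the
#'   target shadows.
#' @param jitterPx per-slice uniform jitter of punctum centres.
#' @return list with `stack` (numeric `[row, col, slice]`, 8-bit range),
#'   `truth`, `somaMask` (logical matrix of all soma shadows), `somaMasks`
#'   (list, one mask per soma), `punctaMasks` (logical `[row, col, slice]`
#'   ground-truth punctum pixels), and `annulusMasks` (list; the perisomatic
#'   annulus of each soma).
#' @examples
#' gt <- PVGroundTruth(somaCenters = c(40L, 40L), seed = 3)
#' pv <- genConfocalPVStack(gt, shape = c(80, 80))
#' dim(pv$stack)
#' @export
genConfocalPVStack <- function(truth, shape = c(256L, 256L),
                               neuropilLevel = 100, somaLevel = 60,
                               punctumLevel = 230, pvSomaLevel = 220,
                               punctumRadiusPx = 1.6, noiseSdFrac = 0.15,
                               nPvSomata = 3L, jitterPx = 0.5) {
  stopifnot(is(truth, "PVGroundTruth"))
  n <- shape[1]; m <- shape[2]
  rs <- truth@somaRadiusPx
  band <- 2 * punctumRadiusPx            # annulus width outside the soma
  centers <- truth@somaCenters
  if (any(centers[, 1] - (rs + band) < 1 | centers[, 1] + (rs + band) > n |
          centers[, 2] - (rs + band) < 1 | centers[, 2] + (rs + band) > m))
    stop("shape too small to contain all somata plus annuli")
  if (nrow(centers) > 1) {
    dmin <- min(stats::dist(centers))
    if (dmin < 2 * (rs + band))
      stop("overlapping somata after ring dilation: ground truth ambiguous")
  }

  set.seed(truth@seed)
  base <- matrix(neuropilLevel, n, m)
  somaMasks <- vector("list", nrow(centers))
  somaMask <- matrix(FALSE, n, m)
  annulusMasks <- vector("list", nrow(centers))
  rowIdx <- matrix(rep(seq_len(n), m), n, m)
  colIdx <- matrix(rep(seq_len(m), each = n), n, m)
  for (k in seq_len(nrow(centers))) {
    d <- sqrt((rowIdx - centers[k, 1])^2 + (colIdx - centers[k, 2])^2)
    somaMasks[[k]] <- d <= rs
    annulusMasks[[k]] <- d > rs & d <= rs + band
    somaMask <- somaMask | somaMasks[[k]]
    base[somaMasks[[k]]] <- somaLevel
  }

  # PV+ somata: bright filled ellipses away from the target shadows
  pvPlaced <- 0L; tries <- 0L
  while (pvPlaced < nPvSomata && tries < 200L) {
    tries <- tries + 1L
    c0 <- c(runif(1, 10, n - 10), runif(1, 10, m - 10))
    if (nrow(centers) &&
        min(sqrt((centers[, 1] - c0[1])^2 + (centers[, 2] - c0[2])^2)) <
          rs + band + 12) next
    a <- runif(1, 4, 7); b <- runif(1, 3, 5); th <- runif(1, 0, pi)
    dr <- rowIdx - c0[1]; dc <- colIdx - c0[2]
    e <- ((dr * cos(th) + dc * sin(th)) / a)^2 +
         ((-dr * sin(th) + dc * cos(th)) / b)^2
    base[e <= 1] <- pvSomaLevel
    pvPlaced <- pvPlaced + 1L
  }

  # punctum centres: perisomatic ring slots + background Poisson field
  ringCenters <- matrix(numeric(), ncol = 2)
  for (k in seq_len(nrow(centers))) {
    rc <- rs + punctumRadiusPx
    nSlots <- max(1L, floor(2 * pi * rc / (2 * punctumRadiusPx)))
    nOn <- round(truth@ringCoverage * nSlots)
    if (nOn > 0) {
      on <- sort(sample.int(nSlots, nOn))
      ang <- (on - 0.5) * 2 * pi / nSlots
      ringCenters <- rbind(ringCenters,
                           cbind(centers[k, 1] + rc * sin(ang),
                                 centers[k, 2] + rc * cos(ang)))
    }
  }
  nBg <- stats::rpois(1, truth@punctaDensityBg * n * m)
  bgCenters <- cbind(runif(nBg, 1, n), runif(nBg, 1, m))
  if (nBg > 0 && nrow(centers) > 0) {
    keep <- rep(TRUE, nBg)
    for (k in seq_len(nrow(centers))) {
      d <- sqrt((bgCenters[, 1] - centers[k, 1])^2 +
                (bgCenters[, 2] - centers[k, 2])^2)
      keep <- keep & d > rs + punctumRadiusPx
    }
    bgCenters <- bgCenters[keep, , drop = FALSE]
  }
  allCenters <- rbind(ringCenters, bgCenters)

  stack <- array(0, c(n, m, truth@nSlices))
  punctaMasks <- array(FALSE, c(n, m, truth@nSlices))
  for (s in seq_len(truth@nSlices)) {
    jc <- allCenters
    if (nrow(jc) > 0 && jitterPx > 0)
      jc <- jc + matrix(runif(2 * nrow(jc), -jitterPx, jitterPx), ncol = 2)
    img <- paintDisks(base, jc, punctumRadiusPx, punctumLevel)
    pm <- paintDisks(matrix(0, n, m), jc, punctumRadiusPx, 1)
    punctaMasks[, , s] <- pm > 0
    if (noiseSdFrac > 0)
      img <- img + matrix(stats::rnorm(n * m), n, m) * noiseSdFrac * sqrt(img)
    img <- round(pmin(pmax(img, 0), 255))
    stack[, , s] <- img
  }
  list(stack = stack, truth = truth, somaMask = somaMask,
       somaMasks = somaMasks, punctaMasks = punctaMasks,
       annulusMasks = annulusMasks)
}

#' Default Semmes-Weinstein filament ladder (grams)
#'
#' @return numeric vector of the standard 0.04-2.0 g filament weights.
#' @export
vfLadderDefault <- function() c(0.04, 0.07, 0.16, 0.4, 0.6, 1.0, 1.4, 2.0)

#' Generate synthetic von Frey responses for two paws
#'
#' Response probability is logistic in log-grams, centred at the true
#' threshold: `p(w) = plogis(slope * log(w / trueThresholdG))`; an infinite
#' slope gives a step (`p = 1` for `w >= trueThresholdG`). Counts are
#' binomial out of `nStimPerFilament`, drawn independently per filament and
#' paw; output is deterministic under the seed.
#'
#' @param truth a [VFGroundTruth-class].
#' @param ladder ascending filament weights in grams within `[0.04, 2.0]`.
#' @param nStimPerFilament stimulations per filament (assay standard: 5).
#' @return list with `ladderG`, `responses` (integer matrix
#'   `[filament, paw]`, columns `left`/`right`), `nStim`, and `truth`.
#' @export
genVFResponses <- function(truth, ladder = vfLadderDefault(),
                           nStimPerFilament = 5L) {
  stopifnot(is(truth, "VFGroundTruth"), nStimPerFilament >= 1)
  if (any(ladder < 0.04 - 1e-12) || any(ladder > 2 + 1e-12) ||
      any(diff(ladder) <= 0))
    stop("ladder must be strictly increasing within the 0.04-2.0 g assay range")
  p <- if (is.infinite(truth@slope)) {
    as.numeric(ladder >= truth@trueThresholdG)
  } else {
    stats::plogis(truth@slope * log(ladder / truth@trueThresholdG))
  }
  set.seed(truth@seed)
  responses <- cbind(
    left = stats::rbinom(length(ladder), nStimPerFilament, p),
    right = stats::rbinom(length(ladder), nStimPerFilament, p))
  list(ladderG = ladder, responses = responses,
       nStim = as.integer(nStimPerFilament), truth = truth)
}
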