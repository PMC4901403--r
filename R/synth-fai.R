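# Synthetic widefield fluorescence sessions with known ground truth.
#
# Each trial is baseline * (1 + r(x, y, t) / 100) + noise, where the response
# field r is separable: a spatial profile (central Gaussian plus a negative
# compact-support annulus) times a temporal kernel (delay, linear rise,
# exponential decay). The baseline carries a smooth polynomial gradient and a
# few dark curvilinear vessel-like structures, emulating light absorption by
# surface vasculature.

# smooth 12-bit baseline with dark vessels; deterministic given the RNG state
synthBaselineImage <- function(shape, nVesselRange = c(2L, 4L)) {
  n <- shape[1]; m <- shape[2]
  u <- matrix(rep((seq_len(n) - 1) / (n - 1), m), n, m)
  v <- matrix(rep((seq_len(m) - 1) / (m - 1), each = n), n, m)
  cf <- runif(5, -1, 1)
  b <- 2000 * (1 + 0.15 * (cf[1] * u + cf[2] * v + cf[3] * u * v +
                           cf[4] * u^2 + cf[5] * v^2))
  nV <- sample(seq(nVesselRange[1], nVesselRange[2]), 1)
  vesselFactor <- matrix(1, n, m)
  for (i in seq_len(nV)) {
    # quadratic Bezier between two random border-ish points
    p0 <- c(runif(1, 1, n), runif(1, 1, m))
    p2 <- c(runif(1, 1, n), runif(1, 1, m))
    p1 <- (p0 + p2) / 2 + runif(2, -n / 4, n / 4)
    tseq <- seq(0, 1, length.out = 4L * n)
    pts <- cbind((1 - tseq)^2 * p0[1] + 2 * (1 - tseq) * tseq * p1[1] + tseq^2 * p2[1],
                 (1 - tseq)^2 * p0[2] + 2 * (1 - tseq) * tseq * p1[2] + tseq^2 * p2[2])
    pts <- round(pts)
    keep <- pts[, 1] >= 1 & pts[, 1] <= n & pts[, 2] >= 1 & pts[, 2] <= m
    pts <- unique(pts[keep, , drop = FALSE])
    vmask <- matrix(FALSE, n, m)
    vmask[pts] <- TRUE
    vmask <- diskDilate(vmask, runif(1, 1, 2))
    vesselFactor[vmask] <- pmin(vesselFactor[vmask], runif(1, 0.6, 0.8))
  }
  b * vesselFactor
}

# spatial response profile in percent units: central Gaussian plus negative
# annulus with compact support (zero for d < 1.5 sigma), so the profile's
# maximum equals amplitudePct exactly at the centre pixel
synthSpatialProfile <- function(shape, truth) {
  n <- shape[1]; m <- shape[2]
  d2 <- outer((seq_len(n) - truth@centerXY[1])^2,
              (seq_len(m) - truth@centerXY[2])^2, "+")
  d <- sqrt(d2)
  s <- truth@sigmaPx
  core <- truth@amplitudePct * exp(-d2 / (2 * s^2))
  ring <- truth@surroundAmplitudePct *
    exp(-((d - 2.5 * s)^2) / (2 * (0.5 * s)^2)) * (d >= 1.5 * s)
  core + ring
}

# temporal kernel: 0 before onset, linear rise over riseS to 1, exponential
# decay with decayTauS; evaluated at the frame times of config
synthTemporalKernel <- function(config, truth) {
  t <- (seq_len(config@nFrames) - config@stimOnsetFrame) / config@frameRateHz -
    truth@onsetS
  g <- numeric(config@nFrames)
  rising <- t >= 0 & t < truth@riseS
  decaying <- t >= truth@riseS
  g[rising] <- t[rising] / truth@riseS
  g[decaying] <- exp(-(t[decaying] - truth@riseS) / truth@decayTauS)
  g
}

#' Generate a synthetic FAI session
#'
#' Produces `nTrials` trial stacks of a stimulus-locked fluorescence response
#' over a textured baseline with trial noise, plus the noise-free template
#' needed by ground-truth oracles. Trials listed in `truth@artifactTrials`
#' receive a global multiplicative step (`artifactMagnitude`, over
#' `artifactLenFrames` consecutive frames), emulating motion/light/equipment
#' artifacts. Output is bit-identical for identical inputs and seed.
#'
#' @param config a [SessionConfig-class].
#' @param truth a [FAIGroundTruth-class].
#' @param nTrials number of trials (>= 1); the assay standard is 40 per limb.
#' @param shape image dimensions `(rows, cols)`; default `c(128, 128)`.
#' @param noiseSdFrac per-pixel Gaussian noise SD as a fraction of the local
#'   baseline (default 0.005, i.e. 0.5 percent of baseline).
#' @param artifactMagnitude multiplicative artifact step (default 1.25).
#' @param artifactLenFrames length of the artifact step (default 3 frames).
#' @return list with `trials` (list of [TrialStack-class]), `truth`,
#'   `baseline` (matrix), `spatial` (percent profile matrix), `temporal`
#'   (kernel per frame), and `config`.
#' @examples
#' sess <- genFAISession(SessionConfig(), FAIGroundTruth(seed = 7), nTrials = 2,
#'                       shape = c(32, 32))
#' length(sess$trials)
#' @export
genFAISession <- function(config, truth, nTrials,
                          shape = c(128L, 128L), noiseSdFrac = 0.005,
                          artifactMagnitude = 1.25, artifactLenFrames = 3L) {
  stopifnot(is(config, "SessionConfig"), is(truth, "FAIGroundTruth"),
            nTrials >= 1)
  if (noiseSdFrac < 0) stop("noise SD must be >= 0")
  if (truth@centerXY[1] < 1 || truth@centerXY[1] > shape[1] ||
      truth@centerXY[2] < 1 || truth@centerXY[2] > shape[2])
    stop("response centre outside image")
  if (length(truth@artifactTrials) && max(truth@artifactTrials) > nTrials)
    stop("artifactTrials must index into 1..nTrials")

  set.seed(truth@seed)
  baseline <- synthBaselineImage(shape)
  spatial <- synthSpatialProfile(shape, truth)
  temporal <- synthTemporalKernel(config, truth)
  noiseSd <- noiseSdFrac * baseline

  # noise-free template stack (shared across trials)
  template <- array(0, c(shape, config@nFrames))
  for (t in seq_len(config@nFrames))
    template[, , t] <- baseline * (1 + spatial * temporal[t] / 100)

  trials <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    f <- template
    if (noiseSdFrac > 0) {
      eps <- array(stats::rnorm(prod(dim(f))), dim(f))
      f <- f + eps * as.vector(noiseSd)
    }
    if (i %in% truth@artifactTrials) {
      len <- min(artifactLenFrames, config@nFrames)
      start <- sample.int(config@nFrames - len + 1L, 1L)
      f[, , start:(start + len - 1L)] <- f[, , start:(start + len - 1L)] *
        artifactMagnitude
    }
    f[f < 0] <- 0
    trials[[i]] <- new("TrialStack", frames = f,
                       trialId = sprintf("trial%03d", i))
  }
  list(trials = trials, truth = truth, baseline = baseline, spatial = spatial,
       temporal = temporal, config = config)
}
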