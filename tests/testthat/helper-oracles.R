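# Independent brute-force oracles. These deliberately share no code with the
# package implementations beyond base R: per-pixel loops, explicit queues,
# and direct convolution sums.

reflect1 <- function(i, n) {
  # symmetric reflection with edge repetition, scalar
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i + 1 - 1   # 0 -> 1, -1 -> 2, ...
    if (i > n) i <- 2 * n - i + 1
  }
  i
}

oracleDiskNeighbors <- function(radius) {
  out <- list()
  r <- ceiling(radius)
  for (dr in -r:r) for (dc in -r:r)
    if (dr^2 + dc^2 <= radius^2 + 1e-9) out[[length(out) + 1]] <- c(dr, dc)
  out
}

oraclePadReflect <- function(img, r) {
  ri <- vapply(seq(1 - r, nrow(img) + r), reflect1, numeric(1), n = nrow(img))
  ci <- vapply(seq(1 - r, ncol(img) + r), reflect1, numeric(1), n = ncol(img))
  img[ri, ci, drop = FALSE]
}

oracleBernsen <- function(img, radius, contrast, bitDepth = 8) {
  n <- nrow(img); m <- ncol(img)
  r <- ceiling(radius)
  p <- oraclePadReflect(img, r)
  nb <- do.call(rbind, oracleDiskNeighbors(radius))
  out <- matrix(FALSE, n, m)
  midgray <- (2^bitDepth - 1) / 2
  for (i in seq_len(n)) for (j in seq_len(m)) {
    vals <- p[cbind(i + r + nb[, 1], j + r + nb[, 2])]
    H <- max(vals); L <- min(vals); mid <- (H + L) / 2
    out[i, j] <- if (H - L >= contrast) img[i, j] > mid else mid >= midgray
  }
  out
}

oracleDiskDilate <- function(mask, radius) {
  n <- nrow(mask); m <- ncol(mask)
  nb <- oracleDiskNeighbors(radius)
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    for (d in nb) {
      ii <- i - d[1]; jj <- j - d[2]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m && mask[ii, jj]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

oracleFloodFill <- function(allowed, seed, connectivity = 4) {
  n <- nrow(allowed); m <- ncol(allowed)
  if (connectivity == 4) {
    nb <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  } else {
    nb <- list()
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) nb[[length(nb) + 1]] <- c(dr, dc)
  }
  vis <- matrix(FALSE, n, m)
  queue <- list(seed)
  vis[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in nb) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= n && q[2] >= 1 && q[2] <= m &&
          allowed[q[1], q[2]] && !vis[q[1], q[2]]) {
        vis[q[1], q[2]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
  }
  vis
}

# partition of a mask into connected components as a canonical list of
# sorted pixel-index vectors
oracleComponents <- function(mask, connectivity = 8) {
  comps <- list()
  remaining <- mask
  while (any(remaining)) {
    idx <- which(remaining)[1]
    seed <- c((idx - 1) %% nrow(mask) + 1, (idx - 1) %/% nrow(mask) + 1)
    comp <- oracleFloodFill(mask, seed, connectivity)
    comps[[length(comps) + 1]] <- sort(which(comp))
    remaining <- remaining & !comp
  }
  comps
}

canonicalComponents <- function(labels) {
  k <- max(labels)
  if (k == 0) return(list())
  out <- lapply(seq_len(k), function(l) sort(which(labels == l)))
  out[order(vapply(out, min, numeric(1)))]
}

oracleGroupMax <- function(stack, group) {
  n <- dim(stack)[3]
  starts <- seq(1, n, by = group)
  out <- array(0, c(dim(stack)[1:2], length(starts)))
  for (g in seq_along(starts)) {
    idx <- starts[g]:min(starts[g] + group - 1, n)
    for (i in seq_len(nrow(stack))) for (j in seq_len(ncol(stack)))
      out[i, j, g] <- max(stack[i, j, idx])
  }
  out
}

# direct 2D convolution with the same truncated normalized Gaussian kernel
# and symmetric-reflection borders
oracleGaussianSmooth <- function(img, sigma) {
  if (sigma == 0) return(img)
  k <- ceiling(3 * sigma)
  w1 <- exp(-((-k:k)^2) / (2 * sigma^2)); w1 <- w1 / sum(w1)
  W <- outer(w1, w1)
  p <- oraclePadReflect(img, k)
  n <- nrow(img); m <- ncol(img)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    out[i, j] <- sum(W * p[(i):(i + 2 * k), (j):(j + 2 * k)])
  out
}

# brute-force pixel enumeration of the half-maximum area of an isotropic
# Gaussian: pixels strictly above half of the (unit) maximum
oracleGaussianHalfMaxCount <- function(sigma, shape, center) {
  cnt <- 0L
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    d2 <- (i - center[1])^2 + (j - center[2])^2
    if (exp(-d2 / (2 * sigma^2)) > 0.5) cnt <- cnt + 1L
  }
  cnt
}
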