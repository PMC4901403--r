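# Low-level image operators with pinned-down semantics. These are written
# out in full (rather than delegated to EBImage) because the quantification
# contracts depend on their exact dialects: Euclidean disk structuring
# elements, symmetric-reflection borders, 4-connected region growing and
# 8-connected component labelling.

reflectIndex <- function(i, n) {
  # symmetric reflection with edge repetition: ... 2 1 | 1 2 ... n | n n-1 ...
  j <- (i - 1L) %% (2L * n)
  j[j < 0L] <- j[j < 0L] + 2L * n
  ifelse(j < n, j + 1L, 2L * n - j)
}

padReflect <- function(m, r) {
  ri <- reflectIndex(seq.int(1L - r, nrow(m) + r), nrow(m))
  ci <- reflectIndex(seq.int(1L - r, ncol(m) + r), ncol(m))
  m[ri, ci, drop = FALSE]
}

shiftMatrix <- function(m, dr, dc, fill = FALSE) {
  # value at (i, j) of the result is m[i - dr, j - dc]; outside -> fill
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  sr <- max(1L, 1L + dr):min(n, n + dr)
  sc <- max(1L, 1L + dc):min(p, p + dc)
  if (dr <= -n || dr >= n || dc <= -p || dc >= p) return(out)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Offsets of a Euclidean disk structuring element
#'
#' All integer offsets `(dr, dc)` with `dr^2 + dc^2 <= radiusPx^2`.
#'
#' @param radiusPx disk radius in pixels (>= 0).
#' @return integer matrix with columns `dr`, `dc`.
#' @export
diskOffsets <- function(radiusPx) {
  stopifnot(radiusPx >= 0)
  r <- floor(radiusPx)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radiusPx^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

#' Binary dilation by a Euclidean disk
#'
#' Pixels outside the image are treated as background.
#'
#' @param mask logical matrix.
#' @param radiusPx disk radius in pixels.
#' @return logical matrix of the same shape.
#' @export
diskDilate <- function(mask, radiusPx) {
  stopifnot(is.logical(mask), is.matrix(mask))
  off <- diskOffsets(radiusPx)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out | shiftMatrix(mask, off[k, 1], off[k, 2], fill = FALSE)
  out
}

# grayscale min/max over a disk neighbourhood, reflective borders
grayExtremeDisk <- function(img, radiusPx, fun) {
  r <- as.integer(ceiling(radiusPx))
  p <- padReflect(img, r)
  off <- diskOffsets(radiusPx)
  n <- nrow(img); m <- ncol(img)
  out <- NULL
  for (k in seq_len(nrow(off))) {
    sub <- p[(r + 1 + off[k, 1]):(r + n + off[k, 1]),
             (r + 1 + off[k, 2]):(r + m + off[k, 2]), drop = FALSE]
    out <- if (is.null(out)) sub else fun(out, sub)
  }
  out
}

#' Grayscale dilation / erosion by a Euclidean disk
#'
#' Local maximum (`grayDilate`) or minimum (`grayErode`) over the disk
#' neighbourhood, with symmetric-reflection borders.
#'
#' @param img numeric matrix.
#' @param radiusPx disk radius in pixels.
#' @return numeric matrix of the same shape.
#' @export
grayDilate <- function(img, radiusPx) grayExtremeDisk(img, radiusPx, pmax)

#' @rdname grayDilate
#' @export
grayErode <- function(img, radiusPx) grayExtremeDisk(img, radiusPx, pmin)

#' Median filter over a Euclidean disk
#'
#' With the default 1-pixel radius the neighbourhood is the 5-point cross
#' (centre plus 4-neighbours); borders are handled by symmetric reflection.
#'
#' @param img numeric matrix.
#' @param radiusPx disk radius in pixels (default 1).
#' @return numeric matrix of the same shape.
#' @export
medianFilterDisk <- function(img, radiusPx = 1) {
  r <- as.integer(ceiling(radiusPx))
  p <- padReflect(img, r)
  off <- diskOffsets(radiusPx)
  n <- nrow(img); m <- ncol(img)
  vals <- lapply(seq_len(nrow(off)), function(k)
    p[(r + 1 + off[k, 1]):(r + n + off[k, 1]),
      (r + 1 + off[k, 2]):(r + m + off[k, 2]), drop = FALSE])
  if (length(vals) == 5L) {
    # median of 5 as the max over all 3-subset minima (branch-free)
    sub3 <- combn(5L, 3L)
    out <- NULL
    for (s in seq_len(ncol(sub3))) {
      mn <- pmin(vals[[sub3[1, s]]], vals[[sub3[2, s]]], vals[[sub3[3, s]]])
      out <- if (is.null(out)) mn else pmax(out, mn)
    }
    return(out)
  }
  stacked <- vapply(vals, as.numeric, numeric(n * m))
  matrix(apply(stacked, 1, stats::median), n, m)
}

#' Seeded flood fill
#'
#' Grows the connected region of `TRUE` pixels of `allowed` containing
#' `seedXY`, using 4- or 8-connectivity.
#'
#' @param allowed logical matrix of fillable pixels.
#' @param seedXY integer `(row, col)` seed; must be `TRUE` in `allowed`.
#' @param connectivity 4 (default) or 8.
#' @return logical matrix: the filled region.
#' @export
floodFill <- function(allowed, seedXY, connectivity = 4) {
  stopifnot(is.logical(allowed), is.matrix(allowed))
  seedXY <- as.integer(seedXY)
  if (seedXY[1] < 1 || seedXY[1] > nrow(allowed) ||
      seedXY[2] < 1 || seedXY[2] > ncol(allowed))
    stop("seed outside image")
  if (!allowed[seedXY[1], seedXY[2]])
    stop("seed is not on a fillable pixel")
  sh <- if (connectivity == 4) {
    list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  } else if (connectivity == 8) {
    g <- expand.grid(dr = -1:1, dc = -1:1)
    g <- g[!(g$dr == 0 & g$dc == 0), ]
    lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i]))
  } else stop("connectivity must be 4 or 8")
  vis <- matrix(FALSE, nrow(allowed), ncol(allowed))
  vis[seedXY[1], seedXY[2]] <- TRUE
  frontier <- vis
  repeat {
    nb <- matrix(FALSE, nrow(allowed), ncol(allowed))
    for (s in sh) nb <- nb | shiftMatrix(frontier, s[1], s[2])
    newpx <- nb & allowed & !vis
    if (!any(newpx)) break
    vis <- vis | newpx
    frontier <- newpx
  }
  vis
}

#' Connected-component labelling
#'
#' Labels connected foreground components (8-connected by default) in raster
#' order of their first pixel.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (integer matrix, 0 = background),
#'   `nComponents`, and `sizes` (pixel count per label).
#' @export
connectedComponents <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  labels <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  remaining <- mask
  while (any(remaining)) {
    idx <- which(remaining)[1]
    seed <- c((idx - 1L) %% nrow(mask) + 1L, (idx - 1L) %/% nrow(mask) + 1L)
    comp <- floodFill(mask, seed, connectivity = connectivity)
    k <- k + 1L
    labels[comp] <- k
    remaining <- remaining & !comp
  }
  sizes <- if (k > 0) tabulate(labels[labels > 0L], nbins = k) else integer()
  list(labels = labels, nComponents = k, sizes = sizes)
}

#' Grouped maximum-intensity projection
#'
#' Projects non-overlapping groups of `group` consecutive slices to single
#' slices by pixel-wise maximum. A trailing remainder shorter than `group` is
#' projected as its own slice.
#'
#' @param stack numeric array `[row, col, slice]`.
#' @param group slices per group (default 5).
#' @return list with `projected` (`[row, col, nGroups]` array) and `groups`
#'   (list of source-slice indices per projection).
#' @export
maxProjectGroups <- function(stack, group = 5) {
  stopifnot(length(dim(stack)) == 3, group >= 1)
  n <- dim(stack)[3]
  groups <- split(seq_len(n), ceiling(seq_len(n) / group))
  proj <- array(0, c(dim(stack)[1:2], length(groups)))
  for (g in seq_along(groups)) {
    proj[, , g] <- Reduce(pmax, lapply(groups[[g]], function(i) stack[, , i]))
  }
  list(projected = proj, groups = unname(groups))
}

#' Spatial Gaussian smoothing
#'
#' Separable 2D Gaussian blur with standard deviation `radiusPx`, applied
#' independently per frame. The kernel is truncated at `ceiling(3 * radiusPx)`
#' taps per side and normalized to unit sum, with symmetric-reflection
#' borders, so a constant image (and the spatial mean) is preserved. A radius
#' of 0 is the identity. There is no temporal smoothing.
#'
#' @param x a `TrialStack`, or a numeric matrix (single frame).
#' @param radiusPx Gaussian standard deviation in pixels (>= 0; default 1.0).
#' @return object of the same type as `x`, smoothed.
#' @export
gaussianSmooth <- function(x, radiusPx = 1.0) {
  stopifnot(radiusPx >= 0)
  if (is(x, "TrialStack")) {
    f <- x@frames
    for (t in seq_len(dim(f)[3]))
      f[, , t] <- gaussianSmoothMatrix(f[, , t], radiusPx)
    return(new("TrialStack", frames = f, trialId = x@trialId))
  }
  stopifnot(is.matrix(x))
  gaussianSmoothMatrix(x, radiusPx)
}

gaussianKernel1d <- function(sigma) {
  k <- ceiling(3 * sigma)
  w <- exp(-((-k:k)^2) / (2 * sigma^2))
  w / sum(w)
}

gaussianSmoothMatrix <- function(m, sigma) {
  if (sigma == 0) return(m)
  w <- gaussianKernel1d(sigma)
  k <- (length(w) - 1L) / 2L
  p <- padReflect(m, k)
  n <- nrow(m); q <- ncol(m)
  # rows
  acc <- matrix(0, n, ncol(p))
  for (j in seq_along(w))
    acc <- acc + w[j] * p[(j):(j + n - 1L), , drop = FALSE]
  # cols
  out <- matrix(0, n, q)
  for (j in seq_along(w))
    out <- out + w[j] * acc[, (j):(j + q - 1L), drop = FALSE]
  out
}
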