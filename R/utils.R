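# Internal numeric helpers shared across modules.

# Wrap angles into [0, 2*pi).
wrapPhase <- function(x) x %% (2 * pi)

# Signed circular difference a - b, in (-pi, pi].
circDiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Flatten a (ny, nx, n) frame array to a (npix, n) matrix with each column
# zero-mean, unit-norm; constant frames become all-zero columns (their ZNCC
# against anything is 0). crossprod() of two such matrices gives the
# zero-normalized cross-correlation of every frame pair.
normalizeFrames <- function(arr) {
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1] * d[2], ncol = d[3])
  m <- sweep(m, 2, colMeans(m), "-")
  nrm <- sqrt(colSums(m^2))
  ok <- nrm > 0
  m[, ok] <- sweep(m[, ok, drop = FALSE], 2, nrm[ok], "/")
  m[, !ok] <- 0
  m
}

normalizeFrame <- function(frame) {
  v <- as.numeric(frame) - mean(frame)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v * 0
}

# Sub-sample peak localization: offset in [-0.5, 0.5] of the parabola through
# (-1, ym1), (0, y0), (1, yp1). Degenerate (flat) curvature returns 0.
quadPeakOffset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}

# 3-D connected-component labeling of a logical array.
# connectivity 26 (default) or 6. Foreground voxels become vertices of a
# graph whose edges join adjacent foreground voxels; components are labels.
label3D <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, d)
  if (!length(fg)) return(lab)
  id <- integer(prod(d))
  id[fg] <- seq_along(fg)

  offs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (connectivity == 26) {
    offs <- c(offs, list(
      c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
      c(0, 1, 1), c(0, 1, -1), c(1, 1, 1), c(1, 1, -1),
      c(1, -1, 1), c(1, -1, -1)))
  }
  ai <- arrayInd(fg, d)
  edges <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    ni <- ai[, 1] + o[1]; nj <- ai[, 2] + o[2]; nk <- ai[, 3] + o[3]
    keep <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    if (!any(keep)) next
    nlin <- (nk[keep] - 1L) * d[1] * d[2] + (nj[keep] - 1L) * d[1] + ni[keep]
    nid <- id[nlin]
    hit <- nid > 0L
    if (!any(hit)) next
    edges[[k]] <- rbind(id[fg[keep]][hit], nid[hit])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && ncol(em))
    g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# Grey-scale 3-D morphological closing of a logical array with a cubic
# 3x3x3 structuring element, via shift-based dilation then erosion.
closing3D <- function(mask) {
  erode <- function(m) shiftReduce(m, min)
  dilate <- function(m) shiftReduce(m, max)
  erode(dilate(mask))
}

shiftReduce <- function(mask, fun) {
  d <- dim(mask)
  out <- mask
  pad <- identical(fun, min)  # border treated as background for erosion
  for (o1 in -1:1) for (o2 in -1:1) for (o3 in -1:1) {
    if (o1 == 0 && o2 == 0 && o3 == 0) next
    sh <- array(if (pad) TRUE else FALSE, d)
    i1 <- seq_len(d[1]); i2 <- seq_len(d[2]); i3 <- seq_len(d[3])
    s1 <- i1 - o1; s2 <- i2 - o2; s3 <- i3 - o3
    k1 <- s1 >= 1 & s1 <= d[1]; k2 <- s2 >= 1 & s2 <= d[2]
    k3 <- s3 >= 1 & s3 <= d[3]
    sh[i1[k1], i2[k2], i3[k3]] <- mask[s1[k1], s2[k2], s3[k3]]
    out <- if (identical(fun, min)) out & sh else out | sh
  }
  out
}

# Otsu threshold of a numeric vector/array scaled to [0, 1].
otsuThreshold <- function(x) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng))) * diff(rng) + rng[1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
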