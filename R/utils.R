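# Low-level 3D array utilities shared across modules: neighbour shifts,
# Otsu thresholding, binary morphology, connected components, BFS wall
# distance and seeded evaluation. All operate on plain R arrays; voxel
# coordinates follow the package convention mm = (index - 1) * spacing
# (0-based voxel-center).

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so seeded phantom generation
#' never disturbs user-level randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a 3D array by `delta` voxels along `axis`; out[i] = a[i + delta],
# border positions take `fill`.
shiftArray <- function(a, axis, delta, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(delta) >= n) return(out)
  dst <- lapply(d, seq_len)
  src <- lapply(d, seq_len)
  if (delta >= 0) {
    dst[[axis]] <- seq_len(n - delta)
    src[[axis]] <- seq_len(n - delta) + delta
  } else {
    dst[[axis]] <- seq(1 - delta, n)
    src[[axis]] <- seq_len(n + delta)
  }
  piece <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(piece)))
}

# Edge-replicated shift (nearest-neighbour padding).
shiftArrayClamp <- function(a, axis, delta) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- pmin(pmax(idx[[axis]] + delta, 1L), d[axis])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Elementwise median across a list of equal-shaped numeric arrays,
# via a vectorised exchange-sort network (no apply()).
vecMedian <- function(cols) {
  k <- length(cols)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - i)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
      cols[[j + 1L]] <- hi
    }
  }
  if (k %% 2L == 1L) cols[[(k + 1L) %/% 2L]] else (cols[[k %/% 2L]] + cols[[k %/% 2L + 1L]]) / 2
}

#' Otsu threshold of a numeric array
#'
#' Histogram-based maximisation of between-class variance; used for the
#' PC-MRA lumen segmentation and the magnitude noise floor.
#'
#' @param x Numeric vector or array.
#' @param nbins Number of histogram bins.
#' @return Scalar threshold; values strictly above it belong to the
#'   foreground class.
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) == 0L) stop("otsuThreshold: no finite values")
  r <- range(x)
  if (diff(r) == 0) stop("otsuThreshold: constant image, no threshold exists")
  brk <- seq(r[1], r[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, brk, rightmost.closed = TRUE, all.inside = TRUE), nbins)
  mids <- (brk[-1L] + brk[-(nbins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  wTot <- w[nbins]
  mTot <- m[nbins]
  w0 <- w[-nbins]
  m0 <- m[-nbins]
  valid <- w0 > 0 & w0 < wTot
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (mTot * w0[valid] - wTot * m0[valid])^2 /
    (w0[valid] * (wTot - w0[valid]))
  k <- which.max(between)
  brk[k + 1L]
}

# 26- or 6-connected neighbour offsets (full set).
neighborOffsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# Undirected edge list over in-mask voxels for the given connectivity.
# Returns a list(from, to, length) of linear voxel indices and the
# Euclidean step length in mm. Each edge appears once.
maskEdges <- function(mask, spacing, connectivity = 26L) {
  d <- dim(mask)
  lin <- array(seq_along(mask), d)
  offs <- neighborOffsets(connectivity)
  # half-space of offsets so each undirected edge is emitted once
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  offs <- offs[keep, , drop = FALSE]
  from <- integer(0)
  to <- integer(0)
  len <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    nb <- lin
    nbMask <- mask
    for (ax in 1:3) {
      if (o[ax] != 0) {
        nb <- shiftArray(nb, ax, o[ax], fill = NA_integer_)
        nbMask <- shiftArray(nbMask, ax, o[ax], fill = FALSE)
      }
    }
    sel <- which(mask & nbMask)
    if (length(sel)) {
      from <- c(from, sel)
      to <- c(to, nb[sel])
      len <- c(len, rep(sqrt(sum((o * spacing)^2)), length(sel)))
    }
  }
  list(from = from, to = to, length = len)
}

# Largest 6-connected component of a binary mask.
largestComponent <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("largestComponent: empty mask")
  e <- maskEdges(mask, spacing = c(1, 1, 1), connectivity = 6L)
  remap <- integer(length(mask))
  remap[idx] <- seq_along(idx)
  g <- igraph::make_graph(rbind(remap[e$from], remap[e$to]),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, dim(mask))
  out[keep] <- TRUE
  out
}

# Binary closing with the 6-connected unit ball.
binaryClosing <- function(mask) {
  dil <- mask
  for (ax in 1:3) {
    for (dl in c(-1L, 1L)) dil <- dil | shiftArray(mask, ax, dl, fill = FALSE)
  }
  ero <- dil
  for (ax in 1:3) {
    for (dl in c(-1L, 1L)) ero <- ero & shiftArray(dil, ax, dl, fill = TRUE)
  }
  ero
}

# BFS (6-connected) distance-to-background in voxel steps; background and
# out-of-grid are distance 0, so boundary mask voxels get 1.
wallDistance <- function(mask) {
  d <- array(Inf, dim(mask))
  d[!mask] <- 0
  repeat {
    m <- d
    for (ax in 1:3) {
      for (dl in c(-1L, 1L)) {
        m <- pmin(m, shiftArray(d, ax, dl, fill = 0) + 1)
      }
    }
    m[!mask] <- 0
    if (identical(m, d)) break
    d <- m
  }
  d
}

# Voxel-center world coordinates (mm) of linear indices in a grid.
voxelCoords <- function(idx, dim, spacing) {
  i3 <- arrayInd(idx, dim)
  (i3 - 1) * rep(spacing, each = nrow(i3))
}

# Moving-average smoothing of a polyline (rows = points), window must be
# odd; endpoints use shrunken windows so the curve ends stay anchored.
smoothPolyline <- function(pts, window = 5L, passes = 1L) {
  n <- nrow(pts)
  if (window < 3L || n < window) return(pts)
  half <- (window - 1L) %/% 2L
  for (p in seq_len(passes)) {
    cs <- apply(rbind(0, pts), 2, cumsum)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    pts <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  }
  pts
}

# Cumulative arc length of a polyline in mm.
polylineArcLength <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg))
}

# Resample a polyline at (approximately) uniform arc-length spacing,
# keeping the exact end points.
resamplePolyline <- function(pts, step) {
  s <- polylineArcLength(pts)
  keep <- c(TRUE, diff(s) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  s <- s[keep]
  L <- s[length(s)]
  if (L <= 0) return(pts)
  n <- max(2L, round(L / step) + 1L)
  si <- seq(0, L, length.out = n)
  out <- sapply(1:3, function(k) stats::approx(s, pts[, k], xout = si)$y)
  matrix(out, ncol = 3)
}

# Squared-distance argmin from each query point (rows of q) to the rows of
# p, computed blockwise with BLAS. Returns list(index, dist2).
nearestPointIndex <- function(q, p, block = 20000L) {
  n <- nrow(q)
  pn2 <- rowSums(p^2)
  qn2 <- rowSums(q^2)
  idx <- integer(n)
  d2 <- numeric(n)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    qb <- q[s:e, , drop = FALSE]
    # argmin_j |q - p_j|^2 = argmax_j (2 q.p_j - |p_j|^2); |q|^2 added after
    score <- 2 * tcrossprod(qb, p)
    score <- score - rep(pn2, each = nrow(score))
    j <- max.col(score, ties.method = "first")
    idx[s:e] <- j
    d2[s:e] <- qn2[s:e] - score[cbind(seq_len(nrow(score)), j)]
  }
  d2[d2 < 0] <- 0
  list(index = idx, dist2 = d2)
}
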