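# Offline velocity corrections applied before analysis: phase-wrap
# correction (velocities beyond +/-VENC alias by multiples of 2*VENC) and
# background phase-offset removal by a weighted polynomial fit to static
# tissue.

#' Correct phase wraps in the velocity data
#'
#' Voxels whose velocity differs from the median of their 6-neighbourhood
#' by more than VENC are shifted by `2 * VENC` toward the neighbourhood
#' median, iterated until no voxel changes or `maxPasses` passes. Each
#' velocity component uses its own VENC. The provenance log records the
#' number of corrected voxels; non-convergence leaves the partial
#' correction in place with a warning.
#'
#' @param data A [FlowDataset-class].
#' @param maxPasses Maximum correction sweeps per component and frame.
#' @return The corrected [FlowDataset-class].
#' @export
unwrapVelocity <- function(data, maxPasses = 5L) {
  vel <- velocities(data)
  d <- dim(vel)
  nt <- d[5]
  vencs <- venc(data)
  totalFixed <- 0L
  unresolved <- 0L
  for (comp in 1:3) {
    vc <- vencs[comp]
    for (t in seq_len(nt)) {
      v <- array(vel[, , , comp, t], d[1:3])
      for (pass in seq_len(maxPasses)) {
        nb <- vector("list", 6L)
        k <- 0L
        for (ax in 1:3) {
          for (dl in c(-1L, 1L)) {
            k <- k + 1L
            nb[[k]] <- shiftArrayClamp(v, ax, dl)
          }
        }
        med <- vecMedian(nb)
        wrapped <- abs(v - med) > vc
        nw <- sum(wrapped)
        if (nw == 0L) break
        v[wrapped] <- v[wrapped] + 2 * vc * sign(med[wrapped] - v[wrapped])
        totalFixed <- totalFixed + nw
      }
      # convergence check after the final pass
      nb <- vector("list", 6L)
      k <- 0L
      for (ax in 1:3) {
        for (dl in c(-1L, 1L)) {
          k <- k + 1L
          nb[[k]] <- shiftArrayClamp(v, ax, dl)
        }
      }
      unresolved <- unresolved + sum(abs(v - vecMedian(nb)) > vc)
      vel[, , , comp, t] <- v
    }
  }
  if (unresolved > 0L) {
    warning("phase unwrap did not converge for ", unresolved,
            " voxels; partial correction kept")
  }
  data@velocity <- vel
  data@provenance <- c(data@provenance,
    sprintf("unwrap: %d voxel corrections applied (%d unresolved)",
            totalFixed, unresolved))
  data
}

#' Identify static tissue
#'
#' Marks voxels whose temporal standard deviation of speed is below
#' `threshold` and whose time-mean reference magnitude lies above an Otsu
#' noise floor. Pulsatile lumen voxels are excluded by the temporal
#' criterion; air by the magnitude criterion.
#'
#' @param data A [FlowDataset-class].
#' @param threshold Temporal speed-sd threshold, m/s; the default is 5% of
#'   the mean VENC, which separates pulsatile lumen from background by a
#'   wide margin in phantoms.
#' @return List of class `StaticTissueMask` with `mask` (logical 3D array)
#'   and `stat` (the temporal speed sd per voxel, m/s).
#' @export
identifyStaticTissue <- function(data, threshold = 0.05 * mean(venc(data))) {
  vel <- velocities(data)
  d <- dim(vel)
  nt <- d[5]
  if (nt < 2L) stop("identifyStaticTissue needs >= 2 timeframes")
  nvox <- prod(d[1:3])
  sumS <- numeric(nvox)
  sumS2 <- numeric(nvox)
  for (t in seq_len(nt)) {
    sp2 <- numeric(nvox)
    for (comp in 1:3) sp2 <- sp2 + as.numeric(vel[, , , comp, t])^2
    sp <- sqrt(sp2)
    sumS <- sumS + sp
    sumS2 <- sumS2 + sp^2
  }
  varS <- pmax(sumS2 / nt - (sumS / nt)^2, 0) * nt / (nt - 1)
  sdS <- array(sqrt(varS), d[1:3])
  mags <- magnitudes(data)
  meanS <- array(0, d[1:3])
  for (t in seq_len(nt)) meanS <- meanS + mags[, , , 1L, t]
  meanS <- meanS / nt
  floor <- tryCatch(otsuThreshold(meanS),
                    error = function(e) stop(
                      "cannot establish a magnitude noise floor: ",
                      conditionMessage(e)))
  mask <- sdS < threshold & meanS > floor
  if (!any(mask)) {
    stop("static tissue mask is empty; increase the temporal-sd threshold")
  }
  structure(list(mask = mask, stat = sdS), class = "StaticTissueMask")
}

# Polynomial design matrix of total degree <= order over normalised voxel
# coordinates in [-1, 1].
polyDesign <- function(coordsNorm, order) {
  terms <- expand.grid(i = 0:order, j = 0:order, k = 0:order)
  terms <- terms[rowSums(terms) <= order, , drop = FALSE]
  X <- matrix(1, nrow(coordsNorm), nrow(terms))
  for (c in seq_len(nrow(terms))) {
    X[, c] <- coordsNorm[, 1]^terms$i[c] *
      coordsNorm[, 2]^terms$j[c] *
      coordsNorm[, 3]^terms$k[c]
  }
  X
}

#' Remove background phase offsets
#'
#' Fits, per velocity component, a 3D polynomial of total degree <=
#' `order` to the velocities of static-tissue voxels by weighted least
#' squares (weights = time-mean reference magnitude, down-weighting noisy
#' voxels) and subtracts the fitted field from every voxel and timeframe.
#' By default the fit uses the time-averaged velocity (offsets are
#' quasi-static); `perTimeframe = TRUE` fits each frame separately.
#'
#' @param data A [FlowDataset-class].
#' @param static A `StaticTissueMask` from [identifyStaticTissue()].
#' @param order Total polynomial degree (default 4).
#' @param perTimeframe Fit per timeframe instead of on the time average.
#' @return The corrected [FlowDataset-class]; the provenance log records
#'   the residual static-tissue mean speed (norm of the mean residual
#'   velocity vector over static tissue, m/s), also available as
#'   `attr(, "residual")`.
#' @export
correctBackgroundPhase <- function(data, static, order = 4L,
                                   perTimeframe = FALSE) {
  stopifnot(inherits(static, "StaticTissueMask"))
  if (order < 0L) stop("order must be >= 0")
  vel <- velocities(data)
  d <- dim(vel)
  nt <- d[5]
  nvox <- prod(d[1:3])
  sIdx <- which(static$mask)
  nTerms <- nrow(subset(expand.grid(i = 0:order, j = 0:order, k = 0:order),
                        i + j + k <= order))
  if (length(sIdx) < nTerms) {
    stop("static mask has fewer voxels (", length(sIdx),
         ") than polynomial terms (", nTerms, ")")
  }
  i3 <- arrayInd(seq_len(nvox), d[1:3])
  coordsNorm <- sweep(sweep(i3 - 1, 2, (d[1:3] - 1) / 2, `-`),
                      2, pmax((d[1:3] - 1) / 2, 1), `/`)
  Xs <- polyDesign(coordsNorm[sIdx, , drop = FALSE], order)
  mags <- magnitudes(data)
  meanS <- array(0, d[1:3])
  for (t in seq_len(nt)) meanS <- meanS + mags[, , , 1L, t]
  w <- as.numeric(meanS)[sIdx] / nt
  if (all(w <= 0)) w <- rep(1, length(w))
  qrX <- qr(Xs * sqrt(w))
  if (qrX$rank < ncol(Xs)) {
    stop("rank-deficient polynomial design: static voxels support only ",
         qrX$rank, " of ", ncol(Xs), " terms (too few or collinear)")
  }
  Xall <- polyDesign(coordsNorm, order)
  fitOne <- function(y) {
    beta <- qr.coef(qrX, y * sqrt(w))
    as.numeric(Xall %*% beta)
  }
  residMean <- numeric(3)
  for (comp in 1:3) {
    if (perTimeframe) {
      res <- numeric(length(sIdx))
      for (t in seq_len(nt)) {
        y <- as.numeric(vel[, , , comp, t])
        offs <- fitOne(y[sIdx])
        vel[, , , comp, t] <- array(y - offs, d[1:3])
        res <- res + (y[sIdx] - offs[sIdx])
      }
      residMean[comp] <- mean(res / nt)
    } else {
      ybar <- numeric(nvox)
      for (t in seq_len(nt)) ybar <- ybar + as.numeric(vel[, , , comp, t])
      ybar <- ybar / nt
      offs <- fitOne(ybar[sIdx])
      for (t in seq_len(nt)) {
        vel[, , , comp, t] <- vel[, , , comp, t] - array(offs, d[1:3])
      }
      residMean[comp] <- mean(ybar[sIdx] - offs[sIdx])
    }
  }
  residual <- sqrt(sum(residMean^2))
  data@velocity <- vel
  data@provenance <- c(data@provenance,
    sprintf("background offset: degree-%d weighted fit to %d static voxels, residual mean speed %.3e m/s",
            order, length(sIdx), residual))
  attr(data, "residual") <- residual
  data
}
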