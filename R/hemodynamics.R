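# Voxel-wise hemodynamics: vorticity, absolute local normalized helicity,
# intravoxel fluctuation intensity and turbulent kinetic energy from the
# motion-encoded magnitude signal model, peak-systole windows, regional
# spatial-mean velocity and the Reynolds number.

#' Hemodynamic parameters
#'
#' @param rho Blood density, kg/m3 (default 1060).
#' @param mu Blood viscosity, Pa.s (default 3.5e-3).
#' @param systoleHalfwidth Half-width of the peak-systole window as a
#'   fraction of the cardiac cycle (default 0.05, i.e. +/-5%).
#' @param lnhEpsilon Floor on the product `|V||omega|` (m/s * 1/s) below
#'   which helicity is undefined (0/0) and the voxel is excluded from
#'   regional averages.
#' @return List of class `HemoParams`.
#' @export
hemoParams <- function(rho = 1060, mu = 3.5e-3, systoleHalfwidth = 0.05,
                       lnhEpsilon = 1e-6) {
  stopifnot(rho > 0, mu > 0, systoleHalfwidth >= 0, systoleHalfwidth < 0.5,
            lnhEpsilon >= 0)
  structure(list(rho = rho, mu = mu, systoleHalfwidth = systoleHalfwidth,
                 lnhEpsilon = lnhEpsilon), class = "HemoParams")
}

# Mask-aware spatial derivative along one axis: central differences where
# both neighbours are in-mask, one-sided where only one is, NA where
# neither is. h in meters so d(velocity)/dx is 1/s.
maskedDeriv <- function(a, mask, axis, h) {
  ap <- shiftArray(a, axis, 1L, fill = NA_real_)
  am <- shiftArray(a, axis, -1L, fill = NA_real_)
  mp <- shiftArray(mask, axis, 1L, fill = FALSE)
  mm <- shiftArray(mask, axis, -1L, fill = FALSE)
  d <- array(NA_real_, dim(a))
  both <- mask & mp & mm
  onlyP <- mask & mp & !mm
  onlyM <- mask & !mp & mm
  d[both] <- (ap[both] - am[both]) / (2 * h)
  d[onlyP] <- (ap[onlyP] - a[onlyP]) / h
  d[onlyM] <- (a[onlyM] - am[onlyM]) / h
  d
}

#' Compute the vorticity field of one timeframe
#'
#' Curl of the velocity (`omega = curl V`, 1/s) by central differences
#' where both axis neighbours lie inside the mask and one-sided
#' differences at the mask boundary; voxels for which a required
#' derivative has no in-mask neighbour are marked undefined (NA), never
#' zero-filled.
#'
#' @param velFrame 4D array `(nx, ny, nz, 3)`, m/s.
#' @param mask Logical lumen mask.
#' @param spacing Voxel spacing, mm.
#' @return 4D array `(nx, ny, nz, 3)` of vorticity, 1/s, NA outside the
#'   mask or where undefined.
#' @export
computeVorticity <- function(velFrame, mask, spacing) {
  if (!any(mask)) stop("empty mask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  hm <- spacing / 1000  # mm -> m
  vx <- velFrame[, , , 1]
  vy <- velFrame[, , , 2]
  vz <- velFrame[, , , 3]
  dvz_dy <- maskedDeriv(vz, mask, 2L, hm[2])
  dvy_dz <- maskedDeriv(vy, mask, 3L, hm[3])
  dvx_dz <- maskedDeriv(vx, mask, 3L, hm[3])
  dvz_dx <- maskedDeriv(vz, mask, 1L, hm[1])
  dvy_dx <- maskedDeriv(vy, mask, 1L, hm[1])
  dvx_dy <- maskedDeriv(vx, mask, 2L, hm[2])
  out <- array(NA_real_, c(dim(mask), 3L))
  out[, , , 1] <- dvz_dy - dvy_dz
  out[, , , 2] <- dvx_dz - dvz_dx
  out[, , , 3] <- dvy_dx - dvx_dy
  out
}

#' Absolute local normalized helicity
#'
#' `LNH = |V . omega| / (|V| |omega|)`: the absolute cosine of the angle
#' between velocity and vorticity. 0 means no helical flow, 1 maximally
#' helical; the range `[0, 1]` follows from Cauchy-Schwarz. Voxels where
#' `|V||omega|` falls below the epsilon floor are undefined (NA) and are
#' excluded from regional averages rather than set to 0.
#'
#' @param velFrame 4D array `(nx, ny, nz, 3)`, m/s.
#' @param vorticity 4D array from [computeVorticity()].
#' @param params A [hemoParams()] list.
#' @return 3D array of LNH in `[0, 1]`, NA where undefined.
#' @export
computeLnh <- function(velFrame, vorticity, params = hemoParams()) {
  dotVW <- velFrame[, , , 1] * vorticity[, , , 1] +
    velFrame[, , , 2] * vorticity[, , , 2] +
    velFrame[, , , 3] * vorticity[, , , 3]
  nV <- sqrt(velFrame[, , , 1]^2 + velFrame[, , , 2]^2 + velFrame[, , , 3]^2)
  nW <- sqrt(vorticity[, , , 1]^2 + vorticity[, , , 2]^2 + vorticity[, , , 3]^2)
  prod <- nV * nW
  lnh <- abs(dotVW) / prod
  lnh[!is.na(prod) & prod < params$lnhEpsilon] <- NA_real_
  pmin(lnh, 1)
}

#' Intravoxel velocity fluctuation intensity from magnitude ratios
#'
#' For asymmetric four-point encoding with motion sensitivity
#' `k_v = pi / VENC`, the fluctuation variance along direction i is
#' `sigma_i^2 = (2 / k_v^2) * ln(|S| / |S_i|)`. The estimate is signed:
#' noise can push `|S_i|` above `|S|`, giving a negative variance estimate
#' so that regional TKE can average slightly below zero instead of being
#' clamped.
#'
#' @param magsFrame 4D array `(nx, ny, nz, 4)`: reference then three
#'   encoded magnitudes.
#' @param venc VENC per direction, m/s (length 1 or 3).
#' @return 4D array `(nx, ny, nz, 3)` of signed sigma^2 in m2/s2, NA where
#'   either magnitude is nonpositive.
#' @export
computeSigmaSquared <- function(magsFrame, venc) {
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  if (any(venc <= 0)) stop("venc must be > 0")
  S <- magsFrame[, , , 1]
  out <- array(NA_real_, c(dim(S), 3L))
  for (i in 1:3) {
    kv <- pi / venc[i]
    Si <- magsFrame[, , , i + 1L]
    s2 <- (2 / kv^2) * log(S / Si)
    s2[S <= 0 | Si <= 0] <- NA_real_
    out[, , , i] <- s2
  }
  out
}

#' Turbulent kinetic energy per voxel
#'
#' `TKE = 1/2 * rho * sum_i sigma_i^2` in J/m3, signed per the sigma^2
#' convention.
#'
#' @param sigma2 4D array `(nx, ny, nz, 3)` from [computeSigmaSquared()].
#' @param params A [hemoParams()] list.
#' @return 3D array, J/m3.
#' @export
computeTke <- function(sigma2, params = hemoParams()) {
  0.5 * params$rho * (sigma2[, , , 1] + sigma2[, , , 2] + sigma2[, , , 3])
}

#' Find peak systole and its analysis window for a region
#'
#' Peak systole is the timeframe with the maximal spatial-mean speed over
#' the region (ties resolved to the earliest frame); the window contains
#' all frames whose cardiac-cycle fraction lies within the systolic
#' half-width of the peak's fraction, measured cyclically.
#'
#' @param data A [FlowDataset-class].
#' @param regionMask Logical 3D array of the region's voxels.
#' @param params A [hemoParams()] list.
#' @return List with `peakFrame` (index), `windowFrames` (integer vector
#'   containing the peak) and `meanSpeed` (per-frame regional mean speed).
#' @export
findPeakSystole <- function(data, regionMask, params = hemoParams()) {
  if (!any(regionMask)) stop("empty region")
  vel <- velocities(data)
  nt <- dim(vel)[5]
  idx <- which(regionMask)
  ms <- vapply(seq_len(nt), function(t) {
    sp2 <- vel[, , , 1, t][idx]^2 + vel[, , , 2, t][idx]^2 +
      vel[, , , 3, t][idx]^2
    mean(sqrt(sp2))
  }, numeric(1))
  peak <- which.max(ms)[1]
  f <- frameTimes(data)
  dd <- abs(f - f[peak])
  dd <- pmin(dd, 1 - dd)  # cyclic distance
  win <- which(dd <= params$systoleHalfwidth + 1e-9)
  list(peakFrame = peak, windowFrames = win, meanSpeed = ms)
}

#' Reynolds number
#'
#' `Re = rho * Velocity * D / mu` with the diameter converted from mm to
#' meters; dimensionless, linear in both velocity and diameter.
#'
#' @param velocity Spatial-mean velocity, m/s.
#' @param diameter Diameter, mm.
#' @param params A [hemoParams()] list.
#' @return Reynolds number.
#' @export
computeReynolds <- function(velocity, diameter, params = hemoParams()) {
  if (any(diameter <= 0)) stop("diameter must be > 0")
  if (any(velocity < 0)) stop("velocity must be >= 0")
  params$rho * velocity * (diameter / 1000) / params$mu
}

#' Regional hemodynamic and geometric metrics for one subject
#'
#' For each of the four regions and the whole aorta: finds the regional
#' peak-systole window, averages the absolute local normalized helicity,
#' the signed TKE and the speed over the region's defined lumen voxels and
#' the window frames, and joins tortuosity, diameter and Reynolds number.
#' Undefined voxels (NA helicity or TKE) are excluded from their
#' respective means and counted.
#'
#' @param data A [FlowDataset-class].
#' @param centerline A [Centerline-class].
#' @param partition A [RegionPartition-class].
#' @param params A [hemoParams()] list.
#' @return data.frame with one row per region (`AAo`, `DAo`, `SAA`, `IAA`,
#'   `Whole`): `tortuosity`, `diameter_mm`, `helicity`, `tke`, `velocity`,
#'   `reynolds`, `peak_frame`, `n_window`, `n_excluded_lnh`.
#' @export
aggregateRegionalMetrics <- function(data, centerline, partition,
                                     params = hemoParams()) {
  spacing <- voxelSpacing(data)
  labels <- regionLabels(partition)
  iv <- regionIntervals(partition)
  geo <- regionGeometry(centerline, partition, spacing)
  vel <- velocities(data)
  mags <- magnitudes(data)
  d3 <- dim(labels)

  nt <- dim(vel)[5]
  regions <- c(iv$region, "Whole")
  idxList <- lapply(regions, function(rg) {
    if (rg == "Whole") which(labels > 0L) else which(labels == match(rg, iv$region))
  })
  names(idxList) <- regions

  # per-frame regional mean speed in one pass over frames
  nvox <- prod(d3)
  vflat <- vel
  dim(vflat) <- c(nvox, 3L, nt)
  meanSpeed <- matrix(NA_real_, nt, length(regions),
                      dimnames = list(NULL, regions))
  lumenIdx <- idxList[["Whole"]]
  posList <- lapply(idxList, match, table = lumenIdx)
  for (t in seq_len(nt)) {
    spd <- sqrt(vflat[lumenIdx, 1, t]^2 + vflat[lumenIdx, 2, t]^2 +
                  vflat[lumenIdx, 3, t]^2)
    for (rg in regions) {
      if (length(posList[[rg]])) meanSpeed[t, rg] <- mean(spd[posList[[rg]]])
    }
  }
  f <- frameTimes(data)
  windowOf <- function(peak) {
    dd <- abs(f - f[peak])
    which(pmin(dd, 1 - dd) <= params$systoleHalfwidth + 1e-9)
  }

  # voxel-wise fields are computed once per needed frame and cached
  frameCache <- new.env(parent = emptyenv())
  fieldsFor <- function(t) {
    key <- as.character(t)
    if (!is.null(frameCache[[key]])) return(frameCache[[key]])
    vf <- vel[, , , , t]   # (nx, ny, nz, 3): frame dim drops
    mf <- mags[, , , , t]
    lumen <- labels > 0L
    vort <- computeVorticity(vf, lumen, spacing)
    lnh <- computeLnh(vf, vort, params)
    tke <- computeTke(computeSigmaSquared(mf, venc(data)), params)
    speed <- sqrt(vf[, , , 1]^2 + vf[, , , 2]^2 + vf[, , , 3]^2)
    frameCache[[key]] <- list(lnh = lnh, tke = tke, speed = speed)
    frameCache[[key]]
  }

  rows <- lapply(regions, function(rg) {
    idx <- idxList[[rg]]
    if (!length(idx)) {
      warning("region ", rg, " has no lumen voxels; metrics set to NA")
      return(data.frame(region = rg, tortuosity = NA_real_,
                        diameter_mm = NA_real_, helicity = NA_real_,
                        tke = NA_real_, velocity = NA_real_,
                        reynolds = NA_real_, peak_frame = NA_integer_,
                        n_window = 0L, n_excluded_lnh = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    peak <- which.max(meanSpeed[, rg])[1]
    win <- windowOf(peak)
    lnhVals <- c(); tkeVals <- c(); spVals <- c()
    nExcl <- 0L
    for (t in win) {
      fl <- fieldsFor(t)
      lv <- fl$lnh[idx]
      nExcl <- nExcl + sum(is.na(lv))
      lnhVals <- c(lnhVals, lv[!is.na(lv)])
      tv <- fl$tke[idx]
      tkeVals <- c(tkeVals, tv[!is.na(tv)])
      spVals <- c(spVals, fl$speed[idx])
    }
    g <- geo[geo$region == rg, ]
    velocity <- mean(spVals)
    data.frame(region = rg,
               tortuosity = g$tortuosity,
               diameter_mm = g$diameter_mm,
               helicity = if (length(lnhVals)) mean(lnhVals) else NA_real_,
               tke = if (length(tkeVals)) mean(tkeVals) else NA_real_,
               velocity = velocity,
               reynolds = computeReynolds(velocity, g$diameter_mm, params),
               peak_frame = peak,
               n_window = length(win),
               n_excluded_lnh = nExcl,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
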