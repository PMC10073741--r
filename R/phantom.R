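# Synthetic 4D flow phantom generator. Geometries are analytic space
# curves with closed-form (or densely integrated) arc length and chord, so
# tortuosity recovery can be tested against exact values; the flow model is
# a Poiseuille (or plug) axial profile plus a forced-vortex swirl, whose
# local normalized helicity has a closed form; the magnitude encoding is
# the exact inverse of the fluctuation estimation model.

#' Default single-peak systolic waveform
#'
#' A raised-sine-squared systolic pulse on the first 40% of the cycle over
#' a diastolic baseline. The maximum falls exactly on a sampled frame
#' (cycle fraction 0.2) for any frame count divisible by 5, so the peak is
#' unique.
#'
#' @param nTimeframes Number of reconstructed timeframes.
#' @param base Diastolic baseline weight.
#' @return Numeric weights in `(0, 1]` of length `nTimeframes`.
#' @export
systolicWaveform <- function(nTimeframes, base = 0.15) {
  f <- seq(0, 1, length.out = nTimeframes + 1L)[seq_len(nTimeframes)]
  w <- rep(base, nTimeframes)
  sys <- f < 0.4
  w[sys] <- base + (1 - base) * sin(pi * f[sys] / 0.4)^2
  w
}

defaultGeometryParams <- function(kind) {
  switch(kind,
    straight = list(length = 100),
    arc = list(radius = 50, angle = pi),
    helix = list(a = 10, b = 20, turns = 1),
    aorta_like = list(
      arch_radius = 26, asc_angle = 2.25, desc_angle = pi / 2,
      desc_length = 90, wiggle_amp = 1, wiggle_periods = 2,
      subclavian_angle = 0.5, renal_fraction = 0.64
    ),
    stop("unknown geometry kind: ", kind)
  )
}

# Densely sampled analytic curve in anatomy coordinates plus exact L, D, T
# and landmark positions. For straight/arc/helix L and D are closed-form;
# for the candy-cane aorta L comes from dense numerical integration of the
# parametrisation (the wiggled limb has no closed-form arc length).
analyticCurve <- function(kind, params, nSamples = 400L) {
  p <- params
  if (kind == "straight") {
    if (p$length <= 0) stop("degenerate curve: zero length")
    t <- seq(0, 1, length.out = nSamples)
    pts <- cbind(0, 0, p$length * t)
    L <- p$length
    D <- p$length
    lm <- c(aortic_valve = 0, iliac_bifurcation = L)
    lmPts <- rbind(pts[1, ], pts[nSamples, ])
  } else if (kind == "arc") {
    if (p$radius <= 0 || p$angle <= 0) stop("degenerate curve: zero length")
    th <- seq(0, p$angle, length.out = nSamples)
    pts <- cbind(p$radius * (1 - cos(th)), 0, p$radius * sin(th))
    L <- p$radius * p$angle
    D <- 2 * p$radius * sin(p$angle / 2)
    lm <- c(aortic_valve = 0, iliac_bifurcation = L)
    lmPts <- rbind(pts[1, ], pts[nSamples, ])
  } else if (kind == "helix") {
    if (p$a < 0 || p$turns <= 0) stop("degenerate curve: zero length")
    tmax <- 2 * pi * p$turns
    t <- seq(0, tmax, length.out = nSamples)
    pts <- cbind(p$a * cos(t), p$a * sin(t), p$b * t)
    L <- tmax * sqrt(p$a^2 + p$b^2)
    D <- sqrt(2 * p$a^2 * (1 - cos(tmax)) + (p$b * tmax)^2)
    lm <- c(aortic_valve = 0, iliac_bifurcation = L)
    lmPts <- rbind(pts[1, ], pts[nSamples, ])
  } else if (kind == "aorta_like") {
    R <- p$arch_radius
    if (R <= 0 || p$desc_length <= 0) stop("degenerate curve: zero length")
    arcLen <- R * (p$asc_angle + p$desc_angle)
    total <- arcLen + p$desc_length
    nArc <- max(8L, round(nSamples * arcLen / total))
    nLimb <- max(8L, nSamples - nArc)
    th <- seq(-p$asc_angle, p$desc_angle, length.out = nArc)
    arcPts <- cbind(R * sin(th), 0, R * cos(th))
    limbStart <- arcPts[nArc, ]
    u <- seq(0, p$desc_length, length.out = nLimb + 1L)[-1L]
    limbPts <- cbind(
      limbStart[1],
      p$wiggle_amp * sin(2 * pi * p$wiggle_periods * u / p$desc_length),
      limbStart[3] - u
    )
    pts <- rbind(arcPts, limbPts)
    s <- polylineArcLength(pts)
    L <- s[length(s)]
    D <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    # landmark arc lengths on the sampled curve
    sApex <- s[which.min(abs(th))]
    iSub <- which.min(abs(th - p$subclavian_angle))
    sSub <- s[iSub]
    limbS <- s[(nArc + 1L):length(s)] - s[nArc]
    limbArc <- limbS[length(limbS)]
    iRenal <- nArc + which.min(abs(limbS - p$renal_fraction * limbArc))
    sRenal <- s[iRenal]
    lm <- c(aortic_valve = 0, arch_top = sApex, left_subclavian = sSub,
            renal_branches = sRenal, iliac_bifurcation = L)
    lmPts <- rbind(pts[1, ], pts[which.min(abs(th)), ], pts[iSub, ],
                   pts[iRenal, ], pts[nrow(pts), ])
  } else {
    stop("unknown geometry kind: ", kind)
  }
  s <- polylineArcLength(pts)
  if (L <= 0 || max(s) <= 0) stop("degenerate curve: zero length")
  rownames(lmPts) <- names(lm)
  list(points = pts, s = s, L = L, D = D,
       tortuosity = (L / D - 1) * 100, landmarks = lm, landmarkPoints = lmPts)
}

#' Generate an analytic centerline with exact length, chord and tortuosity
#'
#' Returns a densely sampled space curve for the spec's geometry together
#' with its analytic arc length `L`, chord `D` and tortuosity
#' `T = (L/D - 1) * 100`. For the straight, arc and helix geometries L and
#' D are closed-form; the candy-cane aorta is integrated densely.
#'
#' @param spec A [PhantomSpec-class].
#' @param nSamples Number of curve samples (>= 200 keeps the polyline
#'   length within 0.05% of the analytic value).
#' @return List with `points` (n x 3 mm), `s` (cumulative arc length), `L`,
#'   `D`, `tortuosity`, `landmarks` (named arc-length positions) and
#'   `landmarkPoints`.
#' @examples
#' gc <- generateCenterline(phantomSpec("arc", list(radius = 50, angle = pi)))
#' gc$tortuosity  # (pi/2 - 1) * 100
#' @export
generateCenterline <- function(spec, nSamples = 400L) {
  analyticCurve(spec@geometryKind, spec@geometryParams, nSamples)
}

# Lumen radius at arc length s (linear proximal->distal taper).
lumenRadiusAt <- function(spec, s, L) {
  r <- spec@lumenRadius
  if (length(r) == 1L) return(rep(r, length(s)))
  r[1] + (r[2] - r[1]) * s / L
}

# Place the anatomy curve inside the voxel grid: translate so that the
# tube (curve plus max lumen radius plus an air margin) fits, and return
# the grid shape in voxels.
placeCurve <- function(spec, curve, marginVoxels = 2L) {
  sp <- spec@voxelSpacing
  rmax <- max(spec@lumenRadius)
  lo <- apply(curve$points, 2, min) - rmax
  hi <- apply(curve$points, 2, max) + rmax
  if (length(spec@gridShape) == 3L) {
    shape <- spec@gridShape
    extent <- (shape - 1L) * sp
    pad <- (extent - (hi - lo)) / 2
    if (any(pad < 0)) stop("lumen does not fit inside the requested grid")
    offset <- pad - lo
  } else {
    offset <- -lo + marginVoxels * sp
    shape <- as.integer(ceiling((hi - lo) / sp) + 2L * marginVoxels + 1L)
  }
  pts <- sweep(curve$points, 2, offset, `+`)
  lmPts <- sweep(curve$landmarkPoints, 2, offset, `+`)
  list(points = pts, landmarkPoints = lmPts, shape = shape)
}

# Unit tangents of a sampled curve by central differences.
curveTangents <- function(pts) {
  n <- nrow(pts)
  tg <- rbind(pts[2, ] - pts[1, ],
              pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE],
              pts[n, ] - pts[n - 1, ])
  tg / sqrt(rowSums(tg^2))
}

#' Generate the velocity field of a phantom
#'
#' Rasterises the tube around the centerline and fills it with an axial
#' profile (parabolic Poiseuille by default, or plug) scaled by the
#' cardiac waveform, plus a forced-vortex azimuthal component
#' `swirl_ratio * peakVelocity * (r / lumenRadius)`. Outside the lumen the
#' velocity is zero. Also returns the exact lumen mask, the prescribed
#' sigma field and per-voxel tube coordinates.
#'
#' @param spec A [PhantomSpec-class].
#' @param curve Placed curve as returned internally; if `NULL` it is
#'   generated and placed automatically.
#' @return List with `velocity` (nx, ny, nz, 3, nt), `lumenMask`,
#'   `sigmaField`, `shape`, `curve` (grid coordinates) and `r` (radial
#'   distance per lumen voxel).
#' @export
generateVelocityField <- function(spec, curve = NULL) {
  if (is.null(curve)) {
    curve <- generateCenterline(spec)
  }
  placed <- placeCurve(spec, curve)
  shape <- placed$shape
  sp <- spec@voxelSpacing
  pts <- placed$points
  tang <- curveTangents(pts)
  s <- curve$s
  L <- max(s)
  rmax <- max(spec@lumenRadius)
  nt <- length(spec@waveform)

  if (min(2 * spec@lumenRadius / sp) < 3) {
    warning("voxel spacing too coarse to resolve lumen (< 3 voxels across diameter)")
  }

  # candidate voxels: bounding box of the tube
  ax <- lapply(1:3, function(k) {
    idx <- which((seq_len(shape[k]) - 1) * sp >= min(pts[, k]) - rmax - sp &
                 (seq_len(shape[k]) - 1) * sp <= max(pts[, k]) + rmax + sp)
    idx
  })
  cand <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  candLin <- cand[, 1] + (cand[, 2] - 1L) * shape[1] +
    (cand[, 3] - 1L) * shape[1] * shape[2]
  coords <- (cand - 1) * sp

  # coarse-to-fine: prune voxels far from the tube with a subsampled
  # curve before the dense nearest-point query
  coarseStep <- max(1L, nrow(pts) %/% 50L)
  coarseIdx <- unique(c(seq(1L, nrow(pts), by = coarseStep), nrow(pts)))
  coarseGap <- max(diff(curve$s[coarseIdx]))
  npc <- nearestPointIndex(coords, pts[coarseIdx, , drop = FALSE])
  near <- sqrt(npc$dist2) <= rmax + coarseGap + sp
  cand <- cand[near, , drop = FALSE]
  candLin <- candLin[near]
  coords <- coords[near, , drop = FALSE]

  # rasterisation resolution: ~1 mm between query samples suffices at
  # 2.5 mm voxels; the full-resolution curve stays in the ground truth
  rasterStep <- max(1L, floor(nrow(pts) / max(2L, ceiling(L))))
  rIdx <- unique(c(seq(1L, nrow(pts), by = rasterStep), nrow(pts)))
  ptsR <- pts[rIdx, , drop = FALSE]
  tangR <- tang[rIdx, , drop = FALSE]
  sR <- s[rIdx]

  np <- nearestPointIndex(coords, ptsR)
  nearest <- np$index
  dvec <- coords - ptsR[nearest, , drop = FALSE]
  tHat <- tangR[nearest, , drop = FALSE]
  axial <- rowSums(dvec * tHat)
  perp <- dvec - axial * tHat
  r <- sqrt(rowSums(perp^2))
  lr <- lumenRadiusAt(spec, sR[nearest], L)

  inside <- r <= lr
  # flat end caps: beyond the curve ends the tube stops
  ds <- mean(diff(sR))
  atStart <- nearest == 1L
  atEnd <- nearest == length(rIdx)
  inside <- inside & !(atStart & axial < -ds / 2) & !(atEnd & axial > ds / 2)

  rho <- ifelse(lr > 0, pmin(r / lr, 1), 0)
  wAx <- if (spec@axialProfile == "parabolic") 1 - rho^2 else rep(1, length(rho))
  vAxial <- spec@peakVelocity * wAx
  vTheta <- spec@swirlRatio * spec@peakVelocity * rho

  rHat <- perp / ifelse(r > 0, r, 1)
  rHat[r == 0, ] <- 0
  aHat <- cbind(
    tHat[, 2] * rHat[, 3] - tHat[, 3] * rHat[, 2],
    tHat[, 3] * rHat[, 1] - tHat[, 1] * rHat[, 3],
    tHat[, 1] * rHat[, 2] - tHat[, 2] * rHat[, 1]
  )
  vpat <- vAxial * tHat + vTheta * aHat
  vpat[!inside, ] <- 0

  lumen <- array(FALSE, shape)
  lumen[candLin[inside]] <- TRUE

  nvox <- prod(shape)
  velocity <- array(0, c(nvox, 3L, nt))
  for (comp in 1:3) {
    base <- numeric(nvox)
    base[candLin] <- vpat[, comp]
    velocity[, comp, ] <- base %o% spec@waveform
  }
  dim(velocity) <- c(shape, 3L, nt)

  sigmaField <- array(0, shape)
  sigmaField[lumen] <- spec@sigmaLevel

  list(velocity = velocity, lumenMask = lumen, sigmaField = sigmaField,
       shape = shape, curve = list(points = pts, s = s,
                                   landmarkPoints = placed$landmarkPoints),
       r = r[inside], nearestS = sR[nearest][inside])
}

#' Encode the motion-sensitised MR magnitude signal
#'
#' Builds the reference magnitude volume and the three velocity-encoded
#' magnitudes according to the intravoxel-fluctuation attenuation model:
#' with `k_v = pi / VENC`, the noise-free encoded magnitude is
#' `|S_i| = |S| * exp(-k_v^2 sigma_i^2 / 2)`, which is the exact inverse of
#' the fluctuation estimation, so encode/decode round-trips exactly.
#' Rician noise is applied to every magnitude volume when the spec's SNR is
#' finite.
#'
#' @param spec A [PhantomSpec-class].
#' @param sigmaField 3D array of fluctuation intensity, m/s (isotropic
#'   across encoding directions).
#' @param lumenMask Logical 3D array.
#' @param baseline Magnitude of the lumen signal (arbitrary units).
#' @param tissue Magnitude of static tissue.
#' @param airShell Thickness (voxels) of the near-zero air shell at the
#'   grid boundary, giving the noise-floor class.
#' @return 5D array `(nx, ny, nz, 4, nt)`; volume 1 is the reference.
#' @export
encodeMrSignal <- function(spec, sigmaField, lumenMask,
                           baseline = 100, tissue = 60, airShell = 2L) {
  if (any(sigmaField < 0)) stop("sigma_field must be >= 0 everywhere")
  if (any(spec@venc <= 0)) stop("venc must be > 0")
  if (max(sigmaField) >= min(spec@venc)) {
    stop("sigma_level >= venc: signal model outside its valid regime")
  }
  shape <- dim(sigmaField)
  nt <- length(spec@waveform)
  S <- array(tissue, shape)
  S[lumenMask] <- baseline
  if (airShell > 0L) {
    inner <- array(FALSE, shape)
    inner[(airShell + 1L):(shape[1] - airShell),
          (airShell + 1L):(shape[2] - airShell),
          (airShell + 1L):(shape[3] - airShell)] <- TRUE
    S[!inner] <- 0
  }
  nvox <- prod(shape)
  mags <- array(0, c(nvox, 4L, nt))
  enc <- vector("list", 4L)
  enc[[1]] <- as.numeric(S)
  for (i in 1:3) {
    kv <- pi / spec@venc[i]
    enc[[i + 1L]] <- as.numeric(S * exp(-kv^2 * sigmaField^2 / 2))
  }
  noiseSd <- if (is.finite(spec@snr)) baseline / spec@snr else 0
  for (j in 1:4) {
    if (noiseSd > 0) {
      re <- matrix(enc[[j]], nvox, nt) +
        stats::rnorm(nvox * nt, 0, noiseSd)
      im <- stats::rnorm(nvox * nt, 0, noiseSd)
      mags[, j, ] <- sqrt(re^2 + im^2)
    } else {
      mags[, j, ] <- enc[[j]] %o% rep(1, nt)
    }
  }
  dim(mags) <- c(shape, 4L, nt)
  mags
}

#' Generate one complete synthetic subject
#'
#' Runs centerline generation, velocity synthesis and magnitude encoding
#' under the spec's seed and assembles a [FlowDataset-class] plus its
#' [GroundTruth-class].
#'
#' @param spec A [PhantomSpec-class].
#' @return List with elements `data` (FlowDataset) and `truth`
#'   (GroundTruth).
#' @examples
#' ph <- generatePhantom(phantomSpec("straight", nTimeframes = 5L))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    curve <- generateCenterline(spec)
    vf <- generateVelocityField(spec, curve)
    mags <- encodeMrSignal(spec, vf$sigmaField, vf$lumenMask)
    velocity <- vf$velocity
    if (spec@velocityNoise && is.finite(spec@snr)) {
      sdv <- mean(spec@venc) / (spec@snr * pi)
      velocity <- velocity + array(stats::rnorm(length(velocity), 0, sdv),
                                   dim(velocity))
    }
    data <- FlowDataset(velocity, mags, spec@venc, spec@voxelSpacing,
                        provenance = sprintf("phantom %s seed %d",
                                             spec@geometryKind, spec@seed))
    peak <- which.max(spec@waveform)[1]
    meanAx <- if (spec@axialProfile == "parabolic") 0.5 else 1
    truth <- new("GroundTruth",
                 centerline = vf$curve$points,
                 arcLength = vf$curve$s,
                 curveLength = curve$L, chordLength = curve$D,
                 tortuosity = curve$tortuosity,
                 lumenMask = vf$lumenMask,
                 landmarks = curve$landmarks,
                 landmarkPoints = vf$curve$landmarkPoints,
                 sigmaLevel = spec@sigmaLevel, swirlRatio = spec@swirlRatio,
                 peakFrame = as.integer(peak),
                 meanSpeed = spec@peakVelocity * meanAx * spec@waveform[peak])
    list(data = data, truth = truth)
  })
}
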