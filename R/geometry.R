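# Geometry pipeline: PC-MRA construction, lumen segmentation, centerline
# extraction, landmark placement, four-region partition, tortuosity and
# diameter.

#' Compute the phase-contrast MR angiogram
#'
#' `PCMRA(x) = sqrt( mean_t( |S(x,t)|^2 * |v(x,t)|^2 ) )`, combining the
#' reference magnitude and the speed so that the flowing lumen is bright
#' and static tissue dark.
#'
#' @param data A [FlowDataset-class].
#' @return Nonnegative 3D array; zero wherever speed is zero at all times.
#' @export
computePcmra <- function(data) {
  vel <- velocities(data)
  mags <- magnitudes(data)
  d <- dim(vel)
  nt <- d[5]
  nvox <- prod(d[1:3])
  dim(vel) <- c(nvox, 3L, nt)
  dim(mags) <- c(nvox, 4L, nt)
  acc <- numeric(nvox)
  for (t in seq_len(nt)) {
    sp2 <- vel[, 1, t]^2 + vel[, 2, t]^2 + vel[, 3, t]^2
    acc <- acc + mags[, 1, t]^2 * sp2
  }
  array(sqrt(acc / nt), d[1:3])
}

#' Segment the aortic lumen from a PC-MRA
#'
#' Hysteresis thresholding seeded by Otsu: the largest 6-connected
#' component above the Otsu threshold seeds a region grown through all
#' voxels above `lowFraction` times that threshold, followed by a
#' one-voxel-ball morphological closing. The low threshold recovers the
#' slow-flow rim of the lumen that a single global threshold clips, while
#' connectivity keeps background speckle out.
#'
#' @param pcmra Nonnegative 3D array from [computePcmra()].
#' @param lowFraction Low-to-high threshold ratio for the hysteresis
#'   growth.
#' @return Logical 3D lumen mask.
#' @export
segmentLumen <- function(pcmra, lowFraction = 0.25) {
  if (any(pcmra < 0)) stop("PC-MRA must be nonnegative")
  if (max(pcmra) == 0) stop("empty segmentation: PC-MRA is identically zero")
  thr <- otsuThreshold(pcmra)
  seed <- pcmra > thr
  if (!any(seed)) stop("empty segmentation: no voxels above threshold")
  seed <- largestComponent(seed)
  cand <- pcmra > lowFraction * thr
  # keep the candidate component(s) containing the seed
  idx <- which(cand)
  e <- maskEdges(cand, spacing = c(1, 1, 1), connectivity = 6L)
  remap <- integer(length(cand))
  remap[idx] <- seq_along(idx)
  g <- igraph::make_graph(rbind(remap[e$from], remap[e$to]),
                          n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  keepComp <- unique(memb[remap[which(seed)]])
  mask <- array(FALSE, dim(cand))
  mask[idx[memb %in% keepComp]] <- TRUE
  binaryClosing(mask)
}

#' Extract an ordered lumen centerline
#'
#' Three stages. (1) Minimal path: a 26-connected graph over the mask
#' voxels with medialness weighting (edge weight = Euclidean step length
#' divided by the 4th power of the mean wall distance of its endpoints)
#' pulls a shortest path between the mask voxels nearest the two supplied
#' endpoints onto the medial axis. (2) The voxel path, pinned to the exact
#' endpoint coordinates, is resampled at uniform spacing and each interior
#' knot is moved to the centroid of the lumen voxels in its perpendicular
#' slab, iterated with a light moving-average smoothing; the slab centroid
#' is the exact cross-section centre for a tubular lumen, which removes
#' the voxel-path meander without the corner-cutting a strong smoothing
#' would introduce. (3) Arc length is accumulated on the refined path.
#'
#' @param mask Logical 3D lumen mask.
#' @param spacing Voxel spacing, mm (length 1 or 3).
#' @param endpoints 2 x 3 matrix of mm coordinates: proximal (valve) end
#'   first, distal (iliac) end second.
#' @param knotSpacing Resampling interval in mm; default twice the mean
#'   voxel spacing.
#' @param refineIterations Centroid-refinement iterations.
#' @param smoothWindow Moving-average window (points, odd) applied within
#'   each refinement iteration.
#' @return A [Centerline-class], ordered from the proximal endpoint.
#' @export
extractCenterline <- function(mask, spacing, endpoints,
                              knotSpacing = NULL, refineIterations = 3L,
                              smoothWindow = 5L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(knotSpacing)) knotSpacing <- 2 * mean(spacing)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask")
  wd <- wallDistance(mask)
  e <- maskEdges(mask, spacing, connectivity = 26L)
  remap <- integer(length(mask))
  remap[idx] <- seq_along(idx)
  medial <- ((wd[e$from] + wd[e$to]) / 2)^4
  g <- igraph::make_graph(rbind(remap[e$from], remap[e$to]),
                          n = length(idx), directed = FALSE)
  coords <- voxelCoords(idx, dim(mask), spacing)
  endpoints <- matrix(as.numeric(endpoints), ncol = 3)
  ends <- nearestPointIndex(endpoints, coords)$index
  comp <- igraph::components(g)
  if (comp$membership[ends[1]] != comp$membership[ends[2]]) {
    stop("endpoints are disconnected in the lumen graph (components ",
         comp$membership[ends[1]], " and ", comp$membership[ends[2]], ")")
  }
  path <- igraph::shortest_paths(g, from = ends[1], to = ends[2],
                                 weights = e$length / medial,
                                 output = "vpath")$vpath[[1]]
  pts <- coords[as.integer(path), , drop = FALSE]
  # pin the exact endpoint coordinates, then refine the interior
  pts <- rbind(endpoints[1, ], pts, endpoints[2, ])
  pts <- resamplePolyline(pts, knotSpacing)
  for (it in seq_len(refineIterations)) {
    n <- nrow(pts)
    tg <- curveTangents(pts)
    asg <- nearestPointIndex(coords, pts)
    axial <- rowSums((coords - pts[asg$index, , drop = FALSE]) *
                       tg[asg$index, , drop = FALSE])
    inSlab <- abs(axial) <= knotSpacing / 2
    upd <- pts
    for (k in setdiff(unique(asg$index[inSlab]), c(1L, n))) {
      upd[k, ] <- colMeans(coords[inSlab & asg$index == k, , drop = FALSE])
    }
    upd <- smoothPolyline(upd, window = smoothWindow, passes = 1L)
    upd[1, ] <- pts[1, ]
    upd[n, ] <- pts[n, ]
    pts <- resamplePolyline(upd, knotSpacing)
  }
  s <- polylineArcLength(pts)
  keep <- c(TRUE, diff(s) > 1e-9)
  new("Centerline", points = pts[keep, , drop = FALSE], s = s[keep])
}

#' Locate the top of the aortic arch
#'
#' The arch top is the most superior centerline point: the point with the
#' maximal coordinate along the superior axis, ties broken by the smallest
#' arc length.
#'
#' @param centerline A [Centerline-class].
#' @param superiorAxis Axis index (1-3) of the superior direction
#'   (default 3, the grid z axis).
#' @return Arc-length position (mm) of the arch top.
#' @details The discrete maximum is refined by fitting a parabola to the
#'   superior coordinate at the three knots around it, giving a
#'   continuous apex position; without this the apex snaps to the knot
#'   grid and jitters by the knot spacing on flat arches.
#' @export
locateArchTop <- function(centerline, superiorAxis = 3L) {
  z <- centerlinePoints(centerline)[, superiorAxis]
  s <- arcLength(centerline)
  k <- which.max(z)
  if (k == 1L || k == length(z)) return(s[k])
  # parabolic vertex through (s, z) at k-1, k, k+1
  s3 <- s[(k - 1L):(k + 1L)]
  z3 <- z[(k - 1L):(k + 1L)]
  if (z3[2] <= z3[1] || z3[2] <= z3[3]) return(s[k])  # plateau: smallest s wins
  denom <- (s3[1] - s3[2]) * (s3[1] - s3[3]) * (s3[2] - s3[3])
  a <- (s3[3] * (z3[2] - z3[1]) + s3[2] * (z3[1] - z3[3]) +
          s3[1] * (z3[3] - z3[2])) / denom
  b <- (s3[3]^2 * (z3[1] - z3[2]) + s3[2]^2 * (z3[3] - z3[1]) +
          s3[1]^2 * (z3[2] - z3[3])) / denom
  if (a >= 0) return(s[k])  # flat or degenerate: keep the first maximum
  min(max(-b / (2 * a), s3[1]), s3[3])
}

# Map landmark points (mm) to arc-length positions on a centerline by
# continuous projection onto the polyline (nearest knot, then orthogonal
# projection onto its adjacent segments).
mapLandmarks <- function(centerline, landmarkPoints) {
  pts <- centerlinePoints(centerline)
  sArc <- arcLength(centerline)
  n <- nrow(pts)
  idx <- nearestPointIndex(landmarkPoints, pts)$index
  s <- vapply(seq_len(nrow(landmarkPoints)), function(i) {
    k <- idx[i]
    p <- landmarkPoints[i, ]
    best <- sArc[k]
    bestD <- sum((p - pts[k, ])^2)
    for (j in c(k - 1L, k)) {
      if (j < 1L || j >= n) next
      seg <- pts[j + 1L, ] - pts[j, ]
      len2 <- sum(seg^2)
      if (len2 <= 0) next
      t <- min(max(sum((p - pts[j, ]) * seg) / len2, 0), 1)
      q <- pts[j, ] + t * seg
      d <- sum((p - q)^2)
      if (d < bestD) {
        bestD <- d
        best <- sArc[j] + t * (sArc[j + 1L] - sArc[j])
      }
    }
    best
  }, numeric(1))
  names(s) <- rownames(landmarkPoints)
  s
}

#' Partition the aorta into the four analysis regions
#'
#' Region intervals on the centerline: AAo = `[valve, arch_top)`, DAo =
#' `[arch_top, midway(subclavian, renal))` with the midway point taken in
#' arc length, SAA = `[midway, renal)`, IAA = `[renal, iliac]`. Every
#' lumen voxel is labelled with the region of its nearest centerline
#' point.
#'
#' @param centerline A [Centerline-class].
#' @param landmarks Named numeric arc-length positions containing
#'   `aortic_valve`, `left_subclavian`, `renal_branches`,
#'   `iliac_bifurcation`, and optionally `arch_top` (otherwise located via
#'   [locateArchTop()]).
#' @param mask Logical lumen mask to label.
#' @param spacing Voxel spacing, mm.
#' @param superiorAxis Superior axis for the arch-top rule.
#' @return A [RegionPartition-class].
#' @export
partitionRegions <- function(centerline, landmarks, mask, spacing,
                             superiorAxis = 3L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  sv <- landmarks[["aortic_valve"]]
  ssub <- landmarks[["left_subclavian"]]
  sren <- landmarks[["renal_branches"]]
  sil <- landmarks[["iliac_bifurcation"]]
  sarch <- if ("arch_top" %in% names(landmarks)) landmarks[["arch_top"]]
           else locateArchTop(centerline, superiorAxis)
  mid <- (ssub + sren) / 2
  bounds <- c(sv, sarch, mid, sren, sil)
  if (any(diff(bounds) <= 0)) {
    lab <- c("aortic_valve", "arch_top", "midway", "renal_branches",
             "iliac_bifurcation")
    bad <- which(diff(bounds) <= 0)
    stop("landmark ordering violated: ", lab[bad[1]], " (",
         format(bounds[bad[1]]), " mm) >= ", lab[bad[1] + 1L], " (",
         format(bounds[bad[1] + 1L]), " mm)")
  }
  regions <- c("AAo", "DAo", "SAA", "IAA")
  intervals <- data.frame(region = regions,
                          s_start = bounds[1:4], s_end = bounds[2:5],
                          stringsAsFactors = FALSE)
  idx <- which(mask)
  labels <- array(0L, dim(mask))
  if (length(idx)) {
    coords <- voxelCoords(idx, dim(mask), spacing)
    nearestS <- arcLength(centerline)[
      nearestPointIndex(coords, centerlinePoints(centerline))$index]
    reg <- findInterval(nearestS, bounds[2:4]) + 1L  # 1..4
    labels[idx] <- reg
  }
  new("RegionPartition", intervals = intervals, labels = labels,
      regionNames = regions)
}

#' Tortuosity of a centerline interval
#'
#' `T = (L / D - 1) * 100` where `L` is the centerline arc length over the
#' interval and `D` the Euclidean (chord) distance between the interval's
#' end points.
#'
#' @param centerline A [Centerline-class].
#' @param interval Length-2 numeric `c(s_start, s_end)` in mm; defaults to
#'   the full centerline.
#' @return Tortuosity in percent.
#' @export
computeTortuosity <- function(centerline, interval = range(arcLength(centerline))) {
  s <- arcLength(centerline)
  if (interval[1] < s[1] - 1e-9 || interval[2] > s[length(s)] + 1e-9 ||
      interval[2] <= interval[1]) {
    stop("interval outside centerline range")
  }
  pts <- centerlinePoints(centerline)
  # interpolate the exact interval endpoints on the polyline instead of
  # snapping to the nearest sample
  interpAt <- function(sq) {
    sq <- min(max(sq, s[1]), s[length(s)])
    j <- findInterval(sq, s, all.inside = TRUE)
    t <- (sq - s[j]) / (s[j + 1L] - s[j])
    pts[j, ] + t * (pts[j + 1L, ] - pts[j, ])
  }
  L <- interval[2] - interval[1]
  D <- sqrt(sum((interpAt(interval[2]) - interpAt(interval[1]))^2))
  if (D <= 1e-9) stop("coincident interval endpoints (D = 0)")
  if (L <= 0) stop("zero-length interval")
  (L / D - 1) * 100
}

#' Mean-cross-section diameter of a region
#'
#' `D = 2 * sqrt(A / pi)` with `A = regional lumen volume / regional
#' centerline length`: the equivalent-circle diameter of the mean cross
#' section.
#'
#' @param partition A [RegionPartition-class].
#' @param region Region name, or `"Whole"` for the entire aorta.
#' @param spacing Voxel spacing, mm.
#' @return Diameter in mm.
#' @export
computeDiameter <- function(partition, region, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  iv <- regionIntervals(partition)
  if (identical(region, "Whole")) {
    nvox <- sum(regionLabels(partition) > 0L)
    L <- max(iv$s_end) - min(iv$s_start)
  } else {
    k <- match(region, iv$region)
    if (is.na(k)) stop("unknown region: ", region)
    nvox <- sum(regionLabels(partition) == k)
    L <- iv$s_end[k] - iv$s_start[k]
  }
  if (nvox == 0L) stop("empty region: ", region)
  if (L <= 0) stop("zero-length region: ", region)
  A <- nvox * prod(spacing) / L
  2 * sqrt(A / pi)
}

#' Per-region geometry table
#'
#' Tortuosity, centerline length, chord, diameter and volume for the four
#' regions and the whole aorta.
#'
#' @param centerline A [Centerline-class].
#' @param partition A [RegionPartition-class].
#' @param spacing Voxel spacing, mm.
#' @return data.frame with one row per region plus `Whole`.
#' @export
regionGeometry <- function(centerline, partition, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  iv <- regionIntervals(partition)
  rows <- lapply(c(iv$region, "Whole"), function(rg) {
    if (rg == "Whole") {
      a <- min(iv$s_start); b <- max(iv$s_end)
      nvox <- sum(regionLabels(partition) > 0L)
    } else {
      k <- match(rg, iv$region)
      a <- iv$s_start[k]; b <- iv$s_end[k]
      nvox <- sum(regionLabels(partition) == k)
    }
    data.frame(region = rg,
               tortuosity = computeTortuosity(centerline, c(a, b)),
               length_mm = b - a,
               chord_mm = (b - a) / (computeTortuosity(centerline, c(a, b)) / 100 + 1),
               diameter_mm = computeDiameter(partition, if (rg == "Whole") "Whole" else rg, spacing),
               volume_mm3 = nvox * prod(spacing),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
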