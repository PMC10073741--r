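#' @import methods
NULL

# ---------------------------------------------------------------------------
# FlowDataset
# ---------------------------------------------------------------------------

#' FlowDataset: a time-resolved 3D phase-contrast velocity dataset
#'
#' Container for one subject's 4D flow MRI data: the velocity vector field,
#' the four motion-encoding magnitude volumes (one reference plus three
#' velocity-encoded, the asymmetric four-point scheme), the per-direction
#' velocity-encoding limit (VENC) and the voxel spacing. Velocities are in
#' m/s in grid axes; magnitudes are arbitrary units and nonnegative.
#'
#' @slot velocity 5D numeric array `(nx, ny, nz, 3, nt)`, m/s.
#' @slot magnitudes 5D numeric array `(nx, ny, nz, 4, nt)`; volume 1 is the
#'   reference `|S|`, volumes 2-4 the encoded `|S_i|`.
#' @slot venc Numeric length 3, m/s, one value per encoding direction.
#' @slot voxelSpacing Numeric length 3, mm.
#' @slot frameTimes Numeric length `nt`, position of each timeframe in the
#'   cardiac cycle on `[0, 1)`, strictly increasing.
#' @slot provenance Character vector, free-text processing log.
#' @export
setClass("FlowDataset",
  representation(
    velocity = "array",
    magnitudes = "array",
    venc = "numeric",
    voxelSpacing = "numeric",
    frameTimes = "numeric",
    provenance = "character"
  )
)

setValidity("FlowDataset", function(object) {
  dv <- dim(object@velocity)
  dm <- dim(object@magnitudes)
  msg <- character(0)
  if (length(dv) != 5L || dv[4] != 3L) {
    msg <- c(msg, "velocity must be (nx, ny, nz, 3, nt)")
  }
  if (length(dm) != 5L || dm[4] != 4L) {
    msg <- c(msg, "magnitudes must be (nx, ny, nz, 4, nt): one reference and three encoded volumes")
  }
  if (length(dv) == 5L && length(dm) == 5L &&
      (!all(dv[1:3] == dm[1:3]) || dv[5] != dm[5])) {
    msg <- c(msg, "velocity and magnitude grids/timeframes disagree")
  }
  if (anyNA(object@velocity) || any(!is.finite(object@velocity))) {
    msg <- c(msg, "velocity must be finite")
  }
  if (any(object@magnitudes < 0)) msg <- c(msg, "magnitudes must be >= 0")
  if (length(object@venc) != 3L || any(object@venc <= 0)) {
    msg <- c(msg, "venc must be 3 positive values (m/s)")
  }
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0)) {
    msg <- c(msg, "voxelSpacing must be 3 positive values (mm)")
  }
  nt <- if (length(dv) == 5L) dv[5] else NA_integer_
  ft <- object@frameTimes
  if (!is.na(nt) && length(ft) != nt) {
    msg <- c(msg, "frameTimes must have one entry per timeframe")
  }
  if (length(ft) > 1L && any(diff(ft) <= 0)) {
    msg <- c(msg, "frameTimes must be strictly increasing")
  }
  if (length(ft) && (any(ft < 0) || any(ft >= 1))) {
    msg <- c(msg, "frameTimes must lie in [0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FlowDataset
#'
#' @param velocity 5D array `(nx, ny, nz, 3, nt)`, m/s.
#' @param magnitudes 5D array `(nx, ny, nz, 4, nt)`, arbitrary units.
#' @param venc VENC in m/s; length 1 (recycled) or 3.
#' @param voxelSpacing Voxel spacing in mm; length 1 (recycled) or 3.
#' @param frameTimes Cardiac-cycle fractions per frame; defaults to a
#'   uniform grid `(0, 1/nt, ...)`.
#' @param provenance Initial processing-log lines.
#' @return A [FlowDataset-class] object.
#' @export
FlowDataset <- function(velocity, magnitudes, venc, voxelSpacing,
                        frameTimes = NULL, provenance = character(0)) {
  nt <- dim(velocity)[5]
  if (is.null(frameTimes)) frameTimes <- seq(0, 1, length.out = nt + 1L)[seq_len(nt)]
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  if (length(voxelSpacing) == 1L) voxelSpacing <- rep(voxelSpacing, 3L)
  new("FlowDataset",
      velocity = velocity, magnitudes = magnitudes,
      venc = as.numeric(venc), voxelSpacing = as.numeric(voxelSpacing),
      frameTimes = as.numeric(frameTimes), provenance = provenance)
}

#' @describeIn FlowDataset-class velocity array accessor
#' @param object,x A `FlowDataset`.
#' @export
setGeneric("velocities", function(object) standardGeneric("velocities"))
#' @rdname FlowDataset-class
#' @export
setMethod("velocities", "FlowDataset", function(object) object@velocity)

#' @rdname FlowDataset-class
#' @export
setGeneric("magnitudes", function(object) standardGeneric("magnitudes"))
#' @rdname FlowDataset-class
#' @export
setMethod("magnitudes", "FlowDataset", function(object) object@magnitudes)

#' @rdname FlowDataset-class
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))
#' @rdname FlowDataset-class
#' @export
setMethod("venc", "FlowDataset", function(object) object@venc)

#' @rdname FlowDataset-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname FlowDataset-class
#' @export
setMethod("voxelSpacing", "FlowDataset", function(object) object@voxelSpacing)

#' @rdname FlowDataset-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname FlowDataset-class
#' @export
setMethod("frameTimes", "FlowDataset", function(object) object@frameTimes)

#' @rdname FlowDataset-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname FlowDataset-class
#' @export
setMethod("nFrames", "FlowDataset", function(object) dim(object@velocity)[5])

#' @rdname FlowDataset-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname FlowDataset-class
#' @export
setMethod("provenance", "FlowDataset", function(object) object@provenance)

setMethod("show", "FlowDataset", function(object) {
  d <- dim(object@velocity)
  cat("FlowDataset:", paste(d[1:3], collapse = " x "), "grid,",
      d[5], "timeframes\n")
  cat("  voxel spacing:", paste(format(object@voxelSpacing), collapse = " x "), "mm\n")
  cat("  VENC:", paste(format(object@venc), collapse = ", "), "m/s\n")
  if (length(object@provenance)) {
    cat("  provenance:", length(object@provenance), "log entries\n")
  }
})

# ---------------------------------------------------------------------------
# PhantomSpec
# ---------------------------------------------------------------------------

#' PhantomSpec: parametric description of one synthetic 4D flow subject
#'
#' Fully determines a synthetic dataset: tubular geometry (straight tube,
#' circular arc, helix, or a candy-cane aorta), lumen radius (optionally
#' tapering from proximal to distal), pulsatile axial flow with a
#' forced-vortex (solid-body) swirl, a prescribed isotropic intravoxel
#' velocity-fluctuation level sigma encoded into magnitude ratios, and
#' Rician magnitude noise. Identical specs (same seed) generate
#' bit-identical datasets.
#'
#' @slot geometryKind One of `"straight"`, `"arc"`, `"helix"`, `"aorta_like"`.
#' @slot geometryParams Named list of curve parameters in mm / radians (see
#'   [generateCenterline()]).
#' @slot lumenRadius Lumen radius in mm; length 1, or length 2
#'   `(proximal, distal)` for a linear taper along arc length.
#' @slot peakVelocity Peak axial velocity in m/s.
#' @slot swirlRatio Peak azimuthal / peak axial velocity, dimensionless >= 0.
#' @slot sigmaLevel Intravoxel velocity fluctuation intensity per direction,
#'   m/s, must be < VENC.
#' @slot axialProfile `"parabolic"` (Poiseuille) or `"plug"` (uniform; gives
#'   the closed-form helicity oracle).
#' @slot waveform Nonnegative per-timeframe weights scaling velocity over
#'   the cardiac cycle.
#' @slot gridShape Integer length 3 (voxels), or empty for automatic sizing
#'   around the geometry.
#' @slot voxelSpacing Isotropic voxel size, mm (default 2.5).
#' @slot venc VENC per direction, m/s.
#' @slot snr Baseline magnitude over Rician noise scale; `Inf` = noise-free.
#' @slot velocityNoise Logical; when TRUE and snr is finite, additive
#'   Gaussian velocity noise with sd `VENC / (snr * pi)` is applied.
#' @slot seed Integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(
    geometryKind = "character",
    geometryParams = "list",
    lumenRadius = "numeric",
    peakVelocity = "numeric",
    swirlRatio = "numeric",
    sigmaLevel = "numeric",
    axialProfile = "character",
    waveform = "numeric",
    gridShape = "integer",
    voxelSpacing = "numeric",
    venc = "numeric",
    snr = "numeric",
    velocityNoise = "logical",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (!object@geometryKind %in% c("straight", "arc", "helix", "aorta_like")) {
    msg <- c(msg, "unknown geometryKind")
  }
  if (!object@axialProfile %in% c("parabolic", "plug")) {
    msg <- c(msg, "axialProfile must be 'parabolic' or 'plug'")
  }
  if (object@swirlRatio < 0) msg <- c(msg, "swirlRatio must be >= 0")
  if (any(object@lumenRadius <= 0)) msg <- c(msg, "lumenRadius must be > 0")
  if (!length(object@lumenRadius) %in% 1:2) {
    msg <- c(msg, "lumenRadius must have length 1 or 2 (proximal, distal)")
  }
  if (object@sigmaLevel < 0) msg <- c(msg, "sigmaLevel must be >= 0")
  if (any(object@sigmaLevel >= object@venc)) {
    msg <- c(msg, "sigmaLevel must be < venc (signal model valid regime)")
  }
  if (any(object@waveform < 0) || length(object@waveform) < 1L) {
    msg <- c(msg, "waveform must be nonnegative with >= 1 timeframe")
  }
  if (length(object@gridShape) && length(object@gridShape) != 3L) {
    msg <- c(msg, "gridShape must be empty (auto) or length 3")
  }
  if (any(object@venc <= 0) || length(object@venc) != 3L) {
    msg <- c(msg, "venc must be 3 positive values")
  }
  if (object@snr <= 0) msg <- c(msg, "snr must be > 0 (Inf for noise-free)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe a single candy-cane aorta subject at the acquisition's
#' native resolution: 2.5 mm isotropic voxels and 40 reconstructed
#' timeframes with a single-peak systolic waveform.
#'
#' @param geometryKind,geometryParams,lumenRadius,peakVelocity,swirlRatio
#'   See [PhantomSpec-class].
#' @param sigmaLevel,axialProfile,waveform,nTimeframes,gridShape See
#'   [PhantomSpec-class]; `waveform = NULL` builds the default systolic
#'   pulse over `nTimeframes` frames.
#' @param voxelSpacing,venc,snr,velocityNoise,seed See [PhantomSpec-class].
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(geometryKind = "aorta_like",
                        geometryParams = list(),
                        lumenRadius = c(11, 7),
                        peakVelocity = 1.5,
                        swirlRatio = 0.3,
                        sigmaLevel = 0.12,
                        axialProfile = "parabolic",
                        waveform = NULL,
                        nTimeframes = 40L,
                        gridShape = NULL,
                        voxelSpacing = 2.5,
                        venc = 2.0,
                        snr = Inf,
                        velocityNoise = FALSE,
                        seed = 1L) {
  if (is.null(waveform)) waveform <- systolicWaveform(nTimeframes)
  defaults <- defaultGeometryParams(geometryKind)
  geometryParams <- utils::modifyList(defaults, geometryParams)
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  new("PhantomSpec",
      geometryKind = geometryKind, geometryParams = geometryParams,
      lumenRadius = as.numeric(lumenRadius),
      peakVelocity = as.numeric(peakVelocity),
      swirlRatio = as.numeric(swirlRatio),
      sigmaLevel = as.numeric(sigmaLevel),
      axialProfile = axialProfile,
      waveform = as.numeric(waveform),
      gridShape = if (is.null(gridShape)) integer(0) else as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      venc = as.numeric(venc), snr = as.numeric(snr),
      velocityNoise = isTRUE(velocityNoise), seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@geometryKind,
      sprintf("| peak %.2f m/s, swirl %.2f, sigma %.3f m/s",
              object@peakVelocity, object@swirlRatio, object@sigmaLevel), "\n")
  cat("  ", length(object@waveform), "timeframes, VENC",
      paste(format(object@venc), collapse = "/"), "m/s, SNR",
      format(object@snr), ", seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' GroundTruth: analytic reference values of a synthetic subject
#'
#' Holds the quantities the phantom prescribes by construction, used by
#' parameter-recovery tests: the densely sampled analytic centerline with
#' exact arc length, chord and tortuosity; the lumen mask; landmark
#' positions; and the prescribed fluctuation and swirl levels.
#'
#' @slot centerline Matrix `n x 3`, mm, grid coordinates.
#' @slot arcLength Numeric length `n`, cumulative arc length, mm.
#' @slot curveLength Total analytic centerline length L, mm.
#' @slot chordLength Analytic chord D, mm.
#' @slot tortuosity Analytic tortuosity `(L/D - 1) * 100`, percent.
#' @slot lumenMask Logical 3D array, the exact rasterised lumen.
#' @slot landmarks Named numeric, arc-length positions (mm) of
#'   `aortic_valve`, `arch_top`, `left_subclavian`, `renal_branches`,
#'   `iliac_bifurcation` (aorta-like geometry; others carry valve/end only).
#' @slot landmarkPoints Matrix of the same landmarks as 3D points (mm).
#' @slot sigmaLevel,swirlRatio Prescribed values copied from the spec.
#' @slot peakFrame Index of the waveform maximum.
#' @slot meanSpeed Prescribed lumen-mean speed at the peak frame, m/s.
#' @export
setClass("GroundTruth",
  representation(
    centerline = "matrix",
    arcLength = "numeric",
    curveLength = "numeric",
    chordLength = "numeric",
    tortuosity = "numeric",
    lumenMask = "array",
    landmarks = "numeric",
    landmarkPoints = "matrix",
    sigmaLevel = "numeric",
    swirlRatio = "numeric",
    peakFrame = "integer",
    meanSpeed = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  if (object@tortuosity < 0) msg <- c(msg, "tortuosity must be >= 0")
  if (any(diff(object@arcLength) <= 0)) {
    msg <- c(msg, "arcLength must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: L = %.2f mm, D = %.2f mm, T = %.2f%%\n",
              object@curveLength, object@chordLength, object@tortuosity))
  cat("  lumen voxels:", sum(object@lumenMask),
      "| landmarks:", paste(names(object@landmarks), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# Centerline
# ---------------------------------------------------------------------------

#' Centerline: ordered lumen centerline with arc length
#'
#' @slot points Matrix `n x 3` of mm coordinates (voxel-center convention,
#'   0-based index times spacing), ordered proximal (valve) to distal
#'   (iliac).
#' @slot s Numeric length `n`, cumulative arc length in mm, strictly
#'   increasing from 0.
#' @export
setClass("Centerline",
  representation(points = "matrix", s = "numeric")
)

setValidity("Centerline", function(object) {
  msg <- character(0)
  if (nrow(object@points) != length(object@s)) {
    msg <- c(msg, "points and s disagree in length")
  }
  if (length(object@s) > 1L && any(diff(object@s) <= 0)) {
    msg <- c(msg, "arc length must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Centerline-class point matrix accessor
#' @param object A `Centerline`.
#' @export
setGeneric("centerlinePoints", function(object) standardGeneric("centerlinePoints"))
#' @rdname Centerline-class
#' @export
setMethod("centerlinePoints", "Centerline", function(object) object@points)

#' @rdname Centerline-class
#' @export
setGeneric("arcLength", function(object) standardGeneric("arcLength"))
#' @rdname Centerline-class
#' @export
setMethod("arcLength", "Centerline", function(object) object@s)

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, length %.2f mm\n",
              nrow(object@points), max(object@s)))
})

# ---------------------------------------------------------------------------
# RegionPartition
# ---------------------------------------------------------------------------

#' RegionPartition: the four-region division of the aorta
#'
#' Arc-length intervals for the ascending (AAo), descending (DAo),
#' suprarenal (SAA) and infrarenal (IAA) abdominal aorta, tiling
#' `[valve, iliac)`, plus a voxel label volume assigning each lumen voxel
#' to the region of its nearest centerline point.
#'
#' @slot intervals data.frame with columns `region`, `s_start`, `s_end`.
#' @slot labels Integer 3D array; 0 outside the lumen, otherwise the row
#'   number of the region in `intervals`.
#' @slot regionNames Character, region names in interval order.
#' @export
setClass("RegionPartition",
  representation(
    intervals = "data.frame",
    labels = "array",
    regionNames = "character"
  )
)

setValidity("RegionPartition", function(object) {
  msg <- character(0)
  iv <- object@intervals
  if (!all(c("region", "s_start", "s_end") %in% names(iv))) {
    msg <- c(msg, "intervals must have region, s_start, s_end")
  } else {
    if (any(iv$s_end <= iv$s_start)) msg <- c(msg, "empty region interval")
    if (nrow(iv) > 1L && any(abs(iv$s_start[-1L] - iv$s_end[-nrow(iv)]) > 1e-9)) {
      msg <- c(msg, "intervals must tile the centerline without gaps/overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionPartition-class interval table accessor
#' @param object A `RegionPartition`.
#' @export
setGeneric("regionIntervals", function(object) standardGeneric("regionIntervals"))
#' @rdname RegionPartition-class
#' @export
setMethod("regionIntervals", "RegionPartition", function(object) object@intervals)

#' @rdname RegionPartition-class
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname RegionPartition-class
#' @export
setMethod("regionLabels", "RegionPartition", function(object) object@labels)

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition:\n")
  iv <- object@intervals
  for (i in seq_len(nrow(iv))) {
    cat(sprintf("  %-4s [%7.2f, %7.2f) mm  %d voxels\n",
                iv$region[i], iv$s_start[i], iv$s_end[i],
                sum(object@labels == i)))
  }
})

# ---------------------------------------------------------------------------
# CohortSpec
# ---------------------------------------------------------------------------

#' CohortSpec: a two-group synthetic cohort design
#'
#' Describes per-group sampling distributions for the geometry and flow
#' parameters of a Young and an Old group, plus coupling rules tying swirl
#' positively to the tortuosity-controlling parameters and the fluctuation
#' level sigma positively to velocity. All sampling flows from the master
#' seed.
#'
#' @slot nYoung,nOld Group sizes (>= 2 for any statistics).
#' @slot young,old Named lists of `c(mean, sd)` pairs for `asc_angle`
#'   (rad), `desc_angle` (rad), `arch_radius` (mm), `desc_length` (mm),
#'   `wiggle_amp` (mm), `peak_velocity` (m/s), `swirl_base` (-),
#'   `sigma_base` (m/s), `lumen_radius_prox` (mm).
#' @slot coupling Named numeric: `swirl_angle`, `swirl_wiggle`,
#'   `sigma_velocity` coupling coefficients.
#' @slot nTimeframes,voxelSpacing,venc,snr Acquisition settings shared by
#'   all subjects.
#' @slot seed Master seed.
#' @export
setClass("CohortSpec",
  representation(
    nYoung = "integer", nOld = "integer",
    young = "list", old = "list",
    coupling = "numeric",
    nTimeframes = "integer",
    voxelSpacing = "numeric",
    venc = "numeric",
    snr = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nYoung < 2L || object@nOld < 2L) {
    msg <- c(msg, "group sizes must be >= 2")
  }
  need <- c("asc_angle", "desc_angle", "arch_radius", "desc_length",
            "wiggle_amp", "peak_velocity", "swirl_base", "sigma_base",
            "lumen_radius_prox")
  for (g in c("young", "old")) {
    pars <- slot(object, g)
    if (!all(need %in% names(pars))) {
      msg <- c(msg, paste0(g, " distributions incomplete"))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d Young + %d Old, %d timeframes, seed %d\n",
              object@nYoung, object@nOld, object@nTimeframes, object@seed))
})
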