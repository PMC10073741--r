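# File interfaces: NIfTI volumes (one 4D file per velocity component and
# per encoding point), JSON sidecar for acquisition parameters and
# provenance, CSV for centerlines, landmarks and metric tables.

#' Write a FlowDataset to a directory
#'
#' Layout: `velocity_<x|y|z>.nii.gz` (4D, m/s), `magnitude_<0..3>.nii.gz`
#' (4D, a.u.; 0 is the reference), and `sidecar.json` holding VENC, voxel
#' spacing, timeframe fractions and the provenance log.
#'
#' @param data A [FlowDataset-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFlowDataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vel <- velocities(data)
  mags <- magnitudes(data)
  sp <- voxelSpacing(data)
  comp <- c("x", "y", "z")
  for (i in 1:3) {
    img <- RNifti::asNifti(array(vel[, , , i, ], dim(vel)[c(1:3, 5)]),
                           pixdim = c(sp, 1))
    RNifti::writeNifti(img, file.path(dir, sprintf("velocity_%s.nii.gz",
                                                   comp[i])))
  }
  for (j in 1:4) {
    img <- RNifti::asNifti(array(mags[, , , j, ], dim(mags)[c(1:3, 5)]),
                           pixdim = c(sp, 1))
    RNifti::writeNifti(img, file.path(dir, sprintf("magnitude_%d.nii.gz",
                                                   j - 1L)))
  }
  sidecar <- list(venc_ms = venc(data), voxel_spacing_mm = sp,
                  n_timeframes = nFrames(data),
                  timeframe_fractions = frameTimes(data),
                  provenance = provenance(data))
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a FlowDataset from a directory written by [writeFlowDataset()]
#'
#' @param dir Directory containing the velocity/magnitude NIfTI files and
#'   `sidecar.json`.
#' @return A [FlowDataset-class].
#' @export
readFlowDataset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                                 simplifyVector = TRUE)
  comp <- c("x", "y", "z")
  vol <- lapply(comp, function(cn) {
    as.array(RNifti::readNifti(file.path(dir, sprintf("velocity_%s.nii.gz",
                                                      cn))))
  })
  d <- dim(vol[[1]])
  vel <- array(0, c(d[1:3], 3L, d[4]))
  for (i in 1:3) vel[, , , i, ] <- vol[[i]]
  mags <- array(0, c(d[1:3], 4L, d[4]))
  for (j in 1:4) {
    mags[, , , j, ] <- as.array(RNifti::readNifti(
      file.path(dir, sprintf("magnitude_%d.nii.gz", j - 1L))))
  }
  FlowDataset(vel, mags, sidecar$venc_ms, sidecar$voxel_spacing_mm,
              frameTimes = sidecar$timeframe_fractions,
              provenance = as.character(sidecar$provenance))
}

#' Write per-run analysis artifacts
#'
#' Writes the lumen mask and region labels (uint8 NIfTI), the centerline
#' as CSV (`x_mm`, `y_mm`, `z_mm`, `s_mm`), the regional metrics CSV and a
#' JSON manifest, alongside the [writeFlowDataset()] layout.
#'
#' @param result An [analyzeSubject()] / [runPipeline()] result.
#' @param spec The generating [PhantomSpec-class] (echoed into the
#'   manifest), or `NULL`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeRunArtifacts <- function(result, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFlowDataset(result$data, file.path(dir, "data"))
  sp <- voxelSpacing(result$data)
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(result$mask),
                                           dim(result$mask)),
                                     pixdim = sp, datatype = "uint8"),
                     file.path(dir, "lumen_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(regionLabels(result$partition),
                                     pixdim = sp, datatype = "uint8"),
                     file.path(dir, "region_labels.nii.gz"))
  cl <- result$centerline
  utils::write.csv(data.frame(x_mm = centerlinePoints(cl)[, 1],
                              y_mm = centerlinePoints(cl)[, 2],
                              z_mm = centerlinePoints(cl)[, 3],
                              s_mm = arcLength(cl)),
                   file.path(dir, "centerline.csv"), row.names = FALSE)
  utils::write.csv(result$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  manifest <- result$manifest
  if (!is.null(spec)) {
    manifest$phantom_spec <- list(
      geometry_kind = spec@geometryKind, geometry_params = spec@geometryParams,
      lumen_radius_mm = spec@lumenRadius, peak_velocity_ms = spec@peakVelocity,
      swirl_ratio = spec@swirlRatio, sigma_level_ms = spec@sigmaLevel,
      axial_profile = spec@axialProfile, snr = spec@snr, seed = spec@seed)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Write cohort-level artifacts
#'
#' The cohort table, group-summary, per-region correlation and regression
#' tables as CSV plus a JSON run manifest.
#'
#' @param result A [runCohortPipeline()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeCohortArtifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$table, file.path(dir, "cohort_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(result$summary)) {
    utils::write.csv(result$summary, file.path(dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$correlations)) {
    corr <- do.call(rbind, lapply(names(result$correlations), function(rg) {
      cbind(region = rg, result$correlations[[rg]])
    }))
    utils::write.csv(corr, file.path(dir, "correlations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$regressions)) {
    reg <- do.call(rbind, lapply(names(result$regressions), function(ss) {
      do.call(rbind, lapply(result$regressions[[ss]], function(r) {
        cbind(subset = ss, model = r$model, r$coefficients,
              r_squared = r$r_squared, n = r$n)
      }))
    }))
    utils::write.csv(reg, file.path(dir, "tke_regressions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a run configuration JSON
#'
#' A single JSON file with stage-scoped sections: `phantom` (PhantomSpec
#' arguments) or `cohort` (CohortSpec arguments), optional `params`
#' (HemoParams overrides), `preprocess` flag and `seed` override.
#'
#' @param path Path to the JSON file.
#' @return List with `spec` or `cohort`, `params`, `preprocess`.
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(preprocess = isTRUE(cfg$preprocess))
  pargs <- if (is.null(cfg$params)) list() else cfg$params
  out$params <- do.call(hemoParams, pargs)
  if (!is.null(cfg$cohort)) {
    args <- cfg$cohort
    if (!is.null(cfg$seed)) args$seed <- cfg$seed
    out$cohort <- do.call(cohortSpec, args)
  } else if (!is.null(cfg$phantom)) {
    args <- cfg$phantom
    if (!is.null(cfg$seed)) args$seed <- cfg$seed
    if (!is.null(args$geometryParams)) {
      args$geometryParams <- as.list(args$geometryParams)
    }
    out$spec <- do.call(phantomSpec, args)
  } else {
    stop("config must contain a 'phantom' or 'cohort' section")
  }
  out
}
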