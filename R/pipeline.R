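# End-to-end orchestration: per-subject analysis (preprocess -> PC-MRA ->
# segmentation -> centerline -> partition -> regional metrics), cohort
# runs, and the qualitative direction checks on cohort results.

#' Analyse one subject end to end
#'
#' Runs the analysis chain on a [FlowDataset-class]: optional phase-wrap
#' and background-offset correction, PC-MRA construction, lumen
#' segmentation, centerline extraction between the valve and iliac
#' landmarks, landmark mapping, four-region partition and regional metric
#' aggregation. Landmarks come from the phantom's [GroundTruth-class] or
#' from an explicit landmark-point matrix (the interface that replaces a
#' manual landmarking step on external data).
#'
#' @param data A [FlowDataset-class].
#' @param truth Optional [GroundTruth-class]; supplies landmark points.
#' @param landmarkPoints Optional named matrix (rows `aortic_valve`,
#'   `left_subclavian`, `renal_branches`, `iliac_bifurcation`, mm) used
#'   when `truth` is absent.
#' @param params A [hemoParams()] list.
#' @param preprocess Apply [unwrapVelocity()] and
#'   [correctBackgroundPhase()] before analysis.
#' @param superiorAxis Superior axis index for the arch-top rule.
#' @return List with `metrics` (the regional metrics data.frame), `mask`,
#'   `centerline`, `partition` and the (possibly corrected) `data`.
#' @export
analyzeSubject <- function(data, truth = NULL, landmarkPoints = NULL,
                           params = hemoParams(), preprocess = FALSE,
                           superiorAxis = 3L) {
  if (preprocess) {
    data <- unwrapVelocity(data)
    static <- identifyStaticTissue(data)
    data <- correctBackgroundPhase(data, static)
  }
  if (is.null(landmarkPoints)) {
    if (is.null(truth)) stop("need either truth or landmarkPoints")
    landmarkPoints <- truth@landmarkPoints
  }
  pcmra <- computePcmra(data)
  mask <- segmentLumen(pcmra)
  spacing <- voxelSpacing(data)
  if (!all(c("aortic_valve", "iliac_bifurcation") %in%
             rownames(landmarkPoints))) {
    stop("landmarkPoints must contain at least aortic_valve and iliac_bifurcation")
  }
  endpoints <- landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ,
                              drop = FALSE]
  cl <- extractCenterline(mask, spacing, endpoints)
  lms <- mapLandmarks(cl, landmarkPoints)
  # geometries without anatomical landmarks (straight tubes, arcs,
  # helices) get a synthetic four-region split at fixed arc-length
  # fractions so the same regional machinery applies
  smax <- max(arcLength(cl))
  if (!"left_subclavian" %in% names(lms)) {
    lms[["left_subclavian"]] <- 0.45 * smax
  }
  if (!"renal_branches" %in% names(lms)) {
    lms[["renal_branches"]] <- 0.80 * smax
  }
  if (!"arch_top" %in% names(lms)) {
    sTop <- locateArchTop(cl, superiorAxis)
    if (sTop <= lms[["aortic_valve"]] || sTop >= lms[["left_subclavian"]]) {
      lms[["arch_top"]] <- 0.30 * smax  # no arch: synthetic split
    }
  }
  partition <- partitionRegions(cl, lms, mask, spacing,
                                superiorAxis = superiorAxis)
  metrics <- aggregateRegionalMetrics(data, cl, partition, params)
  list(metrics = metrics, mask = mask, centerline = cl,
       partition = partition, data = data)
}

#' Assemble a cohort table from per-subject metrics
#'
#' One row per subject x region, with the group label and (for synthetic
#' cohorts) the prescribed ground-truth parameters joined in.
#'
#' @param metricList Named list of per-subject metrics data.frames.
#' @param groups Character vector of group labels, one per subject.
#' @param truthTable Optional ground-truth table from [generateCohort()].
#' @return data.frame: `subject`, `group`, `region`, metric columns.
#' @export
buildCohortTable <- function(metricList, groups, truthTable = NULL) {
  stopifnot(length(metricList) == length(groups))
  ids <- names(metricList)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(metricList))
  rows <- lapply(seq_along(metricList), function(i) {
    m <- metricList[[i]]
    cbind(data.frame(subject = ids[i], group = groups[i],
                     stringsAsFactors = FALSE), m)
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab[, c("subject", "region")])) {
    stop("duplicated (subject, region) pair in cohort table")
  }
  if (!is.null(truthTable)) {
    keep <- setdiff(names(truthTable), c("group"))
    tab <- merge(tab, truthTable[, keep], by = "subject", sort = FALSE)
  }
  tab[order(match(tab$subject, ids)), ]
}

#' Run the full pipeline for one subject specification
#'
#' Simulates the phantom, optionally applies the preprocessing stage, and
#' analyses it. With an output directory the artifacts (NIfTI volumes,
#' centerline and metrics CSVs, JSON manifest) are written; re-running
#' with the same config is bit-identical.
#'
#' @param spec A [PhantomSpec-class] (or a list/JSON path accepted by
#'   [readRunConfig()]).
#' @param params A [hemoParams()] list.
#' @param preprocess Toggle the correction stage.
#' @param outDir Optional output directory.
#' @return The [analyzeSubject()] result, plus `truth` and `manifest`.
#' @export
runPipeline <- function(spec, params = hemoParams(), preprocess = FALSE,
                        outDir = NULL) {
  if (!methods::is(spec, "PhantomSpec")) spec <- do.call(phantomSpec, spec)
  ph <- generatePhantom(spec)
  res <- analyzeSubject(ph$data, truth = ph$truth, params = params,
                        preprocess = preprocess)
  res$truth <- ph$truth
  res$manifest <- list(
    seed = spec@seed, geometry = spec@geometryKind,
    n_timeframes = length(spec@waveform),
    voxel_spacing_mm = spec@voxelSpacing, venc_ms = spec@venc,
    snr = spec@snr, preprocess = preprocess,
    stages = c("simulate", if (preprocess) "preprocess", "geometry",
               "hemodynamics"),
    fingerprint = list(
      velocity_sum = sum(velocities(ph$data)),
      metrics_sum = sum(res$metrics$tke, res$metrics$helicity,
                        res$metrics$velocity, na.rm = TRUE))
  )
  if (!is.null(outDir)) writeRunArtifacts(res, spec, outDir)
  res
}

#' Run the pipeline over a synthetic cohort
#'
#' Generates the cohort, analyses every subject, assembles the cohort
#' table and computes the cohort statistics (group summaries, correlation
#' tables per region, TKE regressions).
#'
#' @param cohort A [CohortSpec-class].
#' @param params A [hemoParams()] list.
#' @param preprocess Toggle the per-subject correction stage.
#' @param stats Compute the statistics layer (disable for plain metric
#'   extraction).
#' @param outDir Optional output directory for CSV/JSON artifacts.
#' @return List with `table` (cohort table), `summary`, `correlations`
#'   (named by region), `regressions` (whole-aorta, by subset) and
#'   `manifest`.
#' @export
runCohortPipeline <- function(cohort, params = hemoParams(),
                              preprocess = FALSE, stats = TRUE,
                              outDir = NULL) {
  gen <- generateCohort(cohort)
  metricList <- lapply(gen$subjects, function(su) {
    analyzeSubject(su$data, truth = su$truth, params = params,
                   preprocess = preprocess)$metrics
  })
  names(metricList) <- vapply(gen$subjects, `[[`, character(1), "id")
  tab <- buildCohortTable(metricList, gen$groups, gen$truthTable)
  out <- list(table = tab)
  if (stats) {
    # the statistics layer needs minimum group sizes; smaller cohorts
    # still return the metric table
    out$summary <- if (cohort@nYoung >= 3L && cohort@nOld >= 3L) {
      summarizeCohort(tab)
    }
    regions <- unique(tab$region)
    if (cohort@nYoung + cohort@nOld >= 4L) {
      out$correlations <- lapply(stats::setNames(nm = regions),
                                 function(rg) correlationMatrix(tab, rg))
    }
    out$regressions <- lapply(
      stats::setNames(nm = c("Young", "Old", "Young+Old")),
      function(ss) {
        nrows <- sum(tab$region == "Whole" &
                       (ss == "Young+Old" | tab$group == ss))
        if (nrows < 4L) return(NULL)   # too few subjects for the fits
        fitTkeRegressions(tab, "Whole", ss)
      })
  }
  out$manifest <- list(seed = cohort@seed, n_young = cohort@nYoung,
                       n_old = cohort@nOld,
                       n_timeframes = cohort@nTimeframes,
                       snr = cohort@snr, preprocess = preprocess,
                       fingerprint = sum(tab$tke, tab$helicity,
                                         tab$tortuosity, na.rm = TRUE))
  if (!is.null(outDir)) writeCohortArtifacts(out, outDir)
  out
}

#' Qualitative direction checks on a cohort result
#'
#' Evaluates, per region, the headline directional findings: tortuosity
#' and helicity higher in Old, TKE, velocity and Reynolds number lower in
#' Old; Spearman rho(tortuosity, helicity) positive in every region; and
#' rho(helicity, TKE) negative outside the ascending aorta (where the
#' valve jet confounds the geometry effect).
#'
#' @param table A cohort table from [buildCohortTable()].
#' @return Named logical vector of the individual checks, with attribute
#'   `all_pass`.
#' @export
directionChecks <- function(table) {
  regions <- c("AAo", "DAo", "SAA", "IAA", "Whole")
  checks <- logical(0)
  gm <- function(rg, m, g) mean(table[[m]][table$region == rg &
                                           table$group == g], na.rm = TRUE)
  for (rg in regions) {
    checks[paste0("tortuosity_old_gt_young_", rg)] <-
      gm(rg, "tortuosity", "Old") > gm(rg, "tortuosity", "Young")
    checks[paste0("helicity_old_gt_young_", rg)] <-
      gm(rg, "helicity", "Old") > gm(rg, "helicity", "Young")
    checks[paste0("tke_old_lt_young_", rg)] <-
      gm(rg, "tke", "Old") < gm(rg, "tke", "Young")
    checks[paste0("velocity_old_lt_young_", rg)] <-
      gm(rg, "velocity", "Old") < gm(rg, "velocity", "Young")
    checks[paste0("reynolds_old_lt_young_", rg)] <-
      gm(rg, "reynolds", "Old") < gm(rg, "reynolds", "Young")
    d <- table[table$region == rg, ]
    checks[paste0("rho_tortuosity_helicity_pos_", rg)] <-
      spearmanCorrelation(d$tortuosity, d$helicity)$rho > 0
    if (rg != "AAo") {
      checks[paste0("rho_helicity_tke_neg_", rg)] <-
        spearmanCorrelation(d$helicity, d$tke)$rho < 0
    }
  }
  structure(checks, all_pass = all(checks))
}
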