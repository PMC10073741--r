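# Two-group synthetic cohort generation. The Young/Old parameter
# distributions are calibrated so the cohort reproduces the directional
# pattern of an ageing aorta: Old subjects get a wider arch entry angle and
# a wigglier abdominal limb (higher tortuosity), more swirl (higher
# helicity), lower peak velocity and lower fluctuation intensity (lower
# velocity, TKE and Reynolds number), and a larger lumen (diameter).

#' Construct a CohortSpec
#'
#' Defaults describe the desk-scale study design: two groups of 10
#' candy-cane aorta subjects at 2.5 mm voxels and 10 timeframes, SNR 30
#' Rician magnitude noise, with group parameter distributions giving
#' ascending-aorta tortuosity near 24% (Young) and 35% (Old) and
#' whole-aorta turbulent kinetic energy near 36 (Young) and 16 (Old) J/m3.
#'
#' @param nYoung,nOld Group sizes.
#' @param young,old Named lists of `c(mean, sd)` sampling parameters;
#'   entries override the defaults.
#' @param coupling Coupling coefficients `swirl_angle`, `swirl_wiggle`
#'   (swirl increases with the tortuosity-controlling parameters) and
#'   `sigma_velocity` (sigma increases with peak velocity).
#' @param nTimeframes,voxelSpacing,venc,snr Shared acquisition settings.
#' @param seed Master seed; everything downstream derives from it.
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(nYoung = 10L, nOld = 10L,
                       young = list(), old = list(),
                       coupling = c(swirl_angle = 0.10, swirl_wiggle = 0.04,
                                    sigma_velocity = 0.03),
                       nTimeframes = 10L, voxelSpacing = 2.5,
                       venc = 2.0, snr = 30, seed = 1L) {
  youngDefault <- list(
    asc_angle = c(2.25, 0.10), desc_angle = c(1.60, 0.05),
    arch_radius = c(26, 1.5),
    desc_length = c(90, 5), wiggle_amp = c(0.8, 0.25),
    peak_velocity = c(1.6, 0.12), swirl_base = c(0.30, 0.04),
    sigma_base = c(0.15, 0.015), lumen_radius_prox = c(11, 0.6)
  )
  oldDefault <- list(
    asc_angle = c(2.60, 0.10), desc_angle = c(1.80, 0.06),
    arch_radius = c(28, 1.5),
    desc_length = c(100, 5), wiggle_amp = c(2.2, 0.4),
    peak_velocity = c(1.0, 0.10), swirl_base = c(0.42, 0.04),
    sigma_base = c(0.10, 0.012), lumen_radius_prox = c(13, 0.7)
  )
  if (length(venc) == 1L) venc <- rep(venc, 3L)
  new("CohortSpec",
      nYoung = as.integer(nYoung), nOld = as.integer(nOld),
      young = utils::modifyList(youngDefault, young),
      old = utils::modifyList(oldDefault, old),
      coupling = coupling,
      nTimeframes = as.integer(nTimeframes),
      voxelSpacing = as.numeric(voxelSpacing),
      venc = as.numeric(venc), snr = as.numeric(snr),
      seed = as.integer(seed))
}

# Sample one subject's PhantomSpec from a group's distributions, applying
# the coupling rules. Invalid draws (e.g. nonpositive radii) are resampled
# with bounded retries.
sampleSubjectSpec <- function(group, coupling, acq, subjectSeed, maxRetry = 5L) {
  draw1 <- function(p) stats::rnorm(1, p[1], p[2])
  for (attempt in seq_len(maxRetry)) {
    asc <- draw1(group$asc_angle)
    desc <- draw1(group$desc_angle)
    archR <- draw1(group$arch_radius)
    descL <- draw1(group$desc_length)
    amp <- abs(draw1(group$wiggle_amp))
    pv <- draw1(group$peak_velocity)
    swirl <- draw1(group$swirl_base) +
      coupling["swirl_angle"] * (asc - 2.4) +
      coupling["swirl_wiggle"] * (amp - 1.5)
    sigma <- draw1(group$sigma_base) +
      coupling["sigma_velocity"] * (pv - group$peak_velocity[1])
    rProx <- draw1(group$lumen_radius_prox)
    ok <- asc > 0.5 && asc < pi && desc > pi / 4 && desc < 2.4 &&
      archR > 10 && descL > 30 &&
      pv > 0.2 && swirl >= 0 && sigma > 0 && sigma < min(acq$venc) &&
      rProx > 4 && pv * (1 + 0.1) < min(acq$venc)
    if (ok) {
      return(phantomSpec(
        geometryKind = "aorta_like",
        geometryParams = list(arch_radius = archR, asc_angle = asc,
                              desc_angle = desc,
                              desc_length = descL, wiggle_amp = amp),
        lumenRadius = c(rProx, 0.62 * rProx),
        peakVelocity = pv, swirlRatio = swirl, sigmaLevel = sigma,
        nTimeframes = acq$nTimeframes, voxelSpacing = acq$voxelSpacing,
        venc = acq$venc, snr = acq$snr, seed = subjectSeed
      ))
    }
  }
  stop("could not sample a physically valid PhantomSpec after ",
       maxRetry, " retries")
}

#' Generate a two-group synthetic cohort
#'
#' Samples per-subject phantom specs from the cohort's group
#' distributions (deterministically from the master seed), generates each
#' subject, and tabulates the prescribed ground truth.
#'
#' @param cohort A [CohortSpec-class].
#' @param generate If `FALSE`, only the specs and ground-truth table are
#'   returned (no image synthesis).
#' @return List with `subjects` (each a list of `spec`, and when generated
#'   `data` and `truth`), `truthTable` (data.frame of every prescribed
#'   parameter per subject) and `groups`.
#' @export
generateCohort <- function(cohort, generate = TRUE) {
  validObject(cohort)
  acq <- list(nTimeframes = cohort@nTimeframes,
              voxelSpacing = cohort@voxelSpacing,
              venc = cohort@venc, snr = cohort@snr)
  n <- cohort@nYoung + cohort@nOld
  groups <- rep(c("Young", "Old"), c(cohort@nYoung, cohort@nOld))
  specs <- withSeed(cohort@seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      g <- if (groups[i] == "Young") cohort@young else cohort@old
      sampleSubjectSpec(g, cohort@coupling, acq, seeds[i])
    })
  })
  subjects <- lapply(seq_len(n), function(i) {
    out <- list(id = sprintf("S%02d", i), group = groups[i], spec = specs[[i]])
    if (generate) {
      ph <- generatePhantom(specs[[i]])
      out$data <- ph$data
      out$truth <- ph$truth
    }
    out
  })
  truthTable <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp <- specs[[i]]
    gp <- sp@geometryParams
    data.frame(
      subject = sprintf("S%02d", i), group = groups[i],
      asc_angle = gp$asc_angle, arch_radius = gp$arch_radius,
      desc_length = gp$desc_length, wiggle_amp = gp$wiggle_amp,
      peak_velocity = sp@peakVelocity, swirl_ratio = sp@swirlRatio,
      sigma_level = sp@sigmaLevel, lumen_radius_prox = sp@lumenRadius[1],
      seed = sp@seed, stringsAsFactors = FALSE
    )
  }))
  list(subjects = subjects, truthTable = truthTable, groups = groups)
}
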