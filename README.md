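# aortaflow

Regional hemodynamic analysis of whole-aorta 4D flow MRI in R.

4D flow MRI delivers a time-resolved 3D velocity vector field plus
motion-encoded magnitude images over the entire aorta. This package
implements the analysis chain that turns such data into per-region
geometry and hemodynamics, for researchers studying how aortic shape —
in particular age-related tortuosity — relates to flow structure:

- **PC-MRA and segmentation** — an angiogram
  `sqrt(mean_t(|S|^2 |v|^2))` built from magnitude and velocity,
  segmented by Otsu-seeded hysteresis thresholding.
- **Centerline and tortuosity** — a medialness-weighted shortest path
  through the lumen, refined to cross-section centroids;
  `T = (L/D - 1) * 100` per region, with `L` the centerline length and
  `D` the chord.
- **Regions** — ascending (AAo), descending (DAo), suprarenal (SAA) and
  infrarenal (IAA) abdominal aorta, split at the arch top (most superior
  centerline point), the arc-length midpoint between the left
  subclavian artery and the renal branches, and the renal branches.
- **Helicity** — absolute local normalized helicity
  `|V.w| / (|V||w|)` with `w = curl V` from mask-aware finite
  differences; 0 = no helical flow, 1 = maximally helical.
- **Turbulent kinetic energy** — from the motion-encoded magnitude
  ratios: `sigma_i^2 = (2/k_v^2) ln(|S|/|S_i|)` with `k_v = pi/VENC`,
  `TKE = 1/2 rho sum_i sigma_i^2` (rho = 1060 kg/m^3), signed so that
  noise-level TKE can average below zero instead of being clamped.
- **Velocity and Reynolds number** — spatial-mean speed in a +/-5%
  systolic window around each region's peak, and
  `Re = rho V D / mu` (mu = 3.5e-3 Pa s).
- **Preprocessing** — offline phase-wrap correction and background
  phase-offset removal by a weighted degree-4 polynomial fit to static
  tissue.
- **Cohort statistics** — normality-gated Welch t / Mann-Whitney
  comparisons, Spearman correlations with interpretation bins, and
  simple/multiple regressions of TKE on helicity and velocity.
- **Synthetic phantoms** — straight tubes, arcs, helices and candy-cane
  aortas with analytic ground truth, exact magnitude-signal encoding,
  Rician noise, and two-group Young/Old cohorts; every estimator is
  validated against closed forms on these phantoms.

## Worked example

Simulate one aorta-like subject and analyse it end to end:

```r
library(aortaflow)
spec <- phantomSpec(nTimeframes = 10L, snr = 30, seed = 7L,
                    sigmaLevel = 0.12)
res <- runPipeline(spec)
res$truth
#> GroundTruth: L = 189.78 mm, D = 86.97 mm, T = 118.20%
#>   lumen voxels: 3173 | landmarks: aortic_valve, arch_top, ...
res$metrics[, c("region", "tortuosity", "diameter_mm", "helicity",
                "tke", "velocity", "reynolds")]
#>   region tortuosity diameter_mm helicity  tke velocity reynolds
#> 1    AAo     23.358        21.4    0.799 22.7    0.862     5577
#> 2    DAo     14.456        18.5    0.808 20.4    0.857     4816
#> 3    SAA      0.171        15.9    0.816 18.6    0.857     4116
#> 4    IAA      0.157        15.1    0.822 20.8    0.847     3871
#> 5  Whole    115.255        18.4    0.807 21.1    0.858     4771
```

The whole-aorta tortuosity (115%) recovers the analytic ground truth
(118%) through segmentation and centerline extraction; the regional TKE
(~20 J/m^3) recovers the prescribed fluctuation level (0.12 m/s ->
22.9 J/m^3 exactly, here under SNR-30 Rician magnitude noise); helicity,
velocity and Reynolds number are the regional window-averaged metrics.

Cohort-level analysis:

```r
res <- runCohortPipeline(cohortSpec(seed = 1L))   # 10 Young + 10 Old
res$summary        # group comparisons per metric and region
res$correlations$Whole
directionChecks(res$table)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/aortaflow.R` (subcommands `simulate`, `simulate-cohort`,
`run`, `run-cohort`, JSON run configs, NIfTI + CSV + JSON outputs).

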