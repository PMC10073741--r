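# Vorticity, local normalized helicity, the magnitude-ratio fluctuation
# estimator, TKE, systole windows, regional aggregation and Reynolds
# number.

rigidRotationField <- function(d3 = c(13L, 13L, 5L), omega = 2, spacing = 2) {
  co <- aortaflow:::voxelCoords(seq_len(prod(d3)), d3, rep(spacing, 3)) / 1000
  ctr <- colMeans(co)
  vel <- array(0, c(d3, 3L))
  vel[, , , 1] <- array(-omega * (co[, 2] - ctr[2]), d3)
  vel[, , , 2] <- array(omega * (co[, 1] - ctr[1]), d3)
  vel
}

test_that("curl of a rigid rotation is exactly twice the angular velocity", {
  d3 <- c(13L, 13L, 5L)
  mask <- array(TRUE, d3)
  vo <- computeVorticity(rigidRotationField(d3), mask, 2)
  expect_equal(unique(round(as.numeric(vo[, , , 3]), 9)), 4)
  expect_equal(max(abs(vo[, , , 1:2])), 0)
  # uniform translation has zero curl
  vel <- array(0, c(d3, 3L)); vel[, , , 2] <- 0.7
  vo0 <- computeVorticity(vel, mask, 2)
  expect_equal(max(abs(vo0), na.rm = TRUE), 0)
})

test_that("Poiseuille vorticity magnitude matches the analytic shear profile", {
  sp <- phantomSpec("straight", list(length = 60), lumenRadius = 12,
                    swirlRatio = 0, peakVelocity = 1, nTimeframes = 1L,
                    waveform = 1, sigmaLevel = 0)
  vf <- generateVelocityField(sp)
  lum <- vf$lumenMask
  vo <- computeVorticity(vf$velocity[, , , , 1], lum, 2.5)
  wmag <- sqrt(vo[, , , 1]^2 + vo[, , , 2]^2 + vo[, , , 3]^2)
  interior <- aortaflow:::wallDistance(lum) >= 2
  idx <- which(interior)
  idxLum <- match(idx, which(lum))
  r <- vf$r[idxLum] / 1000                      # m
  pred <- 2 * 1 * r / (12 / 1000)^2             # |omega| = 2 W0 r / R^2
  ok <- pred > 20                                # clear of the axis
  expect_lt(max(abs(wmag[idx][ok] - pred[ok]) / pred[ok]), 0.02)
})

test_that("LNH matches the forced-vortex closed form and its limits", {
  sp <- phantomSpec("straight", list(length = 80), lumenRadius = 12,
                    swirlRatio = 0.8, axialProfile = "plug",
                    peakVelocity = 1, nTimeframes = 1L, waveform = 1,
                    sigmaLevel = 0)
  vf <- generateVelocityField(sp)
  lum <- vf$lumenMask
  velFrame <- vf$velocity[, , , , 1]
  lnh <- computeLnh(velFrame, computeVorticity(velFrame, lum, 2.5))
  interior <- aortaflow:::wallDistance(lum) >= 2
  idx <- which(interior)
  r <- vf$r[match(idx, which(lum))]             # mm
  pred <- 1 / sqrt(1 + (0.8 * r / 12)^2)        # W / sqrt(W^2 + (Omega r)^2)
  expect_lt(max(abs(lnh[idx] - pred) / pred), 0.02)
  expect_gt(min(lnh[idx][r < 1.5]), 0.99)       # on-axis limit -> 1

  # pure Poiseuille: velocity and vorticity are orthogonal everywhere
  sp0 <- phantomSpec("straight", list(length = 80), lumenRadius = 12,
                     swirlRatio = 0, nTimeframes = 1L, waveform = 1,
                     sigmaLevel = 0)
  vf0 <- generateVelocityField(sp0)
  v0 <- vf0$velocity[, , , , 1]
  l0 <- computeLnh(v0, computeVorticity(v0, vf0$lumenMask, 2.5))
  expect_equal(max(l0[which(aortaflow:::wallDistance(vf0$lumenMask) >= 2)],
                   na.rm = TRUE), 0)
})

test_that("LNH is bounded by Cauchy-Schwarz and exact on orthogonal pairs", {
  set.seed(3)
  d3 <- c(6L, 6L, 6L)
  vel <- array(rnorm(prod(d3) * 3), c(d3, 3L))
  vor <- array(rnorm(prod(d3) * 3), c(d3, 3L))
  lnh <- computeLnh(vel, vor)
  expect_true(all(lnh[!is.na(lnh)] >= 0 & lnh[!is.na(lnh)] <= 1))
  # 100 explicit orthogonal (V, omega) pairs -> LNH 0 to machine precision
  v <- matrix(rnorm(300), 100)
  a <- matrix(rnorm(300), 100)
  w <- a - v * rowSums(a * v) / rowSums(v * v)
  d1 <- c(100L, 1L, 1L)
  lnh0 <- computeLnh(array(v, c(d1, 3L)), array(w, c(d1, 3L)))
  expect_lt(max(lnh0, na.rm = TRUE), 1e-12)
})

test_that("sub-epsilon |V||omega| voxels are excluded, not zeroed", {
  d3 <- c(2L, 2L, 1L)
  vel <- array(1e-6, c(d3, 3L))
  vor <- array(1e-6, c(d3, 3L))
  lnh <- computeLnh(vel, vor, hemoParams(lnhEpsilon = 1e-6))
  expect_true(all(is.na(lnh)))
})

test_that("sigma^2 estimator inverts the attenuation model, keeping the sign", {
  d3 <- c(3L, 3L, 3L)
  mags <- array(100, c(d3, 4L))
  s2 <- computeSigmaSquared(mags, 1.5)
  expect_equal(as.numeric(s2), rep(0, length(s2)))            # no attenuation
  kv <- pi / 1.5
  mags[, , , 2] <- 100 * exp(-kv^2 * 0.01 / 2)
  s2 <- computeSigmaSquared(mags, 1.5)
  expect_equal(unique(round(as.numeric(s2[, , , 1]), 12)), 0.01)
  mags[, , , 3] <- 103                                        # |S_i| > |S|
  s2 <- computeSigmaSquared(mags, 1.5)
  expect_true(all(s2[, , , 2] < 0))
  tke <- computeTke(s2)
  expect_true(all(is.finite(tke)))
})

test_that("TKE evaluates 1/2 rho sum(sigma_i^2) with signed cancellation", {
  d3 <- c(2L, 2L, 2L)
  s2 <- array(0.01, c(d3, 3L))
  expect_equal(as.numeric(computeTke(s2)), rep(0.5 * 1060 * 0.03, 8))
  s2[, , , 1] <- 0.01; s2[, , , 2] <- -0.01; s2[, , , 3] <- 0
  expect_equal(as.numeric(computeTke(s2)), rep(0, 8))
  expect_equal(as.numeric(computeTke(array(0, c(d3, 3L)))), rep(0, 8))
})

test_that("peak systole and the +/-5% window follow the cycle geometry", {
  d3 <- c(4L, 4L, 4L)
  mask <- array(TRUE, d3)
  mkData <- function(w) {
    nt <- length(w)
    vel <- array(0, c(d3, 3L, nt))
    for (t in seq_len(nt)) vel[, , , 3, t] <- w[t]
    FlowDataset(vel, array(1, c(d3, 4L, nt)), venc = 1.5, voxelSpacing = 2.5)
  }
  w <- rep(0.2, 40); w[13] <- 1                   # peak at frame 13 (fraction 0.3)
  ps <- findPeakSystole(mkData(w), mask)
  expect_equal(ps$peakFrame, 13L)
  expect_equal(ps$windowFrames, 11:15)            # +/-5% of 40 frames = +/-2
  ps0 <- findPeakSystole(mkData(rep(0.5, 8)), mask)
  expect_equal(ps0$peakFrame, 1L)                 # tie -> earliest
  ps1 <- findPeakSystole(mkData(1), mask)
  expect_equal(ps1$windowFrames, 1L)
  # window width ~10% of the cycle for any frame count
  for (nt in c(10L, 20L, 40L)) {
    w2 <- systolicWaveform(nt)
    nw <- length(findPeakSystole(mkData(w2), mask)$windowFrames)
    expect_true(nw >= floor(0.1 * nt) && nw <= ceiling(0.1 * nt) + 1L)
  }
})

test_that("Reynolds number is linear in velocity and diameter", {
  expect_equal(computeReynolds(0, 20), 0)
  expect_equal(computeReynolds(1, 20), 1060 * 1 * 0.02 / 3.5e-3)
  expect_equal(computeReynolds(2, 20), 2 * computeReynolds(1, 20))
  expect_equal(computeReynolds(1, 40), 2 * computeReynolds(1, 20))
  # Young whole-aorta means land inside the reported interquartile range
  re <- computeReynolds(0.74, 18)
  expect_gt(re, 3697); expect_lt(re, 4323)
})

test_that("regional aggregation recovers prescribed TKE and mean fields", {
  sp <- phantomSpec(nTimeframes = 10L, sigmaLevel = 0.1, venc = 1.5,
                    seed = 31L)
  ph <- generatePhantom(sp)
  res <- analyzeSubject(ph$data, truth = ph$truth)
  m <- res$metrics
  expect_setequal(m$region, c("AAo", "DAo", "SAA", "IAA", "Whole"))
  # noise-free round trip: every regional TKE is exactly 15.9 J/m3
  expect_equal(m$tke, rep(0.5 * 1060 * 3 * 0.01, 5), tolerance = 1e-9)
  expect_true(all(m$helicity >= 0 & m$helicity <= 1))
  expect_true(all(m$velocity > 0))
  expect_equal(m$reynolds,
               computeReynolds(m$velocity, m$diameter_mm), tolerance = 1e-12)
})

test_that("mean helicity rises with swirl and a uniform field averages to itself", {
  helOf <- function(c) {
    sp <- phantomSpec("straight", list(length = 80), lumenRadius = 12,
                      swirlRatio = c, nTimeframes = 1L, waveform = 1,
                      sigmaLevel = 0)
    vf <- generateVelocityField(sp)
    v <- vf$velocity[, , , , 1]
    lnh <- computeLnh(v, computeVorticity(v, vf$lumenMask, 2.5))
    mean(lnh[vf$lumenMask], na.rm = TRUE)
  }
  h <- vapply(c(0, 0.25, 0.5), helOf, numeric(1))
  expect_true(all(diff(h) > 0))          # rising over the physiological range
  expect_gt(helOf(1), helOf(0))
})
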