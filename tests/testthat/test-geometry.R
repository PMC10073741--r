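# PC-MRA, segmentation, centerline extraction, landmarks, the four-region
# partition, tortuosity and diameter.

test_that("PC-MRA follows its defining formula", {
  d3 <- c(6L, 6L, 6L)
  vel <- array(0, c(d3, 3L, 2L))
  mags <- array(100, c(d3, 4L, 2L))
  d <- FlowDataset(vel, mags, venc = 1.5, voxelSpacing = 2.5)
  expect_equal(computePcmra(d), array(0, d3))        # zero speed -> zero
  vel[, , , 1, ] <- 1
  d <- FlowDataset(vel, mags, venc = 1.5, voxelSpacing = 2.5)
  expect_equal(computePcmra(d), array(100, d3))      # |S| 100 x speed 1
})

test_that("PC-MRA lumen/background contrast exceeds 10:1 on the default phantom", {
  ph <- generatePhantom(phantomSpec(nTimeframes = 10L, snr = 30, seed = 2L))
  p <- computePcmra(ph$data)
  lum <- ph$truth@lumenMask
  expect_gt(mean(p[lum]) / max(mean(p[!lum]), 1e-12), 10)
})

test_that("segmentation recovers the phantom lumen and rejects empty input", {
  ph <- generatePhantom(phantomSpec(nTimeframes = 10L, seed = 1L))
  m <- segmentLumen(computePcmra(ph$data))
  g <- ph$truth@lumenMask
  expect_gte(2 * sum(m & g) / (sum(m) + sum(g)), 0.95)
  expect_error(segmentLumen(array(0, c(5, 5, 5))), "empty")
})

test_that("segmentation stays accurate under SNR-30 magnitude noise", {
  dice <- vapply(1:5, function(s) {
    ph <- generatePhantom(phantomSpec(nTimeframes = 10L, snr = 30,
                                      seed = as.integer(300 + s)))
    m <- segmentLumen(computePcmra(ph$data))
    g <- ph$truth@lumenMask
    2 * sum(m & g) / (sum(m) + sum(g))
  }, numeric(1))
  expect_true(all(dice >= 0.90))
})

test_that("centerline recovery: straight length within 2%, semicircle tortuosity within 5%", {
  sp <- phantomSpec("straight", list(length = 100), lumenRadius = 10,
                    nTimeframes = 1L, waveform = 1, sigmaLevel = 0)
  vf <- generateVelocityField(sp)
  ep <- vf$curve$landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ]
  cl <- extractCenterline(vf$lumenMask, 2.5, ep)
  expect_lt(abs(max(arcLength(cl)) - 100) / 100, 0.02)

  sp2 <- phantomSpec("arc", list(radius = 50, angle = pi), lumenRadius = 10,
                     nTimeframes = 1L, waveform = 1, sigmaLevel = 0)
  vf2 <- generateVelocityField(sp2)
  ep2 <- vf2$curve$landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ]
  cl2 <- extractCenterline(vf2$lumenMask, 2.5, ep2)
  expect_lt(abs(computeTortuosity(cl2) - (pi / 2 - 1) * 100) /
              ((pi / 2 - 1) * 100), 0.05)
})

test_that("disconnected endpoints raise an informative error", {
  mask <- array(FALSE, c(12L, 6L, 6L))
  mask[1:4, 3:4, 3:4] <- TRUE
  mask[9:12, 3:4, 3:4] <- TRUE
  ep <- rbind(c(0, 7.5, 7.5), c(27.5, 7.5, 7.5))
  expect_error(extractCenterline(mask, 2.5, ep), "disconnected")
})

test_that("arch top is the most superior point with smallest-s tie-break", {
  sp <- phantomSpec(nTimeframes = 1L, waveform = 1, sigmaLevel = 0)
  vf <- generateVelocityField(sp)
  ep <- vf$curve$landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ]
  cl <- extractCenterline(vf$lumenMask, 2.5, ep)
  sTop <- locateArchTop(cl)
  truthTop <- aortaflow:::mapLandmarks(
    cl, vf$curve$landmarkPoints["arch_top", , drop = FALSE])
  expect_lt(abs(sTop - truthTop), 2 * 2.5)  # within one knot of truth

  # flat-top tie: first (smallest s) of the tied points wins
  flat <- new("Centerline",
              points = cbind(seq(0, 50, 10), 0, c(0, 10, 10, 10, 5, 0)),
              s = seq(0, 50, 10))
  expect_equal(locateArchTop(flat), 10)

  # straight vertical tube: degenerate, returns the distal extreme
  vert <- straightCenterline(100, 11L)
  expect_equal(locateArchTop(vert), 100)
})

test_that("partition applies the arch-top and arc-length midway rules", {
  cl <- straightCenterline(600, 601L)
  lms <- c(aortic_valve = 0, arch_top = 100, left_subclavian = 150,
           renal_branches = 450, iliac_bifurcation = 600)
  mask <- array(FALSE, c(3L, 3L, 41L))
  mask[2, 2, ] <- TRUE   # thin lumen along the centerline, 15 mm spacing
  part <- partitionRegions(cl, lms, mask, spacing = c(1, 1, 15))
  iv <- regionIntervals(part)
  expect_equal(iv$s_start, c(0, 100, 300, 450))   # midway (150+450)/2 = 300
  expect_equal(iv$s_end, c(100, 300, 450, 600))
  # every lumen voxel labelled exactly once
  expect_equal(sum(regionLabels(part) > 0), sum(mask))

  bad <- lms; bad["arch_top"] <- 0
  expect_error(partitionRegions(cl, bad, mask, spacing = c(1, 1, 15)),
               "ordering")
})

test_that("regional intervals tile the centerline and lengths add up", {
  sp <- phantomSpec(nTimeframes = 1L, waveform = 1, sigmaLevel = 0)
  vf <- generateVelocityField(sp)
  ep <- vf$curve$landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ]
  cl <- extractCenterline(vf$lumenMask, 2.5, ep)
  lms <- aortaflow:::mapLandmarks(cl, vf$curve$landmarkPoints)
  part <- partitionRegions(cl, lms, vf$lumenMask, 2.5)
  iv <- regionIntervals(part)
  expect_equal(iv$s_start[-1], iv$s_end[-4])
  expect_equal(sum(iv$s_end - iv$s_start), max(iv$s_end) - min(iv$s_start))
  lab <- regionLabels(part)
  expect_equal(sum(lab > 0), sum(vf$lumenMask))
})

test_that("tortuosity is invariant under rigid motion and uniform scaling", {
  set.seed(11)
  t <- seq(0, 2, length.out = 200)
  pts <- cbind(30 * cos(t), 30 * sin(t), 15 * t)
  cl <- new("Centerline", points = pts, s = aortaflow:::polylineArcLength(pts))
  t0 <- computeTortuosity(cl)
  for (rep in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    sc <- runif(1, 0.3, 3)
    p2 <- sc * (pts %*% (Rx %*% Rz)) + matrix(runif(3, -50, 50), 200, 3, byrow = TRUE)
    cl2 <- new("Centerline", points = p2, s = aortaflow:::polylineArcLength(p2))
    expect_equal(computeTortuosity(cl2), t0, tolerance = 1e-9)
  }
  expect_gte(t0, 0)
})

test_that("tortuosity rejects degenerate intervals", {
  circ <- seq(0, 2 * pi, length.out = 100)
  pts <- cbind(cos(circ), sin(circ), 0) * 50
  cl <- new("Centerline", points = pts, s = aortaflow:::polylineArcLength(pts))
  expect_error(computeTortuosity(cl), "coincident")  # closed loop, D = 0
  cl2 <- straightCenterline(100, 101L)
  expect_error(computeTortuosity(cl2, c(-5, 50)), "outside")
})

test_that("diameter matches an analytic cylinder and scales with radius", {
  diamOf <- function(rad) {
    sp <- phantomSpec("straight", list(length = 100), lumenRadius = rad,
                      nTimeframes = 1L, waveform = 1, sigmaLevel = 0)
    vf <- generateVelocityField(sp)
    ep <- vf$curve$landmarkPoints[c("aortic_valve", "iliac_bifurcation"), ]
    cl <- extractCenterline(vf$lumenMask, 2.5, ep)
    smax <- max(arcLength(cl))
    lms <- c(aortic_valve = 0, arch_top = 0.3 * smax,
             left_subclavian = 0.45 * smax, renal_branches = 0.8 * smax,
             iliac_bifurcation = smax)
    part <- partitionRegions(cl, lms, vf$lumenMask, 2.5)
    computeDiameter(part, "Whole", 2.5)
  }
  d10 <- diamOf(10)
  expect_lt(abs(d10 - 20) / 20, 0.05)
  d5 <- diamOf(5)
  expect_lt(abs(d5 - 10) / 10, 0.08)  # coarser voxelisation at 4 voxels/diameter
  # empty region errors
  cl <- straightCenterline(100, 101L)
  lms <- c(aortic_valve = 0, arch_top = 30, left_subclavian = 45,
           renal_branches = 80, iliac_bifurcation = 100)
  mask <- array(FALSE, c(3L, 3L, 41L)); mask[2, 2, 1:10] <- TRUE
  part <- partitionRegions(cl, lms, mask, spacing = c(1, 1, 2.5))
  expect_error(computeDiameter(part, "IAA", c(1, 1, 2.5)), "empty")
})
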