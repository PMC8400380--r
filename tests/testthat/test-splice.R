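test_that("noiseless exact-ratio inputs splice back to the high-gain
          k-space", {
  spec <- phantomSpec(M = 220, K = 440)
  acqs <- simulateStudy(spec, receiverModel(),
                        gainsDb = c(12, 6, 0), seeds = c(1L, 2L, 3L))
  sp <- spliceKSpace(acqs$hi, acqs$mid, acqs$lo)
  ref <- kspaceData(acqs$hi)
  err <- max(Mod(kspaceData(splicedKSpace(sp)) - ref)) / max(Mod(ref))
  expect_lt(err, 1e-9)
  expect_equal(sp@phaseOffsetsDeg, c(region2 = 0, region3 = 0))
})

test_that("identical inputs with forced unit factors return the input", {
  acq <- randomAcq(220, 64, gainDb = 0, seed = 8)
  hi <- KSpaceAcquisition(kspaceData(acq), 12)
  mid <- KSpaceAcquisition(kspaceData(acq), 6)
  lo <- KSpaceAcquisition(kspaceData(acq), 0)
  sp <- spliceKSpace(hi, mid, lo, N = 32)
  # all three hold the same data, so every factor estimates to exactly 1
  expect_equal(dg1Average(spliceFactors(sp)), 1, tolerance = 1e-12)
  expect_equal(chainedAverage(spliceFactors(sp)), 1, tolerance = 1e-12)
  expect_equal(kspaceData(splicedKSpace(sp)), kspaceData(acq),
               tolerance = 1e-12)
})

test_that("region provenance follows the canonical line ranges for M=220", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver(),
                        seeds = c(41L, 42L, 43L))
  sp <- spliceKSpace(acqs$hi, acqs$mid, acqs$lo)
  d <- kspaceData(splicedKSpace(sp))
  f <- spliceFactors(sp)
  # every line is bit-identical to (compensated) lines of one source
  expect_identical(d[c(1:36, 185:220), ],
                   kspaceData(acqs$hi)[c(1:36, 185:220), ])
  expect_identical(d[c(37:72, 149:184), ],
                   kspaceData(acqs$mid)[c(37:72, 149:184), ] * f@dg1Avg)
  expect_identical(d[73:148, ],
                   kspaceData(acqs$lo)[73:148, ] * f@chainedAvg)
})

test_that("re-applying the recorded audit reproduces the splice exactly", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver(),
                        seeds = c(44L, 45L, 46L))
  sp <- spliceKSpace(acqs$hi, acqs$mid, acqs$lo)
  meta <- acqMeta(splicedKSpace(sp))
  p <- sp@partition
  d <- kspaceData(acqs$hi)
  r2 <- regionLines(p, 2); r3 <- regionLines(p, 3)
  d[r2, ] <- kspaceData(acqs$mid)[r2, ] * meta$gainCompensation$region2 *
    exp(1i * meta$phaseCompensationDeg$region2 * pi / 180)
  d[r3, ] <- kspaceData(acqs$lo)[r3, ] * meta$gainCompensation$region3 *
    exp(1i * meta$phaseCompensationDeg$region3 * pi / 180)
  expect_identical(d, kspaceData(splicedKSpace(sp)))
})

test_that("amplitude ordering of the spliced regions holds", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver(),
                        seeds = c(47L, 48L, 49L))
  sp <- spliceKSpace(acqs$hi, acqs$mid, acqs$lo)
  p <- sp@partition
  m <- Mod(kspaceData(splicedKSpace(sp)))
  means <- vapply(1:3, function(i) mean(m[regionLines(p, i), ]), numeric(1))
  expect_gt(means[3], means[2])
  expect_gt(means[2], means[1])
})

test_that("splice contract violations are hard errors", {
  acqs <- simulateStudy(phantomSpec(M = 64, K = 64), cleanReceiver(),
                        seeds = c(9L, 10L, 11L))
  expect_error(spliceKSpace(acqs$lo, acqs$mid, acqs$hi),
               "strictly descending")
  small <- randomAcq(16, 16, gainDb = 20)
  expect_error(spliceKSpace(small, acqs$mid, acqs$lo), "same shape")

  # clipping inside a used region: clip the outer lines of the high gain
  hiClipped <- acqs$hi
  hiClipped@meta$clipLines <- c(2L, 3L)
  expect_error(spliceKSpace(hiClipped, acqs$mid, acqs$lo),
               "clipped samples inside used region1.*2, 3")
})

test_that("injected per-scan phase offsets are compensated in the splice", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver(),
                        seeds = c(51L, 52L, 53L),
                        phaseOffsetsDeg = c(0, 40, -20))
  sp <- spliceKSpace(acqs$hi, acqs$mid, acqs$lo)
  # region2 was rotated by -40 deg at acquisition; compensation ~ +(-40)?
  # gamma(hi,mid) = 0 - 40 = -40, so the applied offset is about -40... no:
  # the mid scan carries +40 deg, gamma = phi_hi - phi_mid = -40, and
  # multiplying region2 by e^{i(-40)} removes the +40 it carries.
  expect_lt(abs(sp@phaseOffsetsDeg[["region2"]] - (-40)), 1)
  expect_lt(abs(sp@phaseOffsetsDeg[["region3"]] - 20), 1)
  # after compensation the spliced k-space phase-matches the reference scan
  noiseless <- simulateStudy(phantomSpec(), receiverModel(),
                             gainsDb = c(12, 6, 0), seeds = c(1L, 2L, 3L))
  ref <- kspaceData(noiseless$hi)
  d <- kspaceData(splicedKSpace(sp))
  p <- defaultPartition(220)
  r3 <- regionLines(p, 3)
  strong <- Mod(ref[r3, ]) > 0.1 * max(Mod(ref))
  dphi <- wrapDegrees((Arg(d[r3, ]) - Arg(ref[r3, ]))[strong] * 180 / pi)
  expect_lt(abs(kspaceSplice:::circularMeanDeg(dphi)), 2)
})
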