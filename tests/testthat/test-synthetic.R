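test_that("phantom geometry matches its specification", {
  img <- makePhantom(phantomSpec(M = 64, K = 64, radiusFrac = 0.5,
                                 intensity = 100, edgeSoftness = 0))
  expect_equal(img[33, 33], 100)             # center pixel
  expect_equal(img[1, 1], 0)                 # corner pixel
  expect_setequal(unique(as.vector(img)), c(0, 100))  # hard edge: two values

  # disk area vs pi r^2, counting pixels >= intensity/2
  img256 <- makePhantom(phantomSpec(M = 256, K = 256, radiusFrac = 0.5,
                                    intensity = 100, edgeSoftness = 1))
  r <- 0.5 * 256 / 2
  expect_equal(sum(img256 >= 50), pi * r^2, tolerance = 0.02)

  # softened rim takes intermediate values but stays in [0, intensity]
  soft <- makePhantom(phantomSpec(M = 64, K = 64, edgeSoftness = 3))
  expect_true(all(soft >= 0 & soft <= 100))
  expect_gt(sum(soft > 0 & soft < 100), 0)
})

test_that("identity receiver returns the centered DFT exactly", {
  img <- makePhantom(phantomSpec(M = 32, K = 48))
  acq <- acquire(img, receiverModel(), seed = 1)
  expected <- kspaceSplice:::fftshift2(stats::fft(img))
  expect_equal(kspaceData(acq), expected, tolerance = 1e-12)
  # DC (max amplitude) sits at the matrix center: centered convention
  pk <- arrayInd(which.max(Mod(kspaceData(acq))), dim(acq))
  expect_equal(as.vector(pk), c(32 %/% 2 + 1, 48 %/% 2 + 1))
})

test_that("a 20*log10(2) dB gain doubles every sample", {
  img <- makePhantom(phantomSpec(M = 32, K = 32))
  a0 <- acquire(img, receiverModel(gainDb = 0), seed = 1)
  a2 <- acquire(img, receiverModel(gainDb = 20 * log10(2)), seed = 1)
  expect_equal(kspaceData(a2) / kspaceData(a0),
               matrix(2 + 0i, 32, 32), tolerance = 1e-9)
})

test_that("the mid-rise quantizer meets the textbook SNR for a sine", {
  # full-scale sine: quantization SNR ~ 6.02 b + 1.76 dB
  bits <- 12L
  x <- (1 - 2^-13) * sin(2 * pi * (0:49999) * 0.01237)
  q <- kspaceSplice:::quantizeReal(x, bits, 1)
  snrDb <- 10 * log10(mean(x^2) / mean((q$q - x)^2))
  expect_equal(snrDb, 6.02 * bits + 1.76, tolerance = 1 / 74)

  # quantization error bounded by one half step away from saturation
  step <- 2 / 2^bits
  expect_lt(max(abs(q$q - x)), step)
  # saturation at +/-(fullScale - step/2)
  big <- kspaceSplice:::quantizeReal(c(-5, 5), bits, 1)
  expect_equal(big$q, c(-(1 - step / 2), 1 - step / 2))
  expect_true(all(big$clipped))
})

test_that("acquire is a pure function of image, receiver and seed", {
  img <- makePhantom(phantomSpec(M = 16, K = 16))
  rx <- receiverModel(gainDb = 3, preNoiseSigma = 2, postNoiseSigma = 1,
                      adcBits = 10L, fullScale = 1e4)
  a1 <- acquire(img, rx, seed = 7)
  a2 <- acquire(img, rx, seed = 7)
  expect_identical(kspaceData(a1), kspaceData(a2))
  a3 <- acquire(img, rx, seed = 8)
  expect_false(identical(kspaceData(a1), kspaceData(a3)))
  # caller RNG state is untouched
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(acquire(img, rx, seed = 7)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("noiseless study scales exactly as the gain ladder", {
  spec <- phantomSpec(M = 32, K = 32)
  acqs <- simulateStudy(spec, receiverModel(),
                        gainsDb = c(20 * log10(4), 20 * log10(2), 0),
                        seeds = c(1L, 2L, 3L))
  expect_equal(kspaceData(acqs$hi), 4 * kspaceData(acqs$lo),
               tolerance = 1e-12)
  expect_equal(kspaceData(acqs$mid), 2 * kspaceData(acqs$lo),
               tolerance = 1e-12)
  # Parseval: k-space energy = M*K * image energy (unnormalized forward)
  img <- makePhantom(spec)
  e <- sum(Mod(kspaceData(acqs$lo))^2)
  expect_equal(e, length(img) * sum(img^2), tolerance = 1e-12)
})

test_that("study contract: three descending gains, three distinct seeds", {
  spec <- phantomSpec(M = 16, K = 16)
  rx <- receiverModel()
  expect_error(simulateStudy(spec, rx, gainsDb = c(0, 6, 12),
                             seeds = c(1L, 2L, 3L)), "descending")
  expect_error(simulateStudy(spec, rx, gainsDb = c(12, 6),
                             seeds = c(1L, 2L, 3L)), "three")
  expect_error(simulateStudy(spec, rx, seeds = c(1L, 1L, 2L)), "distinct")
})

test_that("default study clips only central lines of the highest gain", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver())
  p <- defaultPartition(220)
  clHi <- acqMeta(acqs$hi)$clipLines
  expect_gt(length(clHi), 0)                       # central clipping exists
  expect_length(intersect(clHi, regionLines(p, 1)), 0)  # outer lines clean
  expect_true(all(clHi %in% regionLines(p, 3)))
  expect_length(acqMeta(acqs$lo)$clipLines, 0)     # lowest gain never clips
  # clipped samples sit at the saturation rails
  step <- 2 * 1.2e6 / 2^12
  d <- kspaceData(acqs$hi)
  expect_equal(max(abs(Re(d))), 1.2e6 - step / 2)
})

test_that("echo amplitude ordering region3 > region2 > region1 holds", {
  acqs <- simulateStudy(phantomSpec(), studyReceiver())
  p <- defaultPartition(220)
  m <- Mod(kspaceData(acqs$lo))
  means <- vapply(1:3, function(i) mean(m[regionLines(p, i), ]), numeric(1))
  expect_gt(means[3], means[2])
  expect_gt(means[2], means[1])
})
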