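test_that("line groups are consecutive blocks of 4 labeled ceil(m/4)*4", {
  g <- lineGroups(37:44)
  expect_length(g, 2)
  expect_equal(g[[1]]$label, 40L)
  expect_equal(g[[1]]$lines, 37:40)
  expect_equal(g[[2]]$label, 44L)
  expect_equal(g[[2]]$lines, 41:44)
  g1 <- lineGroups(1:4)
  expect_length(g1, 1)
  expect_equal(g1[[1]]$label, 4L)
  expect_error(lineGroups(1:6), "multiple of 4")
})

test_that("middle samples take the centered N columns as magnitudes", {
  # K = 440, N = 120 -> columns 161..280
  z <- matrix(complex(real = 0, imaginary = 0), 12, 440)
  z[5, 161:280] <- 3 + 4i
  acq <- KSpaceAcquisition(z, gainDb = 0)
  expect_equal(middleSamples(acq, 5, 120), rep(5, 120))  # |3+4i| = 5
  z2 <- matrix(3 + 4i, 12, 8)
  acq2 <- KSpaceAcquisition(z2, gainDb = 0)
  expect_equal(middleSamples(acq2, 1, 8), rep(5, 8))     # N = K: whole line
  expect_error(middleSamples(acq2, 1, 9), "N must be")
})

test_that("gain factor is exact on scaled and identical pairs", {
  b <- randomAcq(16, 32, seed = 3)
  a <- KSpaceAcquisition(kspaceData(b) * 2, gainDb = 6)
  f <- gainFactor(a, b, 1:16, N = 16)
  expect_equal(f$beta, rep(2, 4), tolerance = 1e-12)
  expect_equal(f$average, 2, tolerance = 1e-12)
  expect_equal(gainFactor(b, b, 1:16, N = 16)$average, 1,
               tolerance = 1e-15)
  # consistency across true ratios
  for (r in c(1.5, 2, 4, 8)) {
    ar <- KSpaceAcquisition(kspaceData(b) * r, gainDb = 20 * log10(r))
    expect_equal(gainFactor(ar, b, 1:16, N = 16)$average, r,
                 tolerance = 1e-12)
  }
})

test_that("gain factor matches the brute-force oracle", {
  # hand-written toy pair with integer magnitudes, estimated on 8 lines
  M <- 12L; K <- 16L
  B <- matrix(complex(real = rep(1:12, each = K) %% 5 + 1), M, K,
              byrow = TRUE)
  A <- B * 3
  fo <- oracleGainFactor(A, B, 1:8, N = 10)
  f <- gainFactor(KSpaceAcquisition(A, 6), KSpaceAcquisition(B, 0),
                  1:8, N = 10)
  expect_equal(f$labels, fo$labels)
  expect_equal(unname(f$beta), fo$beta)
  expect_equal(f$average, fo$average)

  # property: random instances, implementation == naive loop
  for (seed in 1:5) {
    a <- randomAcq(16, 16, seed = seed)
    b <- randomAcq(16, 16, seed = seed + 50)
    fo <- oracleGainFactor(kspaceData(a), kspaceData(b), 1:16, N = 12)
    f <- gainFactor(a, b, 1:16, N = 12)
    expect_equal(unname(f$beta), fo$beta, tolerance = 1e-14)
    expect_equal(f$average, fo$average, tolerance = 1e-14)
  }
})

test_that("the ratio guard excludes tiny denominators and degenerate
          groups error by name", {
  M <- 12L; K <- 16L
  B <- matrix(complex(real = 1), M, K)
  B[1:4, ] <- 1e-12 + 0i       # a whole group below the guard? no: the
  B[1:4, 8] <- 1 + 0i          # max sets the scale, so keep one real value
  A <- B * 2
  f <- gainFactor(KSpaceAcquisition(A, 6), KSpaceAcquisition(B, 0),
                  1:12, N = 16)
  expect_equal(unname(f$beta), rep(2, 3), tolerance = 1e-12)

  Z <- matrix(complex(real = 0), M, K)
  expect_error(gainFactor(KSpaceAcquisition(A, 6),
                          KSpaceAcquisition(Z, 0), 1:12, N = 16),
               "degenerate|NaN")
})

test_that("gain recovery under noise stays within 5% at SNR >= 20", {
  set.seed(42)
  M <- 16L; K <- 64L; N <- 48L
  amp <- 100; sigma <- 4    # per-sample magnitude SNR = 25
  mk <- function(scale, seed) {
    set.seed(seed)
    z <- matrix(complex(real = amp * scale + rnorm(M * K, sd = sigma),
                        imaginary = rnorm(M * K, sd = sigma)), M, K)
    KSpaceAcquisition(z, gainDb = 20 * log10(scale))
  }
  f <- gainFactor(mk(2, 1), mk(1, 2), 1:16, N = N)
  expect_equal(f$average, 2, tolerance = 0.05)
})

test_that("chained factor averages the per-group products", {
  f12 <- list(labels = c(76L, 80L), beta = c(2, 2))
  f23 <- list(labels = c(76L, 80L), beta = c(1.9, 2.1))
  ch <- chainedGainFactor(f12, f23)
  expect_equal(ch$chained, c(3.8, 4.2))
  expect_equal(ch$average, 4)
  expect_equal(chainedGainFactor(list(labels = 4L, beta = 2),
                                 list(labels = 4L, beta = 2))$average, 4)
  expect_error(chainedGainFactor(list(labels = 4L, beta = 2),
                                 list(labels = 8L, beta = 2)),
               "no common")
})

test_that("amplitude compensation scales magnitude and preserves phase", {
  acq <- randomAcq(16, 24, seed = 9)
  same <- applyGain(acq, 1:16, 1)
  expect_equal(kspaceData(same), kspaceData(acq))
  comp <- applyGain(acq, 5:8, 2)
  expect_equal(Mod(kspaceData(comp)[5:8, ]),
               2 * Mod(kspaceData(acq)[5:8, ]), tolerance = 1e-12)
  expect_lt(max(abs(Arg(kspaceData(comp)[5:8, ]) -
                    Arg(kspaceData(acq)[5:8, ]))), 1e-12)
  expect_equal(kspaceData(comp)[1:4, ], kspaceData(acq)[1:4, ])
  expect_error(applyGain(acq, 1:4, -1), "positive")

  # compensation closes the loop with the estimator on a noiseless pair
  b <- randomAcq(16, 24, seed = 10)
  a <- KSpaceAcquisition(kspaceData(b) * 2, gainDb = 6)
  f <- gainFactor(a, b, 1:16, N = 12)
  fixed <- applyGain(b, 1:16, f$average)
  expect_equal(kspaceData(fixed), kspaceData(a), tolerance = 1e-12)
})

test_that("estimation uses the contracted line sets per region", {
  # dG1 from regions 2-3 of hi/mid, dG2 from region 3 of mid/lo
  acqs <- simulateStudy(phantomSpec(M = 64, K = 64), cleanReceiver(),
                        seeds = c(5L, 6L, 7L))
  p <- defaultPartition(64)
  f <- estimateGainFactors(acqs$hi, acqs$mid, acqs$lo, partition = p,
                           N = 32)
  g23 <- lineGroups(sort(c(regionLines(p, 2), regionLines(p, 3))))
  g3 <- lineGroups(regionLines(p, 3))
  expect_equal(f@dg1Labels,
               unname(vapply(g23, `[[`, integer(1), "label")))
  expect_equal(f@dg2Labels,
               unname(vapply(g3, `[[`, integer(1), "label")))
})
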