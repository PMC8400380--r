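# Brute-force oracle for the gain-difference factor: naive double loop,
# written independently of the vectorized implementation and kept dumb
# on purpose.
oracleGainFactor <- function(A, B, lines, N, eps = 1e-6) {
  stopifnot(length(lines) %% 4 == 0)
  lines <- sort(lines)
  K <- ncol(A)
  start <- floor((K - N) / 2) + 1
  labels <- integer(0)
  betas <- numeric(0)
  for (g in seq(1, length(lines), by = 4)) {
    block <- lines[g:(g + 3)]
    label <- ceiling(block[4] / 4) * 4
    rep <- if (label %in% block) label else block[4]
    da <- numeric(N); db <- numeric(N)
    for (j in 1:N) {
      da[j] <- abs(A[rep, start + j - 1])
      db[j] <- abs(B[rep, start + j - 1])
    }
    mx <- max(db)
    alphas <- numeric(0)
    for (j in 1:N) {
      if (db[j] > eps * mx) alphas <- c(alphas, da[j] / db[j])
    }
    betas <- c(betas, sum(alphas) / length(alphas))
    labels <- c(labels, label)
  }
  list(labels = labels, beta = betas,
       average = sum(betas) / length(betas))
}

# partition invariants used by several property tests
expectValidPartition <- function(p) {
  r1 <- regionLines(p, 1); r2 <- regionLines(p, 2); r3 <- regionLines(p, 3)
  M <- p@M
  expect_setequal(c(r1, r2, r3), seq_len(M))
  expect_equal(anyDuplicated(c(r1, r2, r3)), 0L)
  expect_true(all(diff(r3) == 1))          # central block contiguous
  expect_setequal(M + 1L - r1, r1)         # symmetric about center
  expect_setequal(M + 1L - r2, r2)
}
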