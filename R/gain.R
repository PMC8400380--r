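## Gain-difference factor estimation and amplitude compensation.

#' Consecutive groups of four phase-encoding lines
#'
#' Splits a sorted set of line indices into consecutive blocks of four,
#' in index order. Each block is labeled `ceil(m/4) * 4` where `m` is the
#' block's last line, so labels are multiples of 4 and, whenever the
#' blocks align with the natural 4-line grid (as the default partition
#' guarantees), the label is itself a line of the block -- the group's
#' representative line used for estimation.
#'
#' @param lines sorted integer vector; length must be divisible by 4.
#' @return list of groups, each `list(label =, lines =)`.
#' @examples
#' lineGroups(37:44)
#' @export
lineGroups <- function(lines) {
  lines <- as.integer(lines)
  if (length(lines) == 0L || length(lines) %% 4L != 0L)
    stop("number of lines must be a positive multiple of 4")
  if (is.unsorted(lines, strictly = TRUE))
    stop("lines must be strictly sorted")
  idx <- split(seq_along(lines), rep(seq_len(length(lines) / 4L), each = 4L))
  lapply(idx, function(i) {
    b <- lines[i]
    list(label = as.integer(ceiling(b[4L] / 4) * 4), lines = b)
  })
}

#' Middle-sample magnitudes of one phase-encoding line
#'
#' Magnitudes of the `N` contiguous frequency-encoding samples centered
#' on the line: columns `floor((K - N)/2) + 1` through
#' `floor((K - N)/2) + N` (1-based), the same parity convention for
#' every call.
#'
#' @param acq a [KSpaceAcquisition-class].
#' @param line 1-based line index.
#' @param N number of middle samples, `1 <= N <= K`.
#' @return numeric vector of `N` absolute values.
#' @examples
#' acq <- KSpaceAcquisition(matrix(3 + 4i, 12, 8), gainDb = 0)
#' middleSamples(acq, 1, 4)  # all 5
#' @export
middleSamples <- function(acq, line, N) {
  stopifnot(is(acq, "KSpaceAcquisition"))
  K <- ncol(acq@data)
  N <- as.integer(N)
  if (N < 1L || N > K) stop("N must be in 1..K (K = ", K, ")")
  start <- (K - N) %/% 2L + 1L
  Mod(acq@data[line, start:(start + N - 1L)])
}

#' Estimate the gain-difference factor between two acquisitions
#'
#' For each group of four lines (see [lineGroups()]) the representative
#' line's middle-`N` magnitudes are extracted from both acquisitions
#' (`deltaA`, `deltaB`), the per-sample ratios `alpha_i = deltaA_i /
#' deltaB_i` are formed -- excluding pairs whose denominator is at or
#' below `eps` times the line's maximum magnitude, which guards against
#' quantized zeros -- and averaged into the group factor `beta`. The
#' overall factor is the unweighted mean of the per-group betas.
#'
#' Lines named in `excludeLines` (by default the clipped lines recorded
#' in either acquisition's `meta$clipLines`) never serve as
#' representative lines: a clipped magnitude is not evidence of the gain
#' ratio.
#'
#' @param acqA,acqB same-shape [KSpaceAcquisition-class] objects
#'   (numerator / denominator).
#' @param lines sorted line indices over which to estimate (present in
#'   both acquisitions); count divisible by 4.
#' @param N middle-sample count per line (default 120).
#' @param eps relative denominator guard (default 1e-6).
#' @param excludeLines lines to drop from estimation, or `NULL` to use
#'   the acquisitions' recorded clip lines.
#' @return list with `labels` (integer group labels), `beta` (per-group
#'   factors), `average` (their mean), `N`, `eps` and `nExcludedGroups`.
#' @examples
#' a <- KSpaceAcquisition(matrix(2 + 0i, 12, 16), gainDb = 6)
#' b <- KSpaceAcquisition(matrix(1 + 0i, 12, 16), gainDb = 0)
#' gainFactor(a, b, 1:12, N = 8)$average  # 2
#' @export
gainFactor <- function(acqA, acqB, lines, N = 120L, eps = 1e-6,
                       excludeLines = NULL) {
  stopifnot(is(acqA, "KSpaceAcquisition"), is(acqB, "KSpaceAcquisition"))
  if (!identical(dim(acqA@data), dim(acqB@data)))
    stop("acquisitions must have the same shape")
  if (is.null(excludeLines))
    excludeLines <- union(acqA@meta$clipLines, acqB@meta$clipLines)
  groups <- lineGroups(sort(as.integer(lines)))
  repLine <- function(g) if (g$label %in% g$lines) g$label else g$lines[4L]
  keep <- vapply(groups, function(g) !(repLine(g) %in% excludeLines),
                 logical(1))
  nExcluded <- sum(!keep)
  groups <- groups[keep]
  if (length(groups) == 0L)
    stop("no usable line groups remain after exclusions")
  labels <- vapply(groups, `[[`, integer(1), "label")
  beta <- vapply(groups, function(g) {
    a <- middleSamples(acqA, repLine(g), N)
    b <- middleSamples(acqB, repLine(g), N)
    ok <- b > eps * max(b)
    if (!any(ok))
      stop("degenerate data: all sample pairs excluded in group ", g$label)
    mean(a[ok] / b[ok])
  }, numeric(1))
  list(labels = unname(labels), beta = unname(beta),
       average = mean(beta), N = as.integer(N), eps = eps,
       nExcludedGroups = nExcluded)
}

#' Chain two gain-difference factor estimates
#'
#' The factor between the highest and lowest gains is the per-group
#' product `dG1(g) * dG2(g)` over the group labels common to both
#' estimates (the central-region groups), averaged unweighted.
#'
#' @param factors12 result of [gainFactor()] between the high and mid
#'   gains.
#' @param factors23 result of [gainFactor()] between the mid and low
#'   gains.
#' @return list with `labels`, per-group `chained` products and their
#'   `average`.
#' @examples
#' f12 <- list(labels = c(4L, 8L), beta = c(2, 2))
#' f23 <- list(labels = c(4L, 8L), beta = c(1.9, 2.1))
#' chainedGainFactor(f12, f23)$average  # 4
#' @export
chainedGainFactor <- function(factors12, factors23) {
  common <- intersect(factors12$labels, factors23$labels)
  if (length(common) == 0L)
    stop("no common group labels between the two factor estimates")
  p <- factors12$beta[match(common, factors12$labels)] *
       factors23$beta[match(common, factors23$labels)]
  list(labels = as.integer(common), chained = unname(p),
       average = mean(p))
}

#' Multiply the amplitude of selected lines by a gain factor
#'
#' Scales the complex samples of the given lines by a real positive
#' factor; magnitudes are multiplied, phases untouched, other lines
#' unchanged. The compensation is appended to `meta$compensation`.
#'
#' @param acq a [KSpaceAcquisition-class].
#' @param lines line indices to scale.
#' @param factor positive finite scalar.
#' @return the compensated [KSpaceAcquisition-class].
#' @export
applyGain <- function(acq, lines, factor) {
  stopifnot(is(acq, "KSpaceAcquisition"))
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("factor must be a positive finite scalar")
  lines <- as.integer(lines)
  d <- acq@data
  d[lines, ] <- d[lines, , drop = FALSE] * factor
  meta <- acq@meta
  meta$compensation <- c(meta$compensation,
                         list(list(type = "gain", lines = lines,
                                   factor = factor)))
  KSpaceAcquisition(d, gainDb = acq@gainDb, meta = meta)
}

#' Estimate all gain factors for a three-gain study
#'
#' Runs the full estimation chain: dG1 per group over regions 2-3 of the
#' high- and mid-gain acquisitions, dG2 per group over region 3 of the
#' mid- and low-gain acquisitions, and the chained per-group product
#' averaged over the common region-3 groups.
#'
#' @param acqHi,acqMid,acqLo the three acquisitions, gains strictly
#'   descending.
#' @param partition a [RegionPartition-class]; default
#'   [defaultPartition()] for the line count.
#' @param N middle-sample count (default 120).
#' @param eps denominator guard passed to [gainFactor()].
#' @return a [GainFactors-class].
#' @export
estimateGainFactors <- function(acqHi, acqMid, acqLo,
                                partition = defaultPartition(nrow(
                                  kspaceData(acqHi))),
                                N = 120L, eps = 1e-6) {
  r2 <- regionLines(partition, 2); r3 <- regionLines(partition, 3)
  f1 <- gainFactor(acqHi, acqMid, sort(c(r2, r3)), N = N, eps = eps)
  f2 <- gainFactor(acqMid, acqLo, r3, N = N, eps = eps)
  ch <- chainedGainFactor(f1, f2)
  new("GainFactors",
      dg1Labels = as.integer(f1$labels), dg1PerGroup = unname(f1$beta),
      dg2Labels = as.integer(f2$labels), dg2PerGroup = unname(f2$beta),
      dg1Avg = f1$average, chainedAvg = ch$average, N = as.integer(N))
}

#' Export gain factors as a JSON audit report
#'
#' @param factors a [GainFactors-class].
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
gainFactorsJson <- function(factors, path = NULL) {
  stopifnot(is(factors, "GainFactors"))
  x <- list(dg1_per_group = as.list(stats::setNames(factors@dg1PerGroup,
                                                    factors@dg1Labels)),
            dg2_per_group = as.list(stats::setNames(factors@dg2PerGroup,
                                                    factors@dg2Labels)),
            dg1_avg = factors@dg1Avg, chained_avg = factors@chainedAvg,
            N = factors@N)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
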