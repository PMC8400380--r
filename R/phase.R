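## Per-sample phase differences, central summary and compensation.

#' Per-sample phase-difference map between two acquisitions
#'
#' Computes `gamma[i, j] = arg(A[i, j]) - arg(B[i, j])` in degrees,
#' wrapped to (-180, 180], over the middle `N` frequency-encoding columns
#' of the listed lines. The outer, low-amplitude lines fluctuate wildly
#' under noise, so the summary (circular mean and circular SD) is taken
#' over the noise-robust central window: by default the region-3 lines of
#' [defaultPartition()] that appear in `lines`, minus any clipped lines
#' recorded by the simulator. Samples with zero magnitude in either
#' acquisition are `NA` and excluded from the summary.
#'
#' @param acqA,acqB same-shape [KSpaceAcquisition-class] objects.
#' @param lines line indices to map.
#' @param N middle-column count (default 120), `N <= K`.
#' @param summaryLines lines for the central summary, or `NULL` for the
#'   default window.
#' @param excludeClipped drop clipped lines (from either acquisition's
#'   `meta$clipLines`) from the summary window (default `TRUE`).
#' @return a [PhaseDiffMap-class].
#' @export
phaseDiffMap <- function(acqA, acqB, lines, N = 120L, summaryLines = NULL,
                         excludeClipped = TRUE) {
  stopifnot(is(acqA, "KSpaceAcquisition"), is(acqB, "KSpaceAcquisition"))
  if (!identical(dim(acqA@data), dim(acqB@data)))
    stop("acquisitions must have the same shape")
  M <- nrow(acqA@data); K <- ncol(acqA@data)
  N <- as.integer(N)
  if (N < 1L || N > K) stop("N must be in 1..K")
  lines <- sort(as.integer(lines))
  start <- (K - N) %/% 2L + 1L
  cols <- start:(start + N - 1L)
  A <- acqA@data[lines, cols, drop = FALSE]
  B <- acqB@data[lines, cols, drop = FALSE]
  gamma <- wrapDegrees((Arg(A) - Arg(B)) * 180 / pi)
  zero <- Mod(A) == 0 | Mod(B) == 0
  gamma[zero] <- NA_real_
  if (is.null(summaryLines)) {
    summaryLines <- intersect(regionLines(defaultPartition(M), 3), lines)
  } else {
    summaryLines <- intersect(as.integer(summaryLines), lines)
  }
  if (excludeClipped)
    summaryLines <- setdiff(summaryLines,
                            union(acqA@meta$clipLines, acqB@meta$clipLines))
  if (length(summaryLines) == 0L)
    stop("empty central summary window")
  win <- gamma[match(summaryLines, lines), , drop = FALSE]
  new("PhaseDiffMap", gamma = gamma, lines = lines, N = N,
      summaryLines = as.integer(summaryLines),
      centralOffsetDeg = circularMeanDeg(win),
      centralDispersionDeg = circularSdDeg(win),
      nExcluded = sum(!is.finite(win)))
}

#' Sum the central offsets of two chained phase maps
#'
#' The phase difference between the highest- and lowest-gain
#' acquisitions is the wrapped sum of the high-vs-mid and mid-vs-low
#' central offsets.
#'
#' @param mapAB,mapBC [PhaseDiffMap-class] objects for the chained pairs.
#' @return the wrapped sum in degrees.
#' @examples
#' wrapDegrees(170 + 20)  # the underlying wrap: -170
#' @export
summedPhaseOffset <- function(mapAB, mapBC) {
  stopifnot(is(mapAB, "PhaseDiffMap"), is(mapBC, "PhaseDiffMap"))
  wrapDegrees(mapAB@centralOffsetDeg + mapBC@centralOffsetDeg)
}

#' Decide the phase compensation value
#'
#' Returns 0 when the central phase offset is below `thresholdDeg` in
#' absolute value -- the regime observed on real hardware, where the
#' central phase differences are indistinguishable from zero and the
#' compensation defaults to zero -- and the offset itself otherwise, so
#' that genuinely shifted acquisitions (e.g. simulator-injected offsets)
#' are corrected.
#'
#' @param map a [PhaseDiffMap-class], or directly a numeric offset in
#'   degrees.
#' @param thresholdDeg nonnegative threshold in degrees (default 2).
#' @return the compensation value in degrees.
#' @export
setGeneric("phaseCompensationValue",
           function(map, thresholdDeg = 2) {
             standardGeneric("phaseCompensationValue")
           })

#' @rdname phaseCompensationValue
#' @export
setMethod("phaseCompensationValue", "PhaseDiffMap",
  function(map, thresholdDeg = 2) {
    phaseCompensationValue(map@centralOffsetDeg, thresholdDeg)
  })

#' @rdname phaseCompensationValue
#' @export
setMethod("phaseCompensationValue", "numeric",
  function(map, thresholdDeg = 2) {
    stopifnot(length(map) == 1L, is.finite(map), thresholdDeg >= 0)
    if (abs(map) < thresholdDeg) 0 else map
  })

#' Rotate the phase of selected lines
#'
#' Multiplies the listed lines by `exp(+1i * offsetDeg * pi/180)`;
#' magnitudes are unchanged. The compensation is appended to
#' `meta$compensation`.
#'
#' @param acq a [KSpaceAcquisition-class].
#' @param lines line indices to rotate.
#' @param offsetDeg finite phase offset in degrees.
#' @return the rotated [KSpaceAcquisition-class].
#' @export
applyPhase <- function(acq, lines, offsetDeg) {
  stopifnot(is(acq, "KSpaceAcquisition"),
            length(offsetDeg) == 1L, is.finite(offsetDeg))
  lines <- as.integer(lines)
  d <- acq@data
  d[lines, ] <- d[lines, , drop = FALSE] * exp(1i * offsetDeg * pi / 180)
  meta <- acq@meta
  meta$compensation <- c(meta$compensation,
                         list(list(type = "phase", lines = lines,
                                   offsetDeg = offsetDeg)))
  KSpaceAcquisition(d, gainDb = acq@gainDb, meta = meta)
}
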