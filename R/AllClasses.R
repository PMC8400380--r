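## S4 classes for k-space acquisitions, line partitions and reports.

#' KSpaceAcquisition: one complex k-space matrix with its gain label
#'
#' Holds a complex matrix indexed `[line m, column k]` with `m = 1..M`
#' phase-encoding lines and `k = 1..K` frequency-encoding steps (1-based,
#' as in the public API throughout), the receiver gain under which it was
#' acquired (dB, relative scale) and free-form provenance metadata. The
#' matrix is stored *centered*: the high-amplitude DC region sits at the
#' matrix center, and [reconstructImage()] performs the reordering a
#' standard DFT requires.
#'
#' Validity requires `M >= 12` and `M` divisible by 4 (the line-group
#' machinery works on complete groups of 4), finite data and a finite
#' scalar gain.
#'
#' @slot data complex matrix, lines x frequency-encoding steps.
#' @slot gainDb numeric(1), receiving gain label in dB.
#' @slot meta list of provenance entries (seed, receiver parameters,
#'   clip information, compensation log, ...).
#' @export
setClass("KSpaceAcquisition",
  representation(data = "matrix", gainDb = "numeric", meta = "list"),
  prototype(data = matrix(complex(real = 0), 12, 12), gainDb = 0,
            meta = list()))

setValidity("KSpaceAcquisition", function(object) {
  d <- object@data
  if (!is.matrix(d) || !is.complex(d))
    return("data must be a complex matrix")
  if (nrow(d) < 12L || nrow(d) %% 4L != 0L)
    return("number of phase-encoding lines must be >= 12 and divisible by 4")
  if (anyNA(d) || any(!is.finite(Re(d))) || any(!is.finite(Im(d))))
    return("data contains NA/NaN/Inf")
  if (length(object@gainDb) != 1L || !is.finite(object@gainDb))
    return("gainDb must be a finite scalar")
  TRUE
})

#' Construct a KSpaceAcquisition
#'
#' @param data numeric or complex matrix (numeric input is promoted to
#'   complex with zero imaginary part).
#' @param gainDb receiving gain label in dB.
#' @param meta optional list of provenance metadata.
#' @return a [KSpaceAcquisition-class] object.
#' @examples
#' acq <- KSpaceAcquisition(matrix(1 + 0i, 12, 8), gainDb = 0)
#' dim(acq)
#' @export
KSpaceAcquisition <- function(data, gainDb, meta = list()) {
  if (is.matrix(data) && is.numeric(data)) storage.mode(data) <- "complex"
  new("KSpaceAcquisition", data = data, gainDb = as.numeric(gainDb),
      meta = meta)
}

#' RegionPartition: the three phase-encoding-line regions
#'
#' Partitions the lines `1..M` into an outer region (`region1`, a leading
#' and a trailing block symmetric about the center), an intermediate
#' region (`region2`, likewise two symmetric blocks) and a single
#' contiguous central region (`region3`). Under a common gain the mean
#' echo amplitude obeys region3 > region2 > region1, which is why each
#' region is sourced from a different gain when splicing.
#'
#' @slot region1,region2,region3 integer vectors of line indices (sorted).
#' @slot M integer(1), total line count.
#' @seealso [defaultPartition()]
#' @export
setClass("RegionPartition",
  representation(region1 = "integer", region2 = "integer",
                 region3 = "integer", M = "integer"))

setValidity("RegionPartition", function(object) {
  r1 <- object@region1; r2 <- object@region2; r3 <- object@region3
  M <- object@M
  all3 <- c(r1, r2, r3)
  if (anyDuplicated(all3) || !setequal(all3, seq_len(M)))
    return("regions must be pairwise disjoint and cover 1..M exactly")
  if (length(r3) == 0L || any(diff(sort(r3)) != 1L))
    return("region3 must be a non-empty contiguous central block")
  for (nm in c("region1", "region2")) {
    r <- sort(slot(object, nm))
    if (length(r) == 0L) return(paste0(nm, " must be non-empty"))
    if (length(consecutiveRuns(r)) != 2L)
      return(paste0(nm, " must consist of a leading and a trailing block"))
    if (!setequal(r, M + 1L - r))
      return(paste0(nm, " must be symmetric about the center"))
  }
  TRUE
})

#' GainFactors: estimated gain-difference factors between acquisitions
#'
#' Per-line-group amplitude ratios between the high- and mid-gain
#' acquisitions (dG1, estimated over regions 2-3) and between the mid-
#' and low-gain acquisitions (dG2, region 3 only), their unweighted
#' average, and the chained factor avg[dG1 * dG2] over region-3 groups
#' used to normalize the central region.
#'
#' @slot dg1Labels,dg2Labels integer group labels (multiples of 4, the
#'   phase-encoding line number `ceil(m/4)*4` of each group of 4 lines).
#' @slot dg1PerGroup,dg2PerGroup numeric per-group ratios, aligned with
#'   the label slots.
#' @slot dg1Avg numeric(1), average of `dg1PerGroup`.
#' @slot chainedAvg numeric(1), average of `dg1 * dg2` over the common
#'   region-3 group labels.
#' @slot N integer(1), middle-sample count per line used in estimation.
#' @export
setClass("GainFactors",
  representation(dg1Labels = "integer", dg1PerGroup = "numeric",
                 dg2Labels = "integer", dg2PerGroup = "numeric",
                 dg1Avg = "numeric", chainedAvg = "numeric",
                 N = "integer"))

setValidity("GainFactors", function(object) {
  if (length(object@dg1PerGroup) != length(object@dg1Labels))
    return("dg1PerGroup must align with dg1Labels")
  if (length(object@dg2PerGroup) != length(object@dg2Labels))
    return("dg2PerGroup must align with dg2Labels")
  f <- c(object@dg1PerGroup, object@dg2PerGroup, object@dg1Avg,
         object@chainedAvg)
  if (any(!is.finite(f)) || any(f <= 0))
    return("all gain factors must be finite and > 0")
  TRUE
})

#' PhaseDiffMap: per-sample phase differences between two acquisitions
#'
#' Matrix of phase differences `gamma[i, j] = arg(A) - arg(B)` in degrees,
#' wrapped to (-180, 180], over the middle `N` frequency-encoding columns
#' of the listed lines, together with a circular summary (mean direction
#' and circular SD) over the noise-robust central summary window.
#' Entries where either sample has zero magnitude are `NA` and excluded
#' from summaries.
#'
#' @slot gamma numeric matrix `|lines| x N` of wrapped differences (deg).
#' @slot lines integer line indices (rows of `gamma`).
#' @slot N integer(1), middle-column count.
#' @slot summaryLines integer, lines over which the central summary was
#'   computed.
#' @slot centralOffsetDeg numeric(1), circular mean over the window.
#' @slot centralDispersionDeg numeric(1), circular SD over the window.
#' @slot nExcluded integer(1), excluded (zero-magnitude) entries in the
#'   summary window.
#' @export
setClass("PhaseDiffMap",
  representation(gamma = "matrix", lines = "integer", N = "integer",
                 summaryLines = "integer", centralOffsetDeg = "numeric",
                 centralDispersionDeg = "numeric", nExcluded = "integer"))

setValidity("PhaseDiffMap", function(object) {
  g <- object@gamma
  if (nrow(g) != length(object@lines) || ncol(g) != object@N)
    return("gamma must be |lines| x N")
  gg <- g[is.finite(g)]
  if (length(gg) && (any(gg <= -180) || any(gg > 180)))
    return("gamma entries must lie in (-180, 180]")
  TRUE
})

#' SNRReport: ROI/corner SNR measurement of a magnitude image
#'
#' SNR = SI/SD where SI is the mean intensity over the bright region of
#' interest and SD is the average of the standard deviations of four
#' corner background rectangles.
#'
#' @slot si numeric(1), mean ROI intensity.
#' @slot sdCorners numeric(4), per-corner standard deviations.
#' @slot sd numeric(1), their mean.
#' @slot snr numeric(1), `si / sd`.
#' @slot roiBounds integer(4) `c(row1, row2, col1, col2)`, 1-based
#'   inclusive.
#' @slot cornerBounds list of four integer(4) rectangles, same layout.
#' @slot boostPct numeric(1), percent improvement vs a baseline
#'   (`NA` when not compared).
#' @export
setClass("SNRReport",
  representation(si = "numeric", sdCorners = "numeric", sd = "numeric",
                 snr = "numeric", roiBounds = "integer",
                 cornerBounds = "list", boostPct = "numeric"),
  prototype(boostPct = NA_real_))

setValidity("SNRReport", function(object) {
  if (!(object@sd > 0)) return("sd must be > 0")
  if (abs(object@snr - object@si / object@sd) > 1e-12 * max(1, object@snr))
    return("snr must equal si/sd")
  if (length(object@roiBounds) != 4L || length(object@cornerBounds) != 4L)
    return("roiBounds must be integer(4), cornerBounds a list of 4")
  roi <- object@roiBounds
  for (cb in object@cornerBounds) {
    if (max(roi[1], cb[1]) <= min(roi[2], cb[2]) &&
        max(roi[3], cb[3]) <= min(roi[4], cb[4]))
      return("corner rectangles must be disjoint from the ROI")
  }
  TRUE
})

#' SpliceResult: spliced k-space plus its audit trail
#'
#' @slot kspace [KSpaceAcquisition-class], the spliced k-space labeled at
#'   the reference (highest) gain.
#' @slot factors [GainFactors-class] used for amplitude normalization.
#' @slot phaseOffsetsDeg numeric(2) named `region2`/`region3`, the phase
#'   compensation applied to each region (0 in the default regime).
#' @slot partition [RegionPartition-class] used.
#' @slot phaseReport list with the two phase-difference summaries.
#' @export
setClass("SpliceResult",
  representation(kspace = "KSpaceAcquisition", factors = "GainFactors",
                 phaseOffsetsDeg = "numeric", partition = "RegionPartition",
                 phaseReport = "list"))

#' PhantomSpec: geometry of the homogeneous spherical phantom
#'
#' Describes the simulated imaging sample: a homogeneous disk (the
#' central slice of a spherical water phantom) of constant intensity with
#' a smooth rim, on an `M x K` image grid matching the scan matrix.
#'
#' @slot M,K integer scan-matrix dimensions (lines x frequency steps).
#' @slot radiusFrac numeric(1) in (0, 1), sphere radius as a fraction of
#'   `min(M, K)/2`.
#' @slot intensity numeric(1) > 0, phantom brightness (arbitrary units).
#' @slot edgeSoftness numeric(1) >= 0, pixels of smooth roll-off at the rim.
#' @export
setClass("PhantomSpec",
  representation(M = "integer", K = "integer", radiusFrac = "numeric",
                 intensity = "numeric", edgeSoftness = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (object@M < 1L || object@K < 1L || object@M %% 4L != 0L)
    return("M, K must be positive and M divisible by 4")
  if (!(object@radiusFrac > 0 && object@radiusFrac < 1))
    return("radiusFrac must be in (0, 1)")
  if (!(object@intensity > 0)) return("intensity must be > 0")
  if (object@edgeSoftness < 0) return("edgeSoftness must be >= 0")
  TRUE
})

#' @rdname PhantomSpec-class
#' @param M,K scan-matrix dimensions.
#' @param radiusFrac sphere radius as fraction of `min(M, K)/2`.
#' @param intensity phantom brightness.
#' @param edgeSoftness rim roll-off width in pixels.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(M = 220L, K = 440L, radiusFrac = 0.5,
                        intensity = 100, edgeSoftness = 2) {
  new("PhantomSpec", M = as.integer(M), K = as.integer(K),
      radiusFrac = radiusFrac, intensity = intensity,
      edgeSoftness = edgeSoftness)
}

#' ReceiverModel: the simulated MR receiver chain
#'
#' Parameters of one acquisition through the receiver: thermal noise
#' added before the gain stage (coil/body noise, input-referred), the
#' gain itself with an optional global phase rotation (the programmable
#' attenuator may shift phase between scans), receiver-chain noise added
#' after the gain, and a uniform mid-rise ADC quantizer with clipping
#' applied independently to the real and imaginary channels.
#'
#' @slot gainDb numeric(1), receiving gain in dB.
#' @slot preNoiseSigma,postNoiseSigma numeric(1) >= 0, per-component SD
#'   of circular complex Gaussian noise before/after the gain stage.
#' @slot adcBits integer(1), quantizer bit depth per real channel;
#'   0 disables quantization, otherwise 4..32.
#' @slot fullScale numeric(1) > 0, quantizer saturation amplitude.
#' @slot phaseOffsetDeg numeric(1), global phase rotation of this
#'   acquisition in degrees.
#' @export
setClass("ReceiverModel",
  representation(gainDb = "numeric", preNoiseSigma = "numeric",
                 postNoiseSigma = "numeric", adcBits = "integer",
                 fullScale = "numeric", phaseOffsetDeg = "numeric"))

setValidity("ReceiverModel", function(object) {
  if (!is.finite(object@gainDb)) return("gainDb must be finite")
  if (object@preNoiseSigma < 0 || object@postNoiseSigma < 0)
    return("noise sigmas must be >= 0")
  b <- object@adcBits
  if (!(b == 0L || (b >= 4L && b <= 32L)))
    return("adcBits must be 0 (disabled) or in 4..32")
  if (!(object@fullScale > 0)) return("fullScale must be > 0")
  if (!is.finite(object@phaseOffsetDeg))
    return("phaseOffsetDeg must be finite")
  TRUE
})

#' @rdname ReceiverModel-class
#' @param gainDb receiving gain in dB.
#' @param preNoiseSigma,postNoiseSigma per-component noise SDs.
#' @param adcBits ADC bit depth (0 disables quantization).
#' @param fullScale ADC saturation amplitude.
#' @param phaseOffsetDeg global phase rotation in degrees.
#' @return a [ReceiverModel-class] object.
#' @export
receiverModel <- function(gainDb = 0, preNoiseSigma = 0, postNoiseSigma = 0,
                          adcBits = 0L, fullScale = 1, phaseOffsetDeg = 0) {
  new("ReceiverModel", gainDb = as.numeric(gainDb),
      preNoiseSigma = preNoiseSigma, postNoiseSigma = postNoiseSigma,
      adcBits = as.integer(adcBits), fullScale = fullScale,
      phaseOffsetDeg = phaseOffsetDeg)
}
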