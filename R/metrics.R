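## Image reconstruction and the SI/SD SNR metric.

#' Reconstruct the magnitude image from a k-space acquisition
#'
#' Magnitude of the centered 2-D inverse DFT: the stored k-space is
#' centered (DC at the matrix center), so it is reordered to the
#' wrap-around layout the DFT expects, inverse-transformed and
#' normalized by `1/(M*K)` (the forward simulator uses the unnormalized
#' transform, so `reconstructImage(acquire(img, identity rx))`
#' reproduces `img`).
#'
#' @param acq a [KSpaceAcquisition-class].
#' @return numeric `M x K` magnitude image.
#' @export
reconstructImage <- function(acq) {
  stopifnot(is(acq, "KSpaceAcquisition"))
  d <- acq@data
  Mod(stats::fft(ifftshift2(d), inverse = TRUE)) / length(d)
}

cornerRects <- function(M, K, cornerFrac) {
  h <- max(2L, as.integer(round(cornerFrac * M)))
  w <- max(2L, as.integer(round(cornerFrac * K)))
  list(c(1L, h, 1L, w),
       c(1L, h, K - w + 1L, K),
       c(M - h + 1L, M, 1L, w),
       c(M - h + 1L, M, K - w + 1L, K))
}

rectValues <- function(image, b) image[b[1]:b[2], b[3]:b[4]]

#' Measure the SI/SD signal-to-noise ratio of a magnitude image
#'
#' SI is the mean intensity over a square region of interest placed on
#' the brightest area of the image (the maximum of a boxcar-smoothed
#' copy, so a single noisy pixel cannot steer it; side `roiSize`,
#' default `M/10`); the background is four corner rectangles of
#' `cornerFrac * M` by `cornerFrac * K` pixels whose standard deviations
#' (unbiased, n-1) are averaged into SD; SNR = SI/SD. Passing `bounds`
#' (an existing [SNRReport-class] or a list with `roiBounds` and
#' `cornerBounds`) reuses that geometry, which is how paired
#' spliced-vs-baseline comparisons keep the boost a pure k-space effect.
#'
#' @param image nonnegative numeric matrix.
#' @param roiSize ROI side in pixels, or `NULL` for `round(M/10)`.
#' @param cornerFrac corner size as a fraction of each dimension, in
#'   (0, 0.25] (default 0.1).
#' @param bounds optional geometry to reuse (see above).
#' @param smooth boxcar width for ROI placement (default 5).
#' @return an [SNRReport-class].
#' @export
measureSNR <- function(image, roiSize = NULL, cornerFrac = 0.1,
                       bounds = NULL, smooth = 5L) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(image < 0)) stop("image must be nonnegative")
  M <- nrow(image); K <- ncol(image)
  if (!is.null(bounds)) {
    if (is(bounds, "SNRReport")) {
      roi <- bounds@roiBounds; corners <- bounds@cornerBounds
    } else {
      roi <- as.integer(bounds$roiBounds); corners <- bounds$cornerBounds
    }
  } else {
    if (!(cornerFrac > 0 && cornerFrac <= 0.25))
      stop("cornerFrac must be in (0, 0.25]")
    if (is.null(roiSize)) roiSize <- max(4L, as.integer(round(M / 10)))
    roiSize <- as.integer(roiSize)
    sm <- boxcarSmooth(image, smooth)
    pk <- arrayInd(which.max(sm), dim(sm))
    h1 <- (roiSize - 1L) %/% 2L; h2 <- roiSize - 1L - h1
    r1 <- min(max(pk[1] - h1, 1L), M - roiSize + 1L)
    c1 <- min(max(pk[2] - h1, 1L), K - roiSize + 1L)
    roi <- c(r1, r1 + roiSize - 1L, c1, c1 + roiSize - 1L)
    corners <- cornerRects(M, K, cornerFrac)
  }
  si <- mean(rectValues(image, roi))
  sdCorners <- vapply(corners, function(b) stats::sd(rectValues(image, b)),
                      numeric(1))
  if (any(sdCorners == 0))
    stop("degenerate background: a corner has zero standard deviation, ",
         "SNR is undefined for a noiseless image")
  sdAvg <- mean(sdCorners)
  new("SNRReport", si = si, sdCorners = sdCorners, sd = sdAvg,
      snr = si / sdAvg, roiBounds = as.integer(roi),
      cornerBounds = lapply(corners, as.integer), boostPct = NA_real_)
}

#' Percent SNR improvement of one report over a baseline
#'
#' `100 * (snr_test - snr_baseline) / snr_baseline`. The two reports
#' must share identical ROI and corner bounds (measure the test image
#' with `bounds = baselineReport`), so the comparison is paired.
#'
#' @param test,baseline [SNRReport-class] objects with identical bounds.
#' @return the boost in percent.
#' @examples
#' # arithmetic: 100 * (21.4548 - 19.4104) / 19.4104 = 10.53\%
#' @export
snrBoost <- function(test, baseline) {
  stopifnot(is(test, "SNRReport"), is(baseline, "SNRReport"))
  if (!identical(test@roiBounds, baseline@roiBounds) ||
      !identical(test@cornerBounds, baseline@cornerBounds))
    stop("mismatched ROI/corner bounds: measure the test image with ",
         "bounds = baseline for a paired comparison")
  100 * (test@snr - baseline@snr) / baseline@snr
}
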