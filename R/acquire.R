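## Simulated acquisition: centered 2-D DFT of the image through the
## receiver chain (pre-gain noise, gain + phase, post-gain noise, ADC).

## Uniform mid-rise quantizer with clipping, applied to a real vector.
## 2^bits levels span [-fullScale, fullScale], step = 2*fullScale/2^bits;
## outputs are the level midpoints, saturating at +/-(fullScale - step/2).
quantizeReal <- function(x, bits, fullScale) {
  L <- 2^bits
  step <- 2 * fullScale / L
  code <- floor(x / step)
  clipped <- code > (L / 2 - 1) | code < (-L / 2)
  code <- pmin(pmax(code, -L / 2), L / 2 - 1)
  list(q = (code + 0.5) * step, clipped = clipped)
}

#' Simulate one k-space acquisition through the receiver chain
#'
#' Deterministically maps an image, a receiver model and a seed to a
#' k-space acquisition: the centered 2-D DFT of the image (unnormalized
#' forward transform) receives circular complex Gaussian pre-gain noise,
#' is scaled by `10^(gainDb/20)` and rotated by the receiver's global
#' phase offset, receives post-gain noise, and is finally quantized per
#' real channel by a uniform mid-rise ADC with clipping
#' (`adcBits = 0` skips quantization). The same image, receiver and seed
#' always produce an identical acquisition; the caller's RNG state is
#' left untouched.
#'
#' Lines containing at least one clipped sample are recorded in
#' `meta$clipLines` and are honored downstream: [spliceKSpace()] refuses
#' clipping inside a used region and excludes clipped lines from gain and
#' phase estimation.
#'
#' @param image finite numeric `M x K` matrix (`M` divisible by 4).
#' @param rx a [ReceiverModel-class].
#' @param seed integer seed for the noise draws.
#' @return a [KSpaceAcquisition-class] with the receiver parameters,
#'   seed and clip information in `meta`.
#' @examples
#' img <- makePhantom(phantomSpec(M = 32, K = 32))
#' acq <- acquire(img, receiverModel(gainDb = 6), seed = 1)
#' @export
acquire <- function(image, rx, seed) {
  stopifnot(is.matrix(image), is.numeric(image), is(rx, "ReceiverModel"))
  if (any(!is.finite(image))) stop("image must be finite")
  validObject(rx)
  if (missing(seed) || length(seed) != 1L || !is.finite(seed))
    stop("an explicit scalar seed is required")
  M <- nrow(image); K <- ncol(image)
  withSeed(seed, {
    S <- fftshift2(stats::fft(image))
    if (rx@preNoiseSigma > 0)
      S <- S + matrix(complexNoise(M * K, rx@preNoiseSigma), M, K)
    S <- S * dbToLinear(rx@gainDb) * exp(1i * rx@phaseOffsetDeg * pi / 180)
    if (rx@postNoiseSigma > 0)
      S <- S + matrix(complexNoise(M * K, rx@postNoiseSigma), M, K)
    clipLines <- integer(0)
    nClipped <- 0L
    if (rx@adcBits > 0L) {
      qr <- quantizeReal(Re(S), rx@adcBits, rx@fullScale)
      qi <- quantizeReal(Im(S), rx@adcBits, rx@fullScale)
      S <- matrix(complex(real = qr$q, imaginary = qi$q), M, K)
      clipped <- matrix(qr$clipped | qi$clipped, M, K)
      nClipped <- sum(clipped)
      clipLines <- which(rowSums(clipped) > 0L)
    }
    KSpaceAcquisition(S, gainDb = rx@gainDb, meta = list(
      seed = as.integer(seed),
      receiver = list(gainDb = rx@gainDb, preNoiseSigma = rx@preNoiseSigma,
                      postNoiseSigma = rx@postNoiseSigma,
                      adcBits = rx@adcBits, fullScale = rx@fullScale,
                      phaseOffsetDeg = rx@phaseOffsetDeg),
      clipLines = as.integer(clipLines), nClipped = as.integer(nClipped)))
  })
}

#' Simulate the three-gain study
#'
#' Scans the same phantom three times through an identical receiver
#' except for the gain (descending, 6 dB steps by default) and, when
#' requested, a per-acquisition global phase offset; each scan uses its
#' own seed, i.e. an independent noise realization, as three separate
#' sequence scans would. The highest gain may clip central lines --
#' expected and permitted, since splicing only uses the non-clipping
#' region of each acquisition.
#'
#' @param spec a [PhantomSpec-class].
#' @param baseRx a [ReceiverModel-class]; its `gainDb` and
#'   `phaseOffsetDeg` are overridden per acquisition.
#' @param gainsDb numeric(3), strictly descending gains in dB.
#' @param seeds integer(3), distinct seeds.
#' @param phaseOffsetsDeg numeric(3), per-acquisition phase offsets.
#' @return list of three [KSpaceAcquisition-class] objects named
#'   `hi`, `mid`, `lo`.
#' @export
simulateStudy <- function(spec, baseRx, gainsDb = c(12, 6, 0),
                          seeds = c(101L, 102L, 103L),
                          phaseOffsetsDeg = c(0, 0, 0)) {
  stopifnot(is(spec, "PhantomSpec"), is(baseRx, "ReceiverModel"))
  if (length(gainsDb) != 3L || length(seeds) != 3L)
    stop("exactly three gains and three seeds are required")
  if (any(diff(gainsDb) >= 0))
    stop("gains must be strictly descending")
  if (anyDuplicated(seeds))
    stop("the three scans need distinct seeds (independent noise)")
  if (length(phaseOffsetsDeg) != 3L)
    stop("phaseOffsetsDeg must have length 3")
  img <- makePhantom(spec)
  acqs <- lapply(1:3, function(i) {
    rx <- baseRx
    rx@gainDb <- as.numeric(gainsDb[i])
    rx@phaseOffsetDeg <- as.numeric(phaseOffsetsDeg[i])
    acquire(img, rx, seeds[i])
  })
  names(acqs) <- c("hi", "mid", "lo")
  acqs
}
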