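## Small numeric helpers shared across the package.

#' Convert a gain difference in dB to a linear amplitude ratio
#'
#' A receiver-gain step of `db` decibels multiplies signal amplitude by
#' `10^(db/20)`; a 6 dB step is an amplitude ratio of approximately 2, a
#' 12 dB step approximately 4.
#'
#' @param db numeric vector of gains in dB.
#' @return numeric vector of linear amplitude ratios.
#' @examples
#' dbToLinear(6)   # ~2
#' dbToLinear(12)  # ~4
#' @export
dbToLinear <- function(db) {
  stopifnot(is.numeric(db), all(is.finite(db)))
  10^(db / 20)
}

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles congruent to `x` modulo 360, in (-180, 180].
#' @examples
#' wrapDegrees(c(190, -180, 170 + 20))
#' @export
wrapDegrees <- function(x) {
  w <- x %% 360
  w - 360 * (w > 180)
}

## circular mean direction of angles given in degrees; NA entries dropped
circularMeanDeg <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

## circular standard deviation (degrees), sqrt(-2 log Rbar)
circularSdDeg <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(max(rbar, 1e-12), 1)
  sqrt(-2 * log(rbar)) * 180 / pi
}

## index permutation for a circular shift by `s` (y[i] = x[((i-1-s) mod n)+1])
rollIndex <- function(n, s) {
  ((seq_len(n) - 1L - s) %% n) + 1L
}

## Move DC (element [1,1] of an unshifted DFT) to the matrix center,
## and back. For even dimensions the two are identical; both are kept so
## odd-sized test matrices behave correctly.
fftshift2 <- function(x) {
  x[rollIndex(nrow(x), nrow(x) %/% 2L),
    rollIndex(ncol(x), ncol(x) %/% 2L), drop = FALSE]
}

ifftshift2 <- function(x) {
  x[rollIndex(nrow(x), -(nrow(x) %/% 2L)),
    rollIndex(ncol(x), -(ncol(x) %/% 2L)), drop = FALSE]
}

## running mean along a vector with window w (partial windows at the edges)
runMean <- function(v, w) {
  n <- length(v)
  h <- w %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(0L, seq_len(n) - h - 1L)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

## separable boxcar smoothing of a matrix (used to place the ROI robustly)
boxcarSmooth <- function(x, w = 5L) {
  y <- apply(x, 2L, runMean, w = w)
  t(apply(y, 1L, runMean, w = w))
}

## split a sorted integer vector into maximal runs of consecutive values
consecutiveRuns <- function(x) {
  if (length(x) == 0L) return(list())
  br <- c(0L, which(diff(x) != 1L), length(x))
  lapply(seq_len(length(br) - 1L), function(i) x[(br[i] + 1L):br[i + 1L]])
}

## draw an n-vector of circular complex Gaussian noise, sigma per component
complexNoise <- function(n, sigma) {
  complex(real = rnorm(n, sd = sigma), imaginary = rnorm(n, sd = sigma))
}

## run `expr` under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
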