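#' Render the homogeneous spherical phantom image
#'
#' Produces the `M x K` nonnegative image of a homogeneous disk (the
#' central slice of a spherical water phantom): constant `intensity`
#' strictly inside the sphere, 0 outside, with a raised-cosine roll-off
#' of width `edgeSoftness` pixels at the rim. The radius is
#' `radiusFrac * min(M, K) / 2` pixels, measured from the pixel at
#' `(floor(M/2)+1, floor(K/2)+1)` so that the phantom is centered
#' consistently with the centered k-space convention.
#'
#' @param spec a [PhantomSpec-class].
#' @return numeric `M x K` matrix.
#' @examples
#' img <- makePhantom(phantomSpec(M = 64, K = 64))
#' range(img)
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  M <- spec@M; K <- spec@K
  r <- spec@radiusFrac * min(M, K) / 2
  s <- spec@edgeSoftness
  cr <- M %/% 2L + 1L; cc <- K %/% 2L + 1L
  dy <- (seq_len(M) - cr)^2
  dx <- (seq_len(K) - cc)^2
  d <- sqrt(outer(dy, dx, `+`))
  img <- matrix(0, M, K)
  if (s == 0) {
    img[d <= r] <- spec@intensity
  } else {
    img[d <= r - s] <- spec@intensity
    rim <- d > r - s & d <= r
    img[rim] <- spec@intensity * 0.5 * (1 + cos(pi * (d[rim] - (r - s)) / s))
  }
  img
}
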