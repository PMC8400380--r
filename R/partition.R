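#' Default three-region partition of the phase-encoding lines
#'
#' For a 220-line k-space the regions are the ones used throughout the
#' method: region1 = lines 1-36 and 185-220 (outer), region2 = 37-72 and
#' 149-184 (intermediate), region3 = 73-148 (central). For other `M` the
#' same proportions are scaled (each outer side-block is 36/220 of the
#' lines, each intermediate side-block another 36/220, the central block
#' the remainder), with boundaries rounded to integers so that the
#' partition invariants (disjoint, covering, symmetric, central block
#' contiguous) hold.
#'
#' @param M total number of phase-encoding lines; must be `>= 12` and
#'   divisible by 4.
#' @return a [RegionPartition-class].
#' @examples
#' defaultPartition(220)
#' defaultPartition(20)
#' @export
defaultPartition <- function(M) {
  M <- as.integer(M)
  if (length(M) != 1L || is.na(M) || M < 12L || M %% 4L != 0L)
    stop("M must be a single integer >= 12 and divisible by 4")
  b <- as.integer(round(M * 36 / 220))   # side-block size for regions 1, 2
  b <- max(b, 1L)
  if (4L * b >= M) b <- (M - 4L) %/% 4L  # keep region3 non-empty
  r1 <- c(seq_len(b), seq.int(M - b + 1L, M))
  r2 <- c(seq.int(b + 1L, 2L * b), seq.int(M - 2L * b + 1L, M - b))
  r3 <- seq.int(2L * b + 1L, M - 2L * b)
  new("RegionPartition", region1 = as.integer(r1), region2 = as.integer(r2),
      region3 = as.integer(r3), M = M)
}
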