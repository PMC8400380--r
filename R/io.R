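## On-disk format: a flat binary file `<base>.cplx` of interleaved
## real/imag samples in row-major (line-by-line) order, plus a JSON
## sidecar `<base>.json` holding M, K, gain_db, the storage dtype and the
## free-form meta map. dtype "float64" (default) round-trips double data
## exactly; "float32" is the compact interoperability dialect.

basePath <- function(path) sub("\\.(cplx|json)$", "", path)

#' Write a k-space acquisition to disk
#'
#' Writes `<base>.cplx` (row-major interleaved real/imag binary) and a
#' `<base>.json` sidecar with the shape, the `gain_db` label, the storage
#' dtype and the metadata map. `readKSpace()` on the result reproduces
#' the acquisition exactly when `dtype = "float64"`.
#'
#' @param acq a [KSpaceAcquisition-class].
#' @param path output path; a trailing `.cplx` or `.json` is stripped to
#'   form the base name.
#' @param overwrite logical; error if the files exist and this is `FALSE`.
#' @param dtype `"float64"` (exact) or `"float32"` (compact, lossy for
#'   double-precision data).
#' @return the base path, invisibly.
#' @seealso [readKSpace()]
#' @export
writeKSpace <- function(acq, path, overwrite = FALSE, dtype = c("float64",
                        "float32")) {
  stopifnot(is(acq, "KSpaceAcquisition"))
  validObject(acq)
  dtype <- match.arg(dtype)
  base <- basePath(path)
  bin <- paste0(base, ".cplx"); side <- paste0(base, ".json")
  if (!overwrite && (file.exists(bin) || file.exists(side)))
    stop("output exists (", bin, "); use overwrite = TRUE")
  d <- acq@data
  ## row-major sample order, real/imag interleaved
  v <- rbind(as.vector(Re(t(d))), as.vector(Im(t(d))))
  size <- if (dtype == "float32") 4L else 8L
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(v), con, size = size, endian = "little")
  sidecar <- list(M = nrow(d), K = ncol(d), gain_db = acq@gainDb,
                  dtype = dtype, meta = acq@meta)
  ## digits = I(17): doubles (gain_db, receiver parameters) must survive
  ## the sidecar bit-for-bit
  jsonlite::write_json(sidecar, side, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(base)
}

#' Read a k-space acquisition from disk
#'
#' Reads the `<base>.cplx` + `<base>.json` pair written by
#' [writeKSpace()]. Errors if the sidecar lacks the `gain_db` attribute
#' or if the stored shape does not describe a 2-D matrix.
#'
#' @param path base path or path to either file of the pair.
#' @return a [KSpaceAcquisition-class].
#' @export
readKSpace <- function(path) {
  base <- basePath(path)
  bin <- paste0(base, ".cplx"); side <- paste0(base, ".json")
  if (!file.exists(bin) || !file.exists(side))
    stop("missing k-space file pair: ", base, ".{cplx,json}")
  sc <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(sc$gain_db))
    stop("metadata error: sidecar lacks required 'gain_db' attribute")
  if (is.null(sc$M) || is.null(sc$K) || length(sc$M) != 1L ||
      length(sc$K) != 1L)
    stop("shape error: sidecar must describe a 2-D matrix via scalar M, K")
  if (!is.null(sc$ndim) && sc$ndim != 2L)
    stop("shape error: only 2-D k-space matrices are supported")
  M <- as.integer(sc$M); K <- as.integer(sc$K)
  dtype <- if (is.null(sc$dtype)) "float32" else sc$dtype
  size <- if (dtype == "float32") 4L else 8L
  n <- 2L * M * K
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "numeric", n = n + 1L, size = size, endian = "little")
  if (length(v) != n)
    stop("shape error: file holds ", length(v), " values, expected ", n)
  z <- complex(real = v[seq(1L, n, by = 2L)],
               imaginary = v[seq(2L, n, by = 2L)])
  meta <- if (is.null(sc$meta)) list() else as.list(sc$meta)
  KSpaceAcquisition(matrix(z, nrow = M, ncol = K, byrow = TRUE),
                    gainDb = as.numeric(sc$gain_db), meta = meta)
}
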