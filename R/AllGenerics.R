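## Accessors and show methods.

#' @describeIn KSpaceAcquisition-class the complex k-space matrix.
#' @param acq,object a `KSpaceAcquisition`.
#' @export
kspaceData <- function(acq) {
  stopifnot(is(acq, "KSpaceAcquisition"))
  acq@data
}

#' Receiving gain of an acquisition
#'
#' @param object a [KSpaceAcquisition-class].
#' @return the gain label in dB.
#' @export
setGeneric("gainDb", function(object) standardGeneric("gainDb"))

#' @rdname gainDb
#' @export
setMethod("gainDb", "KSpaceAcquisition", function(object) object@gainDb)

#' Provenance metadata of an acquisition
#'
#' @param object a [KSpaceAcquisition-class].
#' @return the metadata list.
#' @export
setGeneric("acqMeta", function(object) standardGeneric("acqMeta"))

#' @rdname acqMeta
#' @export
setMethod("acqMeta", "KSpaceAcquisition", function(object) object@meta)

#' @describeIn KSpaceAcquisition-class matrix dimensions
#'   (lines, frequency-encoding steps).
#' @export
setMethod("dim", "KSpaceAcquisition", function(x) dim(x@data))

setMethod("show", "KSpaceAcquisition", function(object) {
  d <- dim(object@data)
  cat("KSpaceAcquisition:", d[1], "phase-encoding lines x", d[2],
      "frequency-encoding steps\n")
  cat("  gain:", object@gainDb, "dB\n")
  cl <- object@meta$clipLines
  if (!is.null(cl) && length(cl))
    cat("  clipped lines:", length(cl),
        paste0("(", cl[1], "..", cl[length(cl)], ")"), "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

#' Line indices of one region of a partition
#'
#' @param partition a [RegionPartition-class].
#' @param which region number 1 (outer), 2 (intermediate) or 3 (central).
#' @return sorted integer vector of line indices.
#' @examples
#' regionLines(defaultPartition(220), 3)
#' @export
regionLines <- function(partition, which) {
  stopifnot(is(partition, "RegionPartition"), which %in% 1:3)
  sort(slot(partition, paste0("region", which)))
}

setMethod("show", "RegionPartition", function(object) {
  fmt <- function(r) {
    runs <- consecutiveRuns(sort(r))
    paste(vapply(runs, function(x) paste0(x[1], "-", x[length(x)]),
                 character(1)), collapse = ", ")
  }
  cat("RegionPartition of", object@M, "phase-encoding lines\n")
  cat("  region1 (outer):       ", fmt(object@region1), "\n")
  cat("  region2 (intermediate):", fmt(object@region2), "\n")
  cat("  region3 (central):     ", fmt(object@region3), "\n")
})

#' Average gain-difference factors
#'
#' @param object a [GainFactors-class].
#' @return `dg1Average`: avg[dG1], the tau vs tau-6 dB factor;
#'   `chainedAverage`: avg[dG1*dG2], the tau vs tau-12 dB factor.
#' @export
setGeneric("dg1Average", function(object) standardGeneric("dg1Average"))

#' @rdname dg1Average
#' @export
setMethod("dg1Average", "GainFactors", function(object) object@dg1Avg)

#' @rdname dg1Average
#' @export
setGeneric("chainedAverage",
           function(object) standardGeneric("chainedAverage"))

#' @rdname dg1Average
#' @export
setMethod("chainedAverage", "GainFactors", function(object)
  object@chainedAvg)

setMethod("show", "GainFactors", function(object) {
  cat("GainFactors (N =", object@N, "middle samples per line)\n")
  cat("  dG1 groups:", length(object@dg1Labels),
      " avg[dG1] =", format(object@dg1Avg, digits = 6), "\n")
  cat("  dG2 groups:", length(object@dg2Labels),
      " avg[dG1*dG2] =", format(object@chainedAvg, digits = 6), "\n")
})

#' Central phase-difference summary of a PhaseDiffMap
#'
#' @param object a [PhaseDiffMap-class].
#' @return circular mean (deg) of the phase difference over the central
#'   summary window.
#' @export
setGeneric("centralOffsetDeg",
           function(object) standardGeneric("centralOffsetDeg"))

#' @rdname centralOffsetDeg
#' @export
setMethod("centralOffsetDeg", "PhaseDiffMap", function(object)
  object@centralOffsetDeg)

setMethod("show", "PhaseDiffMap", function(object) {
  cat("PhaseDiffMap:", length(object@lines), "lines x", object@N,
      "middle columns\n")
  cat("  central offset:", format(object@centralOffsetDeg, digits = 4),
      "deg, dispersion:", format(object@centralDispersionDeg, digits = 4),
      "deg (", length(object@summaryLines), "summary lines,",
      object@nExcluded, "excluded )\n")
})

#' SNR value of a report
#'
#' @param object an [SNRReport-class].
#' @return the scalar SNR (SI/SD).
#' @export
setGeneric("snrValue", function(object) standardGeneric("snrValue"))

#' @rdname snrValue
#' @export
setMethod("snrValue", "SNRReport", function(object) object@snr)

setMethod("show", "SNRReport", function(object) {
  cat("SNRReport: SI =", format(object@si, digits = 6),
      " SD =", format(object@sd, digits = 6),
      " SNR =", format(object@snr, digits = 6), "\n")
  cat("  ROI rows", object@roiBounds[1], "-", object@roiBounds[2],
      ", cols", object@roiBounds[3], "-", object@roiBounds[4], "\n")
  if (is.finite(object@boostPct))
    cat("  boost vs baseline:", format(object@boostPct, digits = 5), "%\n")
})

#' Spliced k-space of a SpliceResult
#'
#' @param object a [SpliceResult-class].
#' @return the spliced [KSpaceAcquisition-class].
#' @export
setGeneric("splicedKSpace",
           function(object) standardGeneric("splicedKSpace"))

#' @rdname splicedKSpace
#' @export
setMethod("splicedKSpace", "SpliceResult", function(object) object@kspace)

#' @rdname splicedKSpace
#' @export
setGeneric("spliceFactors",
           function(object) standardGeneric("spliceFactors"))

#' @rdname splicedKSpace
#' @export
setMethod("spliceFactors", "SpliceResult", function(object) object@factors)

setMethod("show", "SpliceResult", function(object) {
  cat("SpliceResult\n")
  cat("  spliced gain label:", object@kspace@gainDb, "dB\n")
  cat("  avg[dG1] =", format(object@factors@dg1Avg, digits = 6),
      " avg[dG1*dG2] =", format(object@factors@chainedAvg, digits = 6), "\n")
  cat("  phase offsets (deg): region2 =",
      format(object@phaseOffsetsDeg[["region2"]], digits = 4),
      ", region3 =",
      format(object@phaseOffsetsDeg[["region3"]], digits = 4), "\n")
})
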