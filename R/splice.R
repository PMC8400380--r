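## Assembly of the spliced k-space from the three acquisitions.

#' Splice three gain-stepped acquisitions into one k-space
#'
#' Executes the full correction-and-splicing chain on three same-shape
#' acquisitions with strictly descending gains:
#' \enumerate{
#'   \item estimate the per-group gain factor dG1 over regions 2-3 of
#'     the high- and mid-gain acquisitions;
#'   \item estimate dG2 over region 3 of the mid- and low-gain
#'     acquisitions;
#'   \item chain them into the per-group product averaged over the
#'     common region-3 groups;
#'   \item assemble K from region1(hi) as acquired, region2(mid)
#'     multiplied by avg[dG1], region3(lo) multiplied by avg[dG1*dG2]
#'     -- i.e. everything normalized *up* to the amplitude scale of the
#'     maximum gain;
#'   \item compute the phase-difference maps, decide the compensation
#'     values (zero below `thresholdDeg`) and rotate regions 2 and 3
#'     accordingly.
#' }
#'
#' When the simulator recorded clip lines, clipping inside a used region
#' (region1 of hi, region2 of mid, region3 of lo) is a hard error naming
#' the lines, and clipped lines are excluded from gain and phase
#' estimation; without clip information the check is advisory.
#'
#' @param acqHi,acqMid,acqLo [KSpaceAcquisition-class] objects with
#'   strictly descending `gainDb`.
#' @param partition a [RegionPartition-class]; default
#'   [defaultPartition()] for the line count.
#' @param N middle-sample count for estimation (default 120).
#' @param thresholdDeg phase-compensation threshold in degrees
#'   (default 2).
#' @param eps denominator guard for the ratio estimator.
#' @return a [SpliceResult-class]; the spliced k-space is labeled at the
#'   reference (highest) gain and its `meta$regionSources` records the
#'   source gain of every region.
#' @export
spliceKSpace <- function(acqHi, acqMid, acqLo,
                         partition = defaultPartition(nrow(
                           kspaceData(acqHi))),
                         N = 120L, thresholdDeg = 2, eps = 1e-6) {
  for (a in list(acqHi, acqMid, acqLo))
    stopifnot(is(a, "KSpaceAcquisition"))
  if (!identical(dim(acqHi@data), dim(acqMid@data)) ||
      !identical(dim(acqHi@data), dim(acqLo@data)))
    stop("the three acquisitions must have the same shape")
  gains <- c(acqHi@gainDb, acqMid@gainDb, acqLo@gainDb)
  if (any(diff(gains) >= 0))
    stop("gains must be strictly descending (got ",
         paste(gains, collapse = ", "), " dB)")
  stopifnot(is(partition, "RegionPartition"))
  validObject(partition)
  if (partition@M != nrow(acqHi@data))
    stop("partition is for ", partition@M, " lines, data has ",
         nrow(acqHi@data))
  r1 <- regionLines(partition, 1)
  r2 <- regionLines(partition, 2)
  r3 <- regionLines(partition, 3)

  ## clip safety: mandatory when the simulator recorded masks
  checkClip <- function(acq, region, which) {
    cl <- acq@meta$clipLines
    if (!is.null(cl) && length(bad <- intersect(cl, region)))
      stop("clipped samples inside used region", which, " (lines ",
           paste(bad, collapse = ", "), ")")
  }
  checkClip(acqHi, r1, 1)
  checkClip(acqMid, r2, 2)
  checkClip(acqLo, r3, 3)

  ## steps 1-3: gain-difference factors
  factors <- estimateGainFactors(acqHi, acqMid, acqLo,
                                 partition = partition, N = N, eps = eps)

  ## step 4: assemble and amplitude-compensate
  d <- acqHi@data
  d[r2, ] <- acqMid@data[r2, , drop = FALSE] * factors@dg1Avg
  d[r3, ] <- acqLo@data[r3, , drop = FALSE] * factors@chainedAvg

  ## step 5: phase maps over the estimation line sets, central summary
  mapHiMid <- phaseDiffMap(acqHi, acqMid, sort(c(r2, r3)), N = N,
                           summaryLines = r3)
  mapMidLo <- phaseDiffMap(acqMid, acqLo, r3, N = N, summaryLines = r3)
  off2 <- phaseCompensationValue(mapHiMid, thresholdDeg)
  off3 <- phaseCompensationValue(summedPhaseOffset(mapHiMid, mapMidLo),
                                 thresholdDeg)
  if (off2 != 0)
    d[r2, ] <- d[r2, , drop = FALSE] * exp(1i * off2 * pi / 180)
  if (off3 != 0)
    d[r3, ] <- d[r3, , drop = FALSE] * exp(1i * off3 * pi / 180)

  spliced <- KSpaceAcquisition(d, gainDb = acqHi@gainDb, meta = list(
    spliced = TRUE,
    regionSources = list(region1 = acqHi@gainDb, region2 = acqMid@gainDb,
                         region3 = acqLo@gainDb),
    gainCompensation = list(region2 = factors@dg1Avg,
                            region3 = factors@chainedAvg),
    phaseCompensationDeg = list(region2 = off2, region3 = off3),
    sourceSeeds = list(hi = acqHi@meta$seed, mid = acqMid@meta$seed,
                       lo = acqLo@meta$seed)))

  new("SpliceResult", kspace = spliced, factors = factors,
      phaseOffsetsDeg = c(region2 = off2, region3 = off3),
      partition = partition,
      phaseReport = list(
        hiMid = list(centralOffsetDeg = mapHiMid@centralOffsetDeg,
                     centralDispersionDeg = mapHiMid@centralDispersionDeg,
                     nExcluded = mapHiMid@nExcluded),
        midLo = list(centralOffsetDeg = mapMidLo@centralOffsetDeg,
                     centralDispersionDeg = mapMidLo@centralDispersionDeg,
                     nExcluded = mapMidLo@nExcluded)))
}

#' Write the audit trail of a splice as JSON
#'
#' Records the per-group factors and averages, the phase offsets, the
#' partition and the source gains -- everything needed to reproduce the
#' spliced k-space from the raw inputs.
#'
#' @param result a [SpliceResult-class].
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written.
#' @export
spliceAuditJson <- function(result, path = NULL) {
  stopifnot(is(result, "SpliceResult"))
  f <- result@factors
  x <- list(
    dg1_per_group = as.list(stats::setNames(f@dg1PerGroup, f@dg1Labels)),
    dg2_per_group = as.list(stats::setNames(f@dg2PerGroup, f@dg2Labels)),
    dg1_avg = f@dg1Avg, chained_avg = f@chainedAvg, N = f@N,
    phase_offsets_deg = as.list(result@phaseOffsetsDeg),
    phase_report = result@phaseReport,
    partition = list(region1 = result@partition@region1,
                     region2 = result@partition@region2,
                     region3 = result@partition@region3),
    region_sources_db = result@kspace@meta$regionSources)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
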