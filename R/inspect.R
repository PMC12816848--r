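## Per-voxel drill-down: activation profiles, histograms and atypical-subject
## flagging. Profiles reuse the exact sampling path of the consistency map so
## the two can never disagree.

#' Extract a per-subject activation profile at one location
#'
#' For a mm coordinate, returns every subject's neighbourhood-sampled masked
#' z under the same relevant-voxel and sampling settings as
#' [computeTwomMap()]; `weightedConsistency(overlapCurve(...))` on the
#' profile therefore reproduces the map value at that voxel exactly (under
#' the default per-voxel grid rule).
#'
#' @param cohort a [Cohort-class].
#' @param mm mm coordinate triple (use `voxelToMm` for voxel indices).
#' @param radiusMm sampling sphere radius (default 2).
#' @param opts a [RelevantVoxelOptions-class].
#' @param aggregate `"max"` (default) or `"mean"`.
#' @return a [VoxelProfile-class].
#' @export
voxelProfile <- function(cohort, mm, radiusMm = 2,
                         opts = relevantVoxelOptions(),
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  aff <- affineMatrix(cohort)
  vox <- mmToVoxel(mm, aff, gridShape(cohort))
  sel <- selectRelevantVoxels(cohort, opts)
  z <- vapply(seq_len(nSubjects(cohort)), function(s)
    sampleNeighborhood(cohort@maps[[s]], vox, radiusMm,
                       maskedValues = sel$maskedValues[[s]],
                       aggregate = aggregate),
    numeric(1))
  samples <- cohortLabels(cohort)
  samples$z_sampled <- z
  new("VoxelProfile", mm = as.numeric(mm), voxel = vox, radiusMm = radiusMm,
      samples = samples)
}

#' Histogram of a voxel profile
#'
#' Counts per z bin (left-closed, right-open; the last bin closed), with the
#' position of the significance marker recorded. Default bins are 0.5
#' z-units wide spanning 0 to the cohort maximum. Counts always sum to N.
#'
#' @param profile a [VoxelProfile-class].
#' @param binEdges explicit ascending bin edges, or `NULL` to build them
#'   from `binWidth`.
#' @param binWidth default bin width in z-units (0.5).
#' @param marker significance level annotated on the histogram (default 3.1).
#' @return data.frame with columns bin_lo, bin_hi, count; attributes
#'   `marker` and `countAboveMarker`.
#' @export
profileHistogram <- function(profile, binEdges = NULL, binWidth = 0.5,
                             marker = 3.1) {
  z <- profile@samples$z_sampled
  if (is.null(binEdges)) {
    top <- max(max(z), binWidth)
    binEdges <- seq(0, ceiling(top / binWidth) * binWidth, by = binWidth)
  }
  if (is.unsorted(binEdges, strictly = TRUE))
    stop("binEdges must be strictly ascending")
  if (min(z) < binEdges[1L] || max(z) > binEdges[length(binEdges)])
    stop("samples fall outside the bin edges")
  k <- findInterval(z, binEdges, rightmost.closed = TRUE)
  counts <- tabulate(k, nbins = length(binEdges) - 1L)
  out <- data.frame(bin_lo = binEdges[-length(binEdges)],
                    bin_hi = binEdges[-1L], count = counts)
  attr(out, "marker") <- marker
  attr(out, "countAboveMarker") <- sum(z >= marker)
  out
}

#' Flag subjects with atypical activation at a voxel
#'
#' Operationalises "atypical" as strong activation at a location the cohort
#' mostly does not activate to significance: subjects whose sampled z is
#' >= `minZ` are flagged only when the cohort engagement proportion at the
#' significance level `engagementTau` is at most `maxCohortFraction` —
#' common activation is never atypical. The gate threshold is deliberately a
#' separate parameter (default 3.1, the single-subject significance level)
#' so that raising `minZ` can only shrink the flagged set.
#'
#' @param profile a [VoxelProfile-class].
#' @param minZ flagging threshold (default 3.1).
#' @param maxCohortFraction engagement gate in (0, 0.5) (default 0.25).
#' @param engagementTau threshold at which the gate engagement is computed
#'   (default 3.1).
#' @return character vector of flagged subject ids (possibly empty).
#' @export
flagAtypicalSubjects <- function(profile, minZ = 3.1, maxCohortFraction = 0.25,
                                 engagementTau = 3.1) {
  if (maxCohortFraction <= 0 || maxCohortFraction >= 0.5)
    stop("maxCohortFraction must lie in (0, 0.5)")
  z <- profile@samples$z_sampled
  engagement <- mean(z >= engagementTau)
  if (engagement == 0 || engagement > maxCohortFraction) return(character(0))
  as.character(profile@samples$subject_id[z >= minZ])
}
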