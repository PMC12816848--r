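## Threshold-weighted overlap mapping: relevant-voxel selection, spherical
## neighbourhood sampling, overlap curves, weighted-AUC consistency and
## engagement maps.

#' Construct relevant-voxel selection options
#'
#' Defaults follow the method's modern variant: positive voxels (z > 0) in
#' clusters of at least 10 voxels, no minimum-subjects criterion
#' (`minSubjects = 1`) and no upper activation cap. The original variant is
#' recovered with `minSubjects = 2` and `upperZCap = 3.09` (p < 0.001);
#' `mode = "all_voxels"` searches every in-brain positive voxel without the
#' cluster-size criterion.
#'
#' @param minZ minimum statistic, exclusive (default 0).
#' @param minClusterVoxels minimum connected-component size (default 10).
#' @param minSubjects minimum number of activating subjects for a voxel to
#'   enter the analysis mask (default 1).
#' @param upperZCap winsorising cap, or `NULL` for none. Values above the cap
#'   are set to the cap rather than excluded, so extreme activators still
#'   count as activating.
#' @param mode `"relevant"` or `"all_voxels"`.
#' @param connectivity cluster connectivity, 26 (default) or 6.
#' @return a [RelevantVoxelOptions-class].
#' @export
relevantVoxelOptions <- function(minZ = 0, minClusterVoxels = 10L,
                                 minSubjects = 1L, upperZCap = NULL,
                                 mode = c("relevant", "all_voxels"),
                                 connectivity = 26L) {
  mode <- match.arg(mode)
  new("RelevantVoxelOptions", minZ = minZ,
      minClusterVoxels = as.integer(minClusterVoxels),
      minSubjects = as.integer(minSubjects),
      upperZCap = if (is.null(upperZCap)) numeric(0) else upperZCap,
      mode = mode, connectivity = as.integer(connectivity))
}

#' Select relevant voxels for overlap mapping
#'
#' Per subject, the relevant-voxel mask keeps voxels with z strictly above
#' `minZ` that belong to connected components of at least `minClusterVoxels`
#' voxels (`all_voxels` mode skips the cluster criterion). The analysis mask
#' keeps voxels relevant in at least `minSubjects` subjects. Masked values
#' are the subject's z inside the mask (winsorised at `upperZCap` when set)
#' and 0 elsewhere, so downstream sampling treats non-relevant voxels as
#' non-activation.
#'
#' @param cohort a [Cohort-class].
#' @param opts a [RelevantVoxelOptions-class].
#' @return list with `subjectMasks` (list of logical arrays), `maskedValues`
#'   (list of numeric arrays) and `analysisMask` (logical array).
#' @export
selectRelevantVoxels <- function(cohort, opts = relevantVoxelOptions()) {
  validObject(opts)
  bm <- brainMask(cohort)
  n <- nSubjects(cohort)
  gs <- gridShape(cohort)
  count <- array(0L, gs)
  subjectMasks <- vector("list", n)
  maskedValues <- vector("list", n)
  for (s in seq_len(n)) {
    z <- cohort@maps[[s]]@data
    pos <- z > opts@minZ
    if (!is.null(bm)) pos <- pos & bm
    if (opts@mode == "relevant" && any(pos)) {
      lab <- .connectedComponents(pos, opts@connectivity)
      sizes <- tabulate(lab)
      small <- which(sizes < opts@minClusterVoxels)
      if (length(small)) pos[lab %in% small] <- FALSE
    }
    mv <- array(0, gs)
    if (length(opts@upperZCap)) {
      mv[pos] <- pmin(z[pos], opts@upperZCap)
    } else {
      mv[pos] <- z[pos]
    }
    subjectMasks[[s]] <- pos
    maskedValues[[s]] <- mv
    count <- count + pos
  }
  analysisMask <- count >= opts@minSubjects
  if (!is.null(bm)) analysisMask <- analysisMask & bm
  names(subjectMasks) <- names(maskedValues) <- subjectId(cohort)
  list(subjectMasks = subjectMasks, maskedValues = maskedValues,
       analysisMask = analysisMask)
}

#' Sample a spherical neighbourhood around one voxel
#'
#' Returns the aggregate (max by default) of the values over all voxels whose
#' centre lies within `radiusMm` of the target voxel's centre; out-of-grid
#' neighbours are ignored and radius 0 degenerates to the voxel's own value.
#' On a 2 mm grid a 2 mm radius covers the centre plus its 6 face neighbours.
#' The max is the default aggregate because the sphere exists to tolerate
#' small spatial misalignment between subjects.
#'
#' @param map a [StatMap-class] (or 3-D array, in which case `affine` is
#'   needed for voxel spacing).
#' @param voxel 0-based voxel index triple.
#' @param radiusMm sphere radius in mm (default 2).
#' @param maskedValues optional array sampled instead of the map's raw data
#'   (e.g. the output of [selectRelevantVoxels()]).
#' @param aggregate `"max"` (default) or `"mean"`.
#' @param affine 4x4 matrix when `map` is a plain array.
#' @return a single numeric value.
#' @export
sampleNeighborhood <- function(map, voxel, radiusMm = 2, maskedValues = NULL,
                               aggregate = c("max", "mean"), affine = NULL) {
  aggregate <- match.arg(aggregate)
  if (is(map, "StatMap")) {
    vol <- map@data
    if (is.null(affine)) affine <- map@affine
  } else {
    vol <- map
    if (is.null(affine)) stop("affine needed for a plain array")
  }
  if (!is.null(maskedValues)) vol <- maskedValues
  dm <- dim(vol)
  if (!.isInGrid(voxel, dm)) stop("voxel outside grid")
  offs <- .neighborOffsets(affine, radiusMm)
  nb <- t(t(offs) + as.integer(voxel))
  ok <- nb[, 1L] >= 0 & nb[, 1L] <= dm[1L] - 1L &
        nb[, 2L] >= 0 & nb[, 2L] <= dm[2L] - 1L &
        nb[, 3L] >= 0 & nb[, 3L] <= dm[3L] - 1L
  vals <- vol[nb[ok, 1L] + 1L + dm[1L] * nb[ok, 2L] +
              dm[1L] * dm[2L] * nb[ok, 3L]]
  if (aggregate == "max") max(vals) else mean(vals)
}

#' Build the overlap curve from per-subject sampled statistics
#'
#' Thresholds are `nGridSteps` even steps spanning (0, tMax]; O(t) is the
#' fraction of subjects whose sample is >= t (a subject exactly at a grid
#' threshold counts as activating). By default tMax is the peak sampled
#' value across subjects at this location; an explicit `gridMax` implements
#' the global/fixed-cap rules. All samples <= 0 give a degenerate curve with
#' O identically 0.
#'
#' @param samples numeric vector, one sampled statistic per subject.
#' @param nGridSteps number of threshold steps (default 100).
#' @param gridMax explicit tMax, or `NULL` for the per-location peak.
#' @return an [OverlapCurve-class].
#' @examples
#' oc <- overlapCurve(c(2, 1, 0), nGridSteps = 4)
#' oc@thresholds  # 0.5 1.0 1.5 2.0
#' oc@fractions   # 2/3 2/3 1/3 1/3
#' @export
overlapCurve <- function(samples, nGridSteps = 100L, gridMax = NULL) {
  n <- length(samples)
  stopifnot(n >= 1L)
  tmax <- if (is.null(gridMax)) max(samples) else gridMax
  if (!is.finite(tmax) || tmax <= 0)
    return(new("OverlapCurve", thresholds = numeric(0),
               fractions = numeric(0), n = as.integer(n)))
  ## t_i = tmax * (i/n): at i = n the ratio is exactly 1, so the peak sample
  ## always counts as activating at the top threshold
  th <- tmax * (seq_len(nGridSteps) / nGridSteps)
  frac <- vapply(th, function(t) sum(samples >= t) / n, numeric(1))
  new("OverlapCurve", thresholds = th, fractions = frac, n = as.integer(n))
}

#' Weighted area-under-curve consistency of an overlap curve
#'
#' C = sum(w(t_i) O(t_i)) / sum(w(t_i)) over the threshold grid, with
#' w(t) = t under linear weighting (the default — more value to higher
#' statistical levels) or w(t) = 1 under uniform weighting. Degenerate
#' curves give 0. The result lies in [0, 1].
#'
#' @param curve an [OverlapCurve-class].
#' @param weighting `"linear"` (default) or `"uniform"`.
#' @return consistency value in [0, 1].
#' @examples
#' weightedConsistency(overlapCurve(c(2, 1, 0), 1000))            # -> 5/12
#' weightedConsistency(overlapCurve(c(2, 1, 0), 1000), "uniform") # -> 1/2
#' @export
weightedConsistency <- function(curve, weighting = c("linear", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(curve@thresholds)) return(0)
  w <- if (weighting == "linear") curve@thresholds else
    rep(1, length(curve@thresholds))
  sum(w * curve@fractions) / sum(w)
}

#' Compute a threshold-weighted overlap (consistency) map
#'
#' The full pipeline: relevant-voxel selection, per-subject spherical
#' neighbourhood sampling of the masked z-values, per-voxel overlap curve
#' over a threshold sweep, and weighted AUC. Voxels outside the analysis
#' mask are 0. The computation is deterministic and invariant to subject
#' order.
#'
#' @param cohort a [Cohort-class].
#' @param opts a [RelevantVoxelOptions-class].
#' @param weighting `"linear"` (default) or `"uniform"`.
#' @param radiusMm neighbourhood sphere radius in mm (default 2).
#' @param gridMaxRule how the top of the threshold grid is set per voxel:
#'   `"per_voxel"` (default; the peak sampled value across subjects at that
#'   voxel), `"global"` (the cohort-wide peak) or `"fixed"` (an explicit
#'   `gridMaxCap`).
#' @param gridMaxCap the cap for `gridMaxRule = "fixed"`.
#' @param nGridSteps threshold steps (default 100; the grid error is bounded
#'   by 1/nGridSteps, well below 1/N for feasible cohort sizes).
#' @param aggregate neighbourhood aggregate, `"max"` (default) or `"mean"`.
#' @return a [ConsistencyMap-class].
#' @examples
#' syn <- makeZmapCohort(cohortRecipe(n = 6, roiSpecs = list(
#'   roiSpec("net", "common_strong", c(8, 8, 8), 2)), seed = 7))
#' cm <- computeTwomMap(syn$cohort)
#' max(voxelData(cm))
#' @export
computeTwomMap <- function(cohort, opts = relevantVoxelOptions(),
                           weighting = c("linear", "uniform"), radiusMm = 2,
                           gridMaxRule = c("per_voxel", "global", "fixed"),
                           gridMaxCap = NULL, nGridSteps = 100L,
                           aggregate = c("max", "mean")) {
  weighting <- match.arg(weighting)
  gridMaxRule <- match.arg(gridMaxRule)
  aggregate <- match.arg(aggregate)
  if (gridMaxRule == "fixed" && (is.null(gridMaxCap) || gridMaxCap <= 0))
    stop("gridMaxRule = 'fixed' needs a positive gridMaxCap")
  sel <- selectRelevantVoxels(cohort, opts)
  S <- .sampledMatrix(cohort, sel, radiusMm, aggregate)
  idx <- which(sel$analysisMask)
  gs <- gridShape(cohort)
  values <- array(0, gs)
  if (length(idx)) {
    Sa <- S[idx, , drop = FALSE]
    tmax <- switch(gridMaxRule,
      per_voxel = do.call(pmax, c(as.data.frame(Sa), list(0))),
      global = rep(max(S, 0), length(idx)),
      fixed = rep(gridMaxCap, length(idx)))
    live <- tmax > 0
    if (any(live)) {
      n <- ncol(Sa)
      ngs <- as.integer(nGridSteps)
      Sl <- Sa[live, , drop = FALSE]
      tl <- tmax[live]
      num <- numeric(sum(live))
      wsum <- 0
      for (i in seq_len(ngs)) {
        wi <- if (weighting == "linear") i else 1
        cnt <- rowSums(Sl >= tl * (i / ngs))
        num <- num + wi * cnt
        wsum <- wsum + wi
      }
      cv <- numeric(length(idx))
      cv[live] <- num / (n * wsum)
      values[idx] <- cv
    }
  }
  new("ConsistencyMap", values = values, affine = affineMatrix(cohort),
      options = opts, weighting = weighting, radiusMm = radiusMm,
      aggregate = aggregate, gridMaxRule = gridMaxRule,
      gridMaxCap = if (is.null(gridMaxCap)) numeric(0) else gridMaxCap,
      nGridSteps = as.integer(nGridSteps))
}

## voxels x subjects matrix of neighbourhood-sampled masked values
.sampledMatrix <- function(cohort, sel, radiusMm, aggregate) {
  offs <- .neighborOffsets(affineMatrix(cohort), radiusMm)
  n <- nSubjects(cohort)
  S <- matrix(0, prod(gridShape(cohort)), n)
  for (s in seq_len(n))
    S[, s] <- as.numeric(.sampleVolume(sel$maskedValues[[s]], offs, aggregate))
  colnames(S) <- subjectId(cohort)
  S
}

#' Map the proportion of subjects engaging each voxel
#'
#' Per voxel, the fraction of subjects whose neighbourhood-sampled masked z
#' meets the threshold: `tau = 0` means "any activation" (sample strictly
#' positive), while e.g. `tau = 3.1` means activation above single-subject
#' significance. Values are multiples of 1/N.
#'
#' @inheritParams computeTwomMap
#' @param tau engagement threshold (>= 0).
#' @return a [StatMap-class] of proportions in [0, 1].
#' @export
engagementMap <- function(cohort, tau = 3.1, radiusMm = 2,
                          opts = relevantVoxelOptions(),
                          aggregate = c("max", "mean")) {
  stopifnot(tau >= 0)
  aggregate <- match.arg(aggregate)
  sel <- selectRelevantVoxels(cohort, opts)
  S <- .sampledMatrix(cohort, sel, radiusMm, aggregate)
  prop <- if (tau == 0) rowMeans(S > 0) else rowMeans(S >= tau)
  new("StatMap", subjectId = sprintf("engagement_tau%g", tau),
      data = array(prop, gridShape(cohort)), affine = affineMatrix(cohort))
}
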