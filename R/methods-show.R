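## Accessors ------------------------------------------------------------------

#' @rdname StatMap-class
#' @export
setMethod("subjectId", "StatMap", function(x) x@subjectId)

#' @rdname StatMap-class
#' @export
setMethod("voxelData", "StatMap", function(x) x@data)

#' @rdname StatMap-class
#' @export
setMethod("affineMatrix", "StatMap", function(x) x@affine)

#' @rdname StatMap-class
#' @export
setMethod("gridShape", "StatMap", function(x) dim(x@data))

#' @rdname ConsistencyMap-class
#' @export
setMethod("voxelData", "ConsistencyMap", function(x) x@values)

#' @rdname ConsistencyMap-class
#' @export
setMethod("affineMatrix", "ConsistencyMap", function(x) x@affine)

#' @rdname ConsistencyMap-class
#' @export
setMethod("gridShape", "ConsistencyMap", function(x) dim(x@values))

#' @rdname Cohort-class
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@maps))

#' @rdname Cohort-class
#' @export
setMethod("cohortMaps", "Cohort", function(x) x@maps)

#' @rdname Cohort-class
#' @export
setMethod("cohortLabels", "Cohort", function(x) x@labels)

#' @rdname Cohort-class
#' @export
setMethod("brainMask", "Cohort",
          function(x) if (length(x@brainMask)) x@brainMask else NULL)

#' @rdname Cohort-class
#' @export
setMethod("subjectId", "Cohort",
          function(x) vapply(x@maps, function(m) m@subjectId, character(1)))

#' @rdname Cohort-class
#' @export
setMethod("affineMatrix", "Cohort", function(x) x@maps[[1L]]@affine)

#' @rdname Cohort-class
#' @export
setMethod("gridShape", "Cohort", function(x) dim(x@maps[[1L]]@data))

#' @rdname VoxelProfile-class
#' @export
setMethod("profileSamples", "VoxelProfile", function(x) x@samples)

## show() ---------------------------------------------------------------------

setMethod("show", "StatMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("StatMap '%s': %dx%dx%d grid, z in [%.2f, %.2f]\n",
              object@subjectId, d[1], d[2], d[3],
              min(object@data), max(object@data)))
})

setMethod("show", "Cohort", function(object) {
  d <- gridShape(object)
  cat(sprintf("Cohort of %d subjects on a %dx%dx%d grid%s\n",
              nSubjects(object), d[1], d[2], d[3],
              if (length(object@brainMask)) " (brain-masked)" else ""))
  extra <- intersect(c("group", "visit"), names(object@labels))
  if (length(extra))
    for (cn in extra)
      cat(sprintf("  %s: %s\n", cn,
                  paste(names(table(object@labels[[cn]])), collapse = ", ")))
})

setMethod("show", "OverlapCurve", function(object) {
  cat(sprintf("OverlapCurve over %d subjects, %d thresholds in (0, %.3f]\n",
              object@n, length(object@thresholds),
              if (length(object@thresholds)) max(object@thresholds) else 0))
})

setMethod("show", "ConsistencyMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ConsistencyMap %dx%dx%d: %s weighting, r=%g mm, %s grid (%d steps)\n",
    d[1], d[2], d[3], object@weighting, object@radiusMm,
    object@gridMaxRule, object@nGridSteps))
  cat(sprintf("  nonzero voxels: %d, max C = %.3f\n",
              sum(object@values > 0), max(object@values)))
})

setMethod("show", "DiceResult", function(object) {
  cat(sprintf("Dice %.2f%% (|A|=%d, |B|=%d, |A n B|=%d)\n",
              object@dicePercent, object@volumeA, object@volumeB,
              object@volumeIntersection))
})

setMethod("show", "VoxelProfile", function(object) {
  cat(sprintf("VoxelProfile at mm (%g, %g, %g), r=%g mm, %d subjects\n",
              object@mm[1], object@mm[2], object@mm[3], object@radiusMm,
              nrow(object@samples)))
})

setMethod("show", "DesignSpec", function(object) {
  cat(sprintf("DesignSpec: %d blocks (%s), TR=%g s, total %g s\n",
              length(object@blockSequence),
              paste(table(object@blockSequence)[c("semantic", "line", "fixation")],
                    c("semantic", "line", "fixation"), collapse = ", "),
              object@trS, designTotalDuration(object)))
})

setMethod("show", "RelevantVoxelOptions", function(object) {
  cat(sprintf(
    "RelevantVoxelOptions: mode=%s, z>%g, cluster>=%d, subjects>=%d, cap=%s\n",
    object@mode, object@minZ, object@minClusterVoxels, object@minSubjects,
    if (length(object@upperZCap)) format(object@upperZCap) else "none"))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf("DesignMatrix: %d volumes x %d regressors (%s), TR=%g s\n",
              nrow(object@matrix), ncol(object@matrix),
              paste(colnames(object@matrix), collapse = ", "), object@trS))
})
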