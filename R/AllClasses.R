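#' @import methods
NULL

## Largest |z| ever stored: the conventional finite ceiling of the normal
## quantile at single precision (qnorm of the smallest representable p).
Z_CLIP <- 8.2

#' StatMap: one subject's 3-D statistical volume
#'
#' A single subject's unthresholded 3-D z-statistic volume together with its
#' voxel-index-to-millimetre affine. Voxel indices are 0-based throughout the
#' package; mm coordinates follow the affine (RAS assumed for reporting).
#'
#' @slot subjectId character scalar identifying the subject.
#' @slot data 3-D numeric array of z-statistics (unitless). Never contains
#'   NaN/Inf: loaders replace them with 0 and report the count.
#' @slot affine 4x4 voxel-index (0-based) to mm transform; must be invertible.
#'
#' @seealso [readStatMap()], [writeVolume()]
#' @export
setClass("StatMap",
  representation(subjectId = "character", data = "array", affine = "matrix"))

setValidity("StatMap", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L || is.na(object@subjectId) ||
      !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty character scalar")
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-D array")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite (NaN/Inf are replaced at load time)")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (!all(is.finite(object@affine)) ||
           abs(det(object@affine)) < 1e-10)
    msg <- c(msg, "affine must be finite and invertible")
  if (length(msg)) msg else TRUE
})

#' Cohort: an ordered set of co-registered StatMaps
#'
#' All maps must share one grid and one affine (entries equal within 1e-4);
#' the cohort is the unit on which overlap mapping operates. Optional
#' per-subject group/visit labels and an optional binary brain mask restrict
#' and annotate downstream analyses.
#'
#' @slot maps list of [StatMap-class] objects, in manifest order.
#' @slot labels data.frame with one row per subject: columns `subject_id` and
#'   optionally `group`, `visit`.
#' @slot brainMask 3-D logical array on the shared grid, or a 0-length logical
#'   when absent.
#'
#' @seealso [loadCohort()], [makeZmapCohort()], [computeTwomMap()]
#' @export
setClass("Cohort",
  representation(maps = "list", labels = "data.frame", brainMask = "logical"))

setValidity("Cohort", function(object) {
  msg <- character(0)
  n <- length(object@maps)
  if (n < 1L) msg <- c(msg, "a Cohort needs at least one StatMap")
  if (!all(vapply(object@maps, is, logical(1), "StatMap")))
    msg <- c(msg, "maps must all be StatMap objects")
  if (n >= 1L && all(vapply(object@maps, is, logical(1), "StatMap"))) {
    ids <- vapply(object@maps, function(m) m@subjectId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicated subject_id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    ref <- object@maps[[1L]]
    for (m in object@maps[-1L]) {
      if (!identical(dim(m@data), dim(ref@data)))
        msg <- c(msg, sprintf("grid mismatch for subject '%s'", m@subjectId))
      else if (max(abs(m@affine - ref@affine)) > 1e-4)
        msg <- c(msg, sprintf("affine mismatch for subject '%s'", m@subjectId))
    }
    if (nrow(object@labels) != n ||
        !"subject_id" %in% names(object@labels) ||
        !identical(as.character(object@labels$subject_id), ids))
      msg <- c(msg, "labels must carry one row per map with matching subject_id")
    if (length(object@brainMask) &&
        !identical(dim(object@brainMask), dim(ref@data)))
      msg <- c(msg, "brainMask grid does not match the maps")
  }
  if (length(msg)) msg else TRUE
})

#' DesignSpec: block-design task timing
#'
#' Timing of the alternating semantic / line-matching block paradigm used to
#' simulate BOLD runs: active blocks of `trialsPerBlock` trials of
#' `trialDurationS` seconds each, a short inter-block delay after every active
#' block, and fixation blocks of `fixationDurationS` seconds.
#'
#' @slot blockSequence character vector of block labels, each one of
#'   "semantic", "line" or "fixation", in presentation order.
#' @slot trialDurationS,trialsPerBlock,interBlockDelayS,fixationDurationS,trS
#'   numeric scalars (seconds / counts); all strictly positive.
#'
#' @seealso [makeDesign()], [simulateBoldCohort()], [buildDesignMatrix()]
#' @export
setClass("DesignSpec",
  representation(blockSequence = "character", trialDurationS = "numeric",
                 trialsPerBlock = "numeric", interBlockDelayS = "numeric",
                 fixationDurationS = "numeric", trS = "numeric"))

setValidity("DesignSpec", function(object) {
  msg <- character(0)
  ok <- c("semantic", "line", "fixation")
  if (!length(object@blockSequence) || !all(object@blockSequence %in% ok))
    msg <- c(msg, "blockSequence must be non-empty with labels semantic/line/fixation")
  for (s in c("trialDurationS", "trialsPerBlock", "interBlockDelayS",
              "fixationDurationS", "trS")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a positive scalar", s))
  }
  if (length(msg)) msg else TRUE
})

#' CohortRecipe: parameters of a synthetic z-map cohort
#'
#' Describes a cohort of N co-registered z-maps with planted regions of
#' interest, smooth background noise, per-subject spatial jitter and optional
#' lesions. The recipe's seed fixes every random draw, so a recipe is a
#' complete, reproducible description of a simulated study.
#'
#' @slot n number of subjects.
#' @slot gridShape integer triple.
#' @slot voxelSizeMm voxel edge length in mm (isotropic grid).
#' @slot roiSpecs list of ROI specifications, see [roiSpec()].
#' @slot noiseSd marginal standard deviation of the background noise field.
#' @slot smoothingFwhmMm spatial FWHM (mm) of background-noise smoothing.
#' @slot jitterMaxVoxels maximum per-axis integer ROI translation per subject.
#' @slot lesionSpec list(center, radiusVox, subjects) or empty list.
#' @slot seed integer seed controlling all randomness.
#'
#' @seealso [cohortRecipe()], [makeZmapCohort()], [simulateBoldCohort()]
#' @export
setClass("CohortRecipe",
  representation(n = "integer", gridShape = "integer", voxelSizeMm = "numeric",
                 roiSpecs = "list", noiseSd = "numeric",
                 smoothingFwhmMm = "numeric", jitterMaxVoxels = "integer",
                 lesionSpec = "list", seed = "integer"))

setValidity("CohortRecipe", function(object) {
  msg <- character(0)
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be a positive integer triple")
  if (object@jitterMaxVoxels < 0L) msg <- c(msg, "jitterMaxVoxels must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  for (r in object@roiSpecs) {
    if (identical(r$rule, "subgroup") && length(r$members) > object@n)
      msg <- c(msg, sprintf("ROI '%s': subgroup size exceeds n", r$roiId))
  }
  if (length(msg)) msg else TRUE
})

#' RelevantVoxelOptions: heuristics selecting voxels eligible for overlap mapping
#'
#' Per subject, a voxel is "relevant" when its z exceeds `minZ` (strictly) and
#' it belongs to a connected component of at least `minClusterVoxels`
#' suprathreshold voxels; tiny clusters are dropped to suppress outlier
#' activations. The analysis mask keeps voxels relevant in at least
#' `minSubjects` subjects. With `upperZCap` set, z-values above the cap are
#' winsorised to the cap so extreme activators still count as activating.
#' `mode = "all_voxels"` searches every in-brain voxel with z > minZ and
#' ignores the cluster-size criterion.
#'
#' @seealso [relevantVoxelOptions()], [selectRelevantVoxels()]
#' @export
setClass("RelevantVoxelOptions",
  representation(minZ = "numeric", minClusterVoxels = "integer",
                 minSubjects = "integer", upperZCap = "numeric",
                 mode = "character", connectivity = "integer"))

setValidity("RelevantVoxelOptions", function(object) {
  msg <- character(0)
  if (object@minSubjects < 1L) msg <- c(msg, "minSubjects must be >= 1")
  if (object@minClusterVoxels < 1L) msg <- c(msg, "minClusterVoxels must be >= 1")
  if (!object@mode %in% c("relevant", "all_voxels"))
    msg <- c(msg, "mode must be 'relevant' or 'all_voxels'")
  if (!object@connectivity %in% c(6L, 26L))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (length(object@upperZCap) > 1L)
    msg <- c(msg, "upperZCap must be empty (none) or a single value")
  if (length(msg)) msg else TRUE
})

#' OverlapCurve: per-voxel survival function of activation across subjects
#'
#' Thresholds are `nGridSteps` even steps spanning (0, tMax]; `fractions[i]`
#' is O(t_i), the fraction of subjects whose sampled statistic is >= t_i.
#' O is non-increasing and O(t)*N is integral at every grid point.
#'
#' @seealso [overlapCurve()], [weightedConsistency()]
#' @export
setClass("OverlapCurve",
  representation(thresholds = "numeric", fractions = "numeric", n = "integer"))

setValidity("OverlapCurve", function(object) {
  msg <- character(0)
  if (length(object@thresholds) != length(object@fractions))
    msg <- c(msg, "thresholds and fractions differ in length")
  if (object@n < 1L) msg <- c(msg, "n must be >= 1")
  if (length(object@fractions)) {
    if (any(object@fractions < -1e-12) || any(object@fractions > 1 + 1e-12))
      msg <- c(msg, "fractions must lie in [0,1]")
    if (any(diff(object@fractions) > 1e-12))
      msg <- c(msg, "fractions must be non-increasing in threshold")
    k <- object@fractions * object@n
    if (max(abs(k - round(k))) > 1e-9)
      msg <- c(msg, "fractions*N must be integers")
    if (is.unsorted(object@thresholds, strictly = TRUE))
      msg <- c(msg, "thresholds must be strictly ascending")
  }
  if (length(msg)) msg else TRUE
})

#' ConsistencyMap: threshold-weighted overlap (consistency) volume
#'
#' Per-voxel consistency in [0,1]: the weighted area under the overlap curve,
#' 0 outside the analysis mask. Carries the settings that produced it so a map
#' is self-describing.
#'
#' @seealso [computeTwomMap()]
#' @export
setClass("ConsistencyMap",
  representation(values = "array", affine = "matrix",
                 options = "RelevantVoxelOptions", weighting = "character",
                 radiusMm = "numeric", aggregate = "character",
                 gridMaxRule = "character", gridMaxCap = "numeric",
                 nGridSteps = "integer"))

setValidity("ConsistencyMap", function(object) {
  msg <- character(0)
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (any(object@values < -1e-12) || any(object@values > 1 + 1e-12))
    msg <- c(msg, "consistency values must lie in [0,1]")
  if (!object@weighting %in% c("uniform", "linear"))
    msg <- c(msg, "weighting must be 'uniform' or 'linear'")
  if (!object@gridMaxRule %in% c("per_voxel", "global", "fixed"))
    msg <- c(msg, "gridMaxRule must be per_voxel/global/fixed")
  if (length(msg)) msg else TRUE
})

#' VoxelProfile: per-subject sampled statistics at one location
#'
#' The unit of per-voxel evidence display: for one mm location, the
#' neighbourhood-sampled masked z of every cohort subject, under the same
#' settings as the consistency map so that profile and map agree exactly.
#'
#' @slot mm,voxel the location in mm and (0-based) voxel indices.
#' @slot radiusMm the sampling sphere radius.
#' @slot samples data.frame with columns subject_id, z_sampled and any label
#'   columns (group, visit) present in the cohort.
#'
#' @seealso [voxelProfile()], [profileHistogram()], [flagAtypicalSubjects()]
#' @export
setClass("VoxelProfile",
  representation(mm = "numeric", voxel = "integer", radiusMm = "numeric",
                 samples = "data.frame"))

setValidity("VoxelProfile", function(object) {
  msg <- character(0)
  if (!all(c("subject_id", "z_sampled") %in% names(object@samples)))
    msg <- c(msg, "samples needs subject_id and z_sampled columns")
  if (length(object@voxel) != 3L || length(object@mm) != 3L)
    msg <- c(msg, "mm and voxel must be triples")
  if (length(msg)) msg else TRUE
})

#' DiceResult: Dice similarity of two binarised activation maps
#'
#' dice = 100 * 2|A n B| / (|A| + |B|), in percent, with the three voxel
#' counts retained.
#'
#' @seealso [diceIndex()]
#' @export
setClass("DiceResult",
  representation(dicePercent = "numeric", volumeA = "integer",
                 volumeB = "integer", volumeIntersection = "integer"))

#' DesignMatrix: volumes x regressors GLM design
#'
#' Condition columns are HRF-convolved boxcars sampled at the TR; an intercept
#' and optional cosine drift columns (high-pass surrogate) complete the model.
#'
#' @seealso [buildDesignMatrix()], [fitGlmContrast()]
#' @export
setClass("DesignMatrix",
  representation(matrix = "matrix", trS = "numeric"))

setValidity("DesignMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@matrix) < 2L)
    msg <- c(msg, "design must have at least 2 columns")
  if (is.null(colnames(object@matrix)))
    msg <- c(msg, "design columns must be named")
  task <- intersect(colnames(object@matrix), c("semantic", "line"))
  if (length(task) &&
      any(vapply(task, function(cn) all(object@matrix[, cn] == 0), logical(1))))
    msg <- c(msg, "task columns must not be all-zero")
  if (length(msg)) msg else TRUE
})
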