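#' @rdname StatMap-class
#' @param object,x an object.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname StatMap-class
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname StatMap-class
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname StatMap-class
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname Cohort-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname Cohort-class
#' @export
setGeneric("cohortMaps", function(x) standardGeneric("cohortMaps"))

#' @rdname Cohort-class
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname Cohort-class
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))

#' @rdname VoxelProfile-class
#' @export
setGeneric("profileSamples", function(x) standardGeneric("profileSamples"))
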