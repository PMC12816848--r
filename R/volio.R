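## Volume and manifest I/O; owns all coordinate conventions.
##
## Conventions: voxel indices are 0-based; mm coordinates follow the volume's
## affine (RAS orientation assumed when reporting peak tables). Grids are
## never resampled here — a grid mismatch within a cohort is an error, because
## all maps are assumed registered to one template upstream.

#' Read a 3-D statistical volume as a StatMap
#'
#' Loads a NIfTI-1 volume containing one subject's unthresholded z-statistics.
#' NaN and infinite voxels are replaced by 0 (non-activation) and the
#' replacement count is reported via a message, because overlap mapping treats
#' non-activation as z <= 0. A 4-D file is accepted only if its fourth
#' dimension is a singleton.
#'
#' @param path path to a readable `.nii` / `.nii.gz` file.
#' @param subjectId identifier stored in the result; defaults to the file
#'   name without extension.
#' @return a [StatMap-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(array(rnorm(8^3), c(8, 8, 8)), diag(c(2, 2, 2, 1)), f)
#' readStatMap(f, subjectId = "s01")
#' @export
readStatMap <- function(path, subjectId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  dat <- array(as.vector(img), dm)   # plain array, no niftiImage attributes
  if (length(dm) == 4L) {
    if (dm[4L] != 1L)
      stop("expected a 3-D volume, got 4-D with ", dm[4L], " volumes: ", path)
    dat <- array(dat, dm[1:3])
  } else if (length(dm) != 3L) {
    stop("expected a 3-D volume, got ", length(dm), "-D: ", path)
  }
  bad <- !is.finite(dat)
  if (any(bad)) {
    message(sprintf("readStatMap: replaced %d non-finite voxel(s) with 0 in %s",
                    sum(bad), path))
    dat[bad] <- 0
  }
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff), 4L, 4L)
  if (abs(det(aff)) < 1e-10) stop("non-invertible affine in ", path)
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  new("StatMap", subjectId = subjectId, data = dat, affine = aff)
}

#' Write a 3-D volume to NIfTI-1
#'
#' Data are stored as float32; re-reading yields bitwise-equal float32 values.
#'
#' @param data 3-D numeric array (finite), or a [StatMap-class] /
#'   [ConsistencyMap-class] (in which case `affine` is taken from the object).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(data, affine = NULL, path) {
  if (is(data, "StatMap") || is(data, "ConsistencyMap")) {
    if (is.null(affine)) affine <- affineMatrix(data)
    data <- voxelData(data)
  }
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (any(!is.finite(data))) stop("data must be finite")
  if (is.null(affine)) stop("affine is required")
  storage.mode(data) <- "double"
  attr(data, "pixdim") <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data, datatype = "float")
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Load a cohort from a TSV manifest
#'
#' The manifest is tab-separated with columns `subject_id`, `path` and
#' optional `group` and `visit`. Relative paths are resolved against the
#' manifest's directory. Maps are loaded in manifest order and checked for an
#' identical grid and affine (entries within 1e-4); a mismatch is an error
#' naming the offending subject, never an implicit resample.
#'
#' @param manifestPath path to the TSV manifest.
#' @param brainMask optional path to a binary NIfTI brain mask on the same
#'   grid, or a 3-D logical array.
#' @return a [Cohort-class].
#' @export
loadCohort <- function(manifestPath, brainMask = NULL) {
  man <- utils::read.delim(manifestPath, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(man) == 0L) stop("no subjects in manifest ", manifestPath)
  if (!all(c("subject_id", "path") %in% names(man)))
    stop("manifest must have columns subject_id and path")
  if (anyDuplicated(man$subject_id))
    stop("duplicated subject_id in manifest: ",
         paste(unique(man$subject_id[duplicated(man$subject_id)]),
               collapse = ", "))
  base <- dirname(normalizePath(manifestPath))
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                  file.path(base, man$path))
  maps <- mapply(readStatMap, paths, man$subject_id, SIMPLIFY = FALSE)
  names(maps) <- NULL
  ref <- maps[[1L]]
  for (m in maps[-1L]) {
    if (!identical(dim(m@data), dim(ref@data)) ||
        max(abs(m@affine - ref@affine)) > 1e-4)
      stop("grid/affine mismatch for subject '", m@subjectId, "'")
  }
  labels <- man[, intersect(c("subject_id", "group", "visit"), names(man)),
                drop = FALSE]
  rownames(labels) <- NULL
  bm <- logical(0)
  if (!is.null(brainMask)) {
    if (is.character(brainMask))
      brainMask <- voxelData(readStatMap(brainMask, "mask")) > 0
    if (!identical(dim(brainMask), dim(ref@data)))
      stop("brain mask grid does not match the cohort")
    bm <- array(as.logical(brainMask), dim(brainMask))
  }
  new("Cohort", maps = maps, labels = labels, brainMask = bm)
}

#' Build a Cohort from in-memory StatMaps
#'
#' @param maps list of [StatMap-class] objects sharing one grid/affine.
#' @param group,visit optional per-subject label vectors.
#' @param brainMask optional 3-D logical array.
#' @return a [Cohort-class].
#' @export
newCohort <- function(maps, group = NULL, visit = NULL, brainMask = NULL) {
  labels <- data.frame(
    subject_id = vapply(maps, function(m) m@subjectId, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(group)) labels$group <- group
  if (!is.null(visit)) labels$visit <- visit
  bm <- if (is.null(brainMask)) logical(0) else
    array(as.logical(brainMask), dim(brainMask))
  new("Cohort", maps = maps, labels = labels, brainMask = bm)
}

#' Convert between voxel indices and mm coordinates
#'
#' `voxelToMm` maps 0-based voxel indices through the affine to mm;
#' `mmToVoxel` inverts and rounds to the nearest 0-based integer voxel,
#' erroring when the result falls outside the grid. The two are mutually
#' inverse up to half a voxel.
#'
#' @param voxel,mm numeric triple (or 3-column matrix of triples).
#' @param affine 4x4 voxel-to-mm matrix.
#' @param gridShape integer triple used for the bounds check.
#' @return a numeric (integer for `mmToVoxel`) triple or matrix of triples.
#' @export
voxelToMm <- function(voxel, affine) {
  v <- rbind(matrix(voxel, ncol = 3L))
  mm <- t(affine %*% rbind(t(v), 1))[, 1:3, drop = FALSE]
  if (length(voxel) == 3L && is.null(dim(voxel))) as.numeric(mm) else mm
}

#' @rdname voxelToMm
#' @export
mmToVoxel <- function(mm, affine, gridShape = NULL) {
  m <- rbind(matrix(mm, ncol = 3L))
  v <- t(solve(affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  v <- round(v)
  if (!is.null(gridShape)) {
    bad <- v[, 1L] < 0 | v[, 1L] > gridShape[1L] - 1L |
           v[, 2L] < 0 | v[, 2L] > gridShape[2L] - 1L |
           v[, 3L] < 0 | v[, 3L] > gridShape[3L] - 1L
    if (any(bad))
      stop("coordinate outside grid: ",
           paste(apply(rbind(m[bad, , drop = FALSE]), 1L, paste,
                       collapse = ","), collapse = "; "))
  }
  storage.mode(v) <- "integer"
  if (length(mm) == 3L && is.null(dim(mm))) as.integer(v) else v
}
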