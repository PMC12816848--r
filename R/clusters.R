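## Connected-component labelling of thresholded maps and peak tables.

#' Label suprathreshold clusters and drop small ones
#'
#' Connected components of `map >= threshold` are labelled; components with
#' fewer than `minSize` voxels are set to background. Surviving components
#' are relabelled 1..K in order of decreasing size (ties by smallest linear
#' voxel index), so labels are deterministic.
#'
#' @param map 3-D numeric array, [StatMap-class] or [ConsistencyMap-class].
#' @param threshold inclusion threshold (>= 0).
#' @param minSize minimum component size in voxels (default 10).
#' @param connectivity 26 (default) or 6.
#' @return integer 3-D array of labels, 0 = background.
#' @export
labelAndFilterClusters <- function(map, threshold, minSize = 10L,
                                   connectivity = 26L) {
  stopifnot(threshold >= 0)
  vol <- if (is(map, "StatMap") || is(map, "ConsistencyMap"))
    voxelData(map) else map
  lab <- .connectedComponents(vol >= threshold, as.integer(connectivity))
  if (!any(lab > 0L)) return(lab)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minSize)
  if (!length(keep)) return(array(0L, dim(vol)))
  firstIdx <- vapply(keep, function(k) which(lab == k)[1L], integer(1))
  ord <- keep[order(-sizes[keep], firstIdx)]
  out <- array(0L, dim(vol))
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  out
}

#' Extract a cluster peak table
#'
#' One row per label with cluster size, peak value and the peak location in
#' mm (via the affine) and 0-based voxel indices. Rows are sorted by
#' descending cluster size; within a cluster, peak ties are broken by the
#' lowest linear voxel index.
#'
#' @param map 3-D numeric array (or [StatMap-class]/[ConsistencyMap-class])
#'   from which peak values are read.
#' @param labels integer label array from [labelAndFilterClusters()] on the
#'   same grid.
#' @param affine 4x4 voxel-to-mm matrix; taken from `map` when it is a
#'   mapped object.
#' @return data.frame with columns cluster_id, size_voxels, peak_value,
#'   peak_x_mm, peak_y_mm, peak_z_mm, peak_vx, peak_vy, peak_vz.
#' @export
clusterPeakTable <- function(map, labels, affine = NULL) {
  if (is(map, "StatMap") || is(map, "ConsistencyMap")) {
    if (is.null(affine)) affine <- affineMatrix(map)
    map <- voxelData(map)
  }
  if (is.null(affine)) stop("affine required for a plain array")
  if (!identical(dim(map), dim(labels)))
    stop("labels grid does not match the map")
  empty <- data.frame(cluster_id = integer(0), size_voxels = integer(0),
                      peak_value = numeric(0), peak_x_mm = numeric(0),
                      peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                      peak_vx = integer(0), peak_vy = integer(0),
                      peak_vz = integer(0))
  K <- max(labels)
  if (K == 0L) return(empty)
  rows <- lapply(seq_len(K), function(k) {
    idx <- which(labels == k)
    vals <- map[idx]
    peak <- idx[which.max(vals)]  # which.max takes the first = lowest index
    vox <- arrayInd(peak, dim(map)) - 1L
    mm <- voxelToMm(as.integer(vox), affine)
    data.frame(cluster_id = k, size_voxels = length(idx),
               peak_value = max(vals), peak_x_mm = mm[1L], peak_y_mm = mm[2L],
               peak_z_mm = mm[3L], peak_vx = vox[1L], peak_vy = vox[2L],
               peak_vz = vox[3L])
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$size_voxels, tab$cluster_id), , drop = FALSE] -> tab
  rownames(tab) <- NULL
  tab
}
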