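## Map-to-map and group-level comparisons.

#' Dice similarity index of two binarised maps
#'
#' Each map is binarised at `value > threshold` (strict, matching the
#' convention of thresholding consistency maps "at 0", i.e. any activation);
#' use `threshold = 3.1 - 1e-9` or `strict = FALSE` for inclusive GLM-map
#' thresholding at z >= 3.1. dice = 100 * 2|A n B| / (|A| + |B|), symmetric
#' in its arguments. Two empty masks are an error (the index is undefined).
#'
#' @param mapA,mapB 3-D arrays or [StatMap-class]/[ConsistencyMap-class]
#'   objects on the same grid.
#' @param threshold binarisation threshold (default 0).
#' @param strict if `TRUE` (default) binarise at `> threshold`, else at
#'   `>= threshold`.
#' @return a [DiceResult-class].
#' @examples
#' a <- array(0, c(5, 5, 5)); b <- a
#' a[1:4, 1:5, 1:5] <- 1      # |A| = 100
#' b[1:2, 1:5, 1:5] <- 1      # |B| = 50
#' b[1:2, 1:5, 5] <- 0; b[1, 1:5, 4] <- 0  # trim overlap...
#' diceIndex(a, a)            # 100%
#' @export
diceIndex <- function(mapA, mapB, threshold = 0, strict = TRUE) {
  va <- if (is.array(mapA)) mapA else voxelData(mapA)
  vb <- if (is.array(mapB)) mapB else voxelData(mapB)
  if (!identical(dim(va), dim(vb))) stop("grid mismatch between the two maps")
  A <- if (strict) va > threshold else va >= threshold
  B <- if (strict) vb > threshold else vb >= threshold
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0L) stop("both masks are empty: Dice undefined")
  nI <- sum(A & B)
  new("DiceResult", dicePercent = 100 * 2 * nI / (nA + nB),
      volumeA = as.integer(nA), volumeB = as.integer(nB),
      volumeIntersection = as.integer(nI))
}

#' Fixed-effects (shared-variance) group combination of z-maps
#'
#' Per voxel, group z = sum(z_i) / sqrt(N): the equal-weight Stouffer
#' combination used as the fixed-effects surrogate, appropriate when
#' per-subject variance maps are not modelled. Under independent
#' standard-normal inputs the result is again standard normal.
#'
#' @param cohort a [Cohort-class] with N >= 2.
#' @param subjectId identifier for the output map.
#' @return a [StatMap-class].
#' @export
fixedEffectsGroupMap <- function(cohort, subjectId = "group") {
  n <- nSubjects(cohort)
  if (n < 2L) stop("fixed-effects combination needs N >= 2")
  acc <- array(0, gridShape(cohort))
  for (m in cohort@maps) acc <- acc + m@data
  new("StatMap", subjectId = subjectId, data = acc / sqrt(n),
      affine = affineMatrix(cohort))
}

#' Paired visit-difference map
#'
#' Subjects are matched by `subject_id` across the two cohorts; per voxel a
#' paired t-statistic of (visit2 - visit1) at N-1 degrees of freedom is
#' converted to z. A voxel with zero mean difference and zero variance is 0;
#' a nonzero constant shift with zero variance is degenerate (infinite t)
#' and clipped to +/- 8.2.
#'
#' @param visit1,visit2 [Cohort-class] objects with matching subject ids,
#'   N >= 3.
#' @param subjectId identifier for the output map.
#' @return a [StatMap-class] of paired-difference z-statistics.
#' @export
pairedDifferenceMap <- function(visit1, visit2, subjectId = "paired_diff") {
  ids1 <- subjectId(visit1); ids2 <- subjectId(visit2)
  if (!setequal(ids1, ids2))
    stop("unmatched subjects: ",
         paste(union(setdiff(ids1, ids2), setdiff(ids2, ids1)),
               collapse = ", "))
  n <- nSubjects(visit1)
  if (n < 3L) stop("paired comparison needs N >= 3")
  ord2 <- match(ids1, ids2)
  gs <- gridShape(visit1)
  D <- vapply(seq_len(n), function(s)
    as.numeric(visit2@maps[[ord2[s]]]@data - visit1@maps[[s]]@data),
    numeric(prod(gs)))
  mu <- rowMeans(D)
  sdd <- sqrt(rowSums((D - mu)^2) / (n - 1L))
  se <- sdd / sqrt(n)
  t <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * 1e12))
  z <- array(.tToZ(t, n - 1L), gs)
  new("StatMap", subjectId = subjectId, data = z,
      affine = affineMatrix(visit1))
}
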