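## Fixture builders and an independent brute-force reference for the
## consistency pipeline. The reference deliberately shares no code with the
## package internals: connected components by hand-rolled BFS, neighbourhoods
## by exhaustive distance scan, consistency by explicit per-threshold loops.

toyAffine <- function(voxMm = 2) diag(c(rep(voxMm, 3), 1))

## Spherical blob of a given value added onto a zero background.
blobMap <- function(id, gs = c(12L, 12L, 12L), center = c(5, 5, 5),
                    radiusVox = 2, value = 5, affine = toyAffine()) {
  vol <- array(0, gs)
  g <- as.matrix(expand.grid(x = 0:(gs[1] - 1), y = 0:(gs[2] - 1),
                             z = 0:(gs[3] - 1)))
  d <- sqrt(rowSums((t(t(g) - center))^2))
  vol[d <= radiusVox + 1e-9] <- value
  new("StatMap", subjectId = id, data = vol, affine = affine)
}

## A map whose data is an arbitrary array.
mapFromArray <- function(id, vol, affine = toyAffine()) {
  new("StatMap", subjectId = id, data = vol, affine = affine)
}

## Cohort in which subject s has value vals[s] in one shared >=10-voxel blob.
valueCohort <- function(vals, center = c(5, 5, 5), radiusVox = 2,
                        gs = c(12L, 12L, 12L)) {
  maps <- lapply(seq_along(vals), function(s)
    blobMap(sprintf("s%02d", s), gs, center, radiusVox, vals[s]))
  newCohort(maps)
}

## ---- independent reference implementations ----

## BFS connected components (26- or 6-connectivity), plain R.
refComponents <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  nextLab <- 0L
  idxs <- which(mask)
  for (start in idxs) {
    if (lab[start] > 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(cur, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- co + offs[r, ]
        if (any(nb < 1L) || any(nb > dm)) next
        ni <- nb[1L] + dm[1L] * (nb[2L] - 1L) + dm[1L] * dm[2L] * (nb[3L] - 1L)
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- nextLab
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

## Relevant-voxel mask for one subject, by the reference component labelling.
refSubjectMask <- function(z, minZ = 0, minCluster = 10L,
                           mode = "relevant", connectivity = 26L) {
  pos <- z > minZ
  if (mode == "all_voxels" || !any(pos)) return(pos)
  lab <- refComponents(pos, connectivity)
  sizes <- table(lab[lab > 0])
  small <- as.integer(names(sizes)[sizes < minCluster])
  pos[lab %in% small] <- FALSE
  pos
}

## Exhaustive-distance neighbour lists: for every voxel, the linear indices
## of all voxels whose centre lies within radiusMm (mm distance via affine).
refNeighborLists <- function(gs, affine, radiusMm) {
  g <- as.matrix(expand.grid(x = 0:(gs[1] - 1), y = 0:(gs[2] - 1),
                             z = 0:(gs[3] - 1)))
  mm <- g %*% t(affine[1:3, 1:3])
  lapply(seq_len(nrow(mm)), function(i) {
    d2 <- rowSums((mm - matrix(mm[i, ], nrow(mm), 3, byrow = TRUE))^2)
    which(d2 <= radiusMm^2 + 1e-9)
  })
}

## Full triple-loop reference consistency map (per voxel / subject / threshold).
refTwomMap <- function(cohort, minZ = 0, minCluster = 10L, minSubjects = 1L,
                       upperZCap = NULL, mode = "relevant", radiusMm = 2,
                       weighting = "linear", nGridSteps = 100L,
                       connectivity = 26L) {
  gs <- dim(cohortMaps(cohort)[[1]]@data)
  aff <- cohortMaps(cohort)[[1]]@affine
  n <- length(cohortMaps(cohort))
  masked <- vector("list", n)
  count <- array(0L, gs)
  for (s in seq_len(n)) {
    z <- cohortMaps(cohort)[[s]]@data
    m <- refSubjectMask(z, minZ, minCluster, mode, connectivity)
    mv <- array(0, gs)
    mv[m] <- if (is.null(upperZCap)) z[m] else pmin(z[m], upperZCap)
    masked[[s]] <- mv
    count <- count + m
  }
  analysis <- count >= minSubjects
  nbrs <- refNeighborLists(gs, aff, radiusMm)
  values <- array(0, gs)
  for (v in which(analysis)) {
    samples <- vapply(seq_len(n),
                      function(s) max(masked[[s]][nbrs[[v]]]), numeric(1))
    tmax <- max(samples)
    if (tmax <= 0) next
    acc <- 0; wacc <- 0
    for (i in seq_len(nGridSteps)) {
      ti <- tmax * (i / nGridSteps)
      Oi <- sum(samples >= ti) / n
      wi <- if (weighting == "linear") ti else 1
      acc <- acc + wi * Oi
      wacc <- wacc + wi
    }
    values[v] <- acc / wacc
  }
  list(values = values, analysisMask = analysis)
}

## Small random cohort with planted blobs, for property tests.
randomCohort <- function(n = 5, gs = c(10L, 10L, 10L), seed = 1,
                         noiseSd = 1) {
  syn <- makeZmapCohort(cohortRecipe(
    n = n, gridShape = gs,
    roiSpecs = list(roiSpec("a", "common_strong", center = gs %/% 2,
                            radiusVox = 2)),
    noiseSd = noiseSd, smoothingFwhmMm = 4, seed = seed))
  syn$cohort
}
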