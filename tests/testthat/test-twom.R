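test_that("relevant-voxel heuristics follow the cluster and subject rules", {
  gs <- c(12L, 12L, 12L)
  ## 9-voxel blob is excluded, 10-voxel blob retained at minCluster = 10
  v9 <- array(0, gs); v9[2:10, 2, 2] <- 4
  v10 <- array(0, gs); v10[2:11, 2, 2] <- 4
  co <- newCohort(list(mapFromArray("a", v9), mapFromArray("b", v10)))
  sel <- selectRelevantVoxels(co, relevantVoxelOptions())
  expect_equal(sum(sel$subjectMasks[["a"]]), 0)
  expect_equal(sum(sel$subjectMasks[["b"]]), 10)
  ## minSubjects toggle: a voxel activated by 1 of 2
  expect_true(any(sel$analysisMask))
  sel2 <- selectRelevantVoxels(co, relevantVoxelOptions(minSubjects = 2))
  expect_false(any(sel2$analysisMask))
  ## all-negative map gives an empty mask
  co2 <- newCohort(list(mapFromArray("n", array(-1, gs))))
  sel3 <- selectRelevantVoxels(co2)
  expect_false(any(sel3$subjectMasks[[1]]))
  ## all_voxels mode ignores the cluster criterion
  sel4 <- selectRelevantVoxels(co, relevantVoxelOptions(mode = "all_voxels"))
  expect_equal(sum(sel4$subjectMasks[["a"]]), 9)
  ## winsorising cap keeps extreme activators as activators
  vHot <- array(0, gs); vHot[2:11, 2, 2] <- 9
  co3 <- newCohort(list(mapFromArray("hot", vHot)))
  sel5 <- selectRelevantVoxels(co3, relevantVoxelOptions(upperZCap = 3.09))
  expect_equal(max(sel5$maskedValues[[1]]), 3.09)
  expect_equal(sum(sel5$subjectMasks[[1]]), 10)
})

test_that("neighbourhood sampling matches a brute-force distance scan", {
  aff <- toyAffine(2)
  set.seed(3)
  vol <- array(rnorm(8^3), c(8, 8, 8))
  m <- mapFromArray("s", vol, aff)
  ## radius 0 degenerates to the voxel's own value
  expect_equal(sampleNeighborhood(m, c(3, 4, 5), 0), vol[4, 5, 6])
  ## radius 2 mm on a 2 mm grid = centre + 6 face neighbours
  v2 <- array(0, c(8, 8, 8)); v2[4, 4, 4] <- 1; v2[5, 4, 4] <- 4
  expect_equal(sampleNeighborhood(mapFromArray("t", v2, aff), c(3, 3, 3), 2), 4)
  ## arbitrary radius vs exhaustive scan at 50 random targets
  nbrs <- refNeighborLists(c(8, 8, 8), aff, 4)
  set.seed(4)
  for (i in 1:50) {
    vox <- sample(0:7, 3, TRUE)
    lin <- vox[1] + 1 + 8 * vox[2] + 64 * vox[3]
    expect_equal(sampleNeighborhood(m, vox, 4), max(vol[nbrs[[lin]]]))
    expect_equal(sampleNeighborhood(m, vox, 4, aggregate = "mean"),
                 mean(vol[nbrs[[lin]]]))
  }
  expect_error(sampleNeighborhood(m, c(8, 0, 0), 2), "outside grid")
})

test_that("overlap curves count activating subjects over the threshold sweep", {
  oc <- overlapCurve(c(2.0, 1.0, 0.0), nGridSteps = 1000)
  ## O = 2/3 on (0,1], 1/3 on (1,2]
  expect_equal(oc@fractions[oc@thresholds <= 1],
               rep(2 / 3, sum(oc@thresholds <= 1)))
  expect_equal(oc@fractions[oc@thresholds > 1],
               rep(1 / 3, sum(oc@thresholds > 1)))
  expect_true(all(diff(oc@fractions) <= 0))
  expect_true(all(abs(oc@fractions * 3 - round(oc@fractions * 3)) < 1e-12))
  ## all equal positive samples: O identically 1 up to tMax
  oc2 <- overlapCurve(rep(2.5, 6), nGridSteps = 50)
  expect_equal(oc2@fractions, rep(1, 50))
  expect_equal(max(oc2@thresholds), 2.5)
  ## degenerate: no positive samples
  oc3 <- overlapCurve(c(-1, 0, -2))
  expect_length(oc3@thresholds, 0)
  expect_equal(weightedConsistency(oc3), 0)
})

test_that("weighted consistency reaches its closed-form continuous limits", {
  ## closed form for samples (2,1,0): integral of t*O(t) on (0,2] / integral t
  ## = 5/12 under linear weighting, 1/2 under uniform
  for (n in c(50, 100, 200, 1000)) {
    cl <- weightedConsistency(overlapCurve(c(2, 1, 0), n), "linear")
    cu <- weightedConsistency(overlapCurve(c(2, 1, 0), n), "uniform")
    expect_lt(abs(cl - 5 / 12), 1 / n)
    expect_lt(abs(cu - 1 / 2), 1 / n)
  }
  ## boundary cases
  expect_equal(weightedConsistency(overlapCurve(rep(3, 5))), 1)
  expect_equal(weightedConsistency(overlapCurve(c(0, 0, 0))), 0)
  ## uniform >= linear for non-increasing, non-constant curves
  set.seed(6)
  for (i in 1:20) {
    s <- round(runif(6, 0, 4), 2)
    oc <- overlapCurve(s, 100)
    if (!length(oc@thresholds) || length(unique(oc@fractions)) == 1) next
    expect_gte(weightedConsistency(oc, "uniform") + 1e-12,
               weightedConsistency(oc, "linear"))
  }
})

test_that("consistency map equals the triple-loop reference on a small cohort", {
  syn <- makeZmapCohort(cohortRecipe(
    n = 8, gridShape = c(12L, 12L, 12L),
    roiSpecs = list(
      roiSpec("strong", "common_strong", c(3, 3, 3), 2),
      roiSpec("weak", "common_weak", c(8, 8, 8), 2),
      roiSpec("sub", "subgroup", c(8, 3, 8), 2, members = c(1, 5))),
    noiseSd = 1, smoothingFwhmMm = 4, jitterMaxVoxels = 1, seed = 77))
  cm <- computeTwomMap(syn$cohort)
  ref <- refTwomMap(syn$cohort)
  expect_lt(max(abs(voxelData(cm) - ref$values)), 1e-9)
  ## also under uniform weighting and a winsorising cap
  opts <- relevantVoxelOptions(upperZCap = 3.09)
  cm2 <- computeTwomMap(syn$cohort, opts, weighting = "uniform")
  ref2 <- refTwomMap(syn$cohort, upperZCap = 3.09, weighting = "uniform")
  expect_lt(max(abs(voxelData(cm2) - ref2$values)), 1e-9)
})

test_that("consistency maps are order-invariant and bounded", {
  syn <- makeZmapCohort(cohortRecipe(
    n = 6, gridShape = c(10L, 10L, 10L),
    roiSpecs = list(roiSpec("a", "common_weak", c(5, 5, 5), 2)),
    noiseSd = 1, seed = 17))
  cm <- computeTwomMap(syn$cohort)
  expect_true(all(voxelData(cm) >= 0 & voxelData(cm) <= 1))
  ## C = 0 outside the analysis mask
  sel <- selectRelevantVoxels(syn$cohort)
  expect_true(all(voxelData(cm)[!sel$analysisMask] == 0))
  ## permuting subject order leaves the map unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  co2 <- newCohort(cohortMaps(syn$cohort)[perm])
  expect_equal(voxelData(computeTwomMap(co2)), voxelData(cm))
})

test_that("doubling the threshold grid changes consistency by < 1/n", {
  set.seed(12)
  samples <- runif(9, 0, 5)
  for (n in c(25, 50, 100)) {
    c1 <- weightedConsistency(overlapCurve(samples, n))
    c2 <- weightedConsistency(overlapCurve(samples, 2 * n))
    expect_lt(abs(c1 - c2), 1 / n)
  }
})

test_that("engagement maps report subject fractions at a threshold", {
  ## 3 of 15 at z=5, 7 more at z=1, 5 at zero
  vals <- c(rep(5, 3), rep(1, 7), rep(0, 5))
  co <- valueCohort(vals)
  e31 <- voxelData(engagementMap(co, tau = 3.1))[6, 6, 6]
  e0 <- voxelData(engagementMap(co, tau = 0))[6, 6, 6]
  expect_equal(e31, 3 / 15)   # 20% above significance
  expect_equal(e0, 10 / 15)   # 66.7% activated to some extent
  ## engagement values are always multiples of 1/N
  em <- voxelData(engagementMap(co, tau = 1))
  expect_true(all(abs(em * 15 - round(em * 15)) < 1e-12))
  ## all-zero cohort: proportion 0 everywhere
  coz <- newCohort(list(mapFromArray("z1", array(0, c(6, 6, 6))),
                        mapFromArray("z2", array(0, c(6, 6, 6)))))
  expect_true(all(voxelData(engagementMap(coz, tau = 0)) == 0))
})

test_that("consistency and sampling are monotone in signal and radius", {
  syn <- makeZmapCohort(cohortRecipe(
    n = 5, gridShape = c(10L, 10L, 10L),
    roiSpecs = list(roiSpec("a", "common_weak", c(5, 5, 5), 2)),
    noiseSd = 1, seed = 31))
  co <- syn$cohort
  ## raising one subject's z at an ROI voxel never decreases C there
  ## (fixed grid: use the fixed-cap rule so tMax does not move)
  base <- computeTwomMap(co, gridMaxRule = "fixed", gridMaxCap = 8)
  m2 <- cohortMaps(co)
  v <- voxelData(m2[[2]]); v[6, 6, 6] <- v[6, 6, 6] + 2
  m2[[2]] <- mapFromArray("s02", v, affineMatrix(co))
  bumped <- computeTwomMap(newCohort(m2), gridMaxRule = "fixed",
                           gridMaxCap = 8)
  expect_gte(voxelData(bumped)[6, 6, 6], voxelData(base)[6, 6, 6] - 1e-12)
  ## increasing radius never decreases sampled values or engagement
  for (r in list(c(0, 2), c(2, 4))) {
    s1 <- sampleNeighborhood(m2[[1]], c(5, 5, 5), r[1])
    s2 <- sampleNeighborhood(m2[[1]], c(5, 5, 5), r[2])
    expect_gte(s2, s1)
    e1 <- voxelData(engagementMap(co, 2, radiusMm = r[1]))
    e2 <- voxelData(engagementMap(co, 2, radiusMm = r[2]))
    expect_true(all(e2 - e1 >= -1e-12))
  }
})

test_that("planted common networks are recovered against background noise", {
  syn <- makeZmapCohort(cohortRecipe(
    n = 15, gridShape = c(16L, 16L, 16L),
    roiSpecs = list(roiSpec("net", "common_strong", c(8, 8, 8), 2)),
    noiseSd = 1, smoothingFwhmMm = 6, seed = 2026))
  roi <- as.matrix(syn$voxels[, c("vx", "vy", "vz")]) + 1L
  lin <- roi[, 1] + 16 * (roi[, 2] - 1) + 256 * (roi[, 3] - 1)
  ## full-cohort engagement at tau = 0+ covers >= 99% of the planted ROI
  e0 <- voxelData(engagementMap(syn$cohort, tau = 0))
  expect_gte(mean(e0[lin] == 1), 0.99)
  ## at the voxel's own value (no neighbourhood dilation) noise voxels
  ## almost never reach 90% engagement; the max-sampled map keeps a
  ## nonzero engagement floor on noise by construction (see vignette)
  e0r0 <- voxelData(engagementMap(syn$cohort, tau = 0, radiusMm = 0))
  noiseIdx <- setdiff(seq_along(e0r0), lin)
  expect_lte(mean(e0r0[noiseIdx] >= 0.9), 0.01)
  expect_gte(mean(e0r0[lin] == 1), 0.99)
})
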