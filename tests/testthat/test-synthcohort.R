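test_that("design variants carry the scanner TRs and block timing", {
  expect_equal(makeDesign("verio")@trS, 3.0)
  expect_equal(makeDesign("prisma")@trS, 0.933)
  ## summed block/delay durations: 14 active blocks of 16 s + 3 s delay,
  ## 4 fixation blocks of 14 s -> 322 s, within 10 s of a 5 min 25 s run
  total <- designTotalDuration(makeDesign("verio"))
  expect_equal(total, 322)
  expect_lt(abs(total - (5 * 60 + 25)), 10)
  expect_error(makeDesign("custom"), "blockSequence")
  seq7 <- makeDesign("verio")@blockSequence
  expect_equal(sum(seq7 == "semantic"), 7)
  expect_equal(sum(seq7 == "line"), 7)
  expect_equal(sum(seq7 == "fixation"), 4)
})

test_that("z-map cohorts plant the three variability scenarios", {
  ## noiseless common_strong: all subjects identical suprathreshold ROI
  rec <- cohortRecipe(n = 15, roiSpecs = list(
    roiSpec("net", "common_strong", center = c(8, 8, 8), radiusVox = 2)),
    noiseSd = 0, seed = 21)
  syn <- makeZmapCohort(rec)
  expect_equal(nSubjects(syn$cohort), 15)
  idx <- as.matrix(syn$voxels[, c("vx", "vy", "vz")]) + 1L
  for (m in cohortMaps(syn$cohort)) {
    expect_true(all(voxelData(m)[idx] >= 5))
    expect_equal(sum(voxelData(m) != 0), nrow(idx))
  }
  ## subgroup: exactly k of N exceed significance inside the ROI
  rec2 <- cohortRecipe(n = 24, roiSpecs = list(
    roiSpec("rIFG", "subgroup", center = c(8, 8, 8), radiusVox = 2,
            members = c(3, 11, 17))), noiseSd = 0, seed = 22)
  syn2 <- makeZmapCohort(rec2)
  above <- vapply(cohortMaps(syn2$cohort),
                  function(m) all(voxelData(m)[idx] > 3.1), logical(1))
  expect_equal(sum(above), 3)
  expect_equal(which(above), c(3L, 11L, 17L))
  expect_equal(syn2$subjects$member, seq_len(24) %in% c(3, 11, 17))
  ## weak ROI amplitudes straddle the significance level
  rec3 <- cohortRecipe(n = 20, roiSpecs = list(
    roiSpec("pMTG", "common_weak", center = c(8, 8, 8), radiusVox = 2)),
    noiseSd = 0, seed = 23)
  syn3 <- makeZmapCohort(rec3)
  amps <- syn3$subjects$amplitude
  expect_true(all(amps >= 1.5 & amps <= 4.5))
  expect_true(any(amps < 3.1) && any(amps > 3.1))
})

test_that("same recipe and seed reproduce bitwise-identical cohorts", {
  rec <- cohortRecipe(n = 4, roiSpecs = list(
    roiSpec("a", "common_weak", c(6, 6, 6), 2)),
    noiseSd = 1, jitterMaxVoxels = 1, seed = 99)
  a <- makeZmapCohort(rec)
  b <- makeZmapCohort(rec)
  for (s in 1:4)
    expect_identical(voxelData(cohortMaps(a$cohort)[[s]]),
                     voxelData(cohortMaps(b$cohort)[[s]]))
  expect_identical(a$subjects, b$subjects)
})

test_that("lesioned subjects have the lesion region forced to zero", {
  rec <- cohortRecipe(n = 3, roiSpecs = list(
    roiSpec("net", "common_strong", c(8, 8, 8), 3)),
    lesionSpec = list(center = c(8, 8, 8), radiusVox = 1, subjects = 2L),
    noiseSd = 0, seed = 5)
  syn <- makeZmapCohort(rec)
  expect_equal(voxelData(cohortMaps(syn$cohort)[[2]])[9, 9, 9], 0)
  expect_gt(voxelData(cohortMaps(syn$cohort)[[1]])[9, 9, 9], 3.1)
})

test_that("BOLD simulation has the right volume count and noiseless recovery", {
  d <- makeDesign("verio")
  rec <- cohortRecipe(n = 1, gridShape = c(6L, 6L, 6L), roiSpecs = list(
    roiSpec("r", "common_strong", c(3, 3, 3), 1, amplitude = 2.5)),
    noiseSd = 0, seed = 13)
  sim <- simulateBoldCohort(d, rec)
  expect_equal(sim$nVolumes, 107)  # floor(322 / 3.0)
  expect_equal(dim(sim$data[[1]])[4], 107)
  X <- buildDesignMatrix(d, 107)
  fit <- fitGlmContrast(sim$data[[1]], X, "semantic-line", what = "fit")
  expect_equal(fit$cope[4, 4, 4], 2.5, tolerance = 1e-6)
  expect_equal(fit$cope[1, 1, 1], 0, tolerance = 1e-6)
  ## planted voxels hit the z ceiling in the noiseless limit
  expect_equal(fit$z[4, 4, 4], 8.2)
  ## TR longer than the shortest block is rejected
  dBad <- makeDesign("custom", blockSequence = makeDesign("verio")@blockSequence,
                     trS = 15)
  expect_error(simulateBoldCohort(dBad, rec), "TR longer")
})

test_that("null BOLD cohorts yield approximately standard-normal z-maps", {
  d <- makeDesign("verio")
  rec <- cohortRecipe(n = 1, gridShape = c(22L, 22L, 22L), roiSpecs = list(),
                      noiseSd = 1, seed = 31)
  sim <- simulateBoldCohort(d, rec)
  X <- buildDesignMatrix(d, sim$nVolumes)
  z <- voxelData(fitGlmContrast(sim$data[[1]], X, "semantic-line",
                                subjectId = "null"))
  expect_gt(length(z), 1e4)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("null cohorts give lower top-end consistency than planted cohorts", {
  recNull <- cohortRecipe(n = 8, gridShape = c(12L, 12L, 12L),
                          roiSpecs = list(), noiseSd = 1, seed = 41)
  recSig <- cohortRecipe(n = 8, gridShape = c(12L, 12L, 12L),
                         roiSpecs = list(roiSpec("net", "common_strong",
                                                 c(6, 6, 6), 2)),
                         noiseSd = 1, seed = 41)
  cNull <- voxelData(computeTwomMap(makeZmapCohort(recNull)$cohort))
  cSig <- voxelData(computeTwomMap(makeZmapCohort(recSig)$cohort))
  expect_lt(quantile(cNull, 0.99), quantile(cSig, 0.99))
})
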