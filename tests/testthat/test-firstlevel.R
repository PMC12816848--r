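test_that("design matrix has convolved task columns, intercept and drift", {
  d <- makeDesign("verio")
  X <- buildDesignMatrix(d, 107, highpassS = 100)
  M <- designMatrix(X)
  expect_equal(sum(grepl("^drift_", colnames(M))), 6)  # floor(2*321/100)
  expect_true(all(c("semantic", "line", "intercept") %in% colnames(M)))
  ## the convolved semantic response peaks with hemodynamic delay:
  ## correlation with the boxcar shifted ~5 s beats the unshifted boxcar
  sched <- twomapper:::.designSchedule(d)
  scanT <- (0:106) * 3
  box <- function(lag) {
    b <- numeric(107)
    for (i in which(sched$condition == "semantic"))
      b[scanT >= sched$onset[i] + lag &
        scanT < sched$onset[i] + sched$duration[i] + lag] <- 1
    b
  }
  expect_gt(cor(M[, "semantic"], box(5)), cor(M[, "semantic"], box(0)))
  ## first semantic block starts at t=0: response at 2 s is far below peak
  expect_lt(M[2, "semantic"], 0.6 * max(M[, "semantic"]))
  ## missing condition and short runs are rejected
  dNoLine <- makeDesign("custom",
                        blockSequence = c("semantic", "fixation", "semantic"),
                        trS = 3)
  expect_error(buildDesignMatrix(dNoLine, 50), "line")
  expect_error(buildDesignMatrix(d, 50), "shorter")
})

test_that("t to z conversion is monotone and matches the quantile oracle", {
  ## frozen dual-oracle value (R qnorm/pt and scipy agree): z(2, 100) = 1.9755
  expect_equal(twomapper:::.tToZ(2, 100), 1.975493, tolerance = 1e-3)
  expect_equal(twomapper:::.tToZ(-2, 100), -1.975493, tolerance = 1e-3)
  expect_equal(twomapper:::.tToZ(0, 100), 0)
  t <- seq(-10, 10, by = 0.25)
  z <- twomapper:::.tToZ(t, 12)
  expect_true(all(diff(z) >= 0))
  expect_true(all(abs(z) <= 8.2))
  expect_equal(twomapper:::.tToZ(1e12, 5), 8.2)
})

test_that("contrast estimates are invariant to orthogonal confounds", {
  d <- makeDesign("verio")
  rec <- cohortRecipe(n = 1, gridShape = c(5L, 5L, 5L), roiSpecs = list(
    roiSpec("r", "common_strong", c(2, 2, 2), 1, amplitude = 3)),
    noiseSd = 0.5, seed = 8)
  sim <- simulateBoldCohort(d, rec)
  X <- buildDesignMatrix(d, sim$nVolumes, highpassS = NULL)
  fit1 <- fitGlmContrast(sim$data[[1]], X, "semantic-line", what = "fit")
  ## add a confound column orthogonal to all existing columns
  M <- designMatrix(X)
  set.seed(1)
  conf <- residuals(lm(rnorm(nrow(M)) ~ M))
  M2 <- cbind(M, confound = conf)
  X2 <- new("DesignMatrix", matrix = M2, trS = 3)
  fit2 <- fitGlmContrast(sim$data[[1]], X2,
                         c(1, -1, rep(0, ncol(M2) - 2)), what = "fit")
  expect_equal(fit2$cope, fit1$cope, tolerance = 1e-9)
  ## rank-deficient design is rejected
  X3 <- new("DesignMatrix", matrix = cbind(M, dup = M[, "semantic"]), trS = 3)
  expect_error(fitGlmContrast(sim$data[[1]], X3, "semantic-line"),
               "rank-deficient")
})

test_that("null z-maps have the advertised upper tail at z > 3.1", {
  d <- makeDesign("verio")
  rec <- cohortRecipe(n = 1, gridShape = c(32L, 32L, 32L), roiSpecs = list(),
                      noiseSd = 1, seed = 55)
  sim <- simulateBoldCohort(d, rec)
  X <- buildDesignMatrix(d, sim$nVolumes)
  z <- voxelData(fitGlmContrast(sim$data[[1]], X, "semantic-line"))
  n <- length(z)
  for (u in c(2, 3, 3.1)) {
    p <- pnorm(-u)
    expect_lt(abs(mean(z > u) - p), 4 * sqrt(p * (1 - p) / n) + 0.2 * p)
  }
})

test_that("cluster-extent thresholding follows size and connectivity rules", {
  vol <- array(0, c(12, 12, 12))
  expect_equal(sum(clusterThresholdMap(array(3.0, c(6, 6, 6)), 3.1, 10)), 0)
  ## single 12-voxel blob at z=4 survives min extent 10
  vol[3:6, 3, 3] <- 4; vol[3:6, 4, 3] <- 4; vol[3:6, 3, 4] <- 4
  m <- clusterThresholdMap(vol, 3.1, 10)
  expect_equal(sum(m), 12)
  ## two blobs of 9 and 10 voxels: only the 10-voxel blob survives
  vol2 <- array(0, c(14, 14, 14))
  vol2[2:10, 2, 2] <- 4                     # 9 voxels
  vol2[2:11, 8, 8] <- 4                     # 10 voxels
  m2 <- clusterThresholdMap(vol2, 3.1, 10)
  expect_equal(sum(m2), 10)
  expect_true(all(which(m2) %in% which(vol2 == 4 &
    slice.index(vol2, 2) == 8)))
})
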