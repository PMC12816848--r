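## Synthetic cohorts with planted ground truth.
##
## Two modes: direct z-map cohorts (the fixture for overlap mapping) and
## block-design BOLD time series (the fixture for the first-level GLM). All
## randomness is fixed by the recipe seed.

.DEFAULT_SEQUENCE <- c("semantic", "line", "semantic", "line", "fixation",
                       "semantic", "line", "semantic", "line", "fixation",
                       "semantic", "line", "semantic", "fixation",
                       "line", "semantic", "line", "fixation")

#' Construct a block-design specification
#'
#' `verio` and `prisma` variants differ only in TR (3.0 s clinical vs 0.933 s
#' multiband research sequence). The default paradigm alternates 7 semantic
#' and 7 line-matching blocks — each 4 trials of 4 s followed by a 3 s
#' inter-block delay — with 4 resting fixation blocks of 14 s interleaved
#' after every 3-4 active blocks, totalling 322 s.
#'
#' @param variant "verio", "prisma" or "custom".
#' @param blockSequence block label sequence; required for "custom".
#' @param trS repetition time in seconds; defaults from the variant.
#' @param trialDurationS,trialsPerBlock,interBlockDelayS,fixationDurationS
#'   timing parameters (seconds / counts).
#' @return a [DesignSpec-class].
#' @examples
#' makeDesign("verio")
#' designTotalDuration(makeDesign("prisma"))
#' @export
makeDesign <- function(variant = c("verio", "prisma", "custom"),
                       blockSequence = NULL, trS = NULL,
                       trialDurationS = 4, trialsPerBlock = 4,
                       interBlockDelayS = 3, fixationDurationS = 14) {
  variant <- match.arg(variant)
  if (variant == "custom" && is.null(blockSequence))
    stop("custom design requires an explicit blockSequence")
  if (is.null(blockSequence)) blockSequence <- .DEFAULT_SEQUENCE
  if (is.null(trS))
    trS <- switch(variant, verio = 3.0, prisma = 0.933,
                  stop("custom design requires an explicit trS"))
  new("DesignSpec", blockSequence = blockSequence,
      trialDurationS = trialDurationS, trialsPerBlock = trialsPerBlock,
      interBlockDelayS = interBlockDelayS,
      fixationDurationS = fixationDurationS, trS = trS)
}

## Block schedule: condition, onset (s), duration (s). Active blocks are
## followed by the inter-block delay; fixation blocks are not.
.designSchedule <- function(design) {
  t0 <- 0
  rows <- lapply(design@blockSequence, function(b) {
    dur <- if (b == "fixation") design@fixationDurationS else
      design@trialsPerBlock * design@trialDurationS
    row <- data.frame(condition = b, onset = t0, duration = dur)
    t0 <<- t0 + dur + if (b == "fixation") 0 else design@interBlockDelayS
    row
  })
  sched <- do.call(rbind, rows)
  attr(sched, "total") <- t0
  sched
}

#' @rdname makeDesign
#' @param design a [DesignSpec-class].
#' @return `designTotalDuration`: total run duration in seconds.
#' @export
designTotalDuration <- function(design) {
  attr(.designSchedule(design), "total")
}

#' Specify a planted region of interest
#'
#' @param roiId short identifier.
#' @param rule amplitude rule: `"common_strong"` (every subject gets
#'   `amplitude`, default 6, well above significance), `"common_weak"` (each
#'   subject draws an amplitude uniformly from `weakRange`, a range straddling
#'   the z = 3.1 significance level) or `"subgroup"` (only the `members` get
#'   `amplitude`).
#' @param center 0-based voxel triple, nominal ROI centre.
#' @param radiusVox sphere radius in voxels.
#' @param amplitude added z (signal) amplitude for strong/subgroup rules.
#' @param weakRange length-2 amplitude range for `"common_weak"`.
#' @param members subject indices (1-based into the cohort) for `"subgroup"`.
#' @return a list consumed by [cohortRecipe()].
#' @export
roiSpec <- function(roiId, rule = c("common_strong", "common_weak", "subgroup"),
                    center, radiusVox = 2, amplitude = 6,
                    weakRange = c(1.5, 4.5), members = integer(0)) {
  rule <- match.arg(rule)
  if (rule == "subgroup" && !length(members))
    stop("subgroup ROI needs member subject indices")
  list(roiId = roiId, rule = rule, center = as.integer(center),
       radiusVox = radiusVox, amplitude = amplitude, weakRange = weakRange,
       members = as.integer(members))
}

#' Construct a synthetic-cohort recipe
#'
#' @param n number of subjects.
#' @param gridShape integer triple (default 16^3).
#' @param roiSpecs list of [roiSpec()] entries.
#' @param noiseSd marginal sd of the smoothed background noise (1 emulates a
#'   null z-map; 0 gives noiseless cohorts).
#' @param smoothingFwhmMm background smoothing FWHM in mm (default 6, a
#'   typical effective smoothness of preprocessed fMRI).
#' @param jitterMaxVoxels per-subject ROI translation drawn uniformly from
#'   `-jitterMaxVoxels..jitterMaxVoxels` per axis (emulates residual
#'   anatomical variability after registration).
#' @param lesionSpec optional `list(center=, radiusVox=, subjects=)`: a
#'   signal-void region forced to 0 in the listed subjects.
#' @param voxelSizeMm isotropic voxel size (default 2, template grid).
#' @param seed integer controlling all randomness.
#' @return a [CohortRecipe-class].
#' @export
cohortRecipe <- function(n, gridShape = c(16L, 16L, 16L), roiSpecs = list(),
                         noiseSd = 1, smoothingFwhmMm = 6,
                         jitterMaxVoxels = 0L, lesionSpec = list(),
                         voxelSizeMm = 2, seed = 1L) {
  new("CohortRecipe", n = as.integer(n), gridShape = as.integer(gridShape),
      voxelSizeMm = voxelSizeMm, roiSpecs = roiSpecs, noiseSd = noiseSd,
      smoothingFwhmMm = smoothingFwhmMm,
      jitterMaxVoxels = as.integer(jitterMaxVoxels), lesionSpec = lesionSpec,
      seed = as.integer(seed))
}

## 0-based voxel coordinates of a sphere, clipped to the grid.
.sphereVoxels <- function(center, radiusVox, gridShape) {
  r <- floor(radiusVox)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g <- g[sqrt(rowSums(g^2)) <= radiusVox + 1e-9, , drop = FALSE]
  vox <- t(t(as.matrix(g)) + as.integer(center))
  ok <- vox[, 1L] >= 0 & vox[, 1L] <= gridShape[1L] - 1L &
        vox[, 2L] >= 0 & vox[, 2L] <= gridShape[2L] - 1L &
        vox[, 3L] >= 0 & vox[, 3L] <= gridShape[3L] - 1L
  if (!all(ok)) stop("ROI extends outside the grid")
  storage.mode(vox) <- "integer"
  unname(vox)
}

## Per-subject amplitude matrix (n x nROI) and jitter offsets (n x 3),
## drawn deterministically from the recipe seed.
.recipeDraws <- function(recipe) {
  set.seed(recipe@seed)
  n <- recipe@n
  nroi <- length(recipe@roiSpecs)
  amp <- matrix(0, n, max(nroi, 1L))
  for (j in seq_len(nroi)) {
    r <- recipe@roiSpecs[[j]]
    amp[, j] <- switch(r$rule,
      common_strong = rep(r$amplitude, n),
      common_weak = stats::runif(n, r$weakRange[1L], r$weakRange[2L]),
      subgroup = {
        a <- numeric(n); a[r$members] <- r$amplitude; a
      })
  }
  jit <- matrix(0L, n, 3L)
  if (recipe@jitterMaxVoxels > 0L)
    jit <- matrix(sample.int(2L * recipe@jitterMaxVoxels + 1L, 3L * n,
                             replace = TRUE) - recipe@jitterMaxVoxels - 1L,
                  n, 3L)
  list(amp = amp, jit = jit)
}

#' Generate a synthetic cohort of z-maps with planted ground truth
#'
#' Each subject's map is spatially smoothed zero-mean Gaussian noise
#' (rescaled so the marginal sd equals `noiseSd`) plus the recipe's ROI
#' amplitudes at per-subject jittered locations; lesioned subjects have the
#' lesion region forced to 0. The ground truth returned alongside the cohort
#' attributes every planted ROI voxel to exactly one rule and lists the
#' per-subject amplitudes, which is sufficient to score recovery.
#'
#' @param recipe a [CohortRecipe-class].
#' @return list with elements `cohort` (a [Cohort-class]), `voxels`
#'   (data.frame roi_id, rule, vx, vy, vz — nominal, unjittered 0-based voxel
#'   coordinates), and `subjects` (data.frame roi_id, subject_id, amplitude,
#'   jitter_x/y/z, member flag).
#' @examples
#' rec <- cohortRecipe(n = 5, roiSpecs = list(
#'   roiSpec("net", "common_strong", center = c(8, 8, 8), radiusVox = 2)),
#'   noiseSd = 0.5, seed = 42)
#' syn <- makeZmapCohort(rec)
#' syn$cohort
#' @export
makeZmapCohort <- function(recipe) {
  validObject(recipe)
  gs <- recipe@gridShape
  aff <- diag(c(rep(recipe@voxelSizeMm, 3L), 1))
  draws <- .recipeDraws(recipe)
  roiVox <- lapply(recipe@roiSpecs, function(r)
    .sphereVoxels(r$center, r$radiusVox, gs))
  lesVox <- if (length(recipe@lesionSpec))
    .sphereVoxels(recipe@lesionSpec$center, recipe@lesionSpec$radiusVox, gs)
  else NULL
  spacing <- rep(recipe@voxelSizeMm, 3L)
  maps <- vector("list", recipe@n)
  for (s in seq_len(recipe@n)) {
    vol <- array(0, gs)
    if (recipe@noiseSd > 0) {
      vol <- array(stats::rnorm(prod(gs)), gs)
      vol <- .smoothVolume(vol, recipe@smoothingFwhmMm, spacing)
      vol <- vol / attr(vol, "sdFactor") * recipe@noiseSd
      attr(vol, "sdFactor") <- NULL
    }
    for (j in seq_along(recipe@roiSpecs)) {
      a <- draws$amp[s, j]
      if (a == 0) next
      vox <- t(t(roiVox[[j]]) + draws$jit[s, ])
      ok <- vox[, 1L] >= 0 & vox[, 1L] <= gs[1L] - 1L &
            vox[, 2L] >= 0 & vox[, 2L] <= gs[2L] - 1L &
            vox[, 3L] >= 0 & vox[, 3L] <= gs[3L] - 1L
      vox <- vox[ok, , drop = FALSE]
      idx <- vox[, 1L] + 1L + gs[1L] * vox[, 2L] + gs[1L] * gs[2L] * vox[, 3L]
      vol[idx] <- vol[idx] + a
    }
    if (!is.null(lesVox) && s %in% recipe@lesionSpec$subjects) {
      idx <- lesVox[, 1L] + 1L + gs[1L] * lesVox[, 2L] +
             gs[1L] * gs[2L] * lesVox[, 3L]
      vol[idx] <- 0
    }
    maps[[s]] <- new("StatMap", subjectId = sprintf("sub-%02d", s),
                     data = vol, affine = aff)
  }
  truthVox <- do.call(rbind, c(list(
    data.frame(roi_id = character(0), rule = character(0),
               vx = integer(0), vy = integer(0), vz = integer(0))),
    lapply(seq_along(recipe@roiSpecs), function(j)
      data.frame(roi_id = recipe@roiSpecs[[j]]$roiId,
                 rule = recipe@roiSpecs[[j]]$rule,
                 vx = roiVox[[j]][, 1L], vy = roiVox[[j]][, 2L],
                 vz = roiVox[[j]][, 3L]))))
  truthSub <- do.call(rbind, c(list(
    data.frame(roi_id = character(0), subject_id = character(0),
               amplitude = numeric(0), jitter_x = integer(0),
               jitter_y = integer(0), jitter_z = integer(0),
               member = logical(0))),
    lapply(seq_along(recipe@roiSpecs), function(j)
      data.frame(roi_id = recipe@roiSpecs[[j]]$roiId,
                 subject_id = sprintf("sub-%02d", seq_len(recipe@n)),
                 amplitude = draws$amp[, j],
                 jitter_x = draws$jit[, 1L], jitter_y = draws$jit[, 2L],
                 jitter_z = draws$jit[, 3L],
                 member = draws$amp[, j] != 0))))
  list(cohort = newCohort(maps), voxels = truthVox, subjects = truthSub)
}

#' Simulate block-design BOLD time series for a cohort
#'
#' Each voxel's series is `baseline` plus, per condition, the planted
#' amplitude times the HRF-convolved boxcar sampled at the TR, plus white
#' Gaussian noise of sd `recipe@noiseSd`. ROI amplitudes are planted on the
#' semantic regressor only, so the semantic-vs-line contrast equals the
#' recipe amplitude. The number of volumes is `floor(total duration / TR)`.
#'
#' @param design a [DesignSpec-class].
#' @param recipe a [CohortRecipe-class]; `noiseSd` is here the temporal
#'   noise sd in signal units.
#' @param baseline constant signal offset (arbitrary units).
#' @return list with `data` (list of 4-D arrays, one per subject), `affine`,
#'   `nVolumes`, and the same `voxels`/`subjects` truth tables as
#'   [makeZmapCohort()].
#' @export
simulateBoldCohort <- function(design, recipe, baseline = 100) {
  validObject(design); validObject(recipe)
  total <- designTotalDuration(design)
  minBlock <- min(design@fixationDurationS,
                  design@trialsPerBlock * design@trialDurationS)
  if (design@trS > minBlock)
    stop("TR longer than the shortest block")
  nvol <- floor(total / design@trS)
  gs <- recipe@gridShape
  nvox <- prod(gs)
  reg <- .convolvedRegressors(design, nvol)   # nvol x 2 (semantic, line)
  draws <- .recipeDraws(recipe)
  roiVox <- lapply(recipe@roiSpecs, function(r)
    .sphereVoxels(r$center, r$radiusVox, gs))
  dat <- vector("list", recipe@n)
  for (s in seq_len(recipe@n)) {
    ampVol <- numeric(nvox)
    for (j in seq_along(recipe@roiSpecs)) {
      a <- draws$amp[s, j]
      if (a == 0) next
      vox <- t(t(roiVox[[j]]) + draws$jit[s, ])
      ok <- vox[, 1L] >= 0 & vox[, 1L] <= gs[1L] - 1L &
            vox[, 2L] >= 0 & vox[, 2L] <= gs[2L] - 1L &
            vox[, 3L] >= 0 & vox[, 3L] <= gs[3L] - 1L
      vox <- vox[ok, , drop = FALSE]
      idx <- vox[, 1L] + 1L + gs[1L] * vox[, 2L] + gs[1L] * gs[2L] * vox[, 3L]
      ampVol[idx] <- ampVol[idx] + a
    }
    ts <- baseline + outer(ampVol, reg[, "semantic"])
    if (recipe@noiseSd > 0)
      ts <- ts + stats::rnorm(length(ts), sd = recipe@noiseSd)
    dat[[s]] <- array(t(ts), c(nvol, gs))        # time-major for a moment
    dat[[s]] <- aperm(dat[[s]], c(2:4, 1L))      # -> x,y,z,t
  }
  truth <- makeZmapTruthTables(recipe, draws, roiVox)
  c(list(data = dat, affine = diag(c(rep(recipe@voxelSizeMm, 3L), 1)),
         nVolumes = nvol, design = design), truth)
}

## shared truth-table builder (kept in sync with makeZmapCohort)
makeZmapTruthTables <- function(recipe, draws, roiVox) {
  truthVox <- do.call(rbind, c(list(
    data.frame(roi_id = character(0), rule = character(0),
               vx = integer(0), vy = integer(0), vz = integer(0))),
    lapply(seq_along(recipe@roiSpecs), function(j)
      data.frame(roi_id = recipe@roiSpecs[[j]]$roiId,
                 rule = recipe@roiSpecs[[j]]$rule,
                 vx = roiVox[[j]][, 1L], vy = roiVox[[j]][, 2L],
                 vz = roiVox[[j]][, 3L]))))
  truthSub <- do.call(rbind, c(list(
    data.frame(roi_id = character(0), subject_id = character(0),
               amplitude = numeric(0), member = logical(0))),
    lapply(seq_along(recipe@roiSpecs), function(j)
      data.frame(roi_id = recipe@roiSpecs[[j]]$roiId,
                 subject_id = sprintf("sub-%02d", seq_len(recipe@n)),
                 amplitude = draws$amp[, j],
                 member = draws$amp[, j] != 0))))
  list(voxels = truthVox, subjects = truthSub)
}

## HRF-convolved boxcars for the two task conditions, sampled at scan times
## (k-1)*TR, k = 1..nvol. Fine-grid (dt = 0.1 s) convolution.
.convolvedRegressors <- function(design, nvol) {
  sched <- .designSchedule(design)
  dt <- 0.1
  total <- max(attr(sched, "total"), nvol * design@trS)
  tfine <- seq(0, total + 32, by = dt)
  hrf <- .canonicalHrf(seq(0, 32, by = dt))
  out <- matrix(0, nvol, 2L, dimnames = list(NULL, c("semantic", "line")))
  scanT <- (seq_len(nvol) - 1L) * design@trS
  for (cond in c("semantic", "line")) {
    box <- numeric(length(tfine))
    for (i in which(sched$condition == cond)) {
      on <- sched$onset[i]; off <- on + sched$duration[i]
      box[tfine >= on & tfine < off] <- 1
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(tfine)] * dt
    out[, cond] <- stats::approx(tfine, conv, xout = scanT, rule = 2)$y
  }
  out
}
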