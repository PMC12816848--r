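## Minimal first-level GLM: design construction, voxelwise OLS contrast with
## t -> z conversion, and fixed-extent cluster thresholding.

#' Build a GLM design matrix for a block design
#'
#' One column per task condition (HRF-convolved boxcar sampled at the TR),
#' plus an intercept and, when `highpassS` is set, a cosine drift basis whose
#' columns span fluctuations slower than the cutoff — the standard discrete
#' cosine surrogate for high-pass filtering, applied identically to data and
#' regressors by inclusion in the model. The number of drift columns is
#' `floor(2 * T / highpassS)` for a run of length T seconds.
#'
#' @param design a [DesignSpec-class].
#' @param nVolumes number of acquired volumes; must cover the design.
#' @param highpassS high-pass cutoff in seconds (default 100), or `NULL` for
#'   no drift columns.
#' @return a [DesignMatrix-class].
#' @examples
#' X <- buildDesignMatrix(makeDesign("verio"), nVolumes = 107)
#' colnames(designMatrix(X))
#' @export
buildDesignMatrix <- function(design, nVolumes, highpassS = 100) {
  total <- designTotalDuration(design)
  if (nVolumes < floor(total / design@trS))
    stop(sprintf("nVolumes (%d) shorter than the design (%d volumes needed)",
                 nVolumes, floor(total / design@trS)))
  for (cond in c("semantic", "line"))
    if (!cond %in% design@blockSequence)
      stop("design has no events for condition '", cond, "'")
  reg <- .convolvedRegressors(design, nVolumes)
  X <- cbind(reg, intercept = 1)
  if (!is.null(highpassS) && highpassS > 0) {
    Tlen <- nVolumes * design@trS
    K <- floor(2 * Tlen / highpassS)
    if (K > 0) {
      j <- seq_len(nVolumes) - 0.5
      drift <- vapply(seq_len(K), function(k) cos(pi * k * j / nVolumes),
                      numeric(nVolumes))
      colnames(drift) <- sprintf("drift_%d", seq_len(K))
      X <- cbind(X, drift)
    }
  }
  new("DesignMatrix", matrix = X, trS = design@trS)
}

#' @rdname buildDesignMatrix
#' @param x a [DesignMatrix-class].
#' @return `designMatrix`: the plain numeric matrix.
#' @export
designMatrix <- function(x) x@matrix

## Resolve a contrast given as numeric weights or "a-b" column names.
.resolveContrast <- function(X, contrast) {
  cn <- colnames(X)
  if (is.character(contrast)) {
    parts <- strsplit(contrast, "-", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !all(parts %in% cn))
      stop("contrast '", contrast, "' must be of the form 'colA-colB'")
    w <- numeric(length(cn)); names(w) <- cn
    w[parts[1L]] <- 1; w[parts[2L]] <- -1
    return(w)
  }
  if (length(contrast) == ncol(X)) return(as.numeric(contrast))
  ## short numeric contrasts are padded with zeros over confound columns
  c(as.numeric(contrast), numeric(ncol(X) - length(contrast)))
}

#' Fit a voxelwise GLM contrast and convert to z
#'
#' Ordinary least squares per voxel; t = c'b / sqrt(s2 * c'(X'X)^-1 c) with
#' the residual variance at (volumes - rank) degrees of freedom; z is the
#' sign-preserving normal quantile of the t tail probability, clipped to
#' +/- 8.2.
#'
#' @param data 4-D array (x, y, z, time).
#' @param design a [DesignMatrix-class] whose rows match the volumes.
#' @param contrast numeric weight vector (length = number of regressors, or
#'   shorter — zero-padded over confounds), or a string like
#'   `"semantic-line"`.
#' @param affine 4x4 voxel-to-mm matrix for the output map.
#' @param subjectId identifier for the output [StatMap-class].
#' @param what `"z"` (default) returns the z StatMap; `"fit"` returns a list
#'   with `z`, `t`, `cope` (contrast of parameter estimates) arrays and `dof`.
#' @return a [StatMap-class] of z-statistics, or the fit list.
#' @export
fitGlmContrast <- function(data, design, contrast, affine = diag(4),
                           subjectId = "glm", what = c("z", "fit")) {
  what <- match.arg(what)
  X <- design@matrix
  dm <- dim(data)
  if (length(dm) != 4L) stop("data must be a 4-D array (x, y, z, time)")
  if (dm[4L] != nrow(X))
    stop("data has ", dm[4L], " volumes but the design has ", nrow(X), " rows")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient design matrix")
  if (nrow(X) < ncol(X) + 2L)
    stop("fewer volumes than regressors + 2")
  w <- .resolveContrast(X, contrast)
  Y <- matrix(data, prod(dm[1:3]), dm[4L])        # voxels x time
  beta <- t(qr.coef(qrX, t(Y)))                   # voxels x regressors
  resid <- Y - beta %*% t(X)
  dof <- nrow(X) - qrX$rank
  s2 <- rowSums(resid^2) / dof
  XtXinv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(w) %*% XtXinv %*% w)
  cope <- drop(beta %*% w)
  se <- sqrt(s2 * cvar)
  tstat <- ifelse(se > 0, cope / se, sign(cope) * Inf)
  tstat[cope == 0 & se == 0] <- 0
  z <- .tToZ(ifelse(is.finite(tstat), tstat, sign(tstat) * 1e12), dof)
  zvol <- array(z, dm[1:3])
  if (what == "fit")
    return(list(z = zvol, t = array(tstat, dm[1:3]),
                cope = array(cope, dm[1:3]), dof = dof))
  new("StatMap", subjectId = subjectId, data = zvol, affine = affine)
}

#' Threshold a z-map with a cluster-extent filter
#'
#' Voxels with z >= `zThresh` are retained only when their connected
#' component has at least `minExtentVoxels` voxels. Extent-based filtering is
#' a deliberate, simpler stand-in for random-field corrected cluster
#' inference; the default extent of 10 voxels matches the relevant-voxel
#' heuristics.
#'
#' @param zmap a [StatMap-class] or 3-D array.
#' @param zThresh cluster-forming threshold (default 3.1).
#' @param minExtentVoxels minimum surviving component size (default 10).
#' @param connectivity 26 (default) or 6.
#' @return 3-D logical array.
#' @export
clusterThresholdMap <- function(zmap, zThresh = 3.1, minExtentVoxels = 10L,
                                connectivity = 26L) {
  stopifnot(zThresh >= 0)
  vol <- if (is(zmap, "StatMap")) zmap@data else zmap
  lab <- .connectedComponents(vol >= zThresh, as.integer(connectivity))
  if (!any(lab > 0L)) return(array(FALSE, dim(vol)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= minExtentVoxels)
  array(lab %in% keep, dim(vol))
}
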