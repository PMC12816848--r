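## Internal numeric/image helpers shared across modules.

## Half neighbourhood offsets (one per unordered pair direction).
.halfOffsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), ncol = 3L, byrow = TRUE)
  } else {
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ## keep strictly "positive" directions: first nonzero component > 0
    keep <- apply(off, 1L, function(d) {
      nz <- which(d != 0L)
      length(nz) > 0L && d[nz[1L]] > 0L
    })
    storage.mode(off) <- "integer"
    off[keep, , drop = FALSE]
  }
}

## 3-D connected-component labelling of a logical array.
## Adjacency edges are enumerated by shifting the mask; components come from
## igraph. Returns an integer array (0 = background), labels in arbitrary order.
.connectedComponents <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  nv <- length(idx)
  if (nv == 0L) return(lab)
  rank <- array(0L, dm)
  rank[idx] <- seq_len(nv)
  co <- arrayInd(idx, dm)
  offs <- .halfOffsets(connectivity)
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], nv, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= dm[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= dm[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= dm[3L]
    if (!any(ok)) next
    nidx <- nb[ok, 1L] + dm[1L] * (nb[ok, 2L] - 1L) +
            dm[1L] * dm[2L] * (nb[ok, 3L] - 1L)
    nr <- rank[nidx]
    hit <- nr > 0L
    if (any(hit)) {
      efrom <- c(efrom, rank[idx[ok]][hit])
      eto <- c(eto, nr[hit])
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(efrom))
    g <- igraph::add_edges(g, rbind(efrom, eto))
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

## Integer voxel offsets whose centre-to-centre mm displacement is <= radiusMm.
.neighborOffsets <- function(affine, radiusMm) {
  R <- affine[1:3, 1:3]
  spacing <- sqrt(colSums(R^2))
  if (radiusMm <= 0) return(matrix(0L, 1L, 3L))
  nmax <- pmax(0L, floor(radiusMm / spacing))
  off <- as.matrix(expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2],
                               dz = -nmax[3]:nmax[3]))
  disp <- off %*% t(R)
  keep <- sqrt(rowSums(disp^2)) <= radiusMm + 1e-9
  off <- off[keep, , drop = FALSE]
  storage.mode(off) <- "integer"
  off
}

## Neighbourhood sampling of a whole volume: per voxel, the max (or mean) of
## vol over the given integer offsets; out-of-grid neighbours are ignored.
.sampleVolume <- function(vol, offsets, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  dm <- dim(vol)
  if (aggregate == "max") {
    out <- array(-Inf, dm)
  } else {
    out <- array(0, dm)
    cnt <- array(0L, dm)
  }
  for (r in seq_len(nrow(offsets))) {
    d <- offsets[r, ]
    sx <- max(1L, 1L - d[1L]):min(dm[1L], dm[1L] - d[1L])
    sy <- max(1L, 1L - d[2L]):min(dm[2L], dm[2L] - d[2L])
    sz <- max(1L, 1L - d[3L]):min(dm[3L], dm[3L] - d[3L])
    if (!length(sx) || !length(sy) || !length(sz)) next
    dx <- sx + d[1L]; dy <- sy + d[2L]; dz <- sz + d[3L]
    if (aggregate == "max") {
      out[dx, dy, dz] <- pmax(out[dx, dy, dz], vol[sx, sy, sz])
    } else {
      out[dx, dy, dz] <- out[dx, dy, dz] + vol[sx, sy, sz]
      cnt[dx, dy, dz] <- cnt[dx, dy, dz] + 1L
    }
  }
  if (aggregate == "mean") out <- out / pmax(cnt, 1L)
  out
}

## Separable Gaussian smoothing along each axis via banded row-normalised
## kernel matrices. Returns the smoothed volume with attribute "sdFactor":
## the interior-voxel factor by which white-noise sd is reduced.
.smoothVolume <- function(vol, fwhmMm, spacingMm) {
  if (fwhmMm <= 0) {
    attr(vol, "sdFactor") <- 1
    return(vol)
  }
  dm <- dim(vol)
  sdFactor <- 1
  for (ax in 1:3) {
    sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / spacingMm[ax]
    hw <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-hw:hw)^2) / (2 * sigma^2))
    k <- k / sum(k)
    sdFactor <- sdFactor * sqrt(sum(k^2))
    d <- dm[ax]
    K <- matrix(0, d, d)
    for (j in seq_len(d)) {
      lo <- max(1L, j - hw); hi <- min(d, j + hw)
      kr <- k[(lo - j + hw + 1L):(hi - j + hw + 1L)]
      K[j, lo:hi] <- kr / sum(kr)
    }
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    pd <- dim(v)
    v <- K %*% matrix(v, pd[1L])
    dim(v) <- pd
    vol <- aperm(v, order(perm))
  }
  attr(vol, "sdFactor") <- sdFactor
  vol
}

## Canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 6),
## scaled to unit peak so planted amplitudes are in signal units.
.canonicalHrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
       stats::dgamma(t, shape = 16, rate = 1) / 6
  h / 0.17544120122995  # peak of the unscaled response (at t ~ 5.0 s)
}

## Sign-preserving t -> z conversion at given dof, computed in log-p space so
## extreme statistics stay accurate, then clipped to +/- Z_CLIP.
.tToZ <- function(t, dof) {
  z <- sign(t) * stats::qnorm(
    stats::pt(abs(t), df = dof, lower.tail = FALSE, log.p = TRUE),
    lower.tail = FALSE, log.p = TRUE)
  z[t == 0] <- 0
  pmin(pmax(z, -Z_CLIP), Z_CLIP)
}

## 0-based voxel triple -> linear 1-based index
.voxLinear <- function(vox, dm) {
  as.integer(vox[1L] + 1L + dm[1L] * vox[2L] + dm[1L] * dm[2L] * vox[3L])
}

.isInGrid <- function(vox, dm) {
  all(vox >= 0) && all(vox <= dm - 1L)
}
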