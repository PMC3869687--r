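#' Global gray-matter signal of an image
#'
#' The conventional global estimate: the mean of voxels whose value exceeds
#' one eighth of the overall mean.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @return positive scalar.
#' @export
computeGlobal <- function(vol) {
  m <- mean(vol@data)
  keep <- vol@data > m / 8
  if (!any(keep)) stop("no voxel exceeds the global threshold (mean/8)")
  mean(vol@data[keep])
}

#' Proportional scaling to a common global
#'
#' Rescales each image by target/global, with the target the arithmetic
#' mean of the globals, so all images share one global signal and gain
#' differences are absorbed before the GLM.
#'
#' @param images list of \linkS4class{Volume3D}.
#' @param globals one positive global value per image (defaults to
#'   [computeGlobal()] of each).
#' @return list of scaled \linkS4class{Volume3D}.
#' @export
proportionalScale <- function(images,
                              globals = vapply(images, computeGlobal,
                                               numeric(1))) {
  if (length(globals) != length(images))
    stop("one global value per image required")
  if (any(globals <= 0)) stop("globals must be positive")
  target <- mean(globals)
  mapply(function(im, g) {
    out <- im
    out@data <- im@data * (target / g)
    out
  }, images, globals, SIMPLIFY = FALSE)
}

#' Construct a two-group design
#'
#' @param images list of smoothed, normalized gray-matter
#'   \linkS4class{Volume3D}s on one grid.
#' @param groups factor (or character) with levels `control` and `patient`.
#' @return a \linkS4class{GroupDesign}.
#' @export
groupDesign <- function(images, groups) {
  groups <- factor(as.character(groups), levels = c("control", "patient"))
  new("GroupDesign", images = images, groups = groups)
}

designMatrixY <- function(design, maskThreshold = 0.05) {
  Y <- vapply(design@images, function(im) as.numeric(im@data),
              numeric(length(design@images[[1]]@data)))
  mask <- rowMeans(Y) > maskThreshold
  list(Y = Y, mask = mask)
}

#' Fit the two-group voxelwise GLM
#'
#' Mass-univariate two-group cell-means model at every voxel of the analysis
#' mask (voxels whose mean gray-matter density across subjects exceeds
#' `maskThreshold`): `t = (mean control - mean patient) / SE` with pooled
#' variance and `df = n - 2` (proportional scaling, not a covariate, handles
#' the global signal, so no degree of freedom is spent on it). The t map is
#' transformed to unit-normal Z via [tToZ()], and the residual smoothness
#' (FWHM per axis) is estimated from the spatial derivatives of the
#' standardized residuals for random-field cluster inference.
#'
#' @param design a \linkS4class{GroupDesign} of proportionally scaled
#'   images.
#' @param maskThreshold analysis-mask threshold on mean gray-matter density.
#' @return a \linkS4class{StatMaps}.
#' @export
fitTwoGroupGLM <- function(design, maskThreshold = 0.05) {
  dy <- designMatrixY(design, maskThreshold)
  dims <- dim(design@images[[1]]@data)
  g1 <- design@groups == "control"
  g2 <- design@groups == "patient"
  n1 <- sum(g1); n2 <- sum(g2)
  df <- n1 + n2 - 2L
  Ym <- dy$Y[dy$mask, , drop = FALSE]
  m1 <- rowMeans(Ym[, g1, drop = FALSE])
  m2 <- rowMeans(Ym[, g2, drop = FALSE])
  rss <- rowSums((Ym[, g1, drop = FALSE] - m1)^2) +
    rowSums((Ym[, g2, drop = FALSE] - m2)^2)
  sp <- sqrt(rss / df)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  tv <- numeric(length(se))
  ok <- se > 0
  tv[ok] <- (m1[ok] - m2[ok]) / se[ok]
  nZeroVar <- sum(!ok)
  if (nZeroVar > 0)
    warning(nZeroVar, " masked voxels had zero residual variance; t set to 0")

  tMap <- array(0, dims)
  tMap[dy$mask] <- tv
  zMap <- array(0, dims)
  zMap[dy$mask] <- tToZ(tv, df)
  maskArr <- array(dy$mask, dims)

  # residual smoothness from standardized residual derivatives
  R <- Ym - cbind(m1)[, rep(1, ncol(Ym))] * rep(g1, each = nrow(Ym)) -
    cbind(m2)[, rep(1, ncol(Ym))] * rep(g2, each = nrow(Ym))
  sdv <- sp
  sdv[sdv <= 0] <- Inf
  U <- R / sdv * sqrt((n1 + n2) / df)  # approx unit-variance fields
  vox <- voxelSize(design@images[[1]])
  nsub <- ncol(U)
  maskLin <- which(maskArr)
  uu <- array(0, c(dims, nsub))
  for (j in seq_len(nsub))
    uu[maskLin + (j - 1) * prod(dims)] <- U[, j]
  lam <- numeric(3)
  for (a in 1:3) {
    dif <- switch(a,
                  uu[-1, , , , drop = FALSE] - uu[-dims[1], , , , drop = FALSE],
                  uu[, -1, , , drop = FALSE] - uu[, -dims[2], , , drop = FALSE],
                  uu[, , -1, , drop = FALSE] - uu[, , -dims[3], , drop = FALSE])
    mboth <- switch(a,
                    maskArr[-1, , ] & maskArr[-dims[1], , ],
                    maskArr[, -1, ] & maskArr[, -dims[2], ],
                    maskArr[, , -1] & maskArr[, , -dims[3]])
    sel <- as.vector(mboth)
    if (!any(sel)) { lam[a] <- NA; next }
    d2 <- matrix(dif, ncol = nsub)[sel, , drop = FALSE]
    lam[a] <- mean(d2^2) / vox[a]^2
  }
  fwhm <- sqrt(4 * log(2) / pmax(lam, 1e-12))
  fwhm[!is.finite(fwhm)] <- max(dims * vox)
  fwhm <- pmin(fwhm, max(dims * vox))

  new("StatMaps", t = tMap, z = zMap, df = as.integer(df), mask = maskArr,
      residFwhmMm = fwhm, affine = design@images[[1]]@affine)
}

#' Transform t statistics to unit-normal Z scores
#'
#' `Z = qnorm(pt(t, df))` computed through complementary log-tail functions,
#' so extreme t (up to |t| ~ 40) maps without saturating at the double
#' precision limit; sign-preserving and strictly monotone.
#'
#' @param t numeric vector of t statistics.
#' @param df degrees of freedom.
#' @return numeric vector of Z scores.
#' @export
tToZ <- function(t, df) {
  stopifnot(df >= 1)
  z <- numeric(length(t))
  a <- abs(t)
  lp <- pt(a, df, lower.tail = FALSE, log.p = TRUE)
  z <- -qnorm(lp, log.p = TRUE)   # upper-tail quantile of |t|'s tail prob
  sign(t) * z
}

#' Threshold a t map and label suprathreshold clusters
#'
#' The suprathreshold set consists of masked voxels whose upper-tail t
#' probability is below `voxelP`; connected components are labeled at the
#' requested connectivity and components smaller than `extentK` voxels are
#' discarded.
#'
#' @param maps a \linkS4class{StatMaps}.
#' @param voxelP voxel-level upper-tail probability threshold.
#' @param connectivity 6, 18 or 26 (18, face+edge, is the conventional
#'   default).
#' @param extentK cluster-extent threshold in voxels.
#' @return list of clusters, each a list with `size` and `voxels` (1-based
#'   linear indices into the analysis grid); empty list if nothing survives.
#' @export
thresholdAndCluster <- function(maps, voxelP = 0.005, connectivity = 18L,
                                extentK = 0L) {
  stopifnot(voxelP > 0, voxelP < 1, connectivity %in% c(6L, 18L, 26L))
  tcrit <- qt(voxelP, maps@df, lower.tail = FALSE)
  supra <- maps@t > tcrit & maps@mask
  if (!any(supra)) return(list())
  lab <- cppLabelComponents(as.logical(supra), dim(supra),
                            as.integer(connectivity))
  sizes <- tabulate(lab)
  keep <- which(sizes >= max(extentK, 1L))
  out <- lapply(keep, function(k)
    list(size = sizes[k], voxels = which(lab == k)))
  out[order(-vapply(out, `[[`, numeric(1), "size"))]
}

#' Random-field cluster p-value
#'
#' Uncorrected cluster-level p from the Gaussian-random-field expected
#' cluster extent approximation: with the Z threshold u implied by `voxelP`,
#' the expected number of clusters comes from the 3D Euler-characteristic
#' density over the resel count of the analysis mask, the expected cluster
#' size from the suprathreshold volume, and
#' `P(extent >= k) = exp(-beta k^(2/3))`.
#'
#' @param clusterSize cluster size in voxels (vectorized).
#' @param maps a \linkS4class{StatMaps} with estimated residual smoothness.
#' @param voxelP the voxel threshold that defined the clusters.
#' @return p-values in (0, 1], decreasing in cluster size.
#' @export
clusterPRFT <- function(clusterSize, maps, voxelP = 0.005) {
  if (any(!is.finite(maps@residFwhmMm)) || any(maps@residFwhmMm <= 0))
    stop("non-finite residual smoothness estimate")
  u <- qnorm(voxelP, lower.tail = FALSE)
  vox <- voxelSize(volume3DFromMaps(maps))
  fwhmVox <- maps@residFwhmMm / vox
  V <- sum(maps@mask)
  resels <- V / prod(fwhmVox)
  rho3 <- (4 * log(2))^1.5 * (2 * pi)^(-2) * (u^2 - 1) * exp(-u^2 / 2)
  Em <- max(resels * rho3, 1e-12)
  EN <- V * pnorm(u, lower.tail = FALSE)
  En <- max(EN / Em, 1e-12)          # expected cluster size, voxels
  beta <- (gamma(2.5) / En)^(2 / 3)
  p <- exp(-beta * pmax(clusterSize, 0)^(2 / 3))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  # expected cluster count, attached so callers can convert the
  # uncorrected cluster p to a familywise (max-statistic) scale via
  # Poisson clumping: p_max = 1 - exp(-Em * p)
  attr(p, "expectedClusters") <- Em
  p
}

volume3DFromMaps <- function(maps)
  volume3D(maps@t, maps@affine, "other")

#' Permutation cluster p-values
#'
#' Relabeling null: for each permutation of the group labels the maximum
#' suprathreshold cluster size is recorded, and each observed cluster's
#' p-value is `(1 + #{perm max >= observed}) / (nPerm + 1)`.
#'
#' @param design the \linkS4class{GroupDesign} (proportionally scaled
#'   images).
#' @param observedSizes observed cluster sizes in voxels.
#' @param voxelP voxel threshold.
#' @param connectivity 6, 18 or 26.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @param maskThreshold analysis-mask threshold (must match the GLM's).
#' @return numeric vector of p-values, one per observed cluster.
#' @export
clusterPPerm <- function(design, observedSizes, voxelP = 0.005,
                         connectivity = 18L, nPerm = 2000L, seed = 1L,
                         maskThreshold = 0.05) {
  stopifnot(nPerm >= 100L)
  n <- length(design@groups)
  n1 <- sum(design@groups == "control")
  if (choose(n, n1) < 20)
    stop("too few distinct permutations (< 20) for a permutation test")
  dy <- designMatrixY(design, maskThreshold)
  Ym <- dy$Y[dy$mask, , drop = FALSE]
  df <- n - 2L
  tcrit <- qt(voxelP, df, lower.tail = FALSE)
  perms <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(i) {
      lab <- integer(n)
      lab[sample.int(n, n1)] <- 1L
      lab
    }, integer(n)))
  })
  maxsz <- cppPermMaxCluster(Ym, perms, tcrit,
                             which(dy$mask) - 1L,
                             dim(design@images[[1]]@data),
                             as.integer(connectivity))
  vapply(observedSizes, function(k) {
    if (k <= 0) return(1)
    (1 + sum(maxsz >= k)) / (nPerm + 1)
  }, numeric(1))
}

#' Benjamini-Hochberg selection over cluster p-values
#'
#' Step-up false discovery rate control across the cluster p-values
#' (topological FDR: the correction is over clusters, not voxels).
#'
#' @param clusterPs cluster p-values.
#' @param q FDR level.
#' @return logical vector of significance flags.
#' @export
fdrSelect <- function(clusterPs, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (!length(clusterPs)) return(logical(0))
  p.adjust(clusterPs, method = "BH") <= q
}

#' Assemble the cluster table
#'
#' One row per reported local peak (up to `maxPeaks` per cluster, at least
#' `peakSepMm` apart), with peak coordinates in world mm. Rows are ordered
#' by cluster size (descending), then peak t (descending) within a cluster.
#' Columns: `cluster_size_voxels`, `volume_mm3`, `peak_p_uncorrected`,
#' `peak_t`, `peak_z`, `x_mm`, `y_mm`, `z_mm`, `cluster_p`,
#' `fdr_significant`.
#'
#' @param clusters output of [thresholdAndCluster()].
#' @param maps the \linkS4class{StatMaps} the clusters came from.
#' @param clusterPs optional per-cluster p-values ([clusterPRFT()] or
#'   [clusterPPerm()]).
#' @param fdrSignificant optional per-cluster significance flags
#'   ([fdrSelect()]).
#' @param maxPeaks,peakSepMm peak reporting rule.
#' @return a `data.frame` cluster table.
#' @export
makeClusterTable <- function(clusters, maps, clusterPs = NULL,
                             fdrSignificant = NULL, maxPeaks = 3L,
                             peakSepMm = 8) {
  cols <- c("cluster_size_voxels", "volume_mm3", "peak_p_uncorrected",
            "peak_t", "peak_z", "x_mm", "y_mm", "z_mm", "cluster_p",
            "fdr_significant")
  if (!length(clusters)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                  cols))
    out$fdr_significant <- logical(0)
    return(out)
  }
  if (is.null(clusterPs)) clusterPs <- rep(NA_real_, length(clusters))
  if (is.null(fdrSignificant)) fdrSignificant <- rep(NA, length(clusters))
  dims <- dim(maps@t)
  voxVol <- prod(voxelSize(volume3DFromMaps(maps)))
  rows <- list()
  ord <- order(-vapply(clusters, `[[`, numeric(1), "size"))
  for (ci in ord) {
    cl <- clusters[[ci]]
    pk <- clusterPeaks(cl$voxels, maps, maxPeaks, peakSepMm)
    for (j in seq_len(nrow(pk))) {
      tv <- pk$t[j]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_size_voxels = cl$size,
        volume_mm3 = cl$size * voxVol,
        peak_p_uncorrected = pt(tv, maps@df, lower.tail = FALSE),
        peak_t = tv,
        peak_z = tToZ(tv, maps@df),
        x_mm = pk$x[j], y_mm = pk$y[j], z_mm = pk$z[j],
        cluster_p = clusterPs[ci],
        fdr_significant = fdrSignificant[ci])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Local maxima of the t map inside a cluster, greedily thinned to >= sepMm
# apart, at most maxPeaks reported.
clusterPeaks <- function(voxels, maps, maxPeaks = 3L, sepMm = 8) {
  dims <- dim(maps@t)
  tvals <- maps@t[voxels]
  idx <- arrayInd(voxels, dims)
  inCluster <- array(FALSE, dims)
  inCluster[voxels] <- TRUE
  isMax <- vapply(seq_along(voxels), function(i) {
    v <- idx[i, ]
    tv <- tvals[i]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      w <- v + c(dx, dy, dz)
      if (any(w < 1) || any(w > dims)) next
      if (inCluster[w[1], w[2], w[3]] && maps@t[w[1], w[2], w[3]] > tv)
        return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- which(isMax)
  cand <- cand[order(-tvals[cand])]
  world <- voxelToWorld(maps@affine, idx - 1L)
  sel <- integer(0)
  for (i in cand) {
    if (length(sel) >= maxPeaks) break
    if (!length(sel) ||
        all(sqrt(colSums((t(world[sel, , drop = FALSE]) - world[i, ])^2)) >=
              sepMm))
      sel <- c(sel, i)
  }
  data.frame(t = tvals[sel], x = world[sel, 1], y = world[sel, 2],
             z = world[sel, 3])
}
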