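#' Segmentation configuration and presets
#'
#' `segmentationConfig` builds a \linkS4class{SegmentationConfig};
#' `segPreset` returns the two named regimes: `"mr-default"` (2/2/2/4
#' Gaussians, light bias regularization, 3 mm sampling) and `"ct-default"`
#' (2/2/3/4 Gaussians, bias field disabled because CT intensities are
#' unbiased, 2 mm sampling). For CT the per-subject Gaussian count can be
#' tuned with [autoAdjustGaussians()] over [ctConfigGrid()].
#'
#' @param nGauss Gaussians per class, named `gm`, `wm`, `csf`, `other`.
#' @param biasReg bias-field regularization (quadratic penalty weight);
#'   `Inf` disables bias-field estimation.
#' @param samplingMm EM sampling distance, mm.
#' @param maxIter,tol EM stopping rule.
#' @return a \linkS4class{SegmentationConfig}.
#' @export
segmentationConfig <- function(nGauss = c(gm = 2L, wm = 2L, csf = 2L,
                                          other = 4L),
                               biasReg = Inf, samplingMm = 3, maxIter = 64L,
                               tol = 1e-4) {
  nGauss <- as.integer(nGauss)
  names(nGauss) <- c("gm", "wm", "csf", "other")
  new("SegmentationConfig", nGauss = nGauss, biasReg = biasReg,
      samplingMm = samplingMm, maxIter = as.integer(maxIter), tol = tol)
}

#' @rdname segmentationConfig
#' @param name preset name, `"mr-default"` or `"ct-default"`.
#' @export
segPreset <- function(name = c("mr-default", "ct-default")) {
  name <- match.arg(name)
  switch(name,
         "mr-default" = segmentationConfig(
           nGauss = c(gm = 2L, wm = 2L, csf = 2L, other = 4L),
           biasReg = 1e-2, samplingMm = 3),
         "ct-default" = segmentationConfig(
           nGauss = c(gm = 2L, wm = 2L, csf = 3L, other = 4L),
           biasReg = Inf, samplingMm = 2))
}

#' Candidate configurations for per-subject CT tuning
#'
#' The CT regime uses 1-2 Gaussians for gray and white matter and 6-8 in
#' total for CSF plus other tissues; the CSF/other split is not pinned down,
#' so the grid enumerates joint totals of 6, 7 and 8.
#'
#' @param samplingMm sampling distance passed to each candidate.
#' @return list of \linkS4class{SegmentationConfig}.
#' @export
ctConfigGrid <- function(samplingMm = 2) {
  grid <- list()
  for (g in 1:2) for (w in 1:2)
    for (co in list(c(2L, 4L), c(3L, 4L), c(4L, 4L)))
      grid[[length(grid) + 1L]] <- segmentationConfig(
        nGauss = c(gm = g, wm = w, csf = co[1], other = co[2]),
        biasReg = Inf, samplingMm = samplingMm)
  grid
}

#' Construct a tissue-prior atlas
#'
#' @param gm,wm,csf prior probability \linkS4class{Volume3D}s on one grid.
#' @param template gray-matter template used as normalization target;
#'   defaults to the gm prior.
#' @return a \linkS4class{TissuePriorAtlas}.
#' @export
tissuePriorAtlas <- function(gm, wm, csf, template = gm) {
  new("TissuePriorAtlas", gm = gm, wm = wm, csf = csf, template = template)
}

# Stack atlas priors into an nvox x 4 matrix (gm, wm, csf, other), floored
# and renormalized so no class has exactly zero prior anywhere.
priorMatrix <- function(atlas, floor = 1e-4) {
  p <- cbind(gm = as.numeric(atlas@gm@data), wm = as.numeric(atlas@wm@data),
             csf = as.numeric(atlas@csf@data))
  p <- cbind(p, other = pmax(0, 1 - rowSums(p)))
  p <- p + floor
  p / rowSums(p)
}

# Linear indices of the EM sampling sub-grid.
samplingIndices <- function(dims, voxMm, samplingMm) {
  stride <- pmax(1L, round(samplingMm / voxMm))
  ix <- seq.int(1L, dims[1], by = stride[1])
  iy <- seq.int(1L, dims[2], by = stride[2])
  iz <- seq.int(1L, dims[3], by = stride[3])
  as.vector(outer(outer(ix, (iy - 1L) * dims[1], "+"),
                  (iz - 1L) * dims[1] * dims[2], "+"))
}

# Initialize Gaussians from the prior MAP labeling; classes with multiple
# Gaussians are split on intensity quantiles. When the priors are spatially
# flat they cannot seed distinct classes, so all Gaussians get staggered
# global quantiles instead (a deterministic symmetric-start breaker).
initGaussians <- function(y, P, nGauss, jitterSd = 0) {
  cls <- max.col(P, ties.method = "first")
  vy <- var(y)
  flat <- all(apply(P, 2, function(col) diff(range(col))) < 1e-8)
  G <- sum(nGauss)
  globalQ <- quantile(y, probs = (seq_len(G) - 0.5) / G, names = FALSE)
  pos <- 0L
  gauss <- data.frame(class = character(0), mean = numeric(0),
                      var = numeric(0), weight = numeric(0))
  for (c in 1:4) {
    k <- nGauss[[c]]
    yc <- y[cls == c]
    if (flat || length(yc) < 4L * k) {
      qs <- globalQ[pos + seq_len(k)]
      vc <- max(vy / G^2, 1e-12)
    } else {
      qs <- quantile(yc, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      vc <- max(var(yc) / k^2, 1e-4 * vy, 1e-12)
    }
    pos <- pos + k
    gauss <- rbind(gauss, data.frame(
      class = names(nGauss)[c], mean = qs, var = vc, weight = 1 / k))
  }
  if (jitterSd > 0)
    gauss$mean <- gauss$mean + rnorm(nrow(gauss), 0, jitterSd * sqrt(vy))
  gauss
}

# Low-frequency separable cosine basis evaluated on a sub-grid (ix/iy/iz are
# 1-based voxel indices along each axis); returns the N x K basis matrix.
dctBasisGrid <- function(ix, iy, iz, dims, nb) {
  bx <- dctAxis(ix, dims[1], nb[1])
  by <- dctAxis(iy, dims[2], nb[2])
  bz <- dctAxis(iz, dims[3], nb[3])
  nx <- length(ix); ny <- length(iy); nz <- length(iz)
  B <- matrix(0, nx * ny * nz, nb[1] * nb[2] * nb[3])
  col <- 0L
  for (kz in seq_len(nb[3])) for (ky in seq_len(nb[2]))
    for (kx in seq_len(nb[1])) {
      col <- col + 1L
      B[, col] <- as.vector(outer(outer(bx[, kx], by[, ky]), bz[, kz]))
    }
  B
}

dctAxis <- function(i, n, nb) {
  x <- (i - 0.5) / n
  outer(x, seq_len(nb) - 1L, function(u, k) cos(pi * k * u))
}

#' Align the tissue priors to a subject
#'
#' Estimates a 12-parameter affine from an intracranial indicator of the
#' subject (the CT brain mask, or a first-pass intracranial posterior for
#' MR) to the atlas's intracranial prior (gm+wm+csf), and pulls the priors
#' into the subject frame. Residual rotation and scale that the rough
#' grid placement leaves behind would otherwise misalign the priors by a
#' voxel or more at the cortical shell, which the low CT tissue contrast
#' cannot overcome; warping the (smooth) priors instead of the subject
#' leaves the subject's voxel data untouched.
#'
#' @param atlas a \linkS4class{TissuePriorAtlas}.
#' @param indicator intracranial indicator \linkS4class{Volume3D} on the
#'   atlas grid (values in \[0,1\]).
#' @param sampleMm,maxit forwarded to [estimateAffine()].
#' @param icv optional precomputed intracranial prior volume (gm+wm+csf).
#' @return a \linkS4class{TissuePriorAtlas} in the subject frame (the
#'   normalization template is left in template space).
#' @export
alignPriorsToSubject <- function(atlas, indicator, sampleMm = 8,
                                 maxit = 25L, icv = NULL) {
  if (is.null(icv))
    icv <- volume3D(atlas@gm@data + atlas@wm@data + atlas@csf@data,
                    atlas@gm@affine, "probability")
  A <- estimateAffine(indicator, icv, sampleMm = sampleMm, maxit = maxit)
  W <- solve(A)
  wp <- function(p) resampleToGrid(p, asGridSpec(atlas@gm), worldMap = W)
  tissuePriorAtlas(wp(atlas@gm), wp(atlas@wm), wp(atlas@csf),
                   template = atlas@template)
}

#' Fit a prior-weighted Gaussian mixture segmentation
#'
#' EM on voxels subsampled at `cfg@samplingMm`: the E-step posterior of
#' Gaussian g belonging to class c at voxel v is proportional to
#' `prior_c(v) * weight_g * N(y_v; mean_g, var_g)`; class posteriors are the
#' sums over each class's Gaussians, re-evaluated at full resolution on
#' exit. The M-step updates means, variances and within-class weights in
#' closed form. For MR (`biasReg < Inf`) a smooth multiplicative bias field
#' on a coarse cosine basis is re-estimated every few iterations from the
#' log-residuals, with quadratic penalty `biasReg`. The EM log-likelihood is
#' checked to be non-decreasing between bias updates.
#'
#' @param vol the \linkS4class{Volume3D} to segment (already on the atlas
#'   grid, see [matchPriorGrid()]).
#' @param atlas a \linkS4class{TissuePriorAtlas} on the same grid.
#' @param cfg a \linkS4class{SegmentationConfig}.
#' @param seed integer seed (restart jitter is the only randomness).
#' @param priors optional precomputed [priorMatrix()]-style nvox x 4 matrix
#'   (lets batch callers reuse one across subjects).
#' @return list with elements `model` (\linkS4class{MixtureModel}) and
#'   `posterior` (\linkS4class{TissuePosterior}).
#' @export
fitMixture <- function(vol, atlas, cfg = segPreset("ct-default"), seed = 1L,
                       priors = NULL) {
  if (!all(gridShape(vol) == gridShape(atlas@gm)))
    stop("volume and atlas must be co-registered on one grid")
  yFull <- as.numeric(vol@data)
  if (var(yFull) < 1e-12) stop("degenerate input: constant image")
  PFull <- if (is.null(priors)) priorMatrix(atlas) else priors
  dims <- dim(vol@data)
  sub <- samplingIndices(dims, voxelSize(vol), cfg@samplingMm)
  y0 <- yFull[sub]
  P <- PFull[sub, , drop = FALSE]
  useBias <- is.finite(cfg@biasReg) && vol@modality == "mr"

  stride <- pmax(1L, round(cfg@samplingMm / voxelSize(vol)))
  if (useBias) {
    nbB <- c(4L, 4L, 4L)
    Bsub <- dctBasisGrid(seq.int(1L, dims[1], by = stride[1]),
                         seq.int(1L, dims[2], by = stride[2]),
                         seq.int(1L, dims[3], by = stride[3]), dims, nbB)
    posW <- as.numeric(y0 > max(y0) * 1e-3)
    BsubW <- Bsub * posW
    biasA <- crossprod(BsubW, Bsub) +
      diag(cfg@biasReg * length(y0), ncol(Bsub))
  }

  fitOnce <- function(jitterSd) {
    gauss <- withSeed(seed, initGaussians(y0, P, cfg@nGauss, jitterSd))
    gcls <- match(gauss$class, c("gm", "wm", "csf", "other")) - 1L
    biasC <- if (useBias) numeric(ncol(Bsub)) else NULL
    y <- y0
    llTrace <- numeric(0)
    converged <- FALSE
    lastReset <- FALSE
    for (it in seq_len(cfg@maxIter)) {
      es <- cppEmResp(y, P, gauss$mean, gauss$var, gauss$weight, gcls)
      r <- es$resp
      ll <- es$loglik
      if (length(llTrace) && !lastReset &&
          ll < tail(llTrace, 1) - 1e-6 * abs(tail(llTrace, 1)))
        warning("EM log-likelihood decreased at iteration ", it)
      if (length(llTrace) && !lastReset &&
          abs(ll - tail(llTrace, 1)) <
            cfg@tol * max(1, abs(tail(llTrace, 1)))) {
        llTrace <- c(llTrace, ll)
        converged <- TRUE
        break
      }
      lastReset <- FALSE
      llTrace <- c(llTrace, ll)
      nk <- colSums(r)
      upd <- nk > 1e-8   # starved Gaussians keep their parameters
      mu <- gauss$mean
      vr <- gauss$var
      mu[upd] <- (colSums(r * y) / nk)[upd]
      vr[upd] <- (colSums(r * (rep(y, times = ncol(r)) -
                                 rep(mu, each = length(y)))^2) / nk)[upd]
      # constrained M-step: a variance floor at 1e-6 of the data variance
      # blocks the spike degeneracy of unpenalized mixtures (point masses
      # such as the windowed CT background are modeled at the floor) while
      # keeping EM monotone; numerical breakdown still triggers a restart
      if (!is.finite(ll) || any(!is.finite(vr)))
        return(list(collapsed = TRUE))
      vr <- pmax(vr, 1e-6 * var(y0))
      gauss$mean <- mu
      gauss$var <- vr
      for (c in unique(gcls)) {
        g <- which(gcls == c)
        gauss$weight[g] <- nk[g] / sum(nk[g])
      }
      # periodic multiplicative bias update (MR only)
      if (useBias && it %% 4L == 0L && it < cfg@maxIter - 4L) {
        target <- log(pmax(y0, max(y0) * 1e-3)) -
          as.vector(r %*% log(pmax(gauss$mean, max(y0) * 1e-3)))
        biasC <- solve(biasA, crossprod(BsubW, target))
        y <- y0 / exp(as.vector(Bsub %*% biasC))
        lastReset <- TRUE
      }
    }
    list(collapsed = FALSE, gauss = gauss, gcls = gcls, llTrace = llTrace,
         converged = converged, biasC = biasC, y = y)
  }

  fit <- NULL
  for (attempt in 0:3) {
    fit <- fitOnce(jitterSd = attempt * 0.05)
    if (!fit$collapsed) break
    seed <- seed + 1000L
  }
  if (is.null(fit) || fit$collapsed)
    stop("variance collapse persisted after 3 jittered restarts")

  # full-resolution posterior
  biasFull <- NULL
  yF <- yFull
  if (useBias && any(fit$biasC != 0)) {
    bx <- dctAxis(seq_len(dims[1]), dims[1], 4L)
    by <- dctAxis(seq_len(dims[2]), dims[2], 4L)
    bz <- dctAxis(seq_len(dims[3]), dims[3], 4L)
    biasFull <- exp(dctEvalSeparable(fit$biasC, bx, by, bz))
    yF <- yFull / as.vector(biasFull)
  }
  esF <- cppEmResp(yF, PFull, fit$gauss$mean, fit$gauss$var,
                   fit$gauss$weight, fit$gcls)
  prob <- array(0, c(dims, 4L),
                dimnames = list(NULL, NULL, NULL,
                                c("gm", "wm", "csf", "other")))
  for (c in 1:4) {
    g <- which(fit$gcls == c - 1L)
    prob[, , , c] <- array(rowSums(esF$resp[, g, drop = FALSE]), dims)
  }
  model <- new("MixtureModel", gaussians = fit$gauss,
               loglik = as.numeric(fit$llTrace), converged = fit$converged,
               bias = biasFull, config = cfg)
  posterior <- new("TissuePosterior", prob = prob, affine = vol@affine)
  list(model = model, posterior = posterior)
}

#' Extract the gray-matter probability map
#'
#' Returns the gray-matter class posterior unchanged (no hard threshold):
#' downstream smoothing converts the probabilities into regional gray-matter
#' density.
#'
#' @param post a \linkS4class{TissuePosterior}.
#' @return a probability \linkS4class{Volume3D}.
#' @export
extractGrayMatter <- function(post) {
  volume3D(post@prob[, , , "gm"], post@affine, "probability")
}

#' Per-subject tuning of the Gaussians-per-class counts
#'
#' Fits every candidate configuration and returns the most successful one.
#' A fit is successful when EM converged and the gray-matter posterior
#' (thresholded at 0.5) reaches Dice >= 0.6 against the MAP labeling of the
#' priors alone -- the guard against gray matter leaking into bone or CSF.
#' Ties are broken by higher mean per-voxel log-likelihood, then by fewer
#' Gaussians; the result is deterministic given the seed.
#'
#' @param vol,atlas,seed as in [fitMixture()].
#' @param cfgGrid non-empty list of candidate
#'   \linkS4class{SegmentationConfig}s (default [ctConfigGrid()]).
#' @return list with elements `config`, `model`, `posterior` and a
#'   `diagnostics` data.frame (one row per candidate).
#' @export
autoAdjustGaussians <- function(vol, atlas, cfgGrid = ctConfigGrid(),
                                seed = 1L) {
  if (!length(cfgGrid)) stop("cfgGrid must be non-empty")
  priorGm <- priorMatrix(atlas)
  mapGm <- array(max.col(priorGm, ties.method = "first") == 1L,
                 gridShape(vol))
  fits <- vector("list", length(cfgGrid))
  dg <- data.frame(candidate = seq_along(cfgGrid), gm = NA, wm = NA,
                     csf = NA, other = NA, converged = FALSE, dice = NA,
                     meanLoglik = NA, error = "")
  for (i in seq_along(cfgGrid)) {
    cfg <- cfgGrid[[i]]
    dg[i, c("gm", "wm", "csf", "other")] <- as.list(cfg@nGauss)
    f <- tryCatch(fitMixture(vol, atlas, cfg, seed = seed),
                  error = function(e) e)
    if (inherits(f, "error")) {
      dg$error[i] <- conditionMessage(f)
      next
    }
    fits[[i]] <- f
    nSamp <- length(samplingIndices(dim(vol@data), voxelSize(vol),
                                    cfg@samplingMm))
    dg$converged[i] <- f$model@converged
    dg$dice[i] <- diceCoef(f$posterior@prob[, , , "gm"] > 0.5, mapGm)
    dg$meanLoglik[i] <- tail(f$model@loglik, 1) / nSamp
  }
  if (all(!dg$converged & is.na(dg$meanLoglik)))
    stop("all candidate configurations failed:\n",
         paste(sprintf("  candidate %d (%d/%d/%d/%d): %s", dg$candidate,
                       dg$gm, dg$wm, dg$csf, dg$other,
                       ifelse(nzchar(dg$error), dg$error,
                              "did not converge")),
               collapse = "\n"))
  success <- dg$converged & !is.na(dg$dice) & dg$dice >= 0.6
  total <- dg$gm + dg$wm + dg$csf + dg$other
  ord <- order(-as.integer(success), -replace(dg$meanLoglik,
                                              is.na(dg$meanLoglik), -Inf),
               total, dg$candidate)
  best <- ord[1]
  list(config = cfgGrid[[best]], model = fits[[best]]$model,
       posterior = fits[[best]]$posterior, diagnostics = dg)
}
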