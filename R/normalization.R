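# Affine + low-frequency cosine-basis normalization of gray-matter maps to
# the gray-matter template. The deformation is template-space pull-back:
# source_world = affine %*% (x + u(x)) for template-space world x, with u a
# separable cosine displacement field over the template field of view.

# World-frame cosine basis along one axis: cos(pi * k * (x - x0) / L).
dctAxisWorld <- function(x, x0, L, nb) {
  u <- (x - x0) / L
  outer(u, seq_len(nb) - 1L, function(v, k) cos(pi * k * v))
}

# Evaluate a separable cosine field with coefficient vector cvec (length
# prod(nb)) given per-axis basis matrices; returns an nx x ny x nz array.
dctEvalSeparable <- function(cvec, bx, by, bz) {
  nb <- c(ncol(bx), ncol(by), ncol(bz))
  n <- c(nrow(bx), nrow(by), nrow(bz))
  t1 <- bx %*% matrix(cvec, nb[1], nb[2] * nb[3])          # nx x (nby*nbz)
  t1 <- aperm(array(t1, c(n[1], nb[2], nb[3])), c(2, 1, 3))
  t2 <- by %*% matrix(t1, nb[2], n[1] * nb[3])             # ny x (nx*nbz)
  t2 <- aperm(array(t2, c(n[2], n[1], nb[3])), c(3, 2, 1)) # nbz x nx x ny
  t3 <- bz %*% matrix(t2, nb[3], n[1] * n[2])              # nz x (nx*ny)
  aperm(array(t3, c(n[3], n[1], n[2])), c(2, 3, 1))
}

# Template-grid world geometry (requires an axis-aligned grid).
axisAlignedBox <- function(grid) {
  grid <- asGridSpec(grid)
  L3 <- grid@affine[1:3, 1:3]
  if (max(abs(L3 - diag(diag(L3)))) > 1e-6 * max(abs(diag(L3))))
    stop("template grid must be axis-aligned for the cosine warp basis")
  vox <- diag(L3)
  x0 <- grid@affine[1:3, 4] - vox / 2
  list(x0 = x0, fov = vox * grid@shape, vox = vox)
}

gradientVolumes <- function(vol) {
  d <- dim(vol@data)
  g <- vector("list", 3)
  inv <- solve(vol@affine[1:3, 1:3])
  gi <- list(array(0, d), array(0, d), array(0, d))
  x <- vol@data
  gi[[1]][2:(d[1] - 1), , ] <- (x[3:d[1], , ] - x[1:(d[1] - 2), , ]) / 2
  gi[[2]][, 2:(d[2] - 1), ] <- (x[, 3:d[2], ] - x[, 1:(d[2] - 2), ]) / 2
  gi[[3]][, , 2:(d[3] - 1)] <- (x[, , 3:d[3]] - x[, , 1:(d[3] - 2)]) / 2
  # world-frame gradient: grad_world = t(inv(A3)) %*% grad_index
  for (a in 1:3)
    g[[a]] <- inv[1, a] * gi[[1]] + inv[2, a] * gi[[2]] + inv[3, a] * gi[[3]]
  g
}

# Sample a source volume (and optionally its gradient volumes) at world
# coordinates; returns intensity vector and N x 3 world gradient.
sampleSource <- function(src, world, grads = NULL) {
  coords <- worldToVoxel(src@affine, world)
  sv <- cppSampleAt(as.numeric(src@data), dim(src@data), coords, 0L)
  if (is.null(grads)) return(list(sv = sv))
  g <- sapply(grads, function(gv)
    cppSampleAt(as.numeric(gv), dim(gv), coords, 0L))
  list(sv = sv, grad = g)
}

# Mean squared difference after optimal global intensity scaling of the
# source onto the template.
scaledMse <- function(tv, sv) {
  ss <- sum(sv * sv)
  a <- if (ss > 1e-12) sum(sv * tv) / ss else 0
  list(mse = mean((tv - a * sv)^2), a = a)
}

#' Estimate the 12-parameter affine onto the template
#'
#' Minimizes the variance-normalized mean squared intensity difference
#' (after optimal global intensity scaling) between the template and the
#' affinely resampled source, by quasi-Newton search from a center-of-mass
#' plus second-moment (principal-axes) initialization. Both maps are
#' smoothed by `estFwhmMm` for the estimation only, and rotation, log-zoom
#' and shear departures from the moment-based initialization carry a
#' quadratic penalty (`affineReg`): gray-matter maps give the similarity
#' surface long flat valleys in these directions, and the penalty keeps the
#' solution near the stable moment estimate rather than letting per-subject
#' noise pick an arbitrary point of the valley. The
#' returned matrix maps template-space world coordinates to source-space
#' world coordinates (the pull-back convention used by
#' [applyNormalization()]). Deterministic.
#'
#' @param srcGm subject gray-matter probability \linkS4class{Volume3D}.
#' @param templateGm template gray-matter \linkS4class{Volume3D}.
#' @param sampleMm spacing of the objective's sampling sub-grid, mm.
#' @param maxit quasi-Newton iteration cap.
#' @param affineReg quadratic penalty weight on rotations, log-zooms and
#'   shears (on the variance-normalized objective scale).
#' @param estFwhmMm Gaussian smoothing applied to both maps before
#'   estimation (0 disables).
#' @return 4x4 affine matrix.
#' @export
estimateAffine <- function(srcGm, templateGm, sampleMm = 8, maxit = 40L,
                           affineReg = 5, estFwhmMm = 8) {
  if (max(srcGm@data) <= 0) stop("empty (all-zero) source volume")
  if (max(templateGm@data) <= 0) stop("empty (all-zero) template volume")
  if (estFwhmMm > 0) {
    srcGm <- smoothGaussian(srcGm, estFwhmMm)
    templateGm <- smoothGaussian(templateGm, estFwhmMm)
  }
  box <- axisAlignedBox(asGridSpec(templateGm))
  stride <- pmax(1L, round(sampleMm / voxelSize(templateGm)))
  gw <- gridWorldCoords(templateGm, stride)
  tv <- as.numeric(templateGm@data)[
    1L + gw$idx[, 1] + dim(templateGm@data)[1] *
      (gw$idx[, 2] + dim(templateGm@data)[2] * gw$idx[, 3])]
  X <- gw$world
  center <- box$x0 + box$fov / 2
  vt <- max(var(tv), 1e-12)

  comS <- centerOfMass(srcGm@data, srcGm@affine)
  comT <- centerOfMass(templateGm@data, templateGm@affine)
  vS <- axisVariances(srcGm@data, srcGm@affine)
  vT <- axisVariances(templateGm@data, templateGm@affine)
  p0 <- c(comS - comT, rep(0, 3), 0.5 * log(vS / vT), rep(0, 3))

  srcVec <- as.numeric(srcGm@data)
  srcDim <- dim(srcGm@data)
  invSrc <- solve(srcGm@affine)
  obj <- function(p) {
    A <- composeAffine(p[1:3], p[4:6], p[7:9], p[10:12], center)
    B <- (invSrc %*% A)[1:3, , drop = FALSE]
    cppScaledMseAt(srcVec, srcDim, X, tv, B) / vt +
      affineReg * sum((p[4:12] - p0[4:12])^2)
  }
  ps <- c(rep(1, 3), rep(0.005, 3), rep(0.005, 3), rep(0.005, 3))
  fit <- optim(p0, obj, method = "BFGS",
               control = list(maxit = maxit, parscale = ps, reltol = 1e-9))
  p <- fit$par
  composeAffine(p[1:3], p[4:6], p[7:9], p[10:12], center)
}

membraneDiag <- function(nb, fov) {
  kx <- rep(seq_len(nb[1]) - 1L, times = nb[2] * nb[3])
  ky <- rep(rep(seq_len(nb[2]) - 1L, each = nb[1]), times = nb[3])
  kz <- rep(seq_len(nb[3]) - 1L, each = nb[1] * nb[2])
  (pi * kx / fov[1])^2 + (pi * ky / fov[2])^2 + (pi * kz / fov[3])^2
}

#' Estimate the regularized low-frequency warp
#'
#' Gauss-Newton minimization of the variance-normalized mean squared
#' difference plus `regLambda` times the membrane energy of the displacement
#' field, over separable cosine-basis coefficients. The basis has
#' `max(2, floor(FOV/cutoffMm))` functions per axis, so a smaller cutoff
#' (shortest represented wavelength) gives a more flexible warp. A small
#' ridge on the zero-frequency modes keeps global translation in the affine
#' rather than the warp, and makes the warp vanish as `regLambda` grows.
#' The objective is forced non-increasing by step halving; displacement is
#' capped at a quarter of the field of view. Deterministic.
#'
#' @param srcGm,templateGm as in [estimateAffine()].
#' @param affine the pre-estimated template-world to source-world affine.
#' @param cutoffMm shortest represented spatial wavelength, mm.
#' @param regLambda membrane-energy weight (on the variance-normalized
#'   objective scale).
#' @param sampleMm spacing of the sampling sub-grid, mm.
#' @param nIter Gauss-Newton iterations.
#' @param estFwhmMm Gaussian smoothing applied to both maps before
#'   estimation (0 disables); the returned parameters are applied to the
#'   unsmoothed map by [applyNormalization()].
#' @return a \linkS4class{NormalizationParams}.
#' @export
estimateWarp <- function(srcGm, templateGm, affine, cutoffMm = 35,
                         regLambda = 1, sampleMm = 8, nIter = 4L,
                         estFwhmMm = 8) {
  if (max(srcGm@data) <= 0) stop("empty (all-zero) source volume")
  if (estFwhmMm > 0) {
    srcGm <- smoothGaussian(srcGm, estFwhmMm)
    templateGm <- smoothGaussian(templateGm, estFwhmMm)
  }
  box <- axisAlignedBox(asGridSpec(templateGm))
  if (cutoffMm <= 2 * max(box$vox))
    stop("cutoffMm must exceed twice the voxel size")
  nb <- pmax(2L, as.integer(floor(box$fov / cutoffMm)))
  K <- prod(nb)

  dims <- dim(templateGm@data)
  stride <- pmax(1L, round(sampleMm / box$vox))
  ix <- seq.int(1L, dims[1], by = stride[1])
  iy <- seq.int(1L, dims[2], by = stride[2])
  iz <- seq.int(1L, dims[3], by = stride[3])
  wx <- box$x0[1] + (ix - 0.5) * box$vox[1]
  wy <- box$x0[2] + (iy - 0.5) * box$vox[2]
  wz <- box$x0[3] + (iz - 0.5) * box$vox[3]
  bx <- dctAxisWorld(wx, box$x0[1], box$fov[1], nb[1])
  by <- dctAxisWorld(wy, box$x0[2], box$fov[2], nb[2])
  bz <- dctAxisWorld(wz, box$x0[3], box$fov[3], nb[3])
  # expanded basis at the sample points
  B <- matrix(0, length(ix) * length(iy) * length(iz), K)
  col <- 0L
  for (kz in seq_len(nb[3])) for (ky in seq_len(nb[2]))
    for (kx in seq_len(nb[1])) {
      col <- col + 1L
      B[, col] <- as.vector(outer(outer(bx[, kx], by[, ky]), bz[, kz]))
    }
  X <- as.matrix(expand.grid(x = wx, y = wy, z = wz))
  tv <- as.numeric(templateGm@data[ix, iy, iz])
  vt <- max(var(tv), 1e-12)
  N <- length(tv)

  pen <- membraneDiag(nb, box$fov)
  ridge <- 1e-3 * mean(pen[pen > 0])
  penDiag <- rep(regLambda * (pen + ridge), 3)

  grads <- gradientVolumes(srcGm)
  AL <- affine[1:3, 1:3]
  At <- affine[1:3, 4]
  maxDisp <- min(box$fov) / 4

  C <- matrix(0, K, 3)
  objective <- function(C) {
    U <- B %*% C
    Y <- (X + U) %*% t(AL) + rep(At, each = N)
    sv <- sampleSource(srcGm, Y)$sv
    sm <- scaledMse(tv, sv)
    sm$mse / vt + sum(penDiag * as.numeric(C)^2)
  }
  curObj <- objective(C)
  trace <- curObj
  for (it in seq_len(nIter)) {
    U <- B %*% C
    Y <- (X + U) %*% t(AL) + rep(At, each = N)
    s <- sampleSource(srcGm, Y, grads)
    sm <- scaledMse(tv, s$sv)
    r <- tv - sm$a * s$sv
    # d resid / d u_axis = -a * (grad_world %*% AL)_axis
    gA <- s$grad %*% AL
    J <- cbind(B * (-sm$a * gA[, 1]), B * (-sm$a * gA[, 2]),
               B * (-sm$a * gA[, 3])) / sqrt(N * vt)
    rhs <- -crossprod(J, r / sqrt(N * vt)) - penDiag * as.numeric(C)
    H <- crossprod(J)
    diag(H) <- diag(H) + penDiag + 1e-10
    dC <- matrix(solve(H, rhs), K, 3)
    step <- 1
    repeat {
      Cn <- C + step * dC
      if (max(abs(B %*% Cn)) > maxDisp) { step <- step / 2; next }
      newObj <- objective(Cn)
      if (is.finite(newObj) && newObj <= curObj + 1e-12) break
      step <- step / 2
      if (step < 1e-4) { Cn <- C; newObj <- curObj; break }
    }
    if (!is.finite(newObj))
      stop("non-finite warp objective; trace: ",
           paste(signif(trace, 6), collapse = ", "))
    C <- Cn
    curObj <- newObj
    trace <- c(trace, curObj)
  }
  out <- new("NormalizationParams", affine = affine, warpCoeffs = C,
             nBasis = nb, bbox0 = box$x0, fovMm = box$fov,
             cutoffMm = cutoffMm, regLambda = regLambda)
  attr(out, "objectiveTrace") <- trace
  out
}

#' Identity normalization parameters
#'
#' @param templateGrid template \linkS4class{GridSpec} (or volume) defining
#'   the warp's field of view.
#' @param cutoffMm,regLambda stored metadata.
#' @return a \linkS4class{NormalizationParams} with identity affine and zero
#'   warp.
#' @export
identityNormalization <- function(templateGrid, cutoffMm = 35,
                                  regLambda = 1) {
  box <- axisAlignedBox(asGridSpec(templateGrid))
  nb <- pmax(2L, as.integer(floor(box$fov / cutoffMm)))
  new("NormalizationParams", affine = diag(4),
      warpCoeffs = matrix(0, prod(nb), 3), nBasis = nb, bbox0 = box$x0,
      fovMm = box$fov, cutoffMm = cutoffMm, regLambda = regLambda)
}

#' Apply normalization parameters, resampling onto the analysis grid
#'
#' Pull-back resampling through affine and warp: each output voxel's world
#' coordinate x is mapped to source world affine %*% (x + u(x)) and the
#' source is sampled there (trilinear).
#'
#' @param vol source-space \linkS4class{Volume3D} to warp (typically the
#'   gray-matter map).
#' @param params a \linkS4class{NormalizationParams}.
#' @param outGrid output \linkS4class{GridSpec} (the 2 mm analysis grid by
#'   default conventions of the pipeline).
#' @param interp `"trilinear"` or `"nearest"`.
#' @return a \linkS4class{Volume3D} on `outGrid`.
#' @export
applyNormalization <- function(vol, params, outGrid,
                               interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  outGrid <- asGridSpec(outGrid)
  box <- axisAlignedBox(outGrid)
  wx <- box$x0[1] + (seq_len(outGrid@shape[1]) - 0.5) * box$vox[1]
  wy <- box$x0[2] + (seq_len(outGrid@shape[2]) - 0.5) * box$vox[2]
  wz <- box$x0[3] + (seq_len(outGrid@shape[3]) - 0.5) * box$vox[3]
  bx <- dctAxisWorld(wx, params@bbox0[1], params@fovMm[1], params@nBasis[1])
  by <- dctAxisWorld(wy, params@bbox0[2], params@fovMm[2], params@nBasis[2])
  bz <- dctAxisWorld(wz, params@bbox0[3], params@fovMm[3], params@nBasis[3])
  n <- prod(outGrid@shape)
  X <- cbind(rep(wx, times = prod(outGrid@shape[2:3])),
             rep(rep(wy, each = outGrid@shape[1]), times = outGrid@shape[3]),
             rep(wz, each = prod(outGrid@shape[1:2])))
  if (any(params@warpCoeffs != 0)) {
    for (a in 1:3)
      X[, a] <- X[, a] +
        as.vector(dctEvalSeparable(params@warpCoeffs[, a], bx, by, bz))
  }
  Y <- X %*% t(params@affine[1:3, 1:3]) +
    rep(params@affine[1:3, 4], each = n)
  coords <- worldToVoxel(vol@affine, Y)
  out <- cppSampleAt(as.numeric(vol@data), dim(vol@data), coords,
                     as.integer(interp == "nearest"))
  dim(out) <- outGrid@shape
  if (vol@modality == "probability") out <- pmin(pmax(out, 0), 1)
  volume3D(out, outGrid@affine, vol@modality)
}
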