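# Internal helpers shared across modules.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# World coordinates (N x 3) of 0-based voxel indices (N x 3) under an affine.
voxelToWorld <- function(affine, idx0) {
  idx0 <- rbind2mat(idx0)
  t(affine[1:3, 1:3] %*% t(idx0) + affine[1:3, 4])
}

# 0-based voxel coordinates of world points (N x 3).
worldToVoxel <- function(affine, world) {
  world <- rbind2mat(world)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(world) + inv[1:3, 4])
}

rbind2mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 3)
}

# World coordinates of every voxel on a regular sub-grid (stride per axis),
# returned as the per-axis coordinate vectors of a separable grid plus the
# full expanded matrix. The grid axes need not be world-axis aligned; the
# expansion handles the general affine.
gridWorldCoords <- function(grid, stride = c(1L, 1L, 1L)) {
  sh <- gridShape(grid)
  ix <- seq.int(1L, sh[1], by = stride[1]) - 1L
  iy <- seq.int(1L, sh[2], by = stride[2]) - 1L
  iz <- seq.int(1L, sh[3], by = stride[3]) - 1L
  idx <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  list(ix = ix, iy = iy, iz = iz,
       world = voxelToWorld(if (is(grid, "GridSpec")) grid@affine else
         grid@affine, idx),
       idx = idx)
}

# Build a 4x4 affine from translation, rotation (radians, applied as
# Rz Ry Rx), log-scales and shears, centred at `center`.
composeAffine <- function(trans = c(0, 0, 0), rot = c(0, 0, 0),
                          logScale = c(0, 0, 0), shear = c(0, 0, 0),
                          center = c(0, 0, 0)) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(exp(logScale))
  H <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  L <- Rz %*% Ry %*% Rx %*% S %*% H
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- trans + center - L %*% center
  A
}

# Dice coefficient between two logical arrays.
diceCoef <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# Center of mass (world mm) of nonnegative weights on a grid.
centerOfMass <- function(data, affine, weights = NULL) {
  w <- if (is.null(weights)) data else weights
  w <- pmax(w, 0)
  tw <- sum(w)
  if (tw <= 0) stop("center of mass undefined: no positive weight")
  d <- dim(data)
  cx <- sum(w * (rep.int(seq_len(d[1]), d[2] * d[3]) - 1)) / tw
  iy <- rep(rep(seq_len(d[2]), each = d[1]), d[3]) - 1
  cy <- sum(w * iy) / tw
  iz <- rep(seq_len(d[3]), each = d[1] * d[2]) - 1
  cz <- sum(w * iz) / tw
  drop(voxelToWorld(affine, c(cx, cy, cz)))
}

# Per-axis world-frame second moments (variances) of a weight volume.
axisVariances <- function(data, affine) {
  w <- pmax(as.vector(data), 0)
  tw <- sum(w)
  d <- dim(data)
  idx <- cbind(rep.int(seq_len(d[1]), d[2] * d[3]) - 1,
               rep(rep(seq_len(d[2]), each = d[1]), d[3]) - 1,
               rep(seq_len(d[3]), each = d[1] * d[2]) - 1)
  xyz <- voxelToWorld(affine, idx)
  mu <- colSums(xyz * w) / tw
  colSums((xyz - rep(mu, each = nrow(xyz)))^2 * w) / tw
}

sameGrid <- function(a, b, tol = 1e-4) {
  all(gridShape(a) == gridShape(b)) &&
    max(abs(volAffine2(a) - volAffine2(b))) < tol
}

volAffine2 <- function(x) if (is(x, "GridSpec")) x@affine else x@affine
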