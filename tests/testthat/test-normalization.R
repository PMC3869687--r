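# Template: the phantom-derived gray-matter prior (a realistic smooth map),
# computed once per test run.
.tplCache <- new.env()
tplVolume <- function() {
  if (is.null(.tplCache$tpl))
    .tplCache$tpl <- phantomAtlas(phantomSpec())@template
  .tplCache$tpl
}

test_that("self-registration returns the identity affine", {
  tpl <- tplVolume()
  A <- estimateAffine(tpl, tpl)
  expect_lt(max(abs(A[1:3, 4])), 0.5)
  expect_lt(max(abs(A[1:3, 1:3] - diag(3))), 1e-3)
})

test_that("a known translation is recovered within 1 mm", {
  tpl <- tplVolume()
  shift <- c(6, -4, 10)
  M <- diag(4); M[1:3, 4] <- shift
  src <- resampleToGrid(tpl, asGridSpec(tpl), worldMap = M)
  # src(x) = tpl(x + shift): the pull-back affine must be the inverse map,
  # a translation by -shift
  A <- estimateAffine(src, tpl)
  expect_lt(max(abs(A[1:3, 4] + shift)), 1)
  expect_lt(max(abs(A[1:3, 1:3] - diag(3))), 0.02)
})

test_that("a known isotropic scale is recovered within 2 percent", {
  tpl <- tplVolume()
  ctr <- drop(ctvbm:::voxelToWorld(volAffine(tpl),
                                   (gridShape(tpl) - 1) / 2))
  M <- diag(4)
  M[1:3, 1:3] <- diag(3) * 1.1
  M[1:3, 4] <- ctr - 1.1 * ctr
  src <- resampleToGrid(tpl, asGridSpec(tpl), worldMap = M)
  # src is the template magnified by 1.1 about the center, so the pull-back
  # scale is 1/1.1; recovered 1.1-equivalent scale within 2 percent
  A <- estimateAffine(src, tpl)
  sc <- sqrt(colSums(A[1:3, 1:3]^2))
  expect_lt(max(abs(1 / sc - 1.1)), 0.022)
})

test_that("empty volumes are rejected", {
  tpl <- tplVolume()
  zero <- volume3D(array(0, dim(volData(tpl))), volAffine(tpl),
                   "probability")
  expect_error(estimateAffine(zero, tpl), "empty")
  expect_error(estimateAffine(tpl, zero), "empty")
  expect_error(estimateWarp(zero, tpl, diag(4)), "empty")
})

test_that("warping an affinely aligned pair leaves coefficients near zero", {
  tpl <- tplVolume()
  p <- estimateWarp(tpl, tpl, diag(4), cutoffMm = 48, regLambda = 1)
  scale <- max(abs(volData(tpl)))
  expect_lt(max(abs(p@warpCoeffs)), 1e-3 * max(1, scale) * 48)
  expect_lt(max(abs(p@warpCoeffs)), 0.5)  # well under a voxel of motion
})

test_that("a known single-basis displacement is recovered", {
  # a smooth texture spanning the whole field of view, so every basis mode
  # is observed (a head-shaped template leaves the displacement outside the
  # head unidentified and the coefficient is not recoverable there)
  base <- tplVolume()
  set.seed(20)
  noise <- volume3D(array(rnorm(prod(gridShape(base))), gridShape(base)),
                    volAffine(base))
  tpl <- smoothGaussian(noise, 16)
  tpl@data <- tpl@data - min(tpl@data) + 0.1
  box <- ctvbm:::axisAlignedBox(asGridSpec(tpl))
  nb <- pmax(2L, as.integer(floor(box$fov / 48)))
  # ground truth: src such that src(x + u(x)) = tpl(x) with u a single
  # 4 mm-amplitude x-axis cosine mode; built by inverting x + u(x) pointwise
  kSel <- c(2L, 1L, 1L)   # second x-frequency, constant in y and z
  idx <- kSel[1] + nb[1] * (kSel[2] - 1L + nb[2] * (kSel[3] - 1L))
  uFun <- function(x) 4 * cos(pi * (x - box$x0[1]) / box$fov[1])
  ax <- ctvbm:::gridAxes(asGridSpec(tpl))
  sh <- gridShape(tpl)
  X <- cbind(rep(ax$x, times = prod(sh[2:3])),
             rep(rep(ax$y, each = sh[1]), times = sh[3]),
             rep(ax$z, each = prod(sh[1:2])))
  xs <- X[, 1]
  for (it in 1:12) xs <- X[, 1] - uFun(xs)   # fixed point of w^{-1}
  coords <- ctvbm:::worldToVoxel(volAffine(tpl), cbind(xs, X[, 2], X[, 3]))
  src <- volume3D(array(ctvbm:::cppSampleAt(as.numeric(volData(tpl)),
                                            dim(volData(tpl)), coords, 0L),
                        sh), volAffine(tpl), "probability")
  p <- estimateWarp(src, tpl, diag(4), cutoffMm = 48, regLambda = 0.01,
                    nIter = 6)
  expect_lt(abs(p@warpCoeffs[idx, 1] - 4), 0.8)   # within 20%
  others <- p@warpCoeffs
  others[idx, 1] <- 0
  expect_lt(max(abs(others)), 1.2)
})

test_that("a smaller cutoff yields at least as many basis functions", {
  tpl <- tplVolume()
  p25 <- estimateWarp(tpl, tpl, diag(4), cutoffMm = 25, regLambda = 10)
  p35 <- estimateWarp(tpl, tpl, diag(4), cutoffMm = 35, regLambda = 10)
  expect_true(all(p25@nBasis >= p35@nBasis))
})

test_that("identity parameters reduce to plain resampling at 2 mm", {
  tpl <- tplVolume()
  out2 <- isotropicGrid(96L, 2)
  idp <- identityNormalization(asGridSpec(tpl))
  a <- applyNormalization(tpl, idp, out2)
  b <- resampleToGrid(tpl, out2)
  expect_equal(volData(a), volData(b), tolerance = 1e-10)
  expect_equal(voxelSize(a), c(2, 2, 2))
})

test_that("estimated warps beat affine alone on a deformed phantom", {
  tpl <- tplVolume()
  box <- ctvbm:::axisAlignedBox(asGridSpec(tpl))
  nb <- pmax(2L, as.integer(floor(box$fov / 48)))
  set.seed(11)
  Ctrue <- matrix(0, prod(nb), 3)
  Ctrue[sample(prod(nb), 5), ] <- rnorm(15, 0, 1.5)
  pTrue <- new("NormalizationParams", affine = diag(4),
               warpCoeffs = Ctrue, nBasis = nb, bbox0 = box$x0,
               fovMm = box$fov, cutoffMm = 48, regLambda = 0.01)
  deformed <- applyNormalization(tpl, pTrue, asGridSpec(tpl))
  A <- estimateAffine(deformed, tpl)
  mseOf <- function(params) {
    back <- applyNormalization(deformed, params, asGridSpec(tpl))
    mean((volData(back) - volData(tpl))^2)
  }
  idA <- identityNormalization(asGridSpec(tpl), 48); idA@affine <- A
  p <- estimateWarp(deformed, tpl, A, cutoffMm = 48, regLambda = 0.01,
                    nIter = 6)
  expect_lt(mseOf(p), 0.7 * mseOf(idA))
})

test_that("the warp objective trace is monotone non-increasing", {
  tpl <- tplVolume()
  box <- ctvbm:::axisAlignedBox(asGridSpec(tpl))
  M <- diag(4); M[1:3, 4] <- c(3, -2, 2)
  src <- resampleToGrid(tpl, asGridSpec(tpl), worldMap = M)
  p <- estimateWarp(src, tpl, M, cutoffMm = 48, regLambda = 0.1, nIter = 5)
  tr <- attr(p, "objectiveTrace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("escalating regularization drives the warp to zero", {
  tpl <- tplVolume()
  M <- diag(4); M[1:3, 4] <- c(4, 0, -3)
  src <- resampleToGrid(tpl, asGridSpec(tpl), worldMap = M)
  norms <- vapply(c(1, 100, 1e6), function(lam) {
    p <- estimateWarp(src, tpl, diag(4), cutoffMm = 48, regLambda = lam,
                      nIter = 3)
    sqrt(sum(p@warpCoeffs^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9))
  expect_lt(norms[3], 0.05)   # far below any voxel-scale displacement
})

test_that("normalizing the template to itself round-trips through any grid", {
  tpl <- tplVolume()
  A <- estimateAffine(tpl, tpl)
  p <- estimateWarp(tpl, tpl, A, cutoffMm = 48, regLambda = 1)
  out <- applyNormalization(tpl, p, asGridSpec(tpl))
  err <- abs(volData(out) - volData(tpl))
  expect_lt(mean(err), 0.01)
  expect_lt(max(err), 0.15)
})
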