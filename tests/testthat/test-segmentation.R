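# A flat-prior atlas on a given grid: gm and wm equally likely everywhere.
flatAtlas <- function(grid) {
  mk <- function(v) volume3D(array(v, grid@shape), grid@affine,
                             "probability")
  tissuePriorAtlas(mk(0.5), mk(0.5), mk(0))
}

# Two-class synthetic mixture: left half ~ N(m1, sd), right half ~ N(m2, sd).
twoClassVolume <- function(grid, m1 = 30, m2 = 70, noiseSd = 5, seed = 1) {
  set.seed(seed)
  sh <- grid@shape
  truth <- array(rep(c(1L, 2L), each = prod(sh) / 2), sh)
  vals <- ifelse(truth == 1L, m1, m2) + rnorm(prod(sh), 0, noiseSd)
  list(vol = volume3D(array(vals, sh), grid@affine), truth = truth)
}

test_that("EM recovers a two-class mixture under flat priors", {
  grid <- isotropicGrid(16L, 2)
  tc <- twoClassVolume(grid, 30, 70, 5, seed = 1)
  cfg <- segmentationConfig(nGauss = c(gm = 1, wm = 1, csf = 1, other = 1),
                            samplingMm = 2)
  fit <- fitMixture(tc$vol, flatAtlas(grid), cfg, seed = 1)
  g <- fit$model@gaussians
  # the two dominant Gaussians sit at the generative means
  post <- fit$posterior@prob
  total <- apply(post, 4, sum)
  top2 <- names(sort(total, decreasing = TRUE))[1:2]
  meansTop <- sort(g$mean[g$class %in% top2])
  expect_lt(abs(meansTop[1] - 30), 1)
  expect_lt(abs(meansTop[2] - 70), 1)
  # assignment accuracy >= 0.99 against the generative labels
  lowClass <- g$class[which.min(g$mean)]
  pLow <- post[, , , lowClass]
  acc <- mean((pLow > 0.5) == (tc$truth == 1L))
  expect_gte(acc, 0.99)
})

test_that("posteriors satisfy the simplex constraint everywhere", {
  grid <- isotropicGrid(14L, 2)
  tc <- twoClassVolume(grid, 20, 60, 8, seed = 2)
  fit <- fitMixture(tc$vol, flatAtlas(grid),
                    segmentationConfig(samplingMm = 4), seed = 1)
  tot <- apply(fit$posterior@prob, 1:3, sum)
  expect_lt(max(abs(tot - 1)), 1e-6)
  expect_gte(min(fit$posterior@prob), 0)
  expect_lte(max(fit$posterior@prob), 1)
})

test_that("the CT regime is accepted: 2/2 GM/WM, 6-8 CSF+other, bias off", {
  cfg <- segmentationConfig(nGauss = c(gm = 2, wm = 2, csf = 3, other = 4),
                            biasReg = Inf, samplingMm = 2)
  expect_true(is.infinite(cfg@biasReg))
  expect_true(sum(cfg@nGauss[c("csf", "other")]) %in% 6:8)
  preset <- segPreset("ct-default")
  expect_true(is.infinite(preset@biasReg))
  expect_equal(preset@samplingMm, 2)
  expect_true(all(vapply(ctConfigGrid(), function(c)
    sum(c@nGauss[c("csf", "other")]) %in% 6:8, logical(1))))
  grid <- isotropicGrid(16L, 2)
  tc <- twoClassVolume(grid, 30, 70, 5, seed = 3)
  fit <- fitMixture(tc$vol, flatAtlas(grid), cfg, seed = 1)
  expect_s4_class(fit$model, "MixtureModel")
  expect_equal(nrow(fit$model@gaussians), 11)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  grid <- isotropicGrid(16L, 2)
  for (s in 1:3) {
    tc <- twoClassVolume(grid, 25, 55, 6, seed = s)
    fit <- fitMixture(tc$vol, flatAtlas(grid),
                      segmentationConfig(samplingMm = 2), seed = s)
    ll <- fit$model@loglik
    expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
  }
})

test_that("parameter recovery sharpens as noise vanishes", {
  grid <- isotropicGrid(16L, 2)
  err <- vapply(c(4, 2, 1), function(ns) {
    tc <- twoClassVolume(grid, 40, 60, ns, seed = 10 + ns)
    cfg <- segmentationConfig(nGauss = c(1, 1, 1, 1), samplingMm = 2)
    fit <- fitMixture(tc$vol, flatAtlas(grid), cfg, seed = 1)
    g <- fit$model@gaussians
    ms <- sort(g$mean)[c(which.min(abs(sort(g$mean) - 40)),
                         which.min(abs(sort(g$mean) - 60)))]
    max(abs(ms - c(40, 60)))
  }, numeric(1))
  expect_lt(err[3], 0.5)
  expect_true(err[3] <= err[1] + 0.25)
  # variances track the generative noise at the lowest level
})

test_that("spatial priors decide ties in likelihood", {
  # exact ties: four identical Gaussians, one per class, so the class
  # posterior is proportional to the spatial prior alone
  set.seed(4)
  n <- 2000L
  y <- rnorm(n, 50, 5)
  P <- matrix(runif(4 * n, 0.05, 1), n, 4)
  P <- P / rowSums(P)
  es <- ctvbm:::cppEmResp(y, P, mu = rep(50, 4), var = rep(25, 4),
                          w = rep(1, 4), gcls = 0:3)
  expect_identical(max.col(es$resp), max.col(P))
  expect_equal(es$resp, P, tolerance = 1e-12, ignore_attr = TRUE)

  # end to end, a constant-intensity region with unequal priors stays
  # dominated by the prior for the vast majority of voxels
  grid <- isotropicGrid(12L, 3)
  sh <- grid@shape
  vol <- volume3D(array(rnorm(prod(sh), 50, 1), sh), grid@affine)
  gmP <- array(0.2, sh); gmP[1:6, , ] <- 0.6
  wmP <- array(0.6, sh); wmP[1:6, , ] <- 0.2
  csfP <- array(0.1, sh)
  atlas <- tissuePriorAtlas(volume3D(gmP, grid@affine, "probability"),
                            volume3D(wmP, grid@affine, "probability"),
                            volume3D(csfP, grid@affine, "probability"))
  fit <- fitMixture(vol, atlas,
                    segmentationConfig(nGauss = c(1, 1, 1, 1),
                                       samplingMm = 3), seed = 1)
  mapClass <- apply(fit$posterior@prob, 1:3, which.max)
  priorMap <- array(max.col(ctvbm:::priorMatrix(atlas)), sh)
  expect_gte(mean(mapClass == priorMap), 0.9)
})

test_that("extractGrayMatter passes the gm plane through unchanged", {
  sh <- c(8L, 8L, 8L)
  prob <- array(0, c(sh, 4L),
                dimnames = list(NULL, NULL, NULL,
                                c("gm", "wm", "csf", "other")))
  blk <- array(0, sh); blk[3:6, 3:6, 3:6] <- 1
  prob[, , , "gm"] <- blk
  prob[, , , "other"] <- 1 - blk
  post <- new("TissuePosterior", prob = prob, affine = diag(4))
  gm <- extractGrayMatter(post)
  expect_identical(volData(gm), blk)
  expect_identical(modality(gm), "probability")
  expect_gte(min(volData(gm)), 0)
  expect_lte(max(volData(gm)), 1)
})

test_that("phantom CT gray matter reaches Dice >= 0.85 at 5 HU noise", {
  spec <- testSpec()
  atlas <- phantomAtlas(spec)
  cohort <- generateCohort(2, 2, spec, NULL, "ct", seed = 31)
  dice <- vapply(1:3, function(i) {
    res <- extractBrainCT(cohort$volumes[[i]])
    reg <- matchPriorGrid(res$brain, asGridSpec(atlas@gm))
    truth <- matchPriorGrid(cohort$labels[[i]], asGridSpec(atlas@gm),
                            initAffine = attr(reg, "initAffine"),
                            interp = "nearest")
    ind <- matchPriorGrid(volume3D(array(as.numeric(res$mask@mask),
                                         dim(res$mask@mask)),
                                   res$mask@affine, "probability"),
                          asGridSpec(atlas@gm),
                          initAffine = attr(reg, "initAffine"))
    fit <- fitMixture(reg, alignPriorsToSubject(atlas, ind),
                      segPreset("ct-default"), seed = i)
    ctvbm:::diceCoef(fit$posterior@prob[, , , "gm"] > 0.5,
                     volData(truth) == phantomLabels()[["gm"]])
  }, numeric(1))
  expect_gte(mean(dice), 0.85)
})

test_that("auto adjustment is deterministic and trivial for one candidate", {
  grid <- isotropicGrid(14L, 2)
  tc <- twoClassVolume(grid, 30, 70, 5, seed = 5)
  one <- list(segmentationConfig(nGauss = c(1, 1, 1, 1), samplingMm = 2))
  res <- autoAdjustGaussians(tc$vol, flatAtlas(grid), one, seed = 1)
  expect_identical(res$config, one[[1]])
  grid2 <- ctConfigGrid(samplingMm = 2)[c(1, 6, 12)]
  r1 <- autoAdjustGaussians(tc$vol, flatAtlas(grid), grid2, seed = 7)
  r2 <- autoAdjustGaussians(tc$vol, flatAtlas(grid), grid2, seed = 7)
  expect_identical(r1$config@nGauss, r2$config@nGauss)
  expect_identical(r1$diagnostics$meanLoglik, r2$diagnostics$meanLoglik)
})

test_that("trimodal CSF/other intensities drive the count to 7 or more", {
  # informative priors with a CSF+other compartment holding three intensity
  # modes: the adjustment should prefer the larger joint counts
  grid <- isotropicGrid(14L, 3)
  sh <- grid@shape
  half <- prod(sh) / 2
  gmP <- array(0, sh); gmP[, , 1:7] <- 0.9
  csfP <- array(0, sh); csfP[, , 8:14] <- 0.9
  atlas <- tissuePriorAtlas(
    volume3D(gmP, grid@affine, "probability"),
    volume3D(array(0.05, sh), grid@affine, "probability"),
    volume3D(csfP, grid@affine, "probability"))
  tally <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- numeric(prod(sh))
    top <- as.vector(slice.index(array(0, sh), 3) >= 8)
    y[!top] <- rnorm(sum(!top), 35, 3)
    modes <- sample(c(0, 30, 80), sum(top), replace = TRUE)
    y[top] <- modes + rnorm(sum(top), 0, 3)
    vol <- volume3D(array(y, sh), grid@affine)
    sel <- autoAdjustGaussians(vol, atlas, ctConfigGrid(samplingMm = 3),
                               seed = s)
    sum(sel$config@nGauss[c("csf", "other")])
  }, numeric(1))
  expect_gt(sum(tally >= 7), sum(tally <= 6))
})

test_that("degenerate inputs are rejected", {
  grid <- isotropicGrid(10L, 2)
  const <- volume3D(array(1, grid@shape), grid@affine)
  expect_error(fitMixture(const, flatAtlas(grid)), "constant image")
})
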