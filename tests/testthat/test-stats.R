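gridVol <- function(arr, voxelMm = 2, modality = "other") {
  volume3D(arr, isotropicGrid(dim(arr), voxelMm)@affine, modality)
}

test_that("the global estimate follows the two-pass mean/8 rule", {
  sh <- c(10L, 10L, 10L)
  arr <- array(0, sh)
  arr[1:100] <- 1            # block = 10% of voxels, overall mean 0.1
  expect_equal(computeGlobal(gridVol(arr)), 1.0)
  expect_equal(computeGlobal(gridVol(array(2.7, sh))), 2.7)
  expect_error(computeGlobal(gridVol(array(0, sh))), "threshold")
})

test_that("proportional scaling equalizes globals", {
  sh <- c(8L, 8L, 8L)
  a <- gridVol(array(2, sh)); b <- gridVol(array(4, sh))
  out <- proportionalScale(list(a, b), c(2, 4))
  expect_equal(volData(out[[1]])[1], 3)   # scaled by 1.5
  expect_equal(volData(out[[2]])[1], 3)   # scaled by 0.75
  # identical images are unchanged
  same <- proportionalScale(list(a, a))
  expect_equal(volData(same[[1]]), volData(a))
  # post-scaling globals agree for random phantoms
  set.seed(30)
  imgs <- lapply(1:4, function(i)
    gridVol(array(runif(prod(sh), 0.1, 1 + i / 4), sh)))
  sc <- proportionalScale(imgs)
  g <- vapply(sc, computeGlobal, numeric(1))
  expect_lt(diff(range(g)) / mean(g), 1e-9)
  expect_error(proportionalScale(list(a), -1), "positive")
})

test_that("voxelwise t matches the scalar pooled two-sample formula", {
  set.seed(31)
  sh <- c(6L, 6L, 6L)
  n1 <- 5L; n2 <- 7L
  vals1 <- 1 + rnorm(n1, 0, 1e-3)
  vals2 <- 0 + rnorm(n2, 0, 1e-3)
  imgs <- lapply(c(vals1, vals2), function(v)
    gridVol(array(v + 0.5, sh)))   # offset keeps the mask everywhere true
  des <- groupDesign(imgs, rep(c("control", "patient"), c(n1, n2)))
  maps <- fitTwoGroupGLM(des)
  # independent scalar oracle
  x1 <- vals1 + 0.5; x2 <- vals2 + 0.5
  sp <- sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  tRef <- (mean(x1) - mean(x2)) / (sp * sqrt(1 / n1 + 1 / n2))
  expect_equal(maps@t[3, 3, 3], tRef, tolerance = 1e-10)
  expect_identical(maps@df, n1 + n2 - 2L)
})

test_that("a symmetric null yields calibrated voxel exceedances", {
  spec <- testSpec()
  cohort <- generateCohort(6, 6, spec, NULL, "ct", seed = 55)
  # skip the heavy chain: use smoothed noisy gray-matter indicators
  imgs <- lapply(seq_along(cohort$volumes), function(i) {
    gm <- volData(cohort$labels[[i]]) == phantomLabels()[["gm"]]
    set.seed(1000 + i)
    arr <- array(as.numeric(gm) + rnorm(length(gm), 0, 0.3),
                 dim(volData(cohort$labels[[i]])))
    smoothGaussian(volume3D(arr, volAffine(cohort$labels[[i]]),
                            "other"), 12)
  })
  des <- groupDesign(proportionalScale(imgs),
                     rep(c("control", "patient"), each = 6))
  maps <- fitTwoGroupGLM(des)
  tcrit <- qt(0.005, maps@df, lower.tail = FALSE)
  frac <- mean(abs(maps@t[maps@mask]) > tcrit) / 2  # one tail
  expect_lt(abs(frac - 0.005), 0.003)
  expect_lt(abs(mean(maps@t[maps@mask])), 0.05)
})

test_that("t-to-Z agrees with the printed table triples at df = 10", {
  expect_equal(tToZ(0, 5), 0)
  expect_equal(tToZ(0, 50), 0)
  expect_equal(tToZ(8.955, 10), 4.595, tolerance = 0.005 / 4.595)
  expect_equal(pt(8.955, 10, lower.tail = FALSE), 2.16e-6,
               tolerance = 0.005)
  expect_equal(tToZ(9.359, 10), 4.677, tolerance = 0.005 / 4.677)
  expect_equal(pt(9.359, 10, lower.tail = FALSE), 1.45e-6,
               tolerance = 0.005)
  expect_equal(qnorm(2.16e-6, lower.tail = FALSE), 4.595,
               tolerance = 0.001)
})

test_that("t-to-Z is odd, strictly monotone and tail-safe", {
  ts <- seq(-12, 12, by = 0.25)
  z10 <- tToZ(ts, 10)
  expect_true(all(diff(z10) > 0))
  expect_equal(z10, -rev(tToZ(rev(-ts), 10)), tolerance = 1e-12)
  # no saturation for extreme t
  z <- tToZ(c(20, 30, 40), 10)
  expect_true(all(is.finite(z)) && all(diff(z) > 0))
  # high df converges to the identity
  expect_lt(max(abs(tToZ(seq(-3, 3, 0.5), 250) - seq(-3, 3, 0.5))), 0.05)
})

statMapsFromT <- function(tArr, df = 10L, voxelMm = 2,
                          fwhm = rep(6, 3)) {
  zArr <- array(tToZ(as.numeric(tArr), df), dim(tArr))
  new("StatMaps", t = tArr, z = zArr, df = as.integer(df),
      mask = array(TRUE, dim(tArr)), residFwhmMm = fwhm,
      affine = isotropicGrid(dim(tArr), voxelMm)@affine)
}

test_that("clustering matches the flood-fill oracle on random masks", {
  set.seed(33)
  df <- 10L
  tcrit <- qt(0.005, df, lower.tail = FALSE)
  for (rep in 1:8) {
    for (conn in c(6L, 18L, 26L)) {
      mask <- array(runif(20^3) < 0.12, c(20L, 20L, 20L))
      tArr <- array(0, dim(mask)); tArr[mask] <- tcrit + 1
      maps <- statMapsFromT(tArr, df)
      cl <- thresholdAndCluster(maps, 0.005, conn, extentK = 0L)
      ref <- floodFillLabels(mask, conn)
      expect_equal(length(cl), max(ref))
      refSizes <- sort(tabulate(ref), decreasing = TRUE)
      expect_equal(vapply(cl, `[[`, numeric(1), "size"), refSizes)
      # identical partitions, not just matching size histograms
      mine <- array(0L, dim(mask))
      for (k in seq_along(cl)) mine[cl[[k]]$voxels] <- k
      expect_identical(canonicalPartition(mine) > 0,
                       canonicalPartition(ref) > 0)
      for (k in seq_along(cl)) {
        refLab <- unique(ref[cl[[k]]$voxels])
        expect_length(refLab, 1)
      }
    }
  }
})

test_that("the extent threshold removes small clusters", {
  df <- 10L
  tArr <- array(0, c(20L, 20L, 20L))
  tArr[2:6, 2:5, 2:6] <- 9       # 100 voxels
  maps <- statMapsFromT(tArr, df)
  expect_length(thresholdAndCluster(maps, 0.005, 18L, extentK = 123L), 0)
  expect_length(thresholdAndCluster(maps, 0.005, 18L, extentK = 100L), 1)
  # the printed cluster sizes 2776/630/366 all survive extent 123
  expect_true(all(c(2776, 630, 366) >= 123))
})

test_that("random-field cluster p-values behave like survival probabilities", {
  maps <- statMapsFromT(array(rnorm(16^3), c(16L, 16L, 16L)), 10L,
                        fwhm = rep(8, 3))
  expect_equal(clusterPRFT(0, maps, 0.005), 1, ignore_attr = TRUE)
  ks <- c(5, 10, 20, 40, 80, 160)
  ps <- clusterPRFT(ks, maps, 0.005)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
  bad <- maps; bad@residFwhmMm <- c(NA, 8, 8)
  expect_error(clusterPRFT(10, bad, 0.005), "smoothness")
})

test_that("permutation p-values honor the add-one rule and edge cases", {
  set.seed(34)
  sh <- c(10L, 10L, 10L)
  imgs <- lapply(1:12, function(i)
    gridVol(array(runif(prod(sh), 0.4, 0.6), sh)))
  des <- groupDesign(imgs, rep(c("control", "patient"), c(5, 7)))
  p <- clusterPPerm(des, observedSizes = c(10^9, 0), voxelP = 0.005,
                    nPerm = 199L, seed = 1, maskThreshold = 0.05)
  expect_equal(p[1], 1 / 200)   # larger than every permutation max
  expect_equal(p[2], 1)         # size zero
  tiny <- groupDesign(imgs[1:4], rep(c("control", "patient"), each = 2))
  expect_error(clusterPPerm(tiny, 5, nPerm = 100L), "distinct permutations")
})

test_that("RFT and permutation cluster p-values agree on matched nulls", {
  # cross-method consistency: the RFT uncorrected cluster p, converted to
  # the max-statistic scale by Poisson clumping (1 - exp(-Em p)), should
  # agree with the permutation estimate within a factor of 2 wherever the
  # permutation p itself is well resolved (0.1-0.9); in the extreme tail
  # both the df-10 Gaussian approximation and the Monte Carlo error of
  # 2000 permutations dominate the comparison
  set.seed(50)
  sh <- c(24L, 24L, 24L)
  mkField <- function() {
    v <- volume3D(array(rnorm(prod(sh)), sh), isotropicGrid(sh, 2)@affine)
    sm <- smoothGaussian(v, 8)
    sm@data <- sm@data / sd(sm@data) + 3
    sm
  }
  checked <- 0L
  for (rep in 1:6) {
    imgs <- lapply(1:12, function(i) mkField())
    des <- groupDesign(imgs, rep(c("control", "patient"), c(5, 7)))
    maps <- fitTwoGroupGLM(des, maskThreshold = -10)
    cl <- thresholdAndCluster(maps, 0.005, 18L, 0L)
    if (!length(cl)) next
    k <- vapply(cl, `[[`, numeric(1), "size")[1]
    pR <- clusterPRFT(k, maps, 0.005)
    pRmax <- 1 - exp(-attr(pR, "expectedClusters") * as.numeric(pR))
    pP <- clusterPPerm(des, k, 0.005, 18L, nPerm = 2000L, seed = rep,
                       maskThreshold = -10)
    if (pP < 0.1 || pP > 0.9) next
    expect_lt(abs(log2(pRmax / pP)), 1)
    checked <- checked + 1L
  }
  expect_gte(checked, 2L)
})

test_that("permutation p-values are super-uniform under the null", {
  # observed cluster sizes from truly null data: P(p <= x) must not
  # exceed x beyond binomial fluctuation
  set.seed(44)
  sh <- c(8L, 8L, 8L)
  ps <- replicate(40, {
    imgs <- lapply(1:10, function(i)
      gridVol(array(0.5 + rnorm(prod(sh), 0, 0.05), sh)))
    des <- groupDesign(imgs, rep(c("control", "patient"), each = 5))
    maps <- fitTwoGroupGLM(des, maskThreshold = 0.05)
    cl <- thresholdAndCluster(maps, 0.01, 18L, 0L)
    obs <- if (length(cl)) cl[[1]]$size else 0
    clusterPPerm(des, obs, voxelP = 0.01, nPerm = 120L,
                 seed = sample.int(1e6, 1))
  })
  for (x in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(ps <= x), x + 2.5 * sqrt(x * (1 - x) / 40))
})

test_that("BH selection matches the hand-computed step-up rule", {
  expect_identical(fdrSelect(0.001, 0.05), TRUE)
  expect_identical(fdrSelect(c(0.01, 0.02, 0.20), 0.05),
                   c(TRUE, TRUE, FALSE))
  expect_identical(fdrSelect(rep(1, 4), 0.05), rep(FALSE, 4))
  expect_identical(fdrSelect(numeric(0), 0.05), logical(0))
  # independent step-up oracle on random p-values
  set.seed(35)
  for (i in 1:20) {
    ps <- runif(sample(1:8, 1))^2
    m <- length(ps)
    ord <- order(ps)
    passes <- which(ps[ord] <= seq_len(m) * 0.05 / m)
    ref <- rep(FALSE, m)
    if (length(passes)) ref[ord[seq_len(max(passes))]] <- TRUE
    expect_identical(fdrSelect(ps, 0.05), ref)
  }
})

test_that("the cluster table reports peaks with the documented schema", {
  df <- 10L
  tArr <- array(0, c(20L, 20L, 20L))
  tArr[4:8, 4:8, 4:8] <- 5
  tArr[6, 6, 6] <- 9            # unique maximum
  maps <- statMapsFromT(tArr, df)
  cl <- thresholdAndCluster(maps, 0.005, 18L, 0L)
  tab <- makeClusterTable(cl, maps, clusterPs = 0.01,
                          fdrSignificant = TRUE)
  expect_identical(names(tab),
                   c("cluster_size_voxels", "volume_mm3",
                     "peak_p_uncorrected", "peak_t", "peak_z", "x_mm",
                     "y_mm", "z_mm", "cluster_p", "fdr_significant"))
  expect_equal(tab$cluster_size_voxels[1], 125)
  expect_equal(tab$peak_t[1], 9)
  peakWorld <- ctvbm:::voxelToWorld(maps@affine, c(5, 5, 5))
  expect_equal(unlist(tab[1, c("x_mm", "y_mm", "z_mm")]), drop(peakWorld),
               ignore_attr = TRUE)
  # 123 voxels at 2 mm convert to 984 mm^3
  tArr2 <- array(0, c(20L, 20L, 20L))
  set.seed(36)
  blob <- sample(which(array(TRUE, c(20, 20, 20))), 123)
  # a connected 123-voxel bar instead: 123 = 3 x 41
  tArr2 <- array(0, c(45L, 10L, 10L))
  tArr2[1:41, 2:4, 5] <- 9
  maps2 <- statMapsFromT(tArr2, df)
  cl2 <- thresholdAndCluster(maps2, 0.005, 18L, 0L)
  tab2 <- makeClusterTable(cl2, maps2)
  expect_equal(tab2$cluster_size_voxels[1], 123)
  expect_equal(tab2$volume_mm3[1], 984)
  # peaks are at least 8 mm apart, at most 3 per cluster
  expect_lte(sum(tab2$cluster_size_voxels == 123), 3)
})

test_that("group designs require two images per group on one grid", {
  sh <- c(6L, 6L, 6L)
  imgs <- lapply(1:3, function(i) gridVol(array(1, sh)))
  expect_error(groupDesign(imgs, c("control", "control", "patient")),
               "at least 2")
})
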