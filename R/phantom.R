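# Synthetic head phantom: paired CT/T1-MR renderings of a labeled head
# geometry with inter-subject jitter and injectable regional atrophy. This
# is the test substrate for the whole pipeline; it emulates a two-group
# cross-sectional cohort, not scanner physics.

#' Tissue label codes of the head phantom
#'
#' @return named integer vector: air 0, skin 1, skull 2, holder 3, csf 4,
#'   gm 5, wm 6.
#' @export
phantomLabels <- function() {
  c(air = 0L, skin = 1L, skull = 2L, holder = 3L, csf = 4L, gm = 5L,
    wm = 6L)
}

#' Construct a head-phantom specification
#'
#' Geometry is a set of nested ellipsoidal shells (white matter core, gray
#' matter shell with a sinusoidally perturbed inner boundary standing in for
#' gyrification, subarachnoid CSF, skull, skin) plus central ventricles and
#' an optional detached head-holder slab below the head. Intensity means sit
#' inside published physiological ranges; in particular the CT gray/white
#' contrast is a realistically small 8 HU (35 vs 27).
#'
#' @param grid \linkS4class{GridSpec} to render on (default 48^3 at 4 mm).
#' @param brainCenterMm,brainRadiiMm brain ellipsoid placement, mm.
#' @param gmThicknessMm mean cortical shell thickness, mm.
#' @param gyralAmpFrac,gyralWavelengthMm amplitude (fraction of GM
#'   thickness) and wavelength of the pseudo-gyral perturbation.
#' @param csfShellMm,skullShellMm,skinShellMm shell thicknesses, mm.
#' @param ventricleRadiiMm central CSF ellipsoid radii, mm.
#' @param holder include the head-holder slab?
#' @param holderGapMm,holderThicknessMm holder placement below the head.
#' @param ctMeansHu,ctNoiseSdHu CT rendering model (HU).
#' @param mrMeans,mrNoiseSd,mrBiasAmp MR rendering model (arbitrary units).
#' @param jitterLogScaleSd,jitterRotSdDeg,jitterTransSdMm,jitterWarpAmpMm
#'   inter-subject variability of the cohort generator.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(grid = isotropicGrid(48L, 4),
                        brainCenterMm = c(0, 0, 12),
                        brainRadiiMm = c(60, 72, 55),
                        gmThicknessMm = 11,
                        gyralAmpFrac = 0.25,
                        gyralWavelengthMm = 30,
                        csfShellMm = 3, skullShellMm = 6, skinShellMm = 5,
                        ventricleRadiiMm = c(14, 20, 12),
                        holder = TRUE, holderGapMm = 6,
                        holderThicknessMm = 8,
                        ctMeansHu = c(air = -1000, skin = 40, skull = 1000,
                                      holder = 60, csf = 8, gm = 35,
                                      wm = 27),
                        ctNoiseSdHu = 5,
                        mrMeans = c(air = 0, skin = 50, skull = 20,
                                    holder = 0, csf = 10, gm = 60, wm = 90),
                        mrNoiseSd = 5, mrBiasAmp = 0.2,
                        jitterLogScaleSd = 0.02, jitterRotSdDeg = 2,
                        jitterTransSdMm = 2, jitterWarpAmpMm = 2) {
  geometry <- list(brainCenterMm = brainCenterMm,
                   brainRadiiMm = brainRadiiMm,
                   gmThicknessMm = gmThicknessMm,
                   gyralAmpFrac = gyralAmpFrac,
                   gyralWavelengthMm = gyralWavelengthMm,
                   csfShellMm = csfShellMm, skullShellMm = skullShellMm,
                   skinShellMm = skinShellMm,
                   ventricleRadiiMm = ventricleRadiiMm,
                   holder = holder, holderGapMm = holderGapMm,
                   holderThicknessMm = holderThicknessMm,
                   ctNoiseSdHu = ctNoiseSdHu, mrNoiseSd = mrNoiseSd,
                   mrBiasAmp = mrBiasAmp)
  jitter <- list(logScaleSd = jitterLogScaleSd, rotSdDeg = jitterRotSdDeg,
                 transSdMm = jitterTransSdMm, warpAmpMm = jitterWarpAmpMm)
  new("PhantomSpec", grid = grid, geometry = geometry,
      ctMeansHu = ctMeansHu, mrMeans = mrMeans, jitter = jitter)
}

#' Construct an atrophy specification
#'
#' @param centerMm world coordinate of the lesion sphere center.
#' @param radiusMm sphere radius, mm.
#' @param severity fraction in (0, 1] of GM voxels inside the sphere
#'   converted to CSF.
#' @return an \linkS4class{AtrophySpec}.
#' @export
atrophySpec <- function(centerMm, radiusMm = 10, severity = 0.3) {
  new("AtrophySpec", centerMm = centerMm, radiusMm = radiusMm,
      severity = severity)
}

#' Default medial lesion site for a phantom
#'
#' A point on the mid-thickness of the gray-matter shell along the +y axis,
#' emulating medial temporal atrophy.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return world coordinate (length 3).
#' @export
defaultAtrophyCenter <- function(spec) {
  g <- spec@geometry
  rMean <- exp(mean(log(g$brainRadiiMm)))
  f <- g$gmThicknessMm / rMean
  g$brainCenterMm + c(0, g$brainRadiiMm[2] * (1 - f / 2), 0)
}

# Per-voxel world coordinates of a grid as separable axis vectors.
gridAxes <- function(grid) {
  grid <- asGridSpec(grid)
  box <- axisAlignedBox(grid)
  list(x = box$x0[1] + (seq_len(grid@shape[1]) - 0.5) * box$vox[1],
       y = box$x0[2] + (seq_len(grid@shape[2]) - 0.5) * box$vox[2],
       z = box$x0[3] + (seq_len(grid@shape[3]) - 0.5) * box$vox[3])
}

#' Generate the phantom tissue label volume
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param seed seed for the gyral-perturbation phases.
#' @return a label \linkS4class{Volume3D} (codes per [phantomLabels()]).
#' @export
makeLabels <- function(spec, seed = 1L) {
  g <- spec@geometry
  rMean <- exp(mean(log(g$brainRadiiMm)))
  fGm <- g$gmThicknessMm / rMean
  fCsf <- g$csfShellMm / rMean
  fSkull <- g$skullShellMm / rMean
  fSkin <- g$skinShellMm / rMean
  if (fGm <= 0 || fCsf <= 0 || fSkull <= 0 || fSkin <= 0)
    stop("degenerate geometry: non-nested shells")
  if (any(g$ventricleRadiiMm >= g$brainRadiiMm * (1 - fGm)))
    stop("degenerate geometry: ventricles reach the cortical shell")

  ax <- gridAxes(spec@grid)
  sh <- spec@grid@shape
  dx <- (ax$x - g$brainCenterMm[1])
  dy <- (ax$y - g$brainCenterMm[2])
  dz <- (ax$z - g$brainCenterMm[3])
  rho2 <- outer(outer((dx / g$brainRadiiMm[1])^2,
                      (dy / g$brainRadiiMm[2])^2, "+"),
                (dz / g$brainRadiiMm[3])^2, "+")
  rho <- sqrt(rho2)

  ph <- withSeed(seed, runif(3, 0, 2 * pi))
  wl <- g$gyralWavelengthMm
  pert <- outer(outer(sin(2 * pi * ax$x / wl + ph[1]),
                      sin(2 * pi * ax$y / wl + ph[2])),
                sin(2 * pi * ax$z / wl + ph[3]))
  gmInner <- 1 - fGm * (1 + g$gyralAmpFrac * pert)

  lab <- array(phantomLabels()[["air"]], sh)
  lab[rho <= 1 + fCsf + fSkull + fSkin] <- phantomLabels()[["skin"]]
  lab[rho <= 1 + fCsf + fSkull] <- phantomLabels()[["skull"]]
  lab[rho <= 1 + fCsf] <- phantomLabels()[["csf"]]
  lab[rho <= 1] <- phantomLabels()[["gm"]]
  lab[rho <= gmInner] <- phantomLabels()[["wm"]]
  vr2 <- outer(outer((dx / g$ventricleRadiiMm[1])^2,
                     (dy / g$ventricleRadiiMm[2])^2, "+"),
               (dz / g$ventricleRadiiMm[3])^2, "+")
  lab[vr2 <= 1] <- phantomLabels()[["csf"]]

  if (isTRUE(g$holder)) {
    zBottom <- g$brainCenterMm[3] -
      g$brainRadiiMm[3] * (1 + fCsf + fSkull + fSkin)
    zHi <- zBottom - g$holderGapMm
    zLo <- zHi - g$holderThicknessMm
    inz <- ax$z >= zLo & ax$z <= zHi
    inx <- abs(dx) <= 0.8 * g$brainRadiiMm[1]
    iny <- abs(dy) <= 0.9 * g$brainRadiiMm[2]
    slab <- outer(outer(inx, iny), inz)
    lab[slab & lab == phantomLabels()[["air"]]] <-
      phantomLabels()[["holder"]]
  }
  volume3D(lab, spec@grid@affine, "label")
}

#' Inject spherical gray-matter atrophy into a label volume
#'
#' Inside the lesion sphere each GM voxel is independently reassigned to CSF
#' with probability `severity`; everything else is untouched.
#'
#' @param labels a label \linkS4class{Volume3D}.
#' @param atrophy an \linkS4class{AtrophySpec}.
#' @param seed seed for the per-voxel Bernoulli draws.
#' @return the modified label \linkS4class{Volume3D}.
#' @export
applyAtrophy <- function(labels, atrophy, seed = 1L) {
  ax <- gridAxes(asGridSpec(labels))
  r2 <- outer(outer((ax$x - atrophy@centerMm[1])^2,
                    (ax$y - atrophy@centerMm[2])^2, "+"),
              (ax$z - atrophy@centerMm[3])^2, "+")
  inside <- r2 <= atrophy@radiusMm^2
  gmIn <- which(inside & labels@data == phantomLabels()[["gm"]])
  if (!length(gmIn)) stop("atrophy sphere does not intersect gray matter")
  hit <- withSeed(seed, runif(length(gmIn)) < atrophy@severity)
  out <- labels@data
  out[gmIn[hit]] <- phantomLabels()[["csf"]]
  volume3D(out, labels@affine, "label")
}

renderFromMeans <- function(labels, means, noiseSd, seed,
                            clip = NULL, bias = NULL, modality,
                            fractions = NULL) {
  if (is.null(fractions)) {
    lut <- means[c("air", "skin", "skull", "holder", "csf", "gm", "wm")]
    out <- array(lut[labels@data + 1L], dim(labels@data))
  } else {
    out <- array(as.vector(fractions %*% means[colnames(fractions)]),
                 dim(labels@data))
  }
  if (!is.null(bias)) out <- out * bias
  if (noiseSd > 0)
    out <- out + withSeed(seed, rnorm(length(out), 0, noiseSd))
  if (!is.null(clip)) out <- pmin(pmax(out, clip[1]), clip[2])
  volume3D(array(out, dim(labels@data)), labels@affine, modality)
}

# Smooth multiplicative bias field with a fixed dynamic range of
# exp(1.25 * amp) across the grid.
mrBiasField <- function(grid, biasAmp, seed) {
  if (biasAmp <= 0) return(NULL)
  ax <- gridAxes(asGridSpec(grid))
  ph <- withSeed(seed + 7L, runif(3, 0, 2 * pi))
  L <- vapply(ax, function(v) diff(range(v)) + 1e-9, numeric(1))
  s <- outer(outer(cos(pi * (ax$x - ax$x[1]) / L[1] + ph[1]),
                   cos(pi * (ax$y - ax$y[1]) / L[2] + ph[2]), "+"),
             cos(pi * (ax$z - ax$z[1]) / L[3] + ph[3]), "+")
  s <- (s - (max(s) + min(s)) / 2) / (max(s) - min(s)) * 1.25
  exp(biasAmp * s)
}

#' Render a CT volume from phantom labels
#'
#' Per-tissue Hounsfield means plus white Gaussian noise, clipped to the
#' 12-bit CT range \[-1024, 3071\].
#'
#' @param labels a label \linkS4class{Volume3D}.
#' @param noiseSdHu noise standard deviation, HU.
#' @param seed noise seed.
#' @param meansHu named per-tissue HU means.
#' @return a CT \linkS4class{Volume3D}.
#' @export
renderCT <- function(labels, noiseSdHu = 5, seed = 1L,
                     meansHu = phantomSpec()@ctMeansHu) {
  renderFromMeans(labels, meansHu, noiseSdHu, seed,
                  clip = c(-1024, 3071), modality = "ct")
}

#' Render a T1-weighted MR volume from phantom labels
#'
#' T1-like per-tissue means (WM > GM > CSF) times a smooth multiplicative
#' bias field plus white Gaussian noise. The bias field is
#' `exp(biasAmp * s(x))` with `s` a three-axis cosine profile normalized to
#' a fixed range of 1.25, so `biasAmp = 0.2` gives a max/min ratio of
#' exp(0.25) ~ 1.28 by construction.
#'
#' @param labels a label \linkS4class{Volume3D}.
#' @param noiseSd noise standard deviation (intensity units).
#' @param biasAmp bias-field amplitude; 0 disables it.
#' @param seed noise/bias-phase seed.
#' @param means named per-tissue intensity means.
#' @return an MR \linkS4class{Volume3D}.
#' @export
renderMR <- function(labels, noiseSd = 5, biasAmp = 0.2, seed = 1L,
                     means = phantomSpec()@mrMeans) {
  bias <- mrBiasField(labels, biasAmp, seed)
  renderFromMeans(labels, means, noiseSd, seed, bias = bias,
                  modality = "mr")
}

# Source-voxel coordinates of a random subject transform (small affine plus
# smooth low-frequency warp) evaluated at every voxel of `outGrid`.
# Consumes RNG.
jitterCoords <- function(labels, jitter, center,
                         outGrid = asGridSpec(labels)) {
  rot <- rnorm(3, 0, jitter$rotSdDeg * pi / 180)
  logsc <- rnorm(3, 0, jitter$logScaleSd)
  trans <- rnorm(3, 0, jitter$transSdMm)
  A <- composeAffine(trans, rot, logsc, c(0, 0, 0), center)
  grid <- asGridSpec(outGrid)
  box <- axisAlignedBox(grid)
  nb <- c(3L, 3L, 3L)
  C <- matrix(rnorm(prod(nb) * 3), prod(nb), 3)
  ax <- gridAxes(grid)
  bx <- dctAxisWorld(ax$x, box$x0[1], box$fov[1], nb[1])
  by <- dctAxisWorld(ax$y, box$x0[2], box$fov[2], nb[2])
  bz <- dctAxisWorld(ax$z, box$x0[3], box$fov[3], nb[3])
  U <- vapply(1:3, function(a)
    as.numeric(dctEvalSeparable(C[, a], bx, by, bz)),
    numeric(prod(grid@shape)))
  rms <- sqrt(mean(rowSums(U^2)))
  if (rms > 0) U <- U * (jitter$warpAmpMm / rms)
  n <- prod(grid@shape)
  X <- cbind(rep(ax$x, times = prod(grid@shape[2:3])),
             rep(rep(ax$y, each = grid@shape[1]), times = grid@shape[3]),
             rep(ax$z, each = prod(grid@shape[1:2]))) + U
  Y <- X %*% t(A[1:3, 1:3]) + rep(A[1:3, 4], each = n)
  worldToVoxel(labels@affine, Y)
}

# Resample a label volume through a subject transform, nearest-neighbour.
jitterLabels <- function(labels, jitter, center) {
  coords <- jitterCoords(labels, jitter, center)
  out <- cppSampleAt(as.numeric(labels@data), dim(labels@data), coords, 1L)
  volume3D(array(out, dim(labels@data)), labels@affine, "label")
}

# Per-tissue partial-volume fractions of a transformed label volume: the
# transform is applied to the tissue indicators with trilinear weighting, so
# an output voxel carries the tissue mixture it covers (the anti-aliased
# model of a scanner voxel). Out-of-field weight is assigned to air.
jitterFractions <- function(labels, coords) {
  codes <- phantomLabels()
  fr <- cppLabelFractions(as.integer(labels@data), dim(labels@data),
                          coords, length(codes))
  colnames(fr) <- names(codes)
  fr
}

#' Generate a two-group phantom cohort
#'
#' Each subject is an independently jittered copy of the canonical phantom
#' (random small affine plus smooth warp); patients additionally receive the
#' atrophy lesion before jittering. Rendering is anti-aliased: the subject
#' transform is applied to the per-tissue indicator maps with trilinear
#' interpolation, so each rendered voxel carries the tissue mixture it
#' covers -- the partial-volume behaviour of a real scanner voxel -- rather
#' than a nearest-neighbour re-discretization of the thin cortical shell.
#' Per-subject truth labels are the majority tissue of each voxel. Fully
#' reproducible from `seed`. The default 7 controls vs 5 patients mirrors a
#' small case-control morphometry study.
#'
#' @param nCtrl,nPat group sizes (>= 2 each).
#' @param spec a \linkS4class{PhantomSpec}.
#' @param atrophy an \linkS4class{AtrophySpec}, or `NULL` for a null cohort.
#' @param modality `"ct"` or `"mr"`.
#' @param seed master seed.
#' @param outDir optional directory; when given, volumes, truth labels,
#'   `groups.tsv` and the spec (JSON) are written there.
#' @param renderVoxelMm optional isotropic voxel size for the rendered
#'   volumes; the anatomy (and the atrophy draw) stays on the spec's label
#'   grid while acquisition is rendered finer, the way an MR acquisition
#'   resolves structures that a coarse label grid defines. `NULL` renders
#'   on the label grid.
#' @return list with `volumes` (list of \linkS4class{Volume3D}), `labels`
#'   (per-subject truth labels), `groups` (data.frame subject/group),
#'   `spec`, `atrophy`, `modality`, `seed`.
#' @export
generateCohort <- function(nCtrl = 7L, nPat = 5L, spec = phantomSpec(),
                           atrophy = NULL, modality = c("ct", "mr"),
                           seed = 1L, outDir = NULL, renderVoxelMm = NULL) {
  modality <- match.arg(modality)
  stopifnot(nCtrl >= 2L, nPat >= 2L)
  base <- makeLabels(spec, seed = seed)
  patBase <- if (is.null(atrophy)) base else
    applyAtrophy(base, atrophy, seed = seed + 1L)
  g <- spec@geometry
  n <- nCtrl + nPat
  groups <- data.frame(
    subject = sprintf("sub-%02d", seq_len(n)),
    group = rep(c("control", "patient"), c(nCtrl, nPat)),
    stringsAsFactors = FALSE)
  volumes <- vector("list", n)
  labels <- vector("list", n)
  outGrid <- if (is.null(renderVoxelMm)) asGridSpec(base) else {
    box <- axisAlignedBox(asGridSpec(base))
    isotropicGrid(as.integer(round(box$fov / renderVoxelMm)), renderVoxelMm,
                  centerMm = box$x0 + box$fov / 2)
  }
  withSeed(seed + 2L, {
    for (i in seq_len(n)) {
      src <- if (groups$group[i] == "patient") patBase else base
      coords <- jitterCoords(src, spec@jitter, g$brainCenterMm, outGrid)
      fr <- jitterFractions(src, coords)
      codes <- phantomLabels()
      lab <- volume3D(array(unname(codes)[max.col(fr, ties.method =
                                                    "first")],
                            outGrid@shape), outGrid@affine, "label")
      noiseSeed <- seed + 100L + i
      volumes[[i]] <- if (modality == "ct")
        renderFromMeans(lab, spec@ctMeansHu, g$ctNoiseSdHu,
                        seed = noiseSeed, clip = c(-1024, 3071),
                        modality = "ct", fractions = fr)
      else
        renderFromMeans(lab, spec@mrMeans, g$mrNoiseSd, seed = noiseSeed,
                        bias = mrBiasField(lab, g$mrBiasAmp, noiseSeed),
                        modality = "mr", fractions = fr)
      labels[[i]] <- lab
    }
  })
  out <- list(volumes = volumes, labels = labels, groups = groups,
              spec = spec, atrophy = atrophy, modality = modality,
              seed = seed)
  if (!is.null(outDir)) writeCohort(out, outDir)
  out
}

writeCohort <- function(cohort, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$volumes)) {
    id <- cohort$groups$subject[i]
    writeVolume(cohort$volumes[[i]],
                file.path(outDir, sprintf("%s_%s.nii.gz", id,
                                          cohort$modality)))
    writeVolume(cohort$labels[[i]],
                file.path(outDir, sprintf("%s_labels.nii.gz", id)))
  }
  write.table(cohort$groups, file.path(outDir, "groups.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  specJson <- list(geometry = cohort$spec@geometry,
                   ctMeansHu = as.list(cohort$spec@ctMeansHu),
                   mrMeans = as.list(cohort$spec@mrMeans),
                   jitter = cohort$spec@jitter,
                   modality = cohort$modality, seed = cohort$seed)
  jsonlite::write_json(specJson, file.path(outDir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Tissue-prior atlas derived from the phantom geometry
#'
#' Builds template-space priors as population averages: tissue indicator
#' maps are averaged across several independent gyral-phase draws of the
#' canonical geometry and then smoothed, exactly how real tissue
#' probability maps are population averages rather than any one subject's
#' anatomy (a synthetic stand-in for such an atlas). The smoothed GM prior
#' doubles as the normalization template.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param fwhmMm smoothing applied to the averaged indicator maps, mm.
#' @param seeds phase seeds averaged over (kept independent of cohort seeds
#'   so the atlas never matches any study subject exactly).
#' @param outGrid optional \linkS4class{GridSpec} to resample the priors
#'   onto (for arms whose acquisitions are rendered finer than the label
#'   grid).
#' @return a \linkS4class{TissuePriorAtlas}.
#' @export
phantomAtlas <- function(spec = phantomSpec(), fwhmMm = 6,
                         seeds = 1000:1005, outGrid = NULL) {
  labs <- lapply(seeds, function(s) makeLabels(spec, seed = s))
  ind <- function(code) {
    acc <- Reduce(`+`, lapply(labs, function(l)
      array(as.numeric(l@data == code), dim(l@data)))) / length(labs)
    sm <- smoothGaussian(volume3D(acc, labs[[1]]@affine, "probability"),
                         fwhmMm)
    if (is.null(outGrid)) sm else resampleToGrid(sm, outGrid)
  }
  gm <- ind(phantomLabels()[["gm"]])
  wm <- ind(phantomLabels()[["wm"]])
  csf <- ind(phantomLabels()[["csf"]])
  tot <- gm@data + wm@data + csf@data
  over <- tot > 1
  if (any(over)) {
    gm@data[over] <- gm@data[over] / tot[over]
    wm@data[over] <- wm@data[over] / tot[over]
    csf@data[over] <- csf@data[over] / tot[over]
  }
  tissuePriorAtlas(gm, wm, csf, template = gm)
}
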