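#' Default pipeline configuration
#'
#' Fills every tunable of the VBM chain with its modality-appropriate
#' default: CT uses the heavy-regularization segmentation regime (bias off,
#' 2 mm sampling), warp cutoff 35 mm and extent threshold 123 voxels; MR
#' uses the light regime (bias on, 3 mm sampling), cutoff 25 mm and extent
#' 381. The analysis grid is 2 mm isotropic over the template field of view,
#' smoothing is 12-mm FWHM, voxel threshold P < 0.005 one-tailed
#' (controls > patients), cluster FDR q = 0.05 at connectivity 18.
#'
#' @param modality `"ct"` or `"mr"`.
#' @return named list of configuration values (every [runVBM()] knob).
#' @export
vbmDefaults <- function(modality = c("ct", "mr")) {
  modality <- match.arg(modality)
  list(modality = modality,
       segPreset = if (modality == "ct") "ct-default" else "mr-default",
       autoAdjust = FALSE,
       ctLoHu = 0, ctHiHu = 100, ctBoneHu = 300, ctCloseMm = 4,
       cutoffMm = if (modality == "ct") 35 else 25,
       regLambda = 1, warp = TRUE, warpIter = 3L, normSampleMm = 8,
       estFwhmMm = 8, priorAlign = TRUE,
       affineMaxit = 40L,
       analysisVoxelMm = 2, fwhmMm = 12,
       voxelP = 0.005, extentK = if (modality == "ct") 123L else 381L,
       clusterQ = 0.05, connectivity = 18L,
       mode = "rft", nPerm = 2000L,
       maskThreshold = 0.05, seed = 1L, outDir = NULL)
}

# Analysis grid: axis-aligned isotropic grid covering the template FOV.
analysisGridFor <- function(templateGrid, voxelMm) {
  box <- axisAlignedBox(asGridSpec(templateGrid))
  shape <- pmax(2L, as.integer(ceiling(box$fov / voxelMm)))
  isotropicGrid(shape, voxelMm, centerMm = box$x0 + box$fov / 2)
}

loadAtlasDir <- function(dir) {
  rd <- function(f) readVolume(file.path(dir, f), modality = "probability")
  tissuePriorAtlas(rd("gm.nii.gz"), rd("wm.nii.gz"), rd("csf.nii.gz"),
                   template = rd("template.nii.gz"))
}

#' Write a tissue-prior atlas to a directory
#'
#' @param atlas a \linkS4class{TissuePriorAtlas}.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeAtlasDir <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeVolume(atlas@gm, file.path(dir, "gm.nii.gz"))
  writeVolume(atlas@wm, file.path(dir, "wm.nii.gz"))
  writeVolume(atlas@csf, file.path(dir, "csf.nii.gz"))
  writeVolume(atlas@template, file.path(dir, "template.nii.gz"))
  invisible(dir)
}

# Scalar configuration fingerprint used to validate the stage cache.
configFingerprint <- function(cfg, subjects) {
  keep <- cfg[vapply(cfg, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  keep$outDir <- NULL
  jsonlite::toJSON(list(cfg = keep[order(names(keep))], subjects = subjects),
                   auto_unbox = TRUE, digits = NA)
}

# One subject through strip -> segment -> normalize -> smooth. `shared`
# carries per-run precomputed objects (prior matrix, smoothed template).
processSubject <- function(vol, atlas, analysisGrid, cfg, subjectSeed,
                           shared = NULL) {
  mask <- NULL
  if (cfg$modality == "ct") {
    bs <- extractBrainCT(vol, ctWindow(cfg$ctLoHu, cfg$ctHiHu, cfg$ctBoneHu),
                         closeRadiusMm = cfg$ctCloseMm)
    vol <- bs$brain
    mask <- bs$mask
  }
  reg <- matchPriorGrid(vol, asGridSpec(atlas@gm))
  scfg <- if (is(cfg$segPreset, "SegmentationConfig")) cfg$segPreset
  else segPreset(cfg$segPreset)
  segAtlas <- atlas
  segPriors <- shared$priors
  if (isTRUE(cfg$priorAlign)) {
    ind <- if (!is.null(mask)) {
      # CT: the brain mask, carried through the same grid placement
      matchPriorGrid(volume3D(array(as.numeric(mask@mask), dim(mask@mask)),
                              mask@affine, "probability"),
                     asGridSpec(atlas@gm),
                     initAffine = attr(reg, "initAffine"))
    } else {
      # MR: intracranial posterior of a first-pass segmentation
      pre <- fitMixture(reg, atlas, scfg, seed = subjectSeed,
                        priors = shared$priors)
      volume3D(1 - pre$posterior@prob[, , , "other"], reg@affine,
               "probability")
    }
    segAtlas <- alignPriorsToSubject(atlas, ind, icv = shared$icv)
    segPriors <- NULL
  }
  if (isTRUE(cfg$autoAdjust) && cfg$modality == "ct") {
    fit <- autoAdjustGaussians(reg, segAtlas, seed = subjectSeed)
  } else {
    fit <- fitMixture(reg, segAtlas, scfg, seed = subjectSeed,
                      priors = segPriors)
  }
  gm <- extractGrayMatter(fit$posterior)
  gmS <- if (cfg$estFwhmMm > 0) smoothGaussian(gm, cfg$estFwhmMm) else gm
  tplS <- if (!is.null(shared$templateSmooth)) shared$templateSmooth
  else if (cfg$estFwhmMm > 0) smoothGaussian(atlas@template, cfg$estFwhmMm)
  else atlas@template
  aff <- estimateAffine(gmS, tplS, sampleMm = cfg$normSampleMm,
                        maxit = cfg$affineMaxit, estFwhmMm = 0)
  params <- if (isTRUE(cfg$warp))
    estimateWarp(gmS, tplS, aff, cutoffMm = cfg$cutoffMm,
                 regLambda = cfg$regLambda, sampleMm = cfg$normSampleMm,
                 nIter = cfg$warpIter, estFwhmMm = 0)
  else {
    p <- identityNormalization(asGridSpec(atlas@template), cfg$cutoffMm,
                               cfg$regLambda)
    p@affine <- aff
    p
  }
  wgm <- applyNormalization(gm, params, analysisGrid)
  smoothGaussian(wgm, cfg$fwhmMm)
}

#' Run the full VBM pipeline on a cohort
#'
#' Orchestrates the chain strip (CT only) -> mixture segmentation ->
#' spatial normalization -> smoothing -> proportional scaling -> two-group
#' GLM -> cluster-extent thresholding -> cluster-level FDR, and returns the
#' statistical maps plus the cluster table. Configuration is a single
#' declarative list (see [vbmDefaults()]); with `outDir` set, per-subject
#' smoothed maps are cached and reused on re-runs with an identical
#' configuration, and all maps, the cluster table (TSV) and a JSON run log
#' are written under `outDir`.
#'
#' @param cohort either the list returned by [generateCohort()] or a list
#'   with `volumes` (list of \linkS4class{Volume3D}) and `groups`
#'   (data.frame with columns subject, group).
#' @param atlas a \linkS4class{TissuePriorAtlas} or a directory written by
#'   [writeAtlasDir()].
#' @param config configuration list; missing entries fall back to
#'   [vbmDefaults()] for the cohort's modality. May also be a path to a
#'   YAML file with the same keys.
#' @return list with `maps` (\linkS4class{StatMaps}), `clusters`,
#'   `table` (the cluster table), `smoothed` (per-subject maps), `config`.
#' @export
runVBM <- function(cohort, atlas, config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  modality <- config$modality %||% cohort$modality %||% "ct"
  cfg <- utils::modifyList(vbmDefaults(modality), config)
  if (is.character(atlas)) atlas <- loadAtlasDir(atlas)
  volumes <- cohort$volumes
  groups <- cohort$groups
  n <- length(volumes)
  stopifnot(n == nrow(groups))
  analysisGrid <- analysisGridFor(asGridSpec(atlas@template),
                                  cfg$analysisVoxelMm)
  fp <- configFingerprint(cfg, groups$subject)

  outDir <- cfg$outDir
  cacheDir <- NULL
  if (!is.null(outDir)) {
    for (d in c("maps", "tables", "logs", "cache"))
      dir.create(file.path(outDir, d), recursive = TRUE,
                 showWarnings = FALSE)
    cacheDir <- file.path(outDir, "cache")
    fpFile <- file.path(cacheDir, "config.json")
    if (file.exists(fpFile) &&
        !identical(paste(readLines(fpFile, warn = FALSE), collapse = "\n"),
                   as.character(fp))) {
      unlink(list.files(cacheDir, full.names = TRUE))
    }
    writeLines(as.character(fp), fpFile)
  }

  shared <- list(priors = priorMatrix(atlas),
                 templateSmooth = if (cfg$estFwhmMm > 0)
                   smoothGaussian(atlas@template, cfg$estFwhmMm)
                 else atlas@template,
                 icv = volume3D(atlas@gm@data + atlas@wm@data +
                                  atlas@csf@data, atlas@gm@affine,
                                "probability"))
  smoothed <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- if (!is.null(cacheDir))
      file.path(cacheDir, sprintf("%s_swgm.nii.gz", groups$subject[i]))
    if (!is.null(cf) && file.exists(cf)) {
      smoothed[[i]] <- readVolume(cf, modality = "probability")
      next
    }
    smoothed[[i]] <- tryCatch(
      processSubject(volumes[[i]], atlas, analysisGrid, cfg,
                     subjectSeed = cfg$seed + 10L * i, shared = shared),
      error = function(e) stop("subject ", groups$subject[i],
                               " failed during processing: ",
                               conditionMessage(e)))
    if (!is.null(cf)) writeVolume(smoothed[[i]], cf)
  }
  d0 <- dim(smoothed[[1]]@data)
  for (i in seq_len(n))
    if (!all(dim(smoothed[[i]]@data) == d0) ||
        max(abs(smoothed[[i]]@affine - smoothed[[1]]@affine)) > 1e-4)
      stop("mixed grids across subjects detected before statistics")

  scaled <- proportionalScale(smoothed)
  design <- groupDesign(scaled, groups$group)
  maps <- fitTwoGroupGLM(design, maskThreshold = cfg$maskThreshold)
  clusters <- thresholdAndCluster(maps, voxelP = cfg$voxelP,
                                  connectivity = cfg$connectivity,
                                  extentK = cfg$extentK)
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  ps <- if (!length(clusters)) numeric(0)
  else if (cfg$mode == "perm")
    clusterPPerm(design, sizes, voxelP = cfg$voxelP,
                 connectivity = cfg$connectivity, nPerm = cfg$nPerm,
                 seed = cfg$seed, maskThreshold = cfg$maskThreshold)
  else clusterPRFT(sizes, maps, voxelP = cfg$voxelP)
  sig <- fdrSelect(ps, q = cfg$clusterQ)
  tab <- makeClusterTable(clusters, maps, clusterPs = ps,
                          fdrSignificant = sig)

  if (!is.null(outDir)) {
    writeVolume(volume3D(maps@t, maps@affine), file.path(outDir, "maps",
                                                         "tmap.nii.gz"))
    writeVolume(volume3D(maps@z, maps@affine), file.path(outDir, "maps",
                                                         "zmap.nii.gz"))
    labArr <- array(0, dim(maps@t))
    for (k in seq_along(clusters)) labArr[clusters[[k]]$voxels] <- k
    writeVolume(volume3D(labArr, maps@affine, "label"),
                file.path(outDir, "maps", "cluster_labels.nii.gz"))
    writeClusterTable(tab, file.path(outDir, "tables", "clusters.tsv"))
    log <- list(config = jsonlite::fromJSON(as.character(fp)),
                df = maps@df, residFwhmMm = maps@residFwhmMm,
                nClusters = length(clusters),
                package = as.character(utils::packageVersion("ctvbm")))
    jsonlite::write_json(log, file.path(outDir, "logs", "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(maps = maps, clusters = clusters, table = tab, smoothed = smoothed,
       config = cfg, analysisGrid = analysisGrid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cluster table as TSV
#'
#' @param tab cluster table from [makeClusterTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(tab, path) {
  write.table(format(tab, digits = 8, scientific = NA, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
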