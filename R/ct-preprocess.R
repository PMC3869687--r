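#' Hounsfield window for CT brain candidacy
#'
#' Brain parenchyma spans roughly 0-60 HU; the defaults accept 0-100 HU as
#' soft-tissue candidates and treat >= 300 HU as bone.
#'
#' @param loHu,hiHu Hounsfield bounds for soft-tissue candidacy.
#' @param boneHu lower Hounsfield bound for bone.
#' @return a \linkS4class{CtWindow}.
#' @export
ctWindow <- function(loHu = 0, hiHu = 100, boneHu = 300) {
  new("CtWindow", loHu = loHu, hiHu = hiHu, boneHu = boneHu)
}

# Integer voxel offsets of an ellipsoidal structuring element with world
# radius radiusMm on a grid with the given voxel sizes.
ballOffsets <- function(radiusMm, voxMm) {
  r <- pmax(1L, floor(radiusMm / voxMm))
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  keep <- (g$x * voxMm[1] / radiusMm)^2 + (g$y * voxMm[2] / radiusMm)^2 +
    (g$z * voxMm[3] / radiusMm)^2 <= 1 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

binaryClose <- function(mask, voxMm, radiusMm) {
  off <- ballOffsets(radiusMm, voxMm)
  d <- dim(mask)
  dil <- cppMorph(as.logical(mask), d, off, 1L)
  out <- cppMorph(dil, d, off, 0L)
  array(out, d)
}

# Fill interior cavities: background components (6-connectivity) that do not
# touch the volume border are inside the mask.
fillHoles <- function(mask) {
  d <- dim(mask)
  lab <- array(cppLabelComponents(!mask, d, 6L), d)
  border <- unique(c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ],
                     lab[, , 1], lab[, , d[3]]))
  border <- border[border > 0L]
  mask | (lab > 0L & !(lab %in% border))
}

largestComponent <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  lab <- cppLabelComponents(as.logical(mask), d, connectivity)
  if (max(lab) == 0L) return(array(FALSE, d))
  sizes <- tabulate(lab)
  array(lab == which.max(sizes), d)
}

#' Extract the brain from a CT head volume
#'
#' Strips skull, scalp, air and any head-holder hardware by Hounsfield
#' windowing plus morphology: soft-tissue candidates (`loHu < HU <= hiHu`)
#' are reduced to their largest 6-connected component, closed with an
#' ellipsoidal element of radius `closeRadiusMm`, hole-filled (so interior
#' CSF and small enclosed bone are retained) and reduced to a single
#' component again. Voxels outside the mask are set to `loHu`, so the
#' returned volume is directly usable as segmenter input.
#'
#' @param vol a CT \linkS4class{Volume3D}.
#' @param window a \linkS4class{CtWindow}.
#' @param closeRadiusMm morphological closing radius, mm.
#' @return a list with elements `mask` (\linkS4class{BrainMask}) and
#'   `brain` (windowed \linkS4class{Volume3D}).
#' @export
extractBrainCT <- function(vol, window = ctWindow(), closeRadiusMm = 4) {
  if (vol@modality != "ct") stop("extractBrainCT expects a CT volume")
  hu <- vol@data
  cand <- hu > window@loHu & hu <= window@hiHu
  if (!any(cand)) stop("no brain tissue found: empty HU candidate set")
  vox <- voxelSize(vol)
  mask <- largestComponent(cand, 6L)
  mask <- binaryClose(mask, vox, closeRadiusMm)
  mask <- fillHoles(mask)
  mask <- largestComponent(mask, 6L)
  if (!any(mask)) stop("no brain tissue found after morphology")
  out <- hu
  out[!mask] <- window@loHu
  list(mask = new("BrainMask", mask = mask, affine = vol@affine),
       brain = volume3D(out, vol@affine, "ct"))
}

#' Resample a subject volume onto the atlas grid
#'
#' Places the head in atlas space with an initial affine (by default a pure
#' translation aligning the volume's intensity center of mass with the atlas
#' field-of-view center) and resamples onto the atlas grid, so that its
#' bounding box and voxel sizes match the tissue probability maps.
#'
#' @param vol a \linkS4class{Volume3D} (typically brain-extracted CT or a
#'   label volume).
#' @param atlasGrid the atlas \linkS4class{GridSpec}.
#' @param initAffine optional 4x4 world-to-world map placing the head in
#'   atlas space; `NULL` uses center-of-mass alignment.
#' @param interp interpolation, `"trilinear"` or `"nearest"`.
#' @return a \linkS4class{Volume3D} on `atlasGrid`. The affine used is
#'   attached as attribute `"initAffine"`.
#' @export
matchPriorGrid <- function(vol, atlasGrid, initAffine = NULL,
                           interp = "trilinear") {
  atlasGrid <- asGridSpec(atlasGrid)
  if (is.null(initAffine)) {
    w <- vol@data - min(vol@data)
    com <- centerOfMass(vol@data, vol@affine, weights = w)
    ctr <- drop(voxelToWorld(atlasGrid@affine, (atlasGrid@shape - 1) / 2))
    # rough placement only: rounding the translation to whole atlas voxels
    # keeps the resampling exact when the grids already agree, so no
    # partial-volume blurring is introduced before segmentation
    vox <- voxelSize(atlasGrid)
    initAffine <- diag(4)
    initAffine[1:3, 4] <- round((com - ctr) / vox) * vox
  }
  out <- resampleToGrid(vol, atlasGrid, interp = interp,
                        worldMap = initAffine)
  attr(out@data, "initAffine") <- NULL
  attr(out, "initAffine") <- initAffine
  out
}
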