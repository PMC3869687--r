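#' @useDynLib ctvbm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dnorm pnorm qnorm pt qt var sd quantile optim rnorm runif
#'   rbinom p.adjust setNames
#' @importFrom utils head tail write.table read.table modifyList
#'   packageVersion
NULL

.MODALITIES <- c("ct", "mr", "probability", "label", "other")

#' GridSpec: a 3D sampling grid
#'
#' A grid is a shape (three positive integers) plus a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm (RAS). The voxel size is
#' derived as the column norms of the 3x3 block of the affine.
#'
#' @slot shape integer(3), grid dimensions.
#' @slot affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @export
setClass("GridSpec", slots = c(shape = "integer", affine = "matrix"))

setValidity("GridSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be 3 positive integers")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  if (!all(is.finite(object@affine)))
    return("affine must be finite")
  if (abs(det(object@affine)) < 1e-12)
    return("affine must be invertible")
  TRUE
})

#' Volume3D: a 3D scalar volume with world geometry
#'
#' The core data object: a 3D array (Hounsfield units for CT, arbitrary
#' units for MR, values in \[0,1\] for tissue probability maps, integer codes
#' for label volumes) together with the 0-based voxel-index to world-mm
#' affine and a modality tag.
#'
#' @slot data 3D numeric array.
#' @slot affine 4x4 voxel-index (0-based) to world-mm (RAS) matrix.
#' @slot modality one of "ct", "mr", "probability", "label", "other".
#' @export
setClass("Volume3D",
         slots = c(data = "array", affine = "matrix", modality = "character"))

setValidity("Volume3D", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must have exactly 3 spatial dimensions")
  if (!all(dim(object@affine) == c(4L, 4L)) || abs(det(object@affine)) < 1e-12)
    return("affine must be an invertible 4x4 matrix")
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    return(sprintf("modality must be one of %s",
                   paste(.MODALITIES, collapse = ", ")))
  if (object@modality == "probability") {
    r <- range(object@data, finite = TRUE)
    if (r[1] < -1e-6 || r[2] > 1 + 1e-6)
      return("probability volumes must lie in [0, 1]")
  }
  TRUE
})

#' BrainMask: a binary brain mask on a source grid
#'
#' @slot mask 3D logical array.
#' @slot affine 4x4 voxel-to-world matrix of the grid the mask lives on.
#' @export
setClass("BrainMask", slots = c(mask = "array", affine = "matrix"))

setValidity("BrainMask", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("mask must be a 3D logical array")
  if (sum(object@mask) < 1L)
    return("mask must contain at least one voxel")
  TRUE
})

#' CtWindow: Hounsfield bounds for CT brain candidacy
#'
#' @slot loHu,hiHu Hounsfield bounds for soft-tissue candidacy.
#' @slot boneHu lower Hounsfield bound for bone exclusion.
#' @export
setClass("CtWindow",
         slots = c(loHu = "numeric", hiHu = "numeric", boneHu = "numeric"))

setValidity("CtWindow", function(object) {
  if (!(object@loHu < object@hiHu && object@hiHu < object@boneHu))
    return("window requires loHu < hiHu < boneHu")
  TRUE
})

#' TissuePriorAtlas: spatial tissue priors plus a gray-matter template
#'
#' Per-class prior probability volumes (gray matter, white matter, CSF; the
#' "other" class is the complement) on a common grid, together with the
#' gray-matter template used as the spatial-normalization target.
#'
#' @slot gm,wm,csf probability \linkS4class{Volume3D} priors.
#' @slot template gray-matter template \linkS4class{Volume3D}.
#' @export
setClass("TissuePriorAtlas",
         slots = c(gm = "Volume3D", wm = "Volume3D", csf = "Volume3D",
                   template = "Volume3D"))

setValidity("TissuePriorAtlas", function(object) {
  d <- dim(object@gm@data)
  for (s in c("wm", "csf", "template"))
    if (!all(dim(slot(object, s)@data) == d))
      return("all atlas volumes must share one grid")
  tot <- object@gm@data + object@wm@data + object@csf@data
  if (max(tot) > 1 + 1e-6)
    return("gm + wm + csf must be <= 1 everywhere")
  TRUE
})

#' SegmentationConfig: mixture-segmentation settings
#'
#' @slot nGauss named integer(4): Gaussians per class (gm, wm, csf, other).
#' @slot biasReg nonnegative bias-field regularization; `Inf` disables the
#'   bias field (the CT regime).
#' @slot samplingMm sampling distance for the EM fit, mm.
#' @slot maxIter,tol EM stopping rule (relative log-likelihood change).
#' @export
setClass("SegmentationConfig",
         slots = c(nGauss = "integer", biasReg = "numeric",
                   samplingMm = "numeric", maxIter = "integer",
                   tol = "numeric"))

setValidity("SegmentationConfig", function(object) {
  if (length(object@nGauss) != 4L || any(object@nGauss < 1L))
    return("nGauss must be 4 counts >= 1 (gm, wm, csf, other)")
  if (!identical(names(object@nGauss), c("gm", "wm", "csf", "other")))
    return("nGauss must be named gm, wm, csf, other")
  if (object@biasReg < 0 || object@samplingMm <= 0 || object@tol <= 0 ||
      object@maxIter < 1L)
    return("invalid biasReg/samplingMm/maxIter/tol")
  TRUE
})

#' MixtureModel: a fitted prior-weighted Gaussian mixture
#'
#' @slot gaussians data.frame with one row per Gaussian: class, mean, var,
#'   weight (within-class mixing weights sum to 1).
#' @slot loglik log-likelihood trace across EM iterations.
#' @slot converged logical convergence flag.
#' @slot bias multiplicative bias field (array) or NULL (CT regime).
#' @slot config the \linkS4class{SegmentationConfig} used.
#' @export
setClass("MixtureModel",
         slots = c(gaussians = "data.frame", loglik = "numeric",
                   converged = "logical", bias = "ANY",
                   config = "SegmentationConfig"))

setValidity("MixtureModel", function(object) {
  g <- object@gaussians
  if (!all(c("class", "mean", "var", "weight") %in% names(g)))
    return("gaussians needs columns class, mean, var, weight")
  if (any(g$var <= 0)) return("variances must be positive")
  w <- tapply(g$weight, g$class, sum)
  if (any(abs(w - 1) > 1e-6))
    return("within-class mixing weights must sum to 1")
  TRUE
})

#' TissuePosterior: per-voxel tissue class probabilities
#'
#' A 4D array (x, y, z, class) of posterior class probabilities for gm, wm,
#' csf and other, summing to 1 at every voxel.
#'
#' @slot prob 4D array, 4th dimension named gm/wm/csf/other.
#' @slot affine 4x4 voxel-to-world matrix of the source grid.
#' @export
setClass("TissuePosterior", slots = c(prob = "array", affine = "matrix"))

setValidity("TissuePosterior", function(object) {
  d <- dim(object@prob)
  if (length(d) != 4L || d[4] != 4L)
    return("prob must be a 4D array with 4 classes")
  if (!identical(dimnames(object@prob)[[4]], c("gm", "wm", "csf", "other")))
    return("classes must be gm, wm, csf, other")
  tot <- object@prob[, , , 1L] + object@prob[, , , 2L] +
    object@prob[, , , 3L] + object@prob[, , , 4L]
  if (max(abs(tot - 1)) > 1e-5)
    return("per-voxel class probabilities must sum to 1")
  TRUE
})

#' NormalizationParams: affine + low-frequency warp into template space
#'
#' The deformation maps template-space world coordinates x to source-space
#' world coordinates via affine %*% (x + u(x)), where u is a separable
#' 3D cosine-basis displacement field defined over the template field of
#' view. `cutoffMm` is the shortest represented spatial wavelength; the
#' number of basis functions per axis is max(2, floor(FOV/cutoff)).
#'
#' @slot affine 4x4 template-world to source-world map.
#' @slot warpCoeffs K x 3 matrix of cosine coefficients (mm), K = prod(nBasis).
#' @slot nBasis integer(3), basis functions per axis.
#' @slot bbox0 numeric(3), world origin of the template field of view.
#' @slot fovMm numeric(3), template field of view extent, mm.
#' @slot cutoffMm shortest represented wavelength, mm.
#' @slot regLambda membrane-energy regularization weight.
#' @export
setClass("NormalizationParams",
         slots = c(affine = "matrix", warpCoeffs = "matrix",
                   nBasis = "integer", bbox0 = "numeric", fovMm = "numeric",
                   cutoffMm = "numeric", regLambda = "numeric"))

setValidity("NormalizationParams", function(object) {
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be 4x4")
  if (!all(is.finite(object@warpCoeffs)))
    return("warp coefficients must be finite")
  if (nrow(object@warpCoeffs) != prod(object@nBasis) ||
      ncol(object@warpCoeffs) != 3L)
    return("warpCoeffs must be prod(nBasis) x 3")
  TRUE
})

#' StatMaps: voxelwise two-group t and Z maps
#'
#' @slot t,z 3D arrays of t and Z statistics (0 outside the analysis mask).
#' @slot df residual degrees of freedom (n - 2).
#' @slot mask 3D logical analysis mask.
#' @slot residFwhmMm numeric(3), estimated residual smoothness (FWHM, mm).
#' @slot affine 4x4 voxel-to-world matrix of the analysis grid.
#' @export
setClass("StatMaps",
         slots = c(t = "array", z = "array", df = "integer", mask = "array",
                   residFwhmMm = "numeric", affine = "matrix"))

setValidity("StatMaps", function(object) {
  if (object@df < 1L) return("df must be >= 1")
  if (!all(dim(object@z) == dim(object@t)) ||
      !all(dim(object@mask) == dim(object@t)))
    return("t, z and mask must share dimensions")
  if (any(!is.finite(object@z[object@mask])))
    return("z must be finite inside the analysis mask")
  TRUE
})

#' GroupDesign: a two-group VBM design
#'
#' @slot images list of \linkS4class{Volume3D} on one common grid.
#' @slot groups factor with levels control, patient.
#' @export
setClass("GroupDesign", slots = c(images = "list", groups = "factor"))

setValidity("GroupDesign", function(object) {
  if (!identical(levels(object@groups), c("control", "patient")))
    return("groups must be a factor with levels control, patient")
  if (length(object@images) != length(object@groups))
    return("one group label per image")
  if (any(table(object@groups) < 2L))
    return("both groups need at least 2 images")
  d <- dim(object@images[[1]]@data)
  a <- object@images[[1]]@affine
  for (im in object@images) {
    if (!all(dim(im@data) == d) || max(abs(im@affine - a)) > 1e-6)
      return("all images must share one grid")
  }
  TRUE
})

#' PhantomSpec: geometry and rendering model of the synthetic head phantom
#'
#' @slot grid the \linkS4class{GridSpec} the phantom is rendered on.
#' @slot geometry named list of geometry parameters in mm (see
#'   [phantomSpec()]).
#' @slot ctMeansHu,mrMeans named per-tissue intensity means.
#' @slot jitter named list: inter-subject variability (log-scale sd,
#'   rotation sd deg, translation sd mm, warp amplitude mm).
#' @export
setClass("PhantomSpec",
         slots = c(grid = "GridSpec", geometry = "list",
                   ctMeansHu = "numeric", mrMeans = "numeric",
                   jitter = "list"))

#' AtrophySpec: a spherical gray-matter lesion
#'
#' @slot centerMm world coordinate of the sphere center.
#' @slot radiusMm sphere radius, mm.
#' @slot severity fraction in (0, 1] of GM voxels converted to CSF inside
#'   the sphere.
#' @export
setClass("AtrophySpec",
         slots = c(centerMm = "numeric", radiusMm = "numeric",
                   severity = "numeric"))

setValidity("AtrophySpec", function(object) {
  if (length(object@centerMm) != 3L) return("centerMm must be length 3")
  if (object@radiusMm <= 0) return("radiusMm must be positive")
  if (object@severity <= 0 || object@severity > 1)
    return("severity must be in (0, 1]")
  TRUE
})
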