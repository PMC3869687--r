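#' Accessors for ctvbm data objects
#'
#' `volData`, `volAffine` and `modality` expose the array, geometry and
#' modality tag of a \linkS4class{Volume3D}; `voxelSize` and `gridShape`
#' report grid geometry for both volumes and \linkS4class{GridSpec} objects;
#' `nVoxels` counts the true voxels of a \linkS4class{BrainMask}.
#'
#' @param x a ctvbm object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("volAffine", function(x) standardGeneric("volAffine"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("asGridSpec", function(x) standardGeneric("asGridSpec"))

#' @rdname accessors
setMethod("volData", "Volume3D", function(x) x@data)
#' @rdname accessors
setMethod("volAffine", "Volume3D", function(x) x@affine)
#' @rdname accessors
setMethod("modality", "Volume3D", function(x) x@modality)
#' @rdname accessors
setMethod("voxelSize", "GridSpec",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname accessors
setMethod("voxelSize", "Volume3D",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname accessors
setMethod("gridShape", "GridSpec", function(x) x@shape)
#' @rdname accessors
setMethod("gridShape", "Volume3D", function(x) as.integer(dim(x@data)))
#' @rdname accessors
setMethod("nVoxels", "BrainMask", function(x) sum(x@mask))
#' @rdname accessors
setMethod("asGridSpec", "Volume3D",
          function(x) new("GridSpec", shape = as.integer(dim(x@data)),
                          affine = x@affine))
#' @rdname accessors
setMethod("asGridSpec", "GridSpec", function(x) x)

setMethod("show", "Volume3D", function(object) {
  vs <- voxelSize(object)
  cat(sprintf("Volume3D [%s]: %s voxels, %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
              object@modality, paste(dim(object@data), collapse = " x "),
              vs[1], vs[2], vs[3],
              min(object@data), max(object@data)))
})

setMethod("show", "GridSpec", function(object) {
  vs <- voxelSize(object)
  cat(sprintf("GridSpec: %s voxels at %.3g x %.3g x %.3g mm\n",
              paste(object@shape, collapse = " x "), vs[1], vs[2], vs[3]))
})

setMethod("show", "BrainMask", function(object) {
  cat(sprintf("BrainMask: %d of %d voxels\n", sum(object@mask),
              length(object@mask)))
})

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: %d Gaussians, loglik %.4g, %s after %d iterations\n",
              nrow(object@gaussians), tail(object@loglik, 1),
              if (object@converged) "converged" else "not converged",
              length(object@loglik)))
  print(object@gaussians, digits = 4)
})

setMethod("show", "TissuePosterior", function(object) {
  d <- dim(object@prob)
  cat(sprintf("TissuePosterior: %d x %d x %d voxels, classes gm/wm/csf/other\n",
              d[1], d[2], d[3]))
})

setMethod("show", "StatMaps", function(object) {
  cat(sprintf("StatMaps: df = %d, %d voxels in mask, max t = %.3f, resid FWHM = %.1f/%.1f/%.1f mm\n",
              object@df, sum(object@mask), max(object@t),
              object@residFwhmMm[1], object@residFwhmMm[2],
              object@residFwhmMm[3]))
})

setMethod("show", "NormalizationParams", function(object) {
  cat(sprintf("NormalizationParams: cutoff %.3g mm, %s basis functions/axis, |coeffs| max %.3g mm\n",
              object@cutoffMm, paste(object@nBasis, collapse = "/"),
              max(abs(object@warpCoeffs))))
})
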