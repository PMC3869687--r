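#' Isotropic Gaussian smoothing
#'
#' Separable convolution with a Gaussian of `sigma = fwhmMm / (2 sqrt(2 ln 2))`
#' per axis (converted to voxel units), truncated at 4 sigma and normalized
#' to unit sum. Boundary handling is zero padding: gray-matter maps are zero
#' outside the head, so zeros are the physically consistent boundary value.
#' Smoothing a normalized gray-matter probability map yields the regional
#' gray-matter density analyzed by the GLM.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param fwhmMm kernel full width at half maximum, mm.
#' @return the smoothed \linkS4class{Volume3D}. If `fwhmMm` is smaller than
#'   half a voxel a warning is emitted and a copy of the input is returned.
#' @export
smoothGaussian <- function(vol, fwhmMm) {
  stopifnot(fwhmMm >= 0)
  vox <- voxelSize(vol)
  if (fwhmMm < min(vox) / 2) {
    warning("fwhmMm is smaller than half a voxel; returning input unchanged")
    return(vol)
  }
  sigmaMm <- fwhmMm / (2 * sqrt(2 * log(2)))
  out <- as.numeric(vol@data)
  d <- dim(vol@data)
  for (a in 1:3) {
    k <- gaussKernel(sigmaMm / vox[a])
    out <- cppConvAxis(out, d, k, a - 1L)
  }
  dim(out) <- d
  mod <- vol@modality
  if (mod == "probability") out <- pmin(pmax(out, 0), 1)
  volume3D(out, vol@affine, mod)
}

# Unit-sum Gaussian taps truncated at 4 sigma (in voxel units).
gaussKernel <- function(sigmaVox) {
  hw <- max(1L, ceiling(4 * sigmaVox))
  k <- dnorm(seq(-hw, hw), sd = sigmaVox)
  k / sum(k)
}
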