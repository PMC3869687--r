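#' Construct a Volume3D
#'
#' @param data 3D numeric array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm (RAS).
#' @param modality one of `"ct"`, `"mr"`, `"probability"`, `"label"`,
#'   `"other"`.
#' @return a \linkS4class{Volume3D}.
#' @export
volume3D <- function(data, affine, modality = "other") {
  storage.mode(data) <- "double"
  new("Volume3D", data = data, affine = affine, modality = modality)
}

#' Construct a GridSpec
#'
#' @param shape grid dimensions, 3 positive integers.
#' @param affine 4x4 voxel-index (0-based) to world-mm matrix.
#' @return a \linkS4class{GridSpec}.
#' @export
gridSpec <- function(shape, affine) {
  new("GridSpec", shape = as.integer(shape), affine = affine)
}

#' Axis-aligned isotropic grid centred on a world point
#'
#' Convenience constructor for analysis grids: `shape` voxels of size
#' `voxelMm`, axis aligned, with the field of view centred at `centerMm`.
#'
#' @param shape grid dimensions (recycled to length 3).
#' @param voxelMm isotropic voxel size, mm.
#' @param centerMm world coordinate of the field-of-view center.
#' @return a \linkS4class{GridSpec}.
#' @export
isotropicGrid <- function(shape, voxelMm, centerMm = c(0, 0, 0)) {
  shape <- rep(as.integer(shape), length.out = 3L)
  a <- diag(c(rep(voxelMm, 3), 1))
  a[1:3, 4] <- centerMm - voxelMm * (shape - 1) / 2
  gridSpec(shape, a)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 file through RNifti, returning the data array and the
#' voxel-to-world affine in the package convention (0-based indices, RAS
#' world axes).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach; `"auto"` keeps `"other"`.
#' @return a \linkS4class{Volume3D}.
#' @export
readVolume <- function(path, modality = "other") {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions")
  aff <- structure(RNifti::xform(img), class = NULL)
  dimnames(aff) <- NULL
  volume3D(array(as.numeric(img), dim = d), aff, modality)
}

#' Write a Volume3D as NIfTI-1
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  vox <- voxelSize(vol)
  img <- RNifti::asNifti(vol@data,
                         reference = list(pixdim = c(1, vox, 0, 0, 0, 0)))
  img <- RNifti::`sform<-`(img, structure(vol@affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a target grid
#'
#' Values are interpolated in world space: each output voxel is mapped
#' through the output affine to world mm and through the inverse source
#' affine into source voxel coordinates. Voxels mapping outside the source
#' field of view are set to 0.
#'
#' @param vol a \linkS4class{Volume3D}.
#' @param grid the target \linkS4class{GridSpec}.
#' @param interp `"trilinear"` or `"nearest"` (use nearest for label
#'   volumes).
#' @param worldMap optional 4x4 matrix mapping output world coordinates to
#'   source world coordinates (defaults to identity).
#' @return a \linkS4class{Volume3D} on `grid`.
#' @export
resampleToGrid <- function(vol, grid, interp = c("trilinear", "nearest"),
                           worldMap = NULL) {
  interp <- match.arg(interp)
  grid <- asGridSpec(grid)
  M <- solve(vol@affine)
  if (!is.null(worldMap)) M <- M %*% worldMap
  M <- M %*% grid@affine
  out <- cppResample(as.numeric(vol@data), dim(vol@data), grid@shape, M,
                     as.integer(interp == "nearest"))
  dim(out) <- grid@shape
  mod <- vol@modality
  if (mod == "probability") out <- pmin(pmax(out, 0), 1)
  volume3D(out, grid@affine, mod)
}
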