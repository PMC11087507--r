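#' LabelVolume: a 3D instance-label grid with voxel-size metadata
#'
#' The central container of the package: an integer 3D array indexed
#' \code{(z, y, x)} where 0 is background and positive integers are object
#' instances (one id per organelle), plus the physical voxel size in
#' nanometres per axis. All downstream operations (shell extraction,
#' contact banding, morphometry) consume and return this class.
#'
#' @slot data integer 3D array, dimensions \code{(nz, ny, nx)}; values >= 0.
#' @slot voxelSize numeric length-3 voxel pitch in nm per \code{(z, y, x)}
#'   axis; strictly positive. FIB-SEM data in this field is commonly
#'   isotropic 8 nm.
#' @slot name free-text identifier carried into result tables as provenance.
#'
#' @seealso [LabelVolume()] for the user-facing constructor,
#'   [readLabelVolume()] / [writeLabelVolume()] for I/O.
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(data = "array", voxelSize = "numeric", name = "character"),
  prototype(voxelSize = c(8, 8, 8), name = "volume"))

setValidity("LabelVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("'data' must be a 3D array (z, y, x)")
  if (!is.numeric(d))
    return("'data' must be numeric (integer labels)")
  if (anyNA(d))
    return("'data' contains NA")
  if (any(d < 0))
    return("labels must be >= 0")
  if (is.double(d) && any(d != trunc(d)))
    return("non-integer labels")
  if (max(d) >= 2^32)
    return("label ids above 32-bit range are not supported")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("'voxelSize' must be 3 positive finite values (nm per z, y, x)")
  if (length(object@name) != 1L)
    return("'name' must be a single string")
  TRUE
})

#' LabelImage2D: a 2D label image with pixel-size metadata
#'
#' Holds a 2D integer label or mask image (rows = y, columns = x) with its
#' physical pixel size in nanometres, as used for TEM region-of-interest
#' analysis.
#'
#' @slot data integer matrix (y, x); values >= 0.
#' @slot pixelSize single positive pixel pitch in nm.
#' @slot name free-text identifier.
#'
#' @seealso [LabelImage2D()], [perimeterDistanceMap()], [shapeMetrics2d()]
#' @exportClass LabelImage2D
setClass("LabelImage2D",
  representation(data = "matrix", pixelSize = "numeric", name = "character"),
  prototype(pixelSize = 8, name = "image"))

setValidity("LabelImage2D", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("'data' must be numeric (integer labels)")
  if (anyNA(d)) return("'data' contains NA")
  if (any(d < 0)) return("labels must be >= 0")
  if (is.double(d) && any(d != trunc(d))) return("non-integer labels")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("'pixelSize' must be a single positive value (nm)")
  TRUE
})

#' SceneSpec: declarative description of a synthetic 3D scene
#'
#' Describes mitochondria (balls, ellipsoids, capsules), ER structures
#' (wrapped shells at controlled voxel gaps, parallel sheet stacks,
#' tubules), lipid droplets and nuclei to be rasterized into label volumes
#' with analytic ground truth. Build with [sceneSpec()] and the shape
#' helpers ([mitoBall()], [erWrap()], ...).
#'
#' @slot dim integer length-3 volume shape \code{(nz, ny, nx)} in voxels.
#' @slot voxelSize numeric length-3 voxel pitch in nm.
#' @slot mitochondria,erStructures,lipidDroplets,nuclei lists of shape
#'   descriptors created by the helper constructors.
#' @slot seed integer RNG seed making generation deterministic.
#' @slot allowBoundary logical; if FALSE (default) objects crossing the
#'   volume boundary are an error.
#'
#' @seealso [generateScene()]
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(dim = "integer", voxelSize = "numeric",
                 mitochondria = "list", erStructures = "list",
                 lipidDroplets = "list", nuclei = "list",
                 seed = "integer", allowBoundary = "logical"),
  prototype(voxelSize = c(8, 8, 8), mitochondria = list(),
            erStructures = list(), lipidDroplets = list(), nuclei = list(),
            seed = 1L, allowBoundary = FALSE))

setValidity("SceneSpec", function(object) {
  if (length(object@dim) != 3L || any(object@dim < 1))
    return("'dim' must be 3 positive integers (nz, ny, nx)")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("'voxelSize' must be 3 positive values")
  for (er in object@erStructures) {
    if (!is.null(er$gap_voxels) && er$gap_voxels < 0)
      return("ER gap_voxels must be >= 0")
  }
  if (length(object@nuclei) > 2L)
    return("at most 2 nuclei per scene")
  TRUE
})
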