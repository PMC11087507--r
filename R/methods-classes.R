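#' Construct a LabelVolume
#'
#' @param data 3D numeric array of non-negative integer labels, indexed
#'   \code{(z, y, x)}.
#' @param voxelSize voxel pitch in nm, either one value (isotropic) or three
#'   values per \code{(z, y, x)} axis. Default 8 nm isotropic.
#' @param name identifier carried through result tables.
#' @return A [LabelVolume-class] object.
#' @examples
#' v <- LabelVolume(array(0L, c(4, 4, 4)))
#' maxLabel(v)
#' @export
LabelVolume <- function(data, voxelSize = 8, name = "volume") {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  storage.mode(data) <- "integer"
  new("LabelVolume", data = data, voxelSize = as.numeric(voxelSize),
      name = as.character(name))
}

#' Construct a LabelImage2D
#'
#' @param data numeric matrix of non-negative integer labels (y, x).
#' @param pixelSize pixel pitch in nm (default 8).
#' @param name identifier.
#' @return A [LabelImage2D-class] object.
#' @export
LabelImage2D <- function(data, pixelSize = 8, name = "image") {
  storage.mode(data) <- "integer"
  new("LabelImage2D", data = data, pixelSize = as.numeric(pixelSize),
      name = as.character(name))
}

#' @describeIn LabelVolume-class the raw integer array (z, y, x)
#' @param x a LabelVolume or LabelImage2D
#' @export
setMethod("labelData", "LabelVolume", function(x) x@data)

#' @export
setMethod("labelData", "LabelImage2D", function(x) x@data)

#' @describeIn LabelVolume-class voxel size in nm per (z, y, x) axis
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

#' @export
setMethod("voxelSize<-", "LabelVolume", function(x, value) {
  if (length(value) == 1L) value <- rep(value, 3L)
  x@voxelSize <- as.numeric(value)
  validObject(x)
  x
})

#' @export
setMethod("pixelSize", "LabelImage2D", function(x) x@pixelSize)

#' @export
setMethod("objectName", "LabelVolume", function(x) x@name)

#' @export
setMethod("objectName", "LabelImage2D", function(x) x@name)

#' @describeIn LabelVolume-class largest label id (0 for an empty volume)
#' @export
setMethod("maxLabel", "LabelVolume", function(x) max(0L, x@data))

#' @export
setMethod("maxLabel", "LabelImage2D", function(x) max(0L, x@data))

#' @describeIn LabelVolume-class sorted vector of label ids present
#' @export
setMethod("labelIds", "LabelVolume", function(x) {
  ids <- sort(unique(as.vector(x@data)))
  ids[ids > 0L]
})

#' @export
setMethod("labelIds", "LabelImage2D", function(x) {
  ids <- sort(unique(as.vector(x@data)))
  ids[ids > 0L]
})

#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "LabelImage2D", function(x) dim(x@data))

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  ids <- labelIds(object)
  cat("LabelVolume '", object@name, "'\n", sep = "")
  cat("  dim (z,y,x): ", paste(d, collapse = " x "),
      "  voxel (nm): ", paste(signif(object@voxelSize, 4), collapse = " x "),
      "\n", sep = "")
  cat("  labels: ", length(ids),
      if (length(ids)) paste0(" (max id ", max(ids), ")") else "",
      "  foreground voxels: ", sum(object@data > 0L), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "LabelImage2D", function(object) {
  d <- dim(object@data)
  cat("LabelImage2D '", object@name, "' ", d[1], " x ", d[2],
      " px @ ", signif(object@pixelSize, 4), " nm/px, ",
      length(labelIds(object)), " labels\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SceneSpec", function(object) {
  cat("SceneSpec ", paste(object@dim, collapse = " x "),
      " voxels @ ", paste(signif(object@voxelSize, 4), collapse = "x"),
      " nm; ", length(object@mitochondria), " mito, ",
      length(object@erStructures), " ER, ",
      length(object@lipidDroplets), " LD, ",
      length(object@nuclei), " nuclei; seed ", object@seed, "\n", sep = "")
  invisible(NULL)
})
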