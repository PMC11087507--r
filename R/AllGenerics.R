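#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("voxelSize<-", function(x, value) standardGeneric("voxelSize<-"))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("objectName", function(x) standardGeneric("objectName"))

#' @export
setGeneric("maxLabel", function(x) standardGeneric("maxLabel"))

#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))
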