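#' Nuclear reference point for mitochondria distance mapping
#'
#' The reference is the nuclear centroid for mononucleate cells and, for
#' binucleate hepatocytes, the midpoint between the two nuclear centroids.
#' Zero or more than two nuclei are an error.
#'
#' @param nuc nuclei [LabelVolume-class] (instance labels).
#' @param cells optional cell-instance [LabelVolume-class]; with
#'   \code{cellId}, only nuclei inside that cell are considered.
#' @param cellId cell instance id to restrict to.
#' @return list(point_um = c(z, y, x) in µm, n_nuclei, cell_id).
#' @export
nucleusReference <- function(nuc, cells = NULL, cellId = NULL) {
  stopifnot(is(nuc, "LabelVolume"))
  d <- nuc@data
  if (!is.null(cells) && !is.null(cellId)) {
    d[cells@data != cellId] <- 0L
  }
  ids <- sort(unique(d[d > 0L]))
  if (length(ids) == 0L) stop("no nucleus found")
  if (length(ids) > 2L) stop(length(ids), " nuclei found; expected 1 or 2")
  vs <- nuc@voxelSize
  cents <- t(vapply(ids, function(id) {
    ai <- arrayInd(which(d == id), dim(d))
    (colMeans(ai) - 0.5) * vs / 1000
  }, numeric(3)))
  list(point_um = colMeans(cents), n_nuclei = length(ids),
       cell_id = cellId %||% NA_integer_)
}

#' Mitochondria-to-nucleus distances
#'
#' Euclidean distance from each mitochondrial centroid ("center of the 3D
#' geometry", the unweighted voxel centroid) to the nuclear reference
#' point, in µm, plus the per-cell relative distance (absolute divided by
#' the maximum absolute distance, so the furthest mitochondrion is exactly
#' 1 independent of cell size).
#'
#' @param metrics output of [instanceMetrics()] (uses the centroid columns
#'   and, when present, \code{cell_id}).
#' @param ref a [nucleusReference()] result, or a list of them (one per
#'   cell id) for per-cell referencing.
#' @return data.frame: \code{mito_id, cell_id, absolute_um, relative}.
#' @export
mitoNucleusDistances <- function(metrics, ref) {
  if (!nrow(metrics)) stop("empty metrics table")
  single <- !is.null(ref$point_um)
  getRef <- function(cid) {
    if (single) return(ref$point_um)
    hit <- Filter(function(r) identical(r$cell_id, cid), ref)
    if (!length(hit)) stop("no nucleus reference for cell ", cid)
    hit[[1]]$point_um
  }
  cent <- as.matrix(metrics[, c("centroid_z_um", "centroid_y_um",
                                "centroid_x_um")])
  cellv <- if ("cell_id" %in% names(metrics)) metrics$cell_id
           else rep(NA_integer_, nrow(metrics))
  absd <- vapply(seq_len(nrow(metrics)), function(i)
    sqrt(sum((cent[i, ] - getRef(cellv[i]))^2)), numeric(1))
  out <- data.frame(mito_id = metrics$object_id, cell_id = cellv,
                    absolute_um = absd)
  grp <- if (all(is.na(cellv))) rep(1L, nrow(out)) else cellv
  out$relative <- absd / ave(absd, grp, FUN = max)
  out
}
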