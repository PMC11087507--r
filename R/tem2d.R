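# exact 2D Euclidean distance (px) from every pixel to the nearest TRUE
# pixel of `mask`; 0 on the mask itself. Delegates to EBImage's exact EDT.
.edt2d <- function(mask) {
  comp <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::imageData(EBImage::distmap(comp, metric = "euclidean")))
}

#' Euclidean distance map from a mitochondrion perimeter
#'
#' Exact 2D Euclidean distance transform of the object's complement, in
#' nm: every outside pixel carries its center-to-center distance to the
#' nearest object pixel (which lies on the perimeter); pixels on or inside
#' the object are 0. This is the distance map ER pixels are scored against
#' in TEM contact analysis.
#'
#' @param mitoMask a [LabelImage2D-class] (binary or single instance).
#' @return Numeric matrix (nm), same shape as the input.
#' @export
perimeterDistanceMap <- function(mitoMask) {
  stopifnot(is(mitoMask, "LabelImage2D"))
  m <- mitoMask@data > 0L
  if (!any(m)) stop("empty mitochondrion mask")
  .edt2d(m) * mitoMask@pixelSize
}

# 4-neighbor binary erosion with out-of-image treated as background
.erode4 <- function(m) {
  p <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  i <- 2:(nrow(m) + 1); j <- 2:(ncol(m) + 1)
  p[i, j] & p[i - 1, j] & p[i + 1, j] & p[i, j - 1] & p[i, j + 1]
}

#' 2D ER band coverage of a mitochondrion perimeter
#'
#' For each perimeter pixel (object minus its 4-neighbor erosion) the
#' Euclidean distance to the nearest ER pixel is measured; per band
#' \code{(lo, hi]} nm (the first band includes 0), coverage is the
#' fraction of perimeter pixels whose nearest ER lies in the band. The
#' distribution of ER-pixel distances to the mitochondrion (from
#' [perimeterDistanceMap()]) is returned alongside, with its mean over ER
#' pixels within the outermost band — the membrane-to-membrane distance
#' readout — and the ER-pixel-weighted band fractions as an alternative
#' statistic.
#'
#' @param mitoMask,erMask [LabelImage2D-class] on the same pixel grid.
#' @param bandsNm list of \code{c(lo, hi)} nm pairs (default 0--24,
#'   25--80: smooth-ER MAM band and rough-ER sheet band).
#' @return list: \code{coverage} (data.frame band, lo_nm, hi_nm,
#'   coverage_perimeter, coverage_er), \code{mean_er_distance_nm},
#'   \code{er_distances_nm}, \code{perimeter_pixels}.
#' @export
erBandCoverage2d <- function(mitoMask, erMask,
                             bandsNm = list(c(0, 24), c(25, 80))) {
  stopifnot(is(mitoMask, "LabelImage2D"), is(erMask, "LabelImage2D"))
  if (!identical(dim(mitoMask@data), dim(erMask@data)))
    stop("mitochondrion and ER images differ in shape")
  px <- mitoMask@pixelSize
  m <- mitoMask@data > 0L
  e <- erMask@data > 0L
  if (!any(m)) stop("empty mitochondrion mask")
  if (!is.list(bandsNm)) bandsNm <- list(bandsNm)
  lo <- vapply(bandsNm, `[`, numeric(1), 1)
  hi <- vapply(bandsNm, `[`, numeric(1), 2)
  perim <- m & !.erode4(m)

  dER <- if (any(e)) .edt2d(e) * px else NULL
  perimDist <- if (is.null(dER)) rep(Inf, sum(perim)) else dER[perim]
  dMito <- .edt2d(m) * px
  erDist <- dMito[e]

  cuts <- c(-Inf, hi)
  cov <- data.frame(band = paste0(lo, "-", hi), lo_nm = lo, hi_nm = hi)
  cov$coverage_perimeter <- vapply(seq_along(hi), function(b)
    mean(perimDist > cuts[b] & perimDist <= cuts[b + 1]), numeric(1))
  cov$coverage_er <- vapply(seq_along(hi), function(b) {
    if (!length(erDist)) return(0)
    mean(erDist > cuts[b] & erDist <= cuts[b + 1])
  }, numeric(1))
  inRange <- erDist[erDist <= max(hi)]
  list(coverage = cov,
       mean_er_distance_nm = if (length(inRange)) mean(inRange) else NA_real_,
       er_distances_nm = erDist,
       perimeter_pixels = sum(perim))
}

#' 2D shape metrics: area, roundness, aspect ratio
#'
#' Standard fitted-ellipse definitions from second-order central moments
#' (with the 1/12 uniform-pixel variance correction): major/minor axis
#' lengths are \eqn{4\sqrt{\lambda}} of the moment eigenvalues, aspect
#' ratio is major/minor, roundness is \eqn{4 A / (\pi \cdot major^2)}.
#' Both equal 1 for a disc.
#'
#' @param mask single-instance [LabelImage2D-class].
#' @return data.frame: \code{area_um2, roundness, aspect_ratio,
#'   major_um, minor_um, pixels}.
#' @export
shapeMetrics2d <- function(mask) {
  stopifnot(is(mask, "LabelImage2D"))
  px <- mask@pixelSize
  idx <- which(mask@data > 0L, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  n <- nrow(idx)
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  raw <- eigen(crossprod(cc) / n, symmetric = TRUE)$values
  if (raw[2] <= 1e-9) stop("degenerate (collinear) mask")
  cv <- crossprod(cc) / n + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE)$values
  major <- 4 * sqrt(ev[1]) * px / 1000
  minor <- 4 * sqrt(ev[2]) * px / 1000
  area <- n * (px / 1000)^2
  data.frame(area_um2 = area,
             roundness = 4 * area / (pi * major^2),
             aspect_ratio = major / minor,
             major_um = major, minor_um = minor, pixels = n)
}
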