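#' Build a 2D TEM scene specification
#'
#' @param dim image shape \code{(ny, nx)} in pixels.
#' @param pixelSize pixel pitch in nm (default 8).
#' @param mitochondria list of [disc2d()] / [ellipse2d()] descriptors.
#' @param erArcs list of [erArc()] descriptors.
#' @param seed RNG seed.
#' @return A plain list spec consumed by [generateTemScene()].
#' @export
temSpec <- function(dim, pixelSize = 8, mitochondria = list(),
                    erArcs = list(), seed = 1L) {
  list(dim = as.integer(dim), pixelSize = pixelSize,
       mitochondria = mitochondria, erArcs = erArcs, seed = as.integer(seed))
}

#' 2D shape descriptors
#'
#' Coordinates are \code{(y, x)} pixel positions; a pixel belongs to a
#' solid iff its center lies on or inside the continuous boundary.
#'
#' @param center center \code{(y, x)}; \code{radius,semiaxes} in pixels;
#'   \code{angle} rotation of the ellipse major axis in radians.
#' @name shapes2d
NULL

#' @rdname shapes2d
#' @export
disc2d <- function(center, radius)
  list(shape = "disc", center = center, radius = radius)

#' @rdname shapes2d
#' @param semiaxes \code{(a, b)} semi-axes in pixels.
#' @param angle rotation in radians.
#' @export
ellipse2d <- function(center, semiaxes, angle = 0)
  list(shape = "ellipse", center = center, semiaxes = semiaxes, angle = angle)

#' @rdname shapes2d
#' @param mito index of the parent mitochondrion.
#' @param gapPx Euclidean gap in pixels: the arc occupies pixels whose
#'   center-to-nearest-mito-pixel distance lies in
#'   \code{[gapPx, gapPx + thickness)}, so the minimum distance equals
#'   \code{gapPx}.
#' @param thickness arc thickness in pixels.
#' @param coverage angular fraction of the full circle covered, in (0, 1].
#' @param theta0 starting angle (radians).
#' @export
erArc <- function(mito, gapPx, thickness = 1, coverage = 1, theta0 = 0)
  list(mito = mito, gap_px = gapPx, thickness = thickness,
       coverage = coverage, theta0 = theta0)

.raster2d <- function(obj, dm) {
  yy <- seq_len(dm[1]); xx <- seq_len(dm[2])
  if (obj$shape == "disc") {
    d2 <- outer((yy - obj$center[1])^2, (xx - obj$center[2])^2, "+")
    which(d2 <= obj$radius^2 + 1e-9)
  } else if (obj$shape == "ellipse") {
    a <- obj$semiaxes; th <- obj$angle
    Y <- outer(yy - obj$center[1], rep(1, dm[2]))
    X <- outer(rep(1, dm[1]), xx - obj$center[2])
    U <- X * cos(th) + Y * sin(th)
    V <- -X * sin(th) + Y * cos(th)
    which((U / a[1])^2 + (V / a[2])^2 <= 1 + 1e-9)
  } else stop("unknown 2D shape")
}

#' Generate a 2D TEM scene with ground truth
#'
#' Rasterizes discs/ellipses (mitochondria) and ER arcs at controlled
#' Euclidean pixel gaps, as analysed by [perimeterDistanceMap()] and
#' [erBandCoverage2d()]. Deterministic given the spec.
#'
#' @param spec a [temSpec()] list.
#' @return list(mito, er ([LabelImage2D-class]), manifest (data.frame)).
#' @export
generateTemScene <- function(spec) {
  dm <- spec$dim
  mito <- matrix(0L, dm[1], dm[2])
  er <- matrix(0L, dm[1], dm[2])
  man <- list()
  for (i in seq_along(spec$mitochondria)) {
    idx <- .raster2d(spec$mitochondria[[i]], dm)
    if (any(mito[idx] > 0L)) stop("mitochondrion ", i, " overlaps another")
    mito[idx] <- i
    obj <- spec$mitochondria[[i]]
    area <- if (obj$shape == "disc") pi * obj$radius^2 else pi * prod(obj$semiaxes)
    man[[length(man) + 1]] <- data.frame(
      class = "mito", id = i, pixels = length(idx),
      analytic_area_px2 = area, gap_px = NA_real_)
  }
  for (i in seq_along(spec$erArcs)) {
    a <- spec$erArcs[[i]]
    sub <- mito == a$mito
    if (!any(sub)) stop("erArc references missing mitochondrion ", a$mito)
    d <- .edt2d(sub)
    ann <- which(d >= a$gap_px & d < a$gap_px + a$thickness & mito == 0L)
    if (a$coverage < 1) {
      ctr <- colMeans(which(sub, arr.ind = TRUE))
      ai <- arrayInd(ann, dm)
      ang <- atan2(ai[, 1] - ctr[1], ai[, 2] - ctr[2]) %% (2 * pi)
      rel <- (ang - a$theta0) %% (2 * pi)
      ann <- ann[rel <= a$coverage * 2 * pi]
    }
    ann <- ann[er[ann] == 0L]
    er[ann] <- i
    man[[length(man) + 1]] <- data.frame(
      class = "er", id = i, pixels = length(ann),
      analytic_area_px2 = NA_real_, gap_px = a$gap_px)
  }
  manifest <- do.call(rbind, man) %||% data.frame()
  if (nrow(manifest)) manifest$seed <- spec$seed
  list(mito = LabelImage2D(mito, spec$pixelSize, "mito2d"),
       er = LabelImage2D(er, spec$pixelSize, "er2d"),
       manifest = manifest)
}

#' Generate synthetic zonation line profiles
#'
#' Emulates plot-profile exports along hand-drawn central-vein to
#' portal-vein lines: intensity is a stated zone function of percent
#' position (0\% = central vein edge, 100\% = portal vein edge) plus
#' Gaussian noise. The noiseless function is returned as ground truth.
#'
#' @param nProfiles number of lines.
#' @param zoneEffect either a function of percent position, or one of
#'   "ramp" (portal-enriched, intensity = percent), "central"
#'   (intensity = 100 - percent), or a single constant.
#' @param noiseSd Gaussian noise sd (intensity units), >= 0.
#' @param seed RNG seed.
#' @param nSamples samples per line.
#' @param lengthUm physical line length range (µm) drawn per profile.
#' @param channel channel name stored with the profiles.
#' @return list(profiles = data.frame(profile_id, channel, position_um,
#'   intensity), truth = function(percent)).
#' @export
generateZonationProfiles <- function(nProfiles, zoneEffect = "ramp",
                                     noiseSd = 0, seed = 1L,
                                     nSamples = 201, lengthUm = c(200, 400),
                                     channel = "marker") {
  stopifnot(noiseSd >= 0)
  f <- if (is.function(zoneEffect)) zoneEffect
  else if (is.numeric(zoneEffect)) function(p) rep(zoneEffect[1], length(p))
  else switch(match.arg(zoneEffect, c("ramp", "central")),
              ramp = function(p) p, central = function(p) 100 - p)
  withr::with_seed(seed, {
    out <- lapply(seq_len(nProfiles), function(i) {
      L <- stats::runif(1, lengthUm[1], lengthUm[2])
      pos <- seq(0, L, length.out = nSamples)
      pct <- 100 * pos / L
      data.frame(profile_id = i, channel = channel, position_um = pos,
                 intensity = f(pct) + stats::rnorm(nSamples, 0, noiseSd))
    })
    list(profiles = do.call(rbind, out), truth = f)
  })
}
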