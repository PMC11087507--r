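#' Build a synthetic scene specification
#'
#' @param dim volume shape \code{(nz, ny, nx)} in voxels.
#' @param voxelSize voxel pitch in nm (1 or 3 values; default 8, the pitch
#'   of isotropic FIB-SEM acquisitions this package targets).
#' @param mitochondria list of [mitoBall()], [mitoEllipsoid()],
#'   [mitoCapsule()] descriptors.
#' @param erStructures list of [erWrap()], [erSheets()], [erTubule()]
#'   descriptors.
#' @param lipidDroplets list of [lipidDroplet()] descriptors.
#' @param nuclei list of up to two [nucleusBall()] descriptors.
#' @param seed integer RNG seed; generation is deterministic given the spec.
#' @param allowBoundary allow objects to be clipped at the volume boundary
#'   instead of erroring.
#' @return A [SceneSpec-class].
#' @seealso [generateScene()]
#' @export
sceneSpec <- function(dim, voxelSize = 8, mitochondria = list(),
                      erStructures = list(), lipidDroplets = list(),
                      nuclei = list(), seed = 1L, allowBoundary = FALSE) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  new("SceneSpec", dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
      mitochondria = mitochondria, erStructures = erStructures,
      lipidDroplets = lipidDroplets, nuclei = nuclei,
      seed = as.integer(seed), allowBoundary = isTRUE(allowBoundary))
}

#' Shape descriptors for synthetic scenes
#'
#' Centers and radii are in voxel units, on the \code{(z, y, x)} axis order.
#' A digital solid includes every voxel whose center lies on or inside the
#' continuous surface, the standard digitization that makes brute-force
#' volume oracles unambiguous.
#'
#' @param center,from,to voxel coordinates \code{(z, y, x)}.
#' @param radius,semiaxes radii in voxels.
#' @name shapes
NULL

#' @rdname shapes
#' @export
mitoBall <- function(center, radius)
  list(shape = "ball", center = center, radius = radius)

#' @rdname shapes
#' @export
mitoEllipsoid <- function(center, semiaxes)
  list(shape = "ellipsoid", center = center, semiaxes = semiaxes)

#' @rdname shapes
#' @export
mitoCapsule <- function(from, to, radius)
  list(shape = "capsule", from = from, to = to, radius = radius)

#' @rdname shapes
#' @export
lipidDroplet <- function(center, radius)
  list(shape = "ball", center = center, radius = radius)

#' @rdname shapes
#' @export
nucleusBall <- function(center, radius)
  list(shape = "ball", center = center, radius = radius)

#' ER structure descriptors
#'
#' \code{erWrap} places ER on the city-block distance ring
#' \code{[gapVoxels + 1, gapVoxels + thickness]} around a mitochondrion,
#' emulating the single curved rough-ER sheet that wraps mitochondria in
#' fasted hepatocytes; \code{gapVoxels} background voxels separate ER from
#' the organelle, so contact is first reached at dilation step
#' \code{gapVoxels + 1}. \code{coverage} restricts the wrap to a spherical
#' cap holding that fraction of directions around the mitochondrion
#' centroid. \code{erSheets} builds a stack of parallel flat sheets (the
#' fed-state morphology); \code{erTubule} a capsule-shaped tubule.
#'
#' @param mito index (1-based, in spec order) of the wrapped mitochondrion.
#' @param gapVoxels background voxels between organelle and ER; >= 0.
#' @param thickness ER thickness in voxels.
#' @param coverage fraction of the solid angle covered, in (0, 1].
#' @param axis cap direction for partial coverage / sheet normal axis
#'   ("z", "y" or "x"); partial-coverage wrap caps default to a
#'   deterministic axis drawn from the scene RNG when NULL.
#' @param center,extent sheet-stack center and lateral half-extent (voxels).
#' @param nSheets,spacing number of sheets and their center-to-center
#'   spacing in voxels.
#' @param from,to,radius tubule end points and radius in voxels.
#' @name erStructures
NULL

#' @rdname erStructures
#' @export
erWrap <- function(mito, gapVoxels, thickness = 1, coverage = 1, axis = NULL)
  list(mode = "wrapped_shell", mito = mito, gap_voxels = gapVoxels,
       thickness = thickness, coverage = coverage, axis = axis)

#' @rdname erStructures
#' @export
erSheets <- function(center, nSheets = 3, spacing = 5, thickness = 1,
                     extent = c(8, 8), axis = "z")
  list(mode = "parallel_sheets", center = center, n_sheets = nSheets,
       spacing = spacing, thickness = thickness, extent = extent, axis = axis)

#' @rdname erStructures
#' @export
erTubule <- function(from, to, radius = 1)
  list(mode = "tubule", from = from, to = to, radius = radius)

# ---- rasterization helpers (voxel units, (z,y,x) order) ----

.bboxGrid <- function(lo, hi, dm) {
  lo <- pmax(1L, floor(lo)); hi <- pmin(dm, ceiling(hi))
  if (any(hi < lo)) return(NULL)
  list(z = lo[1]:hi[1], y = lo[2]:hi[2], x = lo[3]:hi[3])
}

# Returns linear indices of the voxels of a solid, plus whether the
# continuous solid extends beyond the volume.
.rasterSolid <- function(obj, dm) {
  if (obj$shape == "ball") {
    c0 <- obj$center; r <- obj$radius
    g <- .bboxGrid(c0 - r, c0 + r, dm)
    oob <- any(c0 - r < 0.5) || any(c0 + r > dm + 0.5)
    if (is.null(g)) return(list(idx = integer(0), oob = oob))
    zz <- g$z; yy <- g$y; xx <- g$x
    d2 <- outer(outer((zz - c0[1])^2, (yy - c0[2])^2, "+"), (xx - c0[3])^2, "+")
    keep <- which(d2 <= r^2 + 1e-9)
    ai <- arrayInd(keep, c(length(zz), length(yy), length(xx)))
    idx <- (zz[ai[, 1]]) + dm[1] * ((yy[ai[, 2]] - 1L) + dm[2] * (xx[ai[, 3]] - 1L))
  } else if (obj$shape == "ellipsoid") {
    c0 <- obj$center; a <- obj$semiaxes
    g <- .bboxGrid(c0 - a, c0 + a, dm)
    oob <- any(c0 - a < 0.5) || any(c0 + a > dm + 0.5)
    if (is.null(g)) return(list(idx = integer(0), oob = oob))
    zz <- g$z; yy <- g$y; xx <- g$x
    d2 <- outer(outer(((zz - c0[1]) / a[1])^2, ((yy - c0[2]) / a[2])^2, "+"),
                ((xx - c0[3]) / a[3])^2, "+")
    keep <- which(d2 <= 1 + 1e-9)
    ai <- arrayInd(keep, c(length(zz), length(yy), length(xx)))
    idx <- (zz[ai[, 1]]) + dm[1] * ((yy[ai[, 2]] - 1L) + dm[2] * (xx[ai[, 3]] - 1L))
  } else if (obj$shape == "capsule") {
    p1 <- obj$from; p2 <- obj$to; r <- obj$radius
    lo <- pmin(p1, p2) - r; hi <- pmax(p1, p2) + r
    oob <- any(lo < 0.5) || any(hi > dm + 0.5)
    g <- .bboxGrid(lo, hi, dm)
    if (is.null(g)) return(list(idx = integer(0), oob = oob))
    pts <- as.matrix(expand.grid(z = g$z, y = g$y, x = g$x))
    v <- p2 - p1
    L2 <- sum(v^2)
    w <- sweep(pts, 2, p1)
    t <- if (L2 > 0) pmin(1, pmax(0, (w %*% v)[, 1] / L2)) else 0
    proj <- outer(t, v) + rep(p1, each = nrow(pts))
    d2 <- rowSums((pts - proj)^2)
    keep <- pts[d2 <= r^2 + 1e-9, , drop = FALSE]
    idx <- keep[, 1] + dm[1] * ((keep[, 2] - 1L) + dm[2] * (keep[, 3] - 1L))
  } else stop("unknown shape: ", obj$shape)
  list(idx = as.integer(idx), oob = oob)
}

.analyticVolSA <- function(obj) {
  if (obj$shape == "ball") {
    r <- obj$radius
    c(vol = 4 / 3 * pi * r^3, sa = 4 * pi * r^2)
  } else if (obj$shape == "ellipsoid") {
    a <- sort(obj$semiaxes, decreasing = TRUE)
    p <- 1.6075  # Thomsen approximation for ellipsoid surface area
    sa <- 4 * pi * ((a[1]^p * a[2]^p + a[1]^p * a[3]^p + a[2]^p * a[3]^p) / 3)^(1 / p)
    c(vol = 4 / 3 * pi * prod(a), sa = sa)
  } else if (obj$shape == "capsule") {
    r <- obj$radius; h <- sqrt(sum((obj$to - obj$from)^2))
    c(vol = pi * r^2 * h + 4 / 3 * pi * r^3, sa = 2 * pi * r * h + 4 * pi * r^2)
  } else c(vol = NA_real_, sa = NA_real_)
}

#' Generate a synthetic scene with analytic ground truth
#'
#' Rasterizes a [SceneSpec-class] into four instance-label volumes
#' (mitochondria, ER, lipid droplets, nuclei) plus a manifest recording,
#' per object, its voxel count, analytic continuous volume/surface area
#' where defined, centroid, and (for wrapped ER) the constructed gap in
#' voxels. Wrapped-shell ER occupies exactly the city-block distance ring
#' \code{[gap+1, gap+thickness]} of its mitochondrion, the same discrete
#' metric used by [bandContact()], so band assignment of generated contacts
#' is exact by construction. Generation is deterministic for a fixed spec
#' (including its seed).
#'
#' Solid objects (mitochondria, nuclei, droplets) may not overlap; a
#' conflicting request is an error. ER rings are clipped to unoccupied
#' voxels so no inter-class overlap is ever emitted.
#'
#' @param spec a [SceneSpec-class].
#' @return A list with elements \code{mito}, \code{er}, \code{ld},
#'   \code{nuc} ([LabelVolume-class] each) and \code{manifest} (data.frame).
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  withr::with_seed(spec@seed, .generateSceneImpl(spec))
}

.generateSceneImpl <- function(spec) {
  dm <- spec@dim
  vs <- spec@voxelSize
  vvol_um3 <- prod(vs) / 1e9
  mito <- array(0L, dm); er <- array(0L, dm)
  ld <- array(0L, dm); nuc <- array(0L, dm)
  occ <- array(0L, dm)  # any solid occupancy
  man <- list()

  addSolid <- function(arr, objs, class) {
    for (i in seq_along(objs)) {
      r <- .rasterSolid(objs[[i]], dm)
      if (r$oob && !spec@allowBoundary)
        stop(class, " object ", i, " exceeds the volume bounds")
      if (any(occ[r$idx] > 0L))
        stop(class, " object ", i, " overlaps an existing object")
      arr[r$idx] <- i
      occ[r$idx] <<- 1L
      av <- .analyticVolSA(objs[[i]])
      ci <- arrayInd(r$idx, dm)
      man[[length(man) + 1]] <<- data.frame(
        class = class, id = i, shape = objs[[i]]$shape %||% objs[[i]]$mode,
        voxels = length(r$idx), volume_um3 = length(r$idx) * vvol_um3,
        analytic_volume_um3 = av[["vol"]] * vvol_um3,
        # voxel-unit SA maps to physical units only for isotropic voxels
        analytic_sa_um2 = if (length(unique(vs)) == 1L)
          av[["sa"]] * vs[1]^2 / 1e6 else NA_real_,
        cz = mean(ci[, 1]), cy = mean(ci[, 2]), cx = mean(ci[, 3]),
        gap_voxels = NA_real_, coverage = NA_real_)
      arr
    }
    arr
  }
  mito <- addSolid(mito, spec@mitochondria, "mito")
  nuc <- addSolid(nuc, spec@nuclei, "nucleus")
  ld <- addSolid(ld, spec@lipidDroplets, "ld")

  for (i in seq_along(spec@erStructures)) {
    e <- spec@erStructures[[i]]
    if (e$mode == "wrapped_shell") {
      src <- array(0L, dm); src[mito == e$mito] <- 1L
      if (!any(src > 0L)) stop("erWrap references missing mitochondrion ", e$mito)
      K <- e$gap_voxels + e$thickness
      dist <- .bfs_dist_cpp(src, integer(0), as.integer(K), 0L)
      ring <- which(dist >= e$gap_voxels + 1 & dist <= K & occ == 0L)
      if (e$coverage < 1) {
        ctr <- colMeans(arrayInd(which(src > 0L), dm))
        ax <- e$axis %||% sample(c("z", "y", "x"), 1L)
        axv <- c(z = 1, y = 2, x = 3)[[ax]]
        ci <- arrayInd(ring, dm)
        v <- sweep(ci, 2, ctr)
        nr <- sqrt(rowSums(v^2)); nr[nr == 0] <- 1
        cosang <- v[, axv] / nr
        ring <- ring[cosang >= 1 - 2 * e$coverage]
      }
      er[ring] <- i
      man[[length(man) + 1]] <- data.frame(
        class = "er", id = i, shape = "wrapped_shell",
        voxels = length(ring), volume_um3 = length(ring) * vvol_um3,
        analytic_volume_um3 = NA_real_, analytic_sa_um2 = NA_real_,
        cz = mean(arrayInd(ring, dm)[, 1]), cy = mean(arrayInd(ring, dm)[, 2]),
        cx = mean(arrayInd(ring, dm)[, 3]),
        gap_voxels = e$gap_voxels, coverage = e$coverage)
    } else if (e$mode == "parallel_sheets") {
      axv <- c(z = 1, y = 2, x = 3)[[e$axis %||% "z"]]
      lat <- setdiff(1:3, axv)
      vox <- integer(0)
      for (s in seq_len(e$n_sheets)) {
        pos <- e$center[axv] + (s - (e$n_sheets + 1) / 2) * e$spacing
        lo <- hi <- numeric(3)
        lo[axv] <- pos - (e$thickness - 1) / 2; hi[axv] <- pos + (e$thickness - 1) / 2
        lo[lat] <- e$center[lat] - e$extent; hi[lat] <- e$center[lat] + e$extent
        g <- .bboxGrid(lo, hi, dm)
        if (is.null(g)) next
        pts <- as.matrix(expand.grid(z = g$z, y = g$y, x = g$x))
        vox <- c(vox, pts[, 1] + dm[1] * ((pts[, 2] - 1L) + dm[2] * (pts[, 3] - 1L)))
      }
      vox <- vox[occ[vox] == 0L & er[vox] == 0L]
      er[vox] <- i
      ci <- arrayInd(vox, dm)
      man[[length(man) + 1]] <- data.frame(
        class = "er", id = i, shape = "parallel_sheets",
        voxels = length(vox), volume_um3 = length(vox) * vvol_um3,
        analytic_volume_um3 = NA_real_, analytic_sa_um2 = NA_real_,
        cz = mean(ci[, 1]), cy = mean(ci[, 2]), cx = mean(ci[, 3]),
        gap_voxels = NA_real_, coverage = NA_real_)
    } else if (e$mode == "tubule") {
      r <- .rasterSolid(list(shape = "capsule", from = e$from, to = e$to,
                             radius = e$radius), dm)
      if (r$oob && !spec@allowBoundary)
        stop("ER tubule ", i, " exceeds the volume bounds")
      vox <- r$idx[occ[r$idx] == 0L & er[r$idx] == 0L]
      er[vox] <- i
      ci <- arrayInd(vox, dm)
      man[[length(man) + 1]] <- data.frame(
        class = "er", id = i, shape = "tubule",
        voxels = length(vox), volume_um3 = length(vox) * vvol_um3,
        analytic_volume_um3 = NA_real_, analytic_sa_um2 = NA_real_,
        cz = mean(ci[, 1]), cy = mean(ci[, 2]), cx = mean(ci[, 3]),
        gap_voxels = NA_real_, coverage = NA_real_)
    } else stop("unknown ER mode: ", e$mode)
  }

  manifest <- do.call(rbind, man)
  if (!is.null(manifest)) manifest$seed <- spec@seed
  else manifest <- data.frame(class = character(0), id = integer(0))
  list(mito = LabelVolume(mito, vs, "mito"),
       er = LabelVolume(er, vs, "er"),
       ld = LabelVolume(ld, vs, "ld"),
       nuc = LabelVolume(nuc, vs, "nuc"),
       manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random small scene for property testing and calibration
#'
#' Draws non-overlapping mitochondria (balls/ellipsoids, radii 4--8 voxels)
#' and ER structures (wrapped shells at random gaps, plus tubules) inside a
#' cubic volume. The minimum mitochondrial radius of 4 voxels keeps every
#' organelle thicker than the widest contact band, so exterior city-block
#' distances are never shortened by paths through an organelle interior.
#'
#' @param side cube side in voxels (default 48).
#' @param nMito number of mitochondria (default 2).
#' @param nTubule number of ER tubules (default 1).
#' @param radiusRange inclusive range of mitochondrial radii in voxels
#'   (minimum 4, see above).
#' @param gapRange inclusive range of wrapped-ER gaps in voxels.
#' @param coverage wrap coverage fraction.
#' @param voxelSize voxel pitch in nm.
#' @param seed RNG seed.
#' @return As [generateScene()].
#' @export
randomScene <- function(side = 48, nMito = 2, nTubule = 1,
                        radiusRange = c(4, 8), gapRange = c(1, 6),
                        coverage = 1, voxelSize = 8, seed = 1L) {
  withr::with_seed(seed, {
    dm <- rep(side, 3)
    mitos <- list(); centers <- NULL; radii <- numeric(0)
    tries <- 0
    while (length(mitos) < nMito && tries < 200) {
      tries <- tries + 1
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      margin <- r + max(gapRange) + 2
      ctr <- stats::runif(3, 1 + margin, side - margin)
      if (!is.null(centers) &&
          any(sqrt(rowSums(sweep(centers, 2, ctr)^2)) <
              radii + r + 2 * (max(gapRange) + 2)))
        next
      if (stats::runif(1) < 0.5) {
        mitos[[length(mitos) + 1]] <- mitoBall(ctr, r)
      } else {
        ax <- pmax(radiusRange[1], r * stats::runif(3, 0.7, 1.3))
        if (any(ctr - ax < 1 + max(gapRange) + 2) ||
            any(ctr + ax > side - max(gapRange) - 2)) next
        mitos[[length(mitos) + 1]] <- mitoEllipsoid(ctr, ax)
        r <- max(ax)
      }
      centers <- rbind(centers, ctr); radii <- c(radii, r)
    }
    ers <- lapply(seq_along(mitos), function(i)
      erWrap(i, gapVoxels = sample(gapRange[1]:gapRange[2], 1L),
             thickness = 1, coverage = coverage,
             axis = sample(c("z", "y", "x"), 1L)))
    for (t in seq_len(nTubule)) {
      p1 <- stats::runif(3, 3, side - 3); p2 <- stats::runif(3, 3, side - 3)
      ers[[length(ers) + 1]] <- erTubule(p1, p2, radius = 1)
    }
    generateScene(sceneSpec(dm, voxelSize = voxelSize, mitochondria = mitos,
                            erStructures = ers,
                            seed = sample.int(1e6, 1L)))
  })
}
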