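test_that("perimeter distance map is exact Euclidean in nm", {
  m <- matrix(0L, 40, 40); m[10:30, 10:20] <- 1L
  img <- LabelImage2D(m, pixelSize = 8)
  dmap <- perimeterDistanceMap(img)
  expect_equal(dmap[20, 23], 3 * 8)      # 3 px from the straight edge
  expect_true(all(dmap[m > 0] == 0))     # inside and on the object
  expect_equal(dmap[20, 21], 8)

  expect_error(perimeterDistanceMap(LabelImage2D(matrix(0L, 5, 5))), "empty")
})

test_that("disc probe at radius 53 reads within half a pixel of 3 px", {
  side <- 128
  sc <- generateTemScene(temSpec(c(side, side),
                                 mitochondria = list(disc2d(c(64, 64), 50))))
  dmap <- perimeterDistanceMap(sc$mito) / 8  # px
  expect_lt(abs(dmap[64, 64 + 53] - 3), 0.5)
})

test_that("distance maps agree with brute-force nearest-pixel search", {
  for (seed in 1:5) {
    m <- bfRandomMask2d(72, nDiscs = 3, seed = seed)
    img <- LabelImage2D(m * 1L, pixelSize = 8)
    dmap <- perimeterDistanceMap(img)
    obj <- which(m, arr.ind = TRUE)
    probes <- withr::with_seed(seed, sample(which(!m), 150))
    bf <- bfMinEuclid2d(arrayInd(probes, dim(m)), obj) * 8
    expect_equal(dmap[probes], bf)
  }
})

test_that("ER band coverage: quarter arc at 16 nm reads ~25% in 0-24 nm", {
  sc <- generateTemScene(temSpec(c(128, 128),
    mitochondria = list(disc2d(c(64, 64), 40)),
    erArcs = list(erArc(1, gapPx = 2, thickness = 2, coverage = 0.25))))
  cov <- erBandCoverage2d(sc$mito, sc$er)
  band1 <- cov$coverage$coverage_perimeter[1]
  expect_gt(band1, 0.18)
  expect_lt(band1, 0.32)
})

test_that("ER annulus at 60 nm lands fully in the 25-80 nm band", {
  sc <- generateTemScene(temSpec(c(128, 128),
    mitochondria = list(disc2d(c(64, 64), 40)),
    erArcs = list(erArc(1, gapPx = 7.5, thickness = 1.5))))
  cov <- erBandCoverage2d(sc$mito, sc$er)
  expect_equal(cov$coverage$coverage_perimeter[1], 0)
  expect_gt(cov$coverage$coverage_perimeter[2], 0.95)
  expect_gt(cov$mean_er_distance_nm, 24)
  expect_lt(cov$mean_er_distance_nm, 80)

  none <- erBandCoverage2d(sc$mito,
                           LabelImage2D(matrix(0L, 128, 128), 8))
  expect_true(all(none$coverage$coverage_perimeter == 0))
})

test_that("band coverages partition the within-range perimeter fraction", {
  sc <- generateTemScene(temSpec(c(96, 96),
    mitochondria = list(disc2d(c(48, 48), 25)),
    erArcs = list(erArc(1, gapPx = 1, thickness = 2, coverage = 0.5),
                  erArc(1, gapPx = 6, thickness = 2, coverage = 0.4,
                        theta0 = pi))))
  split <- erBandCoverage2d(sc$mito, sc$er,
                            bandsNm = list(c(0, 24), c(25, 80)))
  whole <- erBandCoverage2d(sc$mito, sc$er, bandsNm = list(c(0, 80)))
  expect_equal(sum(split$coverage$coverage_perimeter),
               whole$coverage$coverage_perimeter)

  # per-perimeter-pixel coverage against the brute-force nearest-ER scan
  m <- labelData(sc$mito) > 0
  perim <- which(m & !orgContact:::.erode4(m), arr.ind = TRUE)
  er <- which(labelData(sc$er) > 0, arr.ind = TRUE)
  d <- bfMinEuclid2d(perim, er) * 8
  expect_equal(split$coverage$coverage_perimeter[1], mean(d <= 24))
  expect_equal(split$coverage$coverage_perimeter[2],
               mean(d > 24 & d <= 80))
})

test_that("shape metrics: disc, 2:1 ellipse, counting, rotation, errors", {
  disc <- generateTemScene(temSpec(c(128, 128),
    mitochondria = list(disc2d(c(64, 64), 45))))$mito
  s <- shapeMetrics2d(disc)
  expect_gte(s$aspect_ratio, 1)
  expect_lte(s$aspect_ratio, 1.05)
  expect_gte(s$roundness, 0.95)
  expect_lte(s$roundness, 1.001)

  ell <- generateTemScene(temSpec(c(128, 128),
    mitochondria = list(ellipse2d(c(64, 64), c(40, 20), angle = 0.4))))$mito
  se <- shapeMetrics2d(ell)
  expect_lt(abs(se$aspect_ratio - 2), 0.1)

  m <- matrix(0L, 30, 30); m[5:14, 5:14] <- 1L
  sq <- shapeMetrics2d(LabelImage2D(m, 8))
  expect_equal(sq$area_um2, 100 * (0.008)^2)
  rot <- shapeMetrics2d(LabelImage2D(t(m), 8))
  expect_equal(rot$area_um2, sq$area_um2)
  expect_equal(rot$aspect_ratio, sq$aspect_ratio)
  expect_equal(rot$roundness, sq$roundness)

  line <- matrix(0L, 20, 20); line[5, 3:15] <- 1L
  expect_error(shapeMetrics2d(LabelImage2D(line, 8)), "degenerate")
  expect_error(shapeMetrics2d(LabelImage2D(matrix(0L, 5, 5), 8)), "empty")
})

test_that("grid mismatch between masks is rejected", {
  a <- LabelImage2D(matrix(1L, 10, 10), 8)
  b <- LabelImage2D(matrix(0L, 12, 10), 8)
  expect_error(erBandCoverage2d(a, b), "shape")
})
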