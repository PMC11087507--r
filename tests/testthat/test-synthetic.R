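test_that("digital ball voxel volume matches brute-force enumeration", {
  for (r in c(4, 7.5, 10)) {
    ctr <- c(15, 16, 14)
    sc <- generateScene(sceneSpec(c(30, 30, 30),
                                  mitochondria = list(mitoBall(ctr, r)),
                                  seed = 1))
    expect_identical(sc$manifest$voxels[1], bfBallCount(ctr, r))
    expect_identical(sum(labelData(sc$mito) > 0), bfBallCount(ctr, r))
  }
})

test_that("wrapped ER sits at exactly the requested city-block gap", {
  for (gap in c(0, 3, 5)) {
    sc <- generateScene(sceneSpec(c(26, 26, 26),
      mitochondria = list(mitoBall(c(13, 13, 13), 5)),
      erStructures = list(erWrap(1, gapVoxels = gap)), seed = 2))
    erIdx <- which(labelData(sc$er) > 0)
    mitoIdx <- which(labelData(sc$mito) > 0)
    expect_gt(length(erIdx), 0)
    d <- bfMinL1(arrayInd(erIdx, dim(sc$er)), arrayInd(mitoIdx, dim(sc$mito)))
    expect_true(all(d == gap + 1))
  }
})

test_that("partial coverage reduces the wrap without breaking the gap", {
  full <- generateScene(sceneSpec(c(26, 26, 26),
    mitochondria = list(mitoBall(c(13, 13, 13), 5)),
    erStructures = list(erWrap(1, 2, coverage = 1)), seed = 3))
  half <- generateScene(sceneSpec(c(26, 26, 26),
    mitochondria = list(mitoBall(c(13, 13, 13), 5)),
    erStructures = list(erWrap(1, 2, coverage = 0.5, axis = "z")), seed = 3))
  expect_lt(half$manifest$voxels[2], full$manifest$voxels[2])
  d <- bfMinL1(arrayInd(which(labelData(half$er) > 0), c(26, 26, 26)),
               arrayInd(which(labelData(half$mito) > 0), c(26, 26, 26)))
  expect_true(all(d == 3))
})

test_that("generation is deterministic and manifests are complete", {
  a <- randomScene(side = 40, nMito = 2, seed = 11)
  b <- randomScene(side = 40, nMito = 2, seed = 11)
  expect_identical(labelData(a$mito), labelData(b$mito))
  expect_identical(labelData(a$er), labelData(b$er))
  expect_identical(a$manifest, b$manifest)

  for (cls in c("mito", "er", "ld", "nuc")) {
    want <- sort(a$manifest$id[a$manifest$class ==
                                 c(mito = "mito", er = "er", ld = "ld",
                                   nuc = "nucleus")[[cls]]])
    expect_identical(labelIds(a[[cls]]), as.integer(want))
  }
})

test_that("no inter-class overlap is emitted and conflicts error", {
  sc <- randomScene(side = 40, nMito = 2, nTubule = 2, seed = 5)
  m <- labelData(sc$mito) > 0; e <- labelData(sc$er) > 0
  expect_identical(sum(m & e), 0L)

  expect_error(generateScene(sceneSpec(c(20, 20, 20),
    mitochondria = list(mitoBall(c(10, 10, 10), 5),
                        mitoBall(c(12, 10, 10), 5)), seed = 1)),
    "overlaps")
  expect_error(generateScene(sceneSpec(c(20, 20, 20),
    mitochondria = list(mitoBall(c(3, 10, 10), 5)), seed = 1)),
    "bounds")
  expect_silent(generateScene(sceneSpec(c(20, 20, 20),
    mitochondria = list(mitoBall(c(3, 10, 10), 5)), seed = 1,
    allowBoundary = TRUE)))
})

test_that("2D TEM scenes honor disc areas and arc gaps", {
  sp <- temSpec(c(128, 128), mitochondria = list(disc2d(c(64, 64), 50)),
                erArcs = list(erArc(1, gapPx = 3)), seed = 1)
  sc <- generateTemScene(sp)
  yy <- seq_len(128); xx <- seq_len(128)
  bf <- sum(outer((yy - 64)^2, (xx - 64)^2, "+") <= 50^2 + 1e-9)
  expect_identical(sc$manifest$pixels[1], bf)

  erIdx <- which(labelData(sc$er) > 0, arr.ind = TRUE)
  mIdx <- which(labelData(sc$mito) > 0, arr.ind = TRUE)
  dmin <- min(bfMinEuclid2d(erIdx, mIdx))
  expect_lt(abs(dmin - 3), 0.5)
  expect_gte(dmin, 3 - 1e-9)

  empty <- generateTemScene(temSpec(c(32, 32)))
  expect_identical(maxLabel(empty$mito), 0L)
  expect_identical(maxLabel(empty$er), 0L)
})

test_that("zonation profiles realize the programmed zone function", {
  const <- generateZonationProfiles(3, zoneEffect = 7, noiseSd = 0, seed = 1)
  expect_true(all(const$profiles$intensity == 7))

  ramp <- generateZonationProfiles(1, "ramp", noiseSd = 0, seed = 2,
                                   nSamples = 201)
  p <- percentize(ramp$profiles)
  expect_equal(p$intensity[p$position_pct == 50], 50)
  expect_equal(p$intensity, p$position_pct)

  r1 <- generateZonationProfiles(4, "ramp", noiseSd = 2, seed = 9)
  r2 <- generateZonationProfiles(4, "ramp", noiseSd = 2, seed = 9)
  expect_identical(r1$profiles, r2$profiles)
  expect_error(generateZonationProfiles(2, noiseSd = -1))
})
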