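cubeVol <- function(lo, hi, side = 20, vs = 8) {
  d <- array(0L, rep(side, 3))
  d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  LabelVolume(d, vs)
}

test_that("shell extraction equals object minus one-step erosion", {
  cube <- cubeVol(c(6, 6, 6), c(15, 15, 15))
  sh <- extractShell(cube)
  expect_identical(sum(labelData(sh) > 0), 1000L - 512L)  # 10^3 - 8^3
  core <- labelData(cube); core[labelData(sh) > 0] <- 0L
  expect_identical(sum(core > 0), 512L)

  single <- cubeVol(c(5, 5, 5), c(5, 5, 5))
  expect_identical(labelData(extractShell(single)), labelData(single))

  plate <- cubeVol(c(5, 3, 3), c(5, 12, 12))  # 1-voxel-thick z plate
  expect_identical(labelData(extractShell(plate)), labelData(plate))

  # boundary-touching faces are shell (out-of-volume is background)
  touch <- cubeVol(c(1, 1, 1), c(5, 5, 5), side = 10)
  expect_identical(sum(labelData(extractShell(touch)) > 0), 125L - 27L)
})

test_that("planewise mode erodes per z-slice only", {
  plate <- cubeVol(c(5, 3, 3), c(5, 12, 12))  # single slice in z
  pw <- extractShell(plate, "planewise_xy")
  # in-plane 10x10 square erodes to 8x8: shell is the 36-pixel rim
  expect_identical(sum(labelData(pw) > 0), 100L - 64L)
})

test_that("band contact matches the city-block oracle with exclusivity", {
  for (seed in 1:6) {
    sc <- randomScene(side = 36, nMito = 2, nTubule = 1, seed = seed)
    bc <- bandContact(sc$mito, sc$er)
    sh <- labelData(extractShell(sc$mito))
    shIdx <- which(sh > 0)
    partIdx <- which(labelData(sc$er) > 0)
    if (!length(partIdx)) next
    d <- bfMinL1(arrayInd(shIdx, dim(sc$mito)),
                 arrayInd(partIdx, dim(sc$mito)))
    for (id in labelIds(sc$mito)) {
      mine <- sh[shIdx] == id
      expect_identical(bc$contact_0_24[bc$mito_id == id],
                       sum(mine & d <= 3))
      expect_identical(bc$contact_25_56[bc$mito_id == id],
                       sum(mine & d >= 4 & d <= 7))
      expect_identical(bc$shell_voxels[bc$mito_id == id], sum(mine))
    }
  }
})

test_that("band semantics: a 4-voxel gap is 25-56 nm contact only", {
  sc <- generateScene(sceneSpec(c(30, 30, 30),
    mitochondria = list(mitoBall(c(15, 15, 15), 6)),
    erStructures = list(erWrap(1, gapVoxels = 3)), seed = 1))
  bc <- bandContact(sc$mito, sc$er)   # ER at city-block distance 4
  expect_equal(bc$fraction_0_24, 0)
  expect_gt(bc$fraction_25_56, 0)

  none <- bandContact(sc$mito, LabelVolume(array(0L, c(30, 30, 30)), 8))
  expect_equal(none$fraction_0_24, 0)
  expect_equal(none$fraction_25_56, 0)
})

test_that("coplanar face sheet at gap 1 matches the brute-force count", {
  d <- array(0L, c(32, 32, 32)); d[10:19, 10:19, 10:19] <- 1L
  er <- array(0L, c(32, 32, 32)); er[8, 8:21, 8:21] <- 1L  # sheet, gap 1
  mito <- LabelVolume(d, 8); part <- LabelVolume(er, 8)
  bc <- bandContact(mito, part)
  sh <- labelData(extractShell(mito))
  dmin <- bfMinL1(arrayInd(which(sh > 0), dim(d)),
                  arrayInd(which(er > 0), dim(d)))
  expect_identical(bc$contact_0_24, sum(dmin <= 3))
})

test_that("distance profiles conserve band totals and order", {
  sc <- randomScene(side = 36, nMito = 2, seed = 7)
  bc <- bandContact(sc$mito, sc$er, bandsNm = list(c(0, 56)))
  dp <- distanceProfile(sc$mito, sc$er, maxNm = 56)
  for (id in labelIds(sc$mito)) {
    cum7 <- dp$cumulative_voxels[dp$mito_id == id & dp$step == 7]
    expect_identical(cum7, bc$contact_0_56[bc$mito_id == id])
    expect_true(all(diff(dp$cumulative_voxels[dp$mito_id == id]) >= 0))
    expect_true(all(dp$new_voxels[dp$mito_id == id] >= 0))
  }
})

test_that("partner covering one whole face contacts entirely at step 1", {
  # 1-voxel plate (every voxel is shell) with a coplanar sheet right under
  # it: each plate voxel is contacted at step 1, nothing remains afterwards
  d <- array(0L, c(20, 20, 20)); d[8, 6:14, 6:14] <- 1L
  er <- array(0L, c(20, 20, 20)); er[7, 6:14, 6:14] <- 1L
  dp <- distanceProfile(LabelVolume(d, 8), LabelVolume(er, 8), 56)
  expect_identical(dp$new_voxels[dp$step == 1], 81L)
  expect_true(all(dp$new_voxels[dp$step > 1] == 0L))
})

test_that("wrapped shells at gap 6 put the modal contact at step 7", {
  sc <- generateScene(sceneSpec(c(34, 34, 34),
    mitochondria = list(mitoBall(c(17, 17, 17), 6)),
    erStructures = list(erWrap(1, gapVoxels = 6)), seed = 4))
  dp <- distanceProfile(sc$mito, sc$er, maxNm = 80)
  expect_identical(dp$step[which.max(dp$new_voxels)], 7L)
  expect_identical(dp$distance_nm[which.max(dp$new_voxels)], 56)
})

test_that("sheet contact restricted to a mask behaves as band contact", {
  sc <- randomScene(side = 36, nMito = 1, nTubule = 2, seed = 9)
  full <- sheetContact(sc$mito, sc$er, bandNm = c(0, 56))
  ref <- bandContact(sc$mito, sc$er, bandsNm = list(c(0, 56)))
  expect_equal(full, ref, ignore_attr = TRUE)

  empty <- sheetContact(sc$mito, LabelVolume(array(0L, dim(sc$er)), 8))
  expect_equal(empty$fraction_0_56, rep(0, nrow(empty)))

  # sheets = ER minus tubules: per-band split against the full-ER oracle
  erD <- labelData(sc$er)
  man <- sc$manifest
  tubIds <- man$id[man$class == "er" & man$shape == "tubule"]
  sheets <- erD; sheets[erD %in% tubIds] <- 0L
  tubes <- erD; tubes[!(erD %in% tubIds)] <- 0L
  sOnly <- sheetContact(sc$mito, LabelVolume(sheets, 8), bandNm = c(0, 56))
  shv <- labelData(extractShell(sc$mito))
  dS <- bfMinL1(arrayInd(which(shv > 0), dim(erD)),
                arrayInd(which(sheets > 0), dim(erD)))
  expect_identical(sOnly$contact_0_56[1], sum(dS <= 7))
})

test_that("disjoint partners contribute additively at separated distances", {
  # a tall cube keeps the two partners' 7-step influence regions disjoint,
  # so inner-band claims from one cannot shadow outer-band counts of the
  # other
  d <- array(0L, c(36, 36, 36)); d[10:27, 10:27, 10:27] <- 1L
  mito <- LabelVolume(d, 8)
  a <- array(0L, dim(d)); a[9, 10:27, 10:27] <- 1L    # adjacent, -z face
  b <- array(0L, dim(d)); b[32, 10:27, 10:27] <- 1L   # distance 5, +z face
  joint <- a | b
  bcA <- bandContact(mito, LabelVolume(a * 1L, 8))
  bcB <- bandContact(mito, LabelVolume(b * 1L, 8))
  bcJ <- bandContact(mito, LabelVolume(joint * 1L, 8))
  expect_identical(bcJ$contact_0_24, bcA$contact_0_24 + bcB$contact_0_24)
  expect_identical(bcJ$contact_25_56, bcA$contact_25_56 + bcB$contact_25_56)
})

test_that("band plumbing: exclusivity, monotone cumulative, validation", {
  sc <- randomScene(side = 36, nMito = 2, seed = 13)
  fine <- bandContact(sc$mito, sc$er,
                      bandsNm = list(c(0, 24), c(25, 56)))
  cum <- bandContact(sc$mito, sc$er, bandsNm = list(c(0, 56)))
  expect_identical(fine$contact_0_24 + fine$contact_25_56, cum$contact_0_56)
  expect_true(all(fine$fraction_0_24 >= 0 & fine$fraction_0_24 <= 1))
  expect_true(all(fine$contact_0_24 + fine$contact_25_56 <=
                    fine$shell_voxels))

  small <- LabelVolume(array(0L, c(4, 4, 4)), 8)
  expect_error(bandContact(sc$mito, small), "shape")
  expect_error(bandContact(sc$mito, sc$er,
                           bandsNm = list(c(25, 56), c(0, 24))), "sorted")
  expect_warning(bandContact(sc$mito, sc$er, bandsNm = list(c(0, 30))),
                 "multiple")
})

test_that("partner voxels overlapping mitochondria count at distance 0", {
  d <- array(0L, c(16, 16, 16)); d[5:11, 5:11, 5:11] <- 1L
  er <- array(0L, dim(d)); er[5, 5:11, 5:11] <- 1L  # on the shell itself
  expect_message(bc <- bandContact(LabelVolume(d, 8), LabelVolume(er, 8)),
                 "distance 0")
  expect_gte(bc$contact_0_24, 49L)
})

test_that("contact prevalence thresholds count mitochondria, not voxels", {
  rec <- data.frame(mito_id = 1:4, shell_voxels = rep(100L, 4),
                    contact_0_24 = c(0L, 2L, 5L, 0L),
                    fraction_0_24 = c(0, 0.02, 0.05, 0))
  attr(rec, "bands_nm") <- list(c(0, 24))
  expect_equal(contactPrevalence(rec), 0.5)
  expect_equal(contactPrevalence(rec, minVoxels = 100), 0)
  expect_equal(contactPrevalence(rec, minVoxels = 0), 1)
  expect_equal(contactPrevalence(rec, minFraction = 0.05), 0.25)
  expect_error(contactPrevalence(rec[0, ]), "empty")
})
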