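mkVol <- function(d, vs = 8) LabelVolume(d, voxelSize = vs)

test_that("connected components follow the requested connectivity", {
  d <- array(0L, c(12, 12, 12))
  d[3:5, 3:5, 3:5] <- 1L
  d[8:10, 8:10, 8:10] <- 1L
  expect_identical(maxLabel(labelComponents(mkVol(d))), 2L)

  corner <- array(0L, c(4, 4, 4))
  corner[1, 1, 1] <- 1L; corner[2, 2, 2] <- 1L
  expect_identical(maxLabel(labelComponents(mkVol(corner), 26)), 1L)
  expect_identical(maxLabel(labelComponents(mkVol(corner), 6)), 2L)

  expect_identical(maxLabel(labelComponents(mkVol(array(0L, c(3, 3, 3))))), 0L)
  expect_error(labelComponents(mkVol(d * 2L)), "binary")
  expect_error(labelComponents(mkVol(d), 10), "connectivity")
})

test_that("size and boundary filters behave like the proof-reading step", {
  d <- array(0L, c(20, 20, 20))
  d[1:2, 1:2, 1:2] <- 1L                      # 8 voxels, touches boundary
  d[5:8, 5:8, 5:8] <- 2L                      # 64 voxels
  d[11:17, 11:17, 11:17] <- 3L                # 343 voxels
  v <- mkVol(d)
  expect_identical(labelIds(filterInstances(v, minVoxels = 100)), 3L)
  expect_identical(labelData(filterInstances(v, 0)), d)
  expect_identical(labelIds(filterInstances(v, excludeBoundary = TRUE)),
                   c(2L, 3L))
  expect_error(filterInstances(v, -5), ">= 0")

  rl <- filterInstances(v, minVoxels = 100, relabel = TRUE)
  expect_identical(labelIds(rl), 1L)

  expect_identical(minVoxelPresets()[["lean_fasted"]], 92243)
  expect_identical(labelIds(filterInstances(v, "lean_fed")), integer(0))
})

test_that("MCI^2 and sphericity match symbolic substitution oracles", {
  r <- c(0.3, 1, 7)
  saSphere <- 4 * pi * r^2; vSphere <- 4 / 3 * pi * r^3
  expect_equal(mci2(saSphere, vSphere), rep(9 / (4 * pi), 3))
  expect_equal(sphericity(saSphere, vSphere), rep(1, 3))

  a <- c(0.5, 2)
  expect_equal(mci2(6 * a^2, a^3), rep(216 / (16 * pi^2), 2))
  expect_equal(sphericity(6 * a^2, a^3), rep((pi / 6)^(1 / 3), 2))

  expect_equal(mci2(4 * 5, 8 * 1.3), mci2(5, 1.3))
  expect_error(mci2(0, 1), "positive")
  expect_error(sphericity(1, -1), "positive")
})

test_that("elongating a spheroid at fixed volume strictly lowers sphericity", {
  # prolate spheroid a = b, c = k * a, volume held at 4pi/3
  ks <- c(1.01, 1.5, 2, 4, 8)
  psi <- vapply(ks, function(k) {
    a <- k^(-1 / 3)  # a^2 c = 1
    sphericity(bfProlateSA(a, k * a), 4 / 3 * pi)
  }, numeric(1))
  expect_true(all(diff(psi) < 0))
  expect_lt(max(psi), 1)
})

test_that("cube metrics and voxel-size scaling are exact", {
  d <- array(0L, c(16, 16, 16)); d[4:13, 4:13, 4:13] <- 1L
  m8 <- instanceMetrics(mkVol(d, 8), saMethod = "voxel_face")
  expect_equal(m8$voxels, 1000L)
  expect_equal(m8$volume_um3, 1000 * (0.008)^3)
  expect_equal(m8$sa_um2, 600 * (0.008)^2)

  m16 <- instanceMetrics(mkVol(d, 16), saMethod = "voxel_face")
  expect_equal(m16$volume_um3, 8 * m8$volume_um3)
  expect_equal(m16$sa_um2, 4 * m8$sa_um2)
  expect_equal(m16$sphericity, m8$sphericity)
  expect_equal(m16$mci2, m8$mci2)

  mesh8 <- instanceMetrics(mkVol(d, 8))
  mesh16 <- instanceMetrics(mkVol(d, 16))
  expect_equal(mesh16$sa_um2, 4 * mesh8$sa_um2)
  expect_equal(mesh16$sphericity, mesh8$sphericity)
})

test_that("digital ball r=20 mesh sphericity is within 3% of 1", {
  sc <- generateScene(sceneSpec(c(49, 49, 49),
    mitochondria = list(mitoBall(c(25, 25, 25), 20)), seed = 1))
  m <- instanceMetrics(sc$mito)
  expect_gt(m$sphericity, 0.97)
  expect_lt(m$sphericity, 1.03)
})

test_that("per-instance stats agree with a naive per-voxel implementation", {
  sc <- randomScene(side = 40, nMito = 2, seed = 21)
  v <- sc$mito
  m <- instanceMetrics(v, saMethod = "voxel_face")
  d <- labelData(v)
  expect_identical(sum(m$voxels), sum(d > 0))  # volume conservation
  for (id in labelIds(v)) {
    idx <- which(d == id)
    ai <- arrayInd(idx, dim(d))
    row <- m[m$object_id == id, ]
    expect_identical(row$voxels, length(idx))
    expect_equal(unlist(row[c("centroid_z_um", "centroid_y_um",
                              "centroid_x_um")], use.names = FALSE),
                 (colMeans(ai) - 0.5) * 8 / 1000)
    # naive exposed-face count via six shifted comparisons
    faces <- 0L
    for (off in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                     c(0,0,1), c(0,0,-1))) {
      nb <- sweep(ai, 2, off, "+")
      inb <- nb[, 1] >= 1 & nb[, 1] <= dim(d)[1] &
             nb[, 2] >= 1 & nb[, 2] <= dim(d)[2] &
             nb[, 3] >= 1 & nb[, 3] <= dim(d)[3]
      vals <- rep(0L, nrow(nb))
      vals[inb] <- d[nb[inb, , drop = FALSE]]
      faces <- faces + sum(vals != id)
    }
    expect_equal(row$sa_um2, faces * (0.008)^2)
    expect_false(row$touches_boundary)
  }
  # digital over-estimation: voxel-face SA >= mesh SA on every object
  mesh <- instanceMetrics(v)
  expect_true(all(m$sa_um2 >= mesh$sa_um2))
})

test_that("empty volumes yield empty metric tables", {
  expect_identical(nrow(instanceMetrics(mkVol(array(0L, c(4, 4, 4))))), 0L)
})

test_that("bivariate complex-mitochondria classification counts correctly", {
  tab <- data.frame(mci2 = c(6, 6, 1, 9), volume_um3 = c(4, 1, 5, 3.5))
  expect_equal(classifyComplex(tab), 0.5)
  expect_equal(classifyComplex(tab, 100, 100), 0)
  expect_equal(classifyComplex(tab, 0, 0), 1)
  expect_error(classifyComplex(tab[0, ]), "empty")
})
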