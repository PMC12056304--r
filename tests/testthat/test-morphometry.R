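test_that("maximum Feret diameter matches closed forms and the brute-force oracle", {
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_identical(maxFeretDiameter(one, 1), 0)
  expect_equal(maxFeretDiameter(matrix(TRUE, 10, 10), 1), 9 * sqrt(2))
  expect_equal(maxFeretDiameter(matrix(TRUE, 1, 50), 0.5), 24.5)
  expect_error(maxFeretDiameter(matrix(FALSE, 4, 4), 1), "empty")
  set.seed(7)
  for (k in 1:25) {
    m <- matrix(stats::rbinom(20 * 20, 1, 0.2), 20, 20)
    if (!any(m)) next
    expect_equal(maxFeretDiameter(m, 0.7), bruteFeretPx(m) * 0.7,
                 tolerance = 1e-12)
  }
})

test_that("IOD follows its definition and both forms agree", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(integratedOpticalDensity(m, matrix(0.5, 10, 10), 1), 50)
  expect_equal(integratedOpticalDensity(m, matrix(0, 10, 10), 1), 0)
  two <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  od <- matrix(c(0.2, 0.6, 9, 9), 2, 2)
  expect_equal(integratedOpticalDensity(two, od, 1), 2 * 0.4)
  expect_error(integratedOpticalDensity(matrix(FALSE, 2, 2),
                                        matrix(0, 2, 2), 1), "empty")
  set.seed(8)
  for (k in 1:10) {
    m <- matrix(stats::rbinom(100, 1, 0.4), 10, 10) > 0
    if (!any(m)) next
    od <- matrix(stats::runif(100), 10, 10)
    a <- integratedOpticalDensity(m, od, 0.8, form = "product")
    b <- integratedOpticalDensity(m, od, 0.8, form = "sum")
    expect_lt(abs(a - b) / a, 1e-9)
  }
})

test_that("box-counting dimension hits the analytic fixtures in order", {
  fdLine <- boxCountingFD(generateFractalMask("line", 128))
  fdTri <- boxCountingFD(generateFractalMask("sierpinski_triangle", 7))
  fdSq <- boxCountingFD(generateFractalMask("filled_square", 64))
  expect_gt(fdLine, 0.95); expect_lt(fdLine, 1.05)
  expect_gt(fdTri, 1.55); expect_lt(fdTri, 1.62)
  expect_gte(fdSq, 1.90); expect_lte(fdSq, 2 + 1e-9)
  expect_true(fdLine < fdTri && fdTri < fdSq)
  fdCarpet <- boxCountingFD(generateFractalMask("sierpinski_carpet", 5))
  expect_equal(fdCarpet, log(8) / log(3), tolerance = 0.02)
})

test_that("box-counting dimension is stable under translation and rotation", {
  st <- generateFractalMask("sierpinski_triangle", 6)
  fd0 <- boxCountingFD(st)
  shifted <- matrix(FALSE, nrow(st) + 13, ncol(st) + 5)
  shifted[14:(13 + nrow(st)), 6:(5 + ncol(st))] <- st
  expect_equal(boxCountingFD(shifted), fd0, tolerance = 0.02)
  rotated <- t(st)[ncol(st):1, ]   # 90 degree rotation
  expect_equal(boxCountingFD(rotated), fd0, tolerance = 0.02)
})

test_that("tiny ROIs are rejected with guidance rather than measured", {
  small <- matrix(TRUE, 3, 3)
  expect_error(boxCountingFD(small), "tiny ROIs")
  expect_error(boxCountingFD(matrix(FALSE, 4, 4)), "empty")
})

test_that("measurePlaques returns per-ROI morphometry with region labels", {
  sc <- generateScene(smallSpec(nPlaques = 6, seed = 10))
  maps <- separateStains(renderBrightfield(sc, noiseSD = 0))
  seg <- segmentPlaques(maps)
  pm <- measurePlaques(seg$labels, stainMap(maps, "dab"),
                       pixelSize(sc), sc@regionMap)
  expect_identical(nrow(pm), 6L)
  expect_true(all(pm$region == "cortex"))
  expect_true(all(pm$area_um2 > 0 & pm$iod > 0))
  expect_true(all(is.na(pm$fd) | (pm$fd > 0.8 & pm$fd <= 2)))
  gt <- groundTruth(sc)$plaques
  expect_equal(sort(pm$max_diameter_um), sort(gt$max_diameter_um),
               tolerance = 0.05)
})

test_that("region densities follow the reporting units", {
  labels <- matrix(1L, 1000, 1000)          # 1 mm^2 at 1 um/px
  rm1 <- RegionLabelMap(labels, c("1" = "cortex"), 1)
  tab <- data.frame(id = 1:5, area_um2 = rep(100, 5),
                    iod = c(10, 20, 30, 40, 50),
                    max_diameter_um = rep(11.3, 5), fd = rep(1.2, 5),
                    region = "cortex")
  rd <- regionDensities(tab, rm1)
  expect_equal(rd$plaque_area_um2_per_mm2, 500)
  expect_equal(rd$plaque_count_per_mm2, 5)
  expect_equal(rd$total_iod, 150)
  expect_equal(rd$mean_iod, 30)
  ## empty table gives a zeros row
  rd0 <- regionDensities(tab[0, ], rm1)
  expect_equal(rd0$plaque_area_um2_per_mm2, 0)
  expect_equal(rd0$n_plaques, 0L)
  ## two-metric check of totals vs means
  tab2 <- data.frame(id = 1:2, area_um2 = c(50, 50), iod = c(10, 20),
                     max_diameter_um = c(8, 12), fd = c(1.1, 1.3),
                     region = "cortex")
  rd2 <- regionDensities(tab2, rm1)
  expect_equal(rd2$total_iod, 30)
  expect_equal(rd2$mean_iod, 15)
})

test_that("ROIs falling on background labels are excluded with a warning", {
  labels <- matrix(0L, 40, 40); labels[1:40, 1:20] <- 1L
  rmap <- RegionLabelMap(labels, c("1" = "cortex"), 1)
  seg <- matrix(0L, 40, 40)
  seg[5:8, 5:8] <- 1L       # inside cortex
  seg[5:8, 30:33] <- 2L     # on background
  expect_warning(pm <- measurePlaques(seg, NULL, 1, rmap,
                                      metrics = character(0)),
                 "excluded")
  expect_identical(nrow(pm), 1L)
  expect_identical(pm$region, "cortex")
})
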