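test_that("a pure white image unmixes to zero densities", {
  img <- ImagePlane(array(255, c(4, 4, 3)), 1, "brightfield")
  maps <- separateStains(img)
  expect_true(all(stainMap(maps, "hematoxylin") == 0))
  expect_true(all(stainMap(maps, "dab") == 0))
  expect_true(all(stainMap(maps, "fastred") == 0))
})

test_that("known density mixtures are recovered by unmixing", {
  p <- StainProfile()
  v <- stainMatrix(p)
  mix <- rbind(c(0, 1.0, 0),      # pure DAB
               c(0.3, 0.5, 0),    # hematoxylin + DAB
               c(0.2, 0.4, 0.6))  # all three
  for (k in seq_len(nrow(mix))) {
    od <- as.numeric(v %*% mix[k, ])
    img <- ImagePlane(array(rep(255 * 10^(-od), each = 4),
                            c(2, 2, 3)), 1, "brightfield")
    maps <- separateStains(img, p)
    got <- c(stainMap(maps, "hematoxylin")[1, 1],
             stainMap(maps, "dab")[1, 1],
             stainMap(maps, "fastred")[1, 1])
    expect_equal(got, mix[k, ], tolerance = 0.01)
  }
})

test_that("a degenerate stain basis is rejected", {
  expect_error(StainProfile(dab = c(0.651, 0.701, 0.290)),
               "linearly independent")
})

test_that("plaque segmentation handles blank and thresholded maps", {
  blank <- matrix(0, 32, 32)
  expect_identical(nrow(segmentPlaques(blank, pixelSizeUm = 1)$rois), 0L)
  od <- matrix(0, 32, 32); od[10:20, 10:20] <- 0.5
  seg <- segmentPlaques(od, SegmentationParams(dabOdThreshold = 0.15),
                        pixelSizeUm = 1)
  expect_identical(nrow(seg$rois), 1L)
  expect_identical(seg$rois$n_px, 121L)
  ## threshold above the maximum density gives an empty result
  seg2 <- segmentPlaques(od, SegmentationParams(dabOdThreshold = 0.9),
                         pixelSizeUm = 1)
  expect_identical(nrow(seg2$rois), 0L)
})

test_that("closing merges blobs across a 1-px gap; radius 0 keeps them apart", {
  od <- matrix(0, 16, 16)
  od[4:12, 3:6] <- 0.5
  od[4:12, 8:11] <- 0.5   # column 7 is a 1-px gap
  p1 <- SegmentationParams(minPlaqueAreaUm2 = 1, closingRadiusPx = 1L)
  p0 <- SegmentationParams(minPlaqueAreaUm2 = 1, closingRadiusPx = 0L)
  expect_identical(nrow(segmentPlaques(od, p1, 1)$rois), 1L)
  expect_identical(nrow(segmentPlaques(od, p0, 1)$rois), 2L)
})

test_that("components touching only diagonally are one 8-connected ROI", {
  od <- matrix(0, 12, 12)
  od[3:5, 3:5] <- 1
  od[6:8, 6:8] <- 1     # corner touch at (5,5)-(6,6)
  seg <- segmentPlaques(od, SegmentationParams(minPlaqueAreaUm2 = 1,
                                               closingRadiusPx = 0L), 1)
  expect_identical(nrow(seg$rois), 1L)
})

test_that("raising the threshold never increases total segmented area", {
  set.seed(31)
  base <- matrix(stats::runif(64 * 64), 64, 64)
  ## smooth it a little so components have structure
  od <- (base + rbind(base[-1, ], 0) + cbind(base[, -1], 0)) / 3
  params <- function(thr) SegmentationParams(dabOdThreshold = thr,
                                             minPlaqueAreaUm2 = 4)
  areas <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(thr) {
    sum(segmentPlaques(od, params(thr), 1)$labels > 0)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("plaques are recovered from a noiseless rendered scene", {
  sc <- generateScene(smallSpec(nPlaques = 8, seed = 12))
  gt <- groundTruth(sc)$plaques
  maps <- separateStains(renderBrightfield(sc, noiseSD = 0))
  seg <- segmentPlaques(maps)
  expect_identical(nrow(seg$rois), 8L)
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((seg$rois$centroid_row - gt$centroid_row[i])^2 +
                (seg$rois$centroid_col - gt$centroid_col[i])^2)
    expect_lt(min(d), 2)
    j <- which.min(d)
    expect_lt(abs(seg$rois$area_um2[j] - gt$area_um2[i]) / gt$area_um2[i],
              0.05)
  }
})

test_that("vessel segmentation recovers rendered vessel tubes", {
  sc <- generateScene(smallSpec(nPlaques = 0, vesselCount = 3, seed = 8))
  maps <- separateStains(renderBrightfield(sc, noiseSD = 0))
  vm <- segmentVessels(maps)
  gtv <- sc@vesselMask
  expect_gte(sum(vm == 1L & gtv == 1L) / sum(gtv), 0.90)
  ## blank map and supra-max threshold give empty masks
  expect_true(all(segmentVessels(matrix(0, 8, 8)) == 0L))
  expect_true(all(segmentVessels(stainMap(maps, "fastred"),
                                 SegmentationParams(redOdThreshold = 99)) == 0L))
})

test_that("ThS segmentation counts the planted fibrillar cores", {
  sc <- generateScene(smallSpec(nPlaques = 12, seed = 14,
                                fibrillarCoreFraction = 0.5,
                                typeMix = c(diffuse = 0, dense = 0.5,
                                            dense_core = 0.5)))
  nCores <- sum(groundTruth(sc)$plaques$has_fibrillar_core)
  expect_gt(nCores, 0)
  ts <- segmentThS(renderThS(sc, noiseSD = 0), pixelSizeUm = pixelSize(sc))
  expect_identical(nrow(ts$rois), as.integer(nCores))
  ## degenerate inputs
  expect_identical(nrow(segmentThS(matrix(0, 16, 16),
                                   pixelSizeUm = 1)$rois), 0L)
  sat <- segmentThS(matrix(255, 16, 16), pixelSizeUm = 1)
  expect_identical(nrow(sat$rois), 1L)
  expect_identical(sat$rois$n_px, 256L)
})
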