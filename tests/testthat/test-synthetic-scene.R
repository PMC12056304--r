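test_that("empty scene yields empty masks and ground truth", {
  sc <- generateScene(smallSpec(nPlaques = 0, vesselCount = 0))
  gt <- groundTruth(sc)
  expect_identical(nrow(gt$plaques), 0L)
  expect_identical(nrow(gt$vessels), 0L)
  expect_true(all(sc@plaqueLabels == 0L))
  expect_true(all(sc@vesselMask == 0L))
  expect_true(all(sc@densities$dab == 0))
})

test_that("scene generation is bit-deterministic for a fixed seed", {
  spec <- smallSpec(seed = 17, noiseSD = 2)
  a <- generateScene(spec)
  b <- generateScene(spec)
  expect_identical(a@densities, b@densities)
  expect_identical(a@plaqueLabels, b@plaqueLabels)
  expect_identical(a@vesselMask, b@vesselMask)
  expect_identical(groundTruth(a), groundTruth(b))
  expect_identical(renderBrightfield(a)@data, renderBrightfield(b)@data)
  expect_identical(renderFluorescence(a)@data, renderFluorescence(b)@data)
})

test_that("the requested number of plaques is generated", {
  sc <- generateScene(SceneSpec(nPlaques = 25, seed = 7))
  expect_identical(nrow(groundTruth(sc)$plaques), 25L)
  expect_identical(sort(unique(as.integer(sc@plaqueLabels[sc@plaqueLabels > 0]))),
                   1:25)
})

test_that("a field too small for the requested diameters is rejected", {
  expect_error(SceneSpec(fieldSizePx = c(64L, 64L),
                         diameterRangeUm = c(10, 100)),
               "field too small")
  expect_error(SceneSpec(typeMix = c(diffuse = 0.6, dense = 0.6,
                                     dense_core = -0.2)),
               "sum to 1")
})

test_that("plaque masks are disjoint and conserve area", {
  sc <- generateScene(smallSpec(nPlaques = 10, seed = 3))
  gt <- groundTruth(sc)$plaques
  px2 <- pixelSize(sc)^2
  ## each id labels exactly its own pixels: areas add up to the labelled set
  expect_equal(sum(gt$area_um2), sum(sc@plaqueLabels > 0) * px2)
  expect_lte(sum(gt$area_um2), prod(sc@spec@fieldSize) * px2)
  expect_true(all(gt$area_um2 > 0))
  expect_false(any(duplicated(gt$id)))
  ## contact flag is equivalent to zero distance
  expect_identical(gt$contact, gt$nearest_vessel_um == 0)
})

test_that("ground-truth vessel distances match an independent recomputation", {
  sc <- generateScene(smallSpec(nPlaques = 8, vesselCount = 3, seed = 5))
  gt <- groundTruth(sc)$plaques
  pv <- plaqueVesselTable(sc@plaqueLabels, sc@vesselMask, pixelSize(sc))
  m <- merge(gt, pv, by = "id")
  expect_true(all(abs(m$nearest_vessel_um - m$nearest_distance_um) <=
                    pixelSize(sc) + 1e-9))
  expect_identical(m$contact.x, m$contact.y)
})

test_that("constructed Abeta40/Abeta42 area ratio is recovered on noiseless renders", {
  for (ratio in c(0.5, 0.8)) {
    sc <- generateScene(smallSpec(nPlaques = 10, seed = 9,
                                  ab40Ab42Overlap = 0.5,
                                  ab40Ab42AreaRatio = ratio))
    fl <- renderFluorescence(sc, noiseSD = 0)
    a40 <- channelArea(fl@data[, , 1], 90, pixelSize(sc))
    a42 <- channelArea(fl@data[, , 2], 90, pixelSize(sc))
    expect_lt(abs(a40 / a42 - ratio) / ratio, 0.05)
  }
})

test_that("brightfield render obeys the Beer-Lambert identities", {
  sc <- generateScene(smallSpec(nPlaques = 0, vesselCount = 0))
  ## zero density everywhere: uniform white at the white level
  sc@densities$hematoxylin[] <- 0
  bf <- renderBrightfield(sc, noiseSD = 0)
  expect_true(all(bf@data == 255))
  ## single pixel of DAB: deconvolution returns the density; doubling the
  ## density doubles the DAB-projected optical density
  p <- StainProfile()
  for (d in c(0.5, 1)) {
    sc2 <- sc
    sc2@densities$dab[10, 10] <- d
    bf2 <- renderBrightfield(sc2, noiseSD = 0)
    od <- -log10(pmax(bf2@data[10, 10, ], 0.5) / 255)
    expect_equal(sum(od * stainMatrix(p)[, "dab"]), d, tolerance = 1e-6)
    maps <- separateStains(bf2, p)
    expect_equal(stainMap(maps, "dab")[10, 10], d, tolerance = 0.01)
    expect_lte(max(stainMap(maps, "hematoxylin")[10, 10],
                   stainMap(maps, "fastred")[10, 10]), 0.01)
  }
})

test_that("fluorescence channels are identical at overlap 1 and disjoint at 0", {
  sc1 <- generateScene(smallSpec(nPlaques = 6, seed = 2,
                                 ab40Ab42Overlap = 1, ab40Ab42AreaRatio = 1))
  fl1 <- renderFluorescence(sc1, noiseSD = 0)
  expect_identical(fl1@data[, , 1], fl1@data[, , 2])
  expect_equal(overlapCoefficient(fl1@data[, , 1], fl1@data[, , 2],
                                  thresholds = c(90, 90)), 1)
  sc0 <- generateScene(smallSpec(nPlaques = 6, seed = 2,
                                 ab40Ab42Overlap = 0, ab40Ab42AreaRatio = 1))
  fl0 <- renderFluorescence(sc0, noiseSD = 0)
  a <- fl0@data[, , 1] >= 90; b <- fl0@data[, , 2] >= 90
  expect_false(any(a & b))
  expect_equal(overlapCoefficient(fl0@data[, , 1], fl0@data[, , 2],
                                  thresholds = c(90, 90)), 0)
})

test_that("fractal fixtures have their exact constructions", {
  l <- generateFractalMask("line", 128)
  expect_identical(sum(l), 128L)
  expect_identical(sum(rowSums(l) > 0), 1L)
  sq <- generateFractalMask("filled_square", 64)
  expect_identical(dim(sq), c(64L, 64L))
  expect_true(all(sq))
  st <- generateFractalMask("sierpinski_triangle", 7)
  expect_equal(sum(st), 3^7)
  carpet <- generateFractalMask("sierpinski_carpet", 4)
  expect_equal(sum(carpet), 8^4)
  expect_error(generateFractalMask("blob", 16), "unknown fractal kind")
  expect_error(generateFractalMask("sierpinski_triangle", 3), "depth")
})

test_that("planted vessel-contact fraction raises the contact rate", {
  scLo <- generateScene(smallSpec(nPlaques = 12, vesselCount = 2, seed = 21,
                                  contactFraction = 0))
  scHi <- generateScene(smallSpec(nPlaques = 12, vesselCount = 2, seed = 21,
                                  contactFraction = 0.75))
  expect_gt(sum(groundTruth(scHi)$plaques$contact),
            sum(groundTruth(scLo)$plaques$contact))
})
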