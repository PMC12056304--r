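test_that("the 0-um contact convention fires on overlap and 8-adjacency", {
  p <- matrix(0, 16, 16); p[4:6, 4:6] <- 1
  vOverlap <- matrix(0, 16, 16); vOverlap[5, 5] <- 1
  r <- nearestVesselDistance(p, vOverlap, 0.5)
  expect_identical(r, list(distance_um = 0, contact = TRUE))
  vDiag <- matrix(0, 16, 16); vDiag[7, 7] <- 1   # diagonal neighbour of (6,6)
  r <- nearestVesselDistance(p, vDiag, 0.5)
  expect_identical(r, list(distance_um = 0, contact = TRUE))
  vFar <- matrix(0, 16, 16); vFar[6, 10] <- 1    # 4 px right of the plaque edge
  r <- nearestVesselDistance(p, vFar, 0.5)
  expect_false(r$contact)
  expect_equal(r$distance_um, 4 * 0.5)
})

test_that("a plaque 20 px from a vessel at 0.5 um/px is 10 um away", {
  p <- matrix(0, 32, 32); p[1, 1] <- 1
  v <- matrix(0, 32, 32); v[1, 21] <- 1
  r <- nearestVesselDistance(p, v, 0.5)
  expect_equal(r$distance_um, 10)
  expect_false(r$contact)
})

test_that("distance transform equals the brute-force pairwise minimum", {
  set.seed(99)
  for (k in 1:40) {
    nr <- sample(8:64, 1); nc <- sample(8:64, 1)
    p <- matrix(stats::rbinom(nr * nc, 1, 0.06), nr, nc)
    v <- matrix(stats::rbinom(nr * nc, 1, 0.04), nr, nc)
    if (!any(p) || !any(v)) next
    px <- stats::runif(1, 0.2, 2)
    r <- nearestVesselDistance(p, v, px)
    dminPx <- bruteMinDistancePx(p, v)
    if (dminPx <= sqrt(2) + 1e-9) {
      expect_true(r$contact)
      expect_identical(r$distance_um, 0)
    } else {
      expect_false(r$contact)
      expect_equal(r$distance_um, dminPx * px, tolerance = 1e-12)
    }
  }
})

test_that("distances are invariant under joint translation of both masks", {
  p <- matrix(0, 40, 40); p[5:8, 5:8] <- 1
  v <- matrix(0, 40, 40); v[20:22, 25:27] <- 1
  r0 <- nearestVesselDistance(p, v, 1)
  sh <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  r1 <- nearestVesselDistance(sh(p, 7, 3), sh(v, 7, 3), 1)
  expect_equal(r1$distance_um, r0$distance_um, tolerance = 1e-12)
})

test_that("an empty vessel mask yields an undefined-distance sentinel", {
  p <- matrix(0, 8, 8); p[2, 2] <- 1
  expect_warning(r <- nearestVesselDistance(p, matrix(0, 8, 8), 1),
                 "undefined")
  expect_true(is.na(r$distance_um))
})

test_that("association frequency is the contact percentage, order-invariant", {
  rec <- data.frame(id = 1:4, nearest_distance_um = c(0, 5, 9, 14),
                    contact = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(associationFrequency(rec), 25)
  expect_equal(associationFrequency(rec[sample(4), ]), 25)
  rec$contact <- TRUE; rec$nearest_distance_um <- 0
  expect_equal(associationFrequency(rec), 100)
  rec$contact <- FALSE
  expect_equal(associationFrequency(rec), 0)
  expect_error(associationFrequency(rec[0, ]), "undefined")
})

test_that("mean non-contact distance disregards 0-um plaques", {
  rec <- data.frame(nearest_distance_um = c(0, 10, 20),
                    contact = c(TRUE, FALSE, FALSE))
  expect_equal(meanNoncontactDistance(rec), 15)
  one <- data.frame(nearest_distance_um = 7.5, contact = FALSE)
  expect_equal(meanNoncontactDistance(one), 7.5)
  allc <- data.frame(nearest_distance_um = c(0, 0), contact = c(TRUE, TRUE))
  expect_error(meanNoncontactDistance(allc), "contact")
})

test_that("diameter-distance correlation recovers planted and null effects", {
  rec <- simulateRecords(2000, -0.2, seed = 123)
  r <- diameterDistanceCorrelation(rec)
  expect_lt(abs(r$r - (-0.2)), 0.06)
  expect_identical(r$n, 2000L)
  recNull <- simulateRecords(2000, 0, seed = 456)
  expect_lt(abs(diameterDistanceCorrelation(recNull)$r), 0.06)
  ## exact anticorrelation
  exact <- data.frame(max_diameter_um = c(30, 25, 20, 15),
                      nearest_distance_um = c(5, 10, 15, 20),
                      contact = FALSE)
  expect_equal(diameterDistanceCorrelation(exact)$r, -1)
  expect_error(diameterDistanceCorrelation(exact[1:3, ]), "at least 4")
})
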