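#' Generate a ground-truthed synthetic histology scene
#'
#' Builds one synthetic field according to a \linkS4class{SceneSpec}:
#' smoothed random-walk vessel tubes, non-overlapping plaques of three
#' morphological archetypes (diffuse Gaussian blob, dense deposit with a
#' steep radial profile, dense core plus diffuse corona), per-stain optical
#' density maps (DAB on plaques, Fast Red on vessels, uniform hematoxylin
#' counterstain), noiseless Abeta40/Abeta42 fluorescence channels constructed
#' to a target overlap coefficient and area ratio, a ThS layer marking
#' fibrillar cores, and ground-truth tables (geometry, nearest-vessel
#' distance with the 0-um contact convention, fibrillar flags).
#'
#' The generator is bit-deterministic for a fixed seed. Ground-truth
#' nearest-vessel distances use pixel-centre (edge-to-edge) semantics on the
#' realised masks: the minimum Euclidean distance from any plaque pixel to
#' any vessel pixel, zero (contact) when a plaque pixel overlaps or is
#' 8-adjacent to a vessel pixel.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return A \linkS4class{Scene}.
#' @examples
#' sc <- generateScene(SceneSpec(nPlaques = 5, fieldSizePx = c(128, 128),
#'                               diameterRangeUm = c(8, 20), seed = 3))
#' nrow(groundTruth(sc)$plaques)
#' @export
generateScene <- function(spec) {
  methods::validObject(spec)
  withSeed(spec@seed, {
    nr <- spec@fieldSize[1L]; nc <- spec@fieldSize[2L]
    px <- spec@pixelSizeUm

    ## ---- vessels: random-walk centrelines dilated to vesselRadiusUm ----
    rpx <- spec@vesselRadiusUm / px
    vesselMask <- matrix(0L, nr, nc)
    vesselRows <- list()
    if (spec@vesselCount > 0L) {
      pr <- pc <- numeric(0)
      lens <- integer(spec@vesselCount)
      for (v in seq_len(spec@vesselCount)) {
        side <- sample.int(4L, 1L)
        p <- switch(side,
          c(1, runif(1, 1, nc)), c(nr, runif(1, 1, nc)),
          c(runif(1, 1, nr), 1), c(runif(1, 1, nr), nc))
        ang <- switch(side, pi / 2, -pi / 2, 0, pi) + runif(1, -0.5, 0.5)
        ## heading angle measured in (col, row) plane; steps of 1.25 px with
        ## small angular jitter give a gently curving tube
        pts <- matrix(NA_real_, nrow = 4L * (nr + nc), ncol = 2L)
        k <- 0L
        while (p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
               k < nrow(pts)) {
          k <- k + 1L
          pts[k, ] <- p
          ang <- ang + rnorm(1, 0, 0.12)
          p <- p + 1.25 * c(sin(ang), cos(ang))
        }
        pts <- pts[seq_len(k), , drop = FALSE]
        lens[v] <- k
        pr <- c(pr, pts[, 1]); pc <- c(pc, pts[, 2])
      }
      vesselMask <- vesselMask |
        stampDiscs(round(pr), round(pc), rpx, c(nr, nc))
      storage.mode(vesselMask) <- "integer"
      vesselRows <- data.frame(id = seq_len(spec@vesselCount),
                               centreline_px = lens,
                               radius_um = spec@vesselRadiusUm)
    } else {
      vesselRows <- data.frame(id = integer(0), centreline_px = integer(0),
                               radius_um = numeric(0))
    }

    ## ---- plaque placement -------------------------------------------------
    n <- spec@nPlaques
    types <- character(0)
    if (n > 0L) {
      types <- sample(names(spec@typeMix), n, replace = TRUE,
                      prob = spec@typeMix)
      diams <- runif(n, spec@diameterRangeUm[1L], spec@diameterRangeUm[2L])
      ord <- order(diams, decreasing = TRUE)  # place large plaques first
      types <- types[ord]; diams <- diams[ord]
      radPx <- diams / 2 / px
      nContact <- round(spec@contactFraction * n)
      onVessel <- rep(c(TRUE, FALSE), c(nContact, n - nContact))
      vesselIdx <- which(vesselMask == 1L)
      cent <- matrix(NA_real_, n, 2L)
      for (i in seq_len(n)) {
        R <- radPx[i]
        placed <- FALSE
        for (att in seq_len(4000L)) {
          ## a planted contact may be unsatisfiable on a short vessel tube:
          ## fall back to natural placement after enough failed attempts
          if (onVessel[i] && att <= 1500L && length(vesselIdx)) {
            vi <- vesselIdx[sample.int(length(vesselIdx), 1L)]
            c0 <- c((vi - 1L) %% nr + 1L, (vi - 1L) %/% nr + 1L)
            ## keep the plaque inside the field
            c0 <- c(min(max(c0[1L], R + 2), nr - R - 1),
                    min(max(c0[2L], R + 2), nc - R - 1))
          } else {
            c0 <- c(runif(1, R + 2, nr - R - 1), runif(1, R + 2, nc - R - 1))
          }
          ok <- TRUE
          if (i > 1L) {
            d <- sqrt((cent[seq_len(i - 1L), 1L] - c0[1L])^2 +
                      (cent[seq_len(i - 1L), 2L] - c0[2L])^2)
            ## separation keeps masks disjoint after boundary wobble and the
            ## closing step used at segmentation time
            ok <- all(d > 1.15 * (radPx[seq_len(i - 1L)] + R) + 5)
          }
          if (ok) { cent[i, ] <- c0; placed <- TRUE; break }
        }
        if (!placed)
          stop(sprintf(paste0("field %d x %d px too small to place %d ",
                              "non-overlapping plaques of up to %.1f um"),
                       nr, nc, n, spec@diameterRangeUm[2L]))
      }
    } else {
      diams <- numeric(0); radPx <- numeric(0)
      cent <- matrix(numeric(0), 0L, 2L)
    }

    ## ---- realise plaque masks and DAB densities ---------------------------
    dab <- matrix(0, nr, nc)
    plaqueLabels <- matrix(0L, nr, nc)
    ths <- matrix(8, nr, nc)
    hasCore <- rep(FALSE, n)
    if (n > 0L) {
      candidates <- which(types %in% c("dense", "dense_core"))
      nCore <- round(spec@fibrillarCoreFraction * length(candidates))
      if (nCore > 0L)
        hasCore[candidates[sample.int(length(candidates), nCore)]] <- TRUE
    }
    pixIdx <- vector("list", n)
    for (i in seq_len(n)) {
      R <- radPx[i]
      ## smooth angular wobble of the outline (low-order harmonics)
      amp <- runif(3, 0, 0.04)
      pha <- runif(3, 0, 2 * pi)
      r1 <- floor(max(1, cent[i, 1L] - R * 1.2 - 2))
      r2 <- ceiling(min(nr, cent[i, 1L] + R * 1.2 + 2))
      c1 <- floor(max(1, cent[i, 2L] - R * 1.2 - 2))
      c2 <- ceiling(min(nc, cent[i, 2L] + R * 1.2 + 2))
      dy <- (r1:r2) - cent[i, 1L]
      dx <- (c1:c2) - cent[i, 2L]
      rr <- sqrt(outer(dy^2, dx^2, "+"))
      th <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
      Rb <- R * (1 + amp[1] * cos(2 * th + pha[1]) +
                     amp[2] * cos(3 * th + pha[2]) +
                     amp[3] * cos(5 * th + pha[3]))
      inside <- rr <= Rb
      dloc <- matrix(0, nrow(inside), ncol(inside))
      coreR <- clip01(max(0.3 * R, 3.5 / px), 0, 0.8 * R)
      if (types[i] == "diffuse") {
        dloc[inside] <- 0.28 + 0.42 * exp(-(rr[inside] / (0.55 * R))^2)
      } else if (types[i] == "dense") {
        dloc[inside] <- 0.30 + 0.65 * (1 - clip01(rr[inside] / R, 0, 1)^4)
      } else {  # dense_core: compact core plus fainter corona
        core <- inside & rr <= coreR
        cor <- inside & !core
        dloc[core] <- 1.10
        frac <- clip01((rr[cor] - coreR) / pmax(Rb[cor] - coreR, 1e-6), 0, 1)
        dloc[cor] <- 0.55 - 0.25 * frac
      }
      sub <- matrix(FALSE, nr, nc)
      sub[r1:r2, c1:c2] <- inside
      free <- sub & plaqueLabels == 0L
      plaqueLabels[free] <- i
      blk <- dab[r1:r2, c1:c2]
      put <- inside & (plaqueLabels[r1:r2, c1:c2] == i)
      blk[put] <- dloc[put]
      dab[r1:r2, c1:c2] <- blk
      pixIdx[[i]] <- which(plaqueLabels == i)
      if (hasCore[i]) {
        thsR <- if (types[i] == "dense_core") coreR else
          max(0.5 * R, 3.5 / px)
        tb <- ths[r1:r2, c1:c2]
        tput <- put & rr <= thsR
        tb[tput] <- 200
        ths[r1:r2, c1:c2] <- tb
      }
    }

    ## ---- other stains -----------------------------------------------------
    hematoxylin <- matrix(0.25, nr, nc)
    fastred <- matrix(0, nr, nc)
    fastred[vesselMask == 1L] <- 0.80

    ## ---- region map -------------------------------------------------------
    regionMap <- if (spec@regionLayout == "single") {
      RegionLabelMap(matrix(1L, nr, nc), c("1" = "cortex"), px)
    } else {
      lab <- matrix(0L, nr, nc)
      hr <- nr %/% 2L; hc <- nc %/% 2L
      lab[1:hr, 1:hc] <- 1L; lab[1:hr, (hc + 1L):nc] <- 2L
      lab[(hr + 1L):nr, 1:hc] <- 3L; lab[(hr + 1L):nr, (hc + 1L):nc] <- 4L
      RegionLabelMap(lab, c("1" = "cortex", "2" = "hippocampus",
                            "3" = "striatum", "4" = "thalamus"), px)
    }

    ## ---- fluorescence channels at the constructed overlap -----------------
    fluor <- buildFluorChannels(plaqueLabels, pixIdx, cent,
                                spec@ab40Ab42Overlap, spec@ab40Ab42AreaRatio,
                                c(nr, nc))

    ## ---- ground truth -----------------------------------------------------
    if (n > 0L) {
      areaPx <- vapply(pixIdx, length, integer(1))
      if (sum(vesselMask) > 0L) {
        dt <- EBImage::distmap(1L - vesselMask, metric = "euclidean")
        dmin <- vapply(pixIdx, function(ii) min(dt[ii]), numeric(1))
      } else {
        dmin <- rep(NA_real_, n)
      }
      contact <- !is.na(dmin) & dmin <= sqrt(2) + 1e-9
      distUm <- ifelse(contact, 0, dmin * px)
      feret <- vapply(seq_len(n), function(i) {
        m <- matrix(FALSE, nr, nc); m[pixIdx[[i]]] <- TRUE
        maxFeretDiameter(m, px)
      }, numeric(1))
      region <- vapply(pixIdx, majorityLabel, integer(1),
                       labels = regionMap@labels)
      plaques <- data.frame(
        id = seq_len(n), type = types,
        centroid_row = vapply(pixIdx, function(ii) mean((ii - 1L) %% nr), numeric(1)),
        centroid_col = vapply(pixIdx, function(ii) mean((ii - 1L) %/% nr), numeric(1)),
        area_um2 = areaPx * px^2,
        max_diameter_um = feret,
        has_fibrillar_core = hasCore,
        nearest_vessel_um = distUm,
        contact = contact,
        region = unname(regionMap@regionNames[as.character(region)]),
        stringsAsFactors = FALSE)
    } else {
      plaques <- data.frame(
        id = integer(0), type = character(0), centroid_row = numeric(0),
        centroid_col = numeric(0), area_um2 = numeric(0),
        max_diameter_um = numeric(0), has_fibrillar_core = logical(0),
        nearest_vessel_um = numeric(0), contact = logical(0),
        region = character(0), stringsAsFactors = FALSE)
    }

    truth <- list(plaques = plaques, vessels = vesselRows,
                  overlap = fluor$realizedOverlap,
                  area_ratio_40_42 = fluor$realizedRatio)
    methods::new("Scene", spec = spec,
                 densities = list(hematoxylin = hematoxylin, dab = dab,
                                  fastred = fastred),
                 fluor = list(ab40 = fluor$ab40, ab42 = fluor$ab42),
                 ths = ths, plaqueLabels = plaqueLabels,
                 vesselMask = vesselMask, regionMap = regionMap,
                 truth = truth)
  })
}

## Construct noiseless Abeta40/Abeta42 channels so that the pixelwise
## Manders overlap of the pair equals `rho` and the Abeta40/Abeta42 area
## ratio equals `ratio`. Abeta42 covers every plaque; Abeta40 takes the
## innermost rho*sqrt(ratio) fraction of each plaque's pixels plus an
## external ring making its total area ratio*|plaque|. Deterministic:
## pixels are ranked by distance from the plaque centroid.
buildFluorChannels <- function(plaqueLabels, pixIdx, cent, rho, ratio, dm) {
  nr <- dm[1L]; nc <- dm[2L]
  ab42 <- matrix(4, nr, nc)
  ab40 <- matrix(4, nr, nc)
  n <- length(pixIdx)
  nAB <- 0; nA <- 0; nB <- 0
  anyPlaque <- plaqueLabels > 0L
  for (i in seq_len(n)) {
    ii <- pixIdx[[i]]
    nb <- length(ii)
    if (!nb) next
    ab42[ii] <- 180
    rows <- (ii - 1L) %% nr + 1L
    cols <- (ii - 1L) %/% nr + 1L
    d2 <- (rows - cent[i, 1L])^2 + (cols - cent[i, 2L])^2
    ordIn <- ii[order(d2, ii)]
    nIn <- round(rho * sqrt(ratio) * nb)
    nTot <- round(ratio * nb)
    nOut <- max(0L, nTot - nIn)
    if (nIn > 0L) ab40[ordIn[seq_len(nIn)]] <- 180
    if (nOut > 0L) {
      ## external ring: nearest free pixels (not on any plaque, not already
      ## assigned) around the plaque, taken from a growing local window
      half <- ceiling(sqrt(nb * (1 + ratio) / pi)) + 8L
      take <- integer(0)
      repeat {
        r1 <- max(1L, floor(cent[i, 1L]) - half)
        r2 <- min(nr, ceiling(cent[i, 1L]) + half)
        c1 <- max(1L, floor(cent[i, 2L]) - half)
        c2 <- min(nc, ceiling(cent[i, 2L]) + half)
        wr <- rep.int(r1:r2, times = c2 - c1 + 1L)
        wc <- rep(c1:c2, each = r2 - r1 + 1L)
        wi <- wr + (wc - 1L) * nr
        cand <- wi[!anyPlaque[wi] & ab40[wi] < 100]
        if (length(cand) >= nOut ||
            (r1 == 1L && r2 == nr && c1 == 1L && c2 == nc)) {
          rr2 <- ((cand - 1L) %% nr + 1L - cent[i, 1L])^2 +
            ((cand - 1L) %/% nr + 1L - cent[i, 2L])^2
          take <- cand[order(rr2, cand)][seq_len(min(nOut, length(cand)))]
          break
        }
        half <- half * 2L
      }
      ab40[take] <- 180
      nOut <- length(take)
    }
    nAB <- nAB + nIn
    nA <- nA + nIn + nOut
    nB <- nB + nb
  }
  realized <- if (nA > 0 && nB > 0) nAB / sqrt(nA * nB) else NA_real_
  list(ab40 = ab40, ab42 = ab42,
       realizedOverlap = realized,
       realizedRatio = if (nB > 0) nA / nB else NA_real_)
}
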