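#' Maximum (Feret) diameter of a mask
#'
#' The maximum pairwise Euclidean distance between foreground pixel
#' centres, in micrometres. Computed on the convex hull of the pixel
#' centres (the diameter of a point set is attained on its hull), which
#' keeps large deposits cheap; a single-pixel mask has diameter 0.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @return Maximum diameter in micrometres.
#' @examples
#' m <- matrix(TRUE, 10, 10)
#' maxFeretDiameter(m, 1)  # 9 * sqrt(2)
#' @export
maxFeretDiameter <- function(mask, pixelSizeUm) {
  idx <- which(mask > 0)
  if (!length(idx)) stop("cannot measure the diameter of an empty mask")
  if (length(idx) == 1L) return(0)
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  if (length(idx) > 3L) {
    h <- grDevices::chull(c, r)
    ## chull can drop collinear extremes only when all points are collinear;
    ## keep the bounding-box extremes to be safe
    ex <- c(which.min(r), which.max(r), which.min(c), which.max(c))
    h <- unique(c(h, ex))
    r <- r[h]; c <- c[h]
  }
  d2 <- outer(r, r, "-")^2 + outer(c, c, "-")^2
  sqrt(max(d2)) * pixelSizeUm
}

#' Integrated optical density of a ROI
#'
#' IOD is defined as the ROI area times the average pixel intensity over
#' the ROI; with the area in um^2 and intensity as deconvolved DAB optical
#' density this equals the sum of per-pixel OD times the pixel area
#' (\code{form = "sum"}), identically.
#'
#' @param mask logical or 0/1 matrix selecting the ROI.
#' @param od intensity raster, same shape; by convention the DAB
#'   optical-density map (a raw-intensity raster may be passed instead for
#'   comparability with intensity-based packages).
#' @param pixelSizeUm micrometres per pixel.
#' @param form \code{"product"} (area x mean intensity) or \code{"sum"}
#'   (sum of intensity x pixel area); mathematically identical.
#' @return IOD in um^2 x intensity units.
#' @examples
#' m <- matrix(TRUE, 10, 10)
#' integratedOpticalDensity(m, matrix(0.5, 10, 10), 1)  # 50
#' @export
integratedOpticalDensity <- function(mask, od, pixelSizeUm,
                                     form = c("product", "sum")) {
  form <- match.arg(form)
  idx <- which(mask > 0)
  if (!length(idx)) stop("cannot compute IOD of an empty mask")
  stopifnot(identical(dim(mask), dim(od)))
  px2 <- pixelSizeUm^2
  if (form == "product") length(idx) * px2 * mean(od[idx])
  else sum(od[idx]) * px2
}

#' Box-counting fractal dimension of a binary mask
#'
#' Crops the mask to its bounding box, pads it into a square whose side is
#' a power of two (at least 16), counts the number of boxes \eqn{N(s)} of
#' size \eqn{s = 2, 4, 8, \ldots, side/2} (grid anchored at the bounding-box
#' origin) containing at least one foreground pixel, and returns the slope
#' of the ordinary least squares regression of \eqn{\log N(s)} on
#' \eqn{\log(1/s)}. For planar masks the estimate lies in [0, 2]: about 1
#' for curves, about 2 for filled regions, and the analytic dimension for
#' self-similar fixtures (\code{\link{generateFractalMask}}).
#'
#' @param mask logical or 0/1 matrix.
#' @param offsetAverage average \eqn{N(s)} over four grid offsets instead
#'   of the single anchored grid (default \code{FALSE}).
#' @return The fractal dimension estimate.
#' @examples
#' boxCountingFD(generateFractalMask("filled_square", 64))  # 2
#' @export
boxCountingFD <- function(mask, offsetAverage = FALSE) {
  idx <- which(mask > 0)
  if (!length(idx)) stop("cannot compute the fractal dimension of an empty mask")
  nr <- nrow(mask)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  r <- r - min(r); c <- c - min(c)
  ext <- max(max(r), max(c)) + 1L
  if (ext < 8L)
    stop(paste0("fewer than 3 usable box sizes: ROI bounding box is below ",
                "8 px; skip the FD measurement for tiny ROIs"))
  side <- max(16L, 2L^ceiling(log2(ext)))
  sizes <- 2L^(1:(log2(side) - 1L))
  counts <- vapply(sizes, function(s) {
    offs <- if (offsetAverage) {
      o <- unique(c(0L, s %/% 2L))
      as.matrix(expand.grid(o, o))
    } else matrix(0L, 1L, 2L)
    mean(apply(offs, 1L, function(o) {
      bi <- (r + o[1L]) %/% s
      bj <- (c + o[2L]) %/% s
      length(unique(bi * (side %/% s + 2L) + bj))
    }))
  }, numeric(1))
  x <- log(1 / sizes)
  y <- log(counts)
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Measure all plaque ROIs of a label image
#'
#' Computes, for every labelled ROI: area (um^2), maximum Feret diameter
#' (um), integrated optical density over the supplied intensity raster,
#' box-counting fractal dimension (NA for ROIs too small to support three
#' box sizes), 0-based centroid, and the anatomical region covering the
#' majority of the ROI mask (ROIs falling entirely on background are
#' excluded with a warning).
#'
#' @param labels integer label matrix from \code{\link{segmentPlaques}} (or
#'   the list it returns).
#' @param od intensity raster for IOD (DAB optical density by convention);
#'   \code{NULL} skips IOD.
#' @param pixelSizeUm micrometres per pixel.
#' @param regionMap optional \linkS4class{RegionLabelMap} used to assign a
#'   region to each ROI.
#' @param metrics subset of \code{c("diameter", "iod", "fd")} to compute in
#'   addition to area and centroid.
#' @return data.frame with one row per ROI: id, area_um2, centroid_row,
#'   centroid_col, max_diameter_um, iod, fd, region.
#' @export
measurePlaques <- function(labels, od = NULL, pixelSizeUm,
                           regionMap = NULL,
                           metrics = c("diameter", "iod", "fd")) {
  if (is.list(labels) && !is.matrix(labels)) labels <- labels$labels
  stopifnot(is.matrix(labels))
  n <- max(labels)
  nr <- nrow(labels)
  px2 <- pixelSizeUm^2
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ii <- which(labels == i)
    if (!length(ii)) next
    rec <- data.frame(id = i, area_um2 = length(ii) * px2,
                      centroid_row = mean((ii - 1L) %% nr),
                      centroid_col = mean((ii - 1L) %/% nr))
    m <- NULL
    if (any(c("diameter", "fd") %in% metrics)) {
      m <- matrix(FALSE, nr, ncol(labels)); m[ii] <- TRUE
    }
    rec$max_diameter_um <- if ("diameter" %in% metrics)
      maxFeretDiameter(m, pixelSizeUm) else NA_real_
    rec$iod <- if ("iod" %in% metrics && !is.null(od))
      integratedOpticalDensity(m %||% (labels == i), od, pixelSizeUm)
    else NA_real_
    rec$fd <- if ("fd" %in% metrics)
      tryCatch(boxCountingFD(m), error = function(e) NA_real_)
    else NA_real_
    rec$region <- if (!is.null(regionMap)) {
      lab <- majorityLabel(ii, regionMap@labels)
      if (lab == 0L) NA_character_
      else unname(regionMap@regionNames[as.character(lab)])
    } else NA_character_
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      max_diameter_um = numeric(0), iod = numeric(0),
                      fd = numeric(0), region = character(0))
  if (!is.null(regionMap) && any(is.na(out$region)) && nrow(out)) {
    warning(sprintf("%d ROI(s) on background labels were excluded",
                    sum(is.na(out$region))))
    out <- out[!is.na(out$region), , drop = FALSE]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-region plaque density summary
#'
#' Aggregates a plaque metrics table over the regions of a label map:
#' total plaque area per mm^2 of region, plaque count per mm^2, total
#' (cumulated) IOD, mean per-plaque IOD, mean diameter, and mean fractal
#' dimension. Regions without plaques get a zeros row.
#'
#' @param plaqueTable data.frame from \code{\link{measurePlaques}} with a
#'   \code{region} column.
#' @param regionMap a \linkS4class{RegionLabelMap}.
#' @return data.frame with one row per named region.
#' @export
regionDensities <- function(plaqueTable, regionMap) {
  areas <- regionAreas(regionMap)
  out <- lapply(seq_len(nrow(areas)), function(k) {
    reg <- areas$region[k]
    mm2 <- areas$area_mm2[k]
    sub <- plaqueTable[!is.na(plaqueTable$region) &
                         plaqueTable$region == reg, , drop = FALSE]
    data.frame(
      region = reg, region_area_mm2 = mm2, n_plaques = nrow(sub),
      plaque_area_um2_per_mm2 = sum(sub$area_um2) / mm2,
      plaque_count_per_mm2 = nrow(sub) / mm2,
      total_iod = if (nrow(sub)) sum(sub$iod, na.rm = TRUE) else 0,
      mean_iod = if (nrow(sub)) mean(sub$iod, na.rm = TRUE) else 0,
      mean_diameter_um = if (nrow(sub)) mean(sub$max_diameter_um, na.rm = TRUE) else 0,
      mean_fd = if (nrow(sub) && any(!is.na(sub$fd))) mean(sub$fd, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
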