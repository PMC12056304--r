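#' Separate stains by optical-density unmixing
#'
#' Converts a brightfield RGB image into per-stain density maps. Each
#' pixel's per-channel optical density is \eqn{OD_c = -\log_{10}(I_c / W)}
#' (intensities clamped at 0.5 to guard the logarithm), and the 3x3 linear
#' system defined by the stain matrix is solved per pixel; negative
#' densities are clipped to zero. This is the reproducible realisation of
#' threshold gating on a sampled DAB RGB profile: the stain vectors play the
#' role of the sampled profile and are applied identically to every image.
#'
#' @param image a 3-channel brightfield \linkS4class{ImagePlane}.
#' @param profile a \linkS4class{StainProfile}.
#' @return A \linkS4class{StainMaps}.
#' @examples
#' sc <- generateScene(SceneSpec(nPlaques = 3, fieldSizePx = c(96, 96),
#'                               diameterRangeUm = c(8, 16), noiseSD = 0))
#' maps <- separateStains(renderBrightfield(sc), StainProfile())
#' max(stainMap(maps, "dab"))
#' @export
separateStains <- function(image, profile = StainProfile()) {
  stopifnot(methods::is(image, "ImagePlane"))
  if (modality(image) != "brightfield" || length(dim(image@data)) != 3L ||
      dim(image@data)[3L] != 3L)
    stop("separateStains requires a 3-channel brightfield image")
  v <- stainMatrix(profile)
  W <- whiteLevel(profile)
  inv <- tryCatch(solve(v), error = function(e)
    stop("configuration error: singular stain matrix"))
  d <- image@data
  nr <- dim(d)[1L]; nc <- dim(d)[2L]
  od <- -log10(pmax(d, 0.5) / W)
  odMat <- matrix(od, ncol = 3L)        # pixels x channels
  dens <- odMat %*% t(inv)              # pixels x stains
  dens[dens < 0] <- 0
  methods::new("StainMaps",
    hematoxylin = matrix(dens[, 1L], nr, nc),
    dab = matrix(dens[, 2L], nr, nc),
    fastred = matrix(dens[, 3L], nr, nc),
    pixelSize = pixelSize(image))
}

## 8-connected component labelling: EBImage::bwlabel (4-connected) followed
## by a union-find merge of labels that touch diagonally.
label8 <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  L <- EBImage::bwlabel(m)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  nlab <- max(L)
  if (nlab <= 1L) return(L)
  parent <- seq_len(nlab)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(L); nc <- ncol(L)
  pairs <- NULL
  for (dc in c(1L, -1L)) {
    a <- L[1:(nr - 1L), if (dc == 1L) 1:(nc - 1L) else 2:nc]
    b <- L[2:nr, if (dc == 1L) 2:nc else 1:(nc - 1L)]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, unique(cbind(a[sel], b[sel])))
  }
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- findRoot(pairs[k, 1L]); rb <- findRoot(pairs[k, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), findRoot, integer(1))
  ids <- match(roots, sort(unique(roots)))
  pos <- L > 0L
  L[pos] <- ids[L[pos]]
  L
}

## Threshold -> closing -> hole fill -> 8-connected components -> area
## filter. Shared by plaque and ThS segmentation.
componentsFromRaster <- function(raster, threshold, closingRadiusPx,
                                 minAreaUm2, pixelSizeUm) {
  mask <- raster >= threshold
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(raster), ncol(raster)),
                rois = emptyRoiTable()))
  }
  m <- matrix(as.numeric(mask), nrow(raster), ncol(raster))
  if (closingRadiusPx > 0L) {
    brush <- EBImage::makeBrush(2L * closingRadiusPx + 1L, shape = "disc")
    m <- EBImage::closing(m, brush)
  }
  m <- EBImage::fillHull(m)
  L <- label8(m > 0.5)
  counts <- tabulate(L[L > 0L])
  keep <- which(counts * pixelSizeUm^2 >= minAreaUm2)
  if (!length(keep)) {
    return(list(labels = matrix(0L, nrow(raster), ncol(raster)),
                rois = emptyRoiTable()))
  }
  ids <- match(L, keep)                 # NA for dropped/background
  L2 <- matrix(0L, nrow(L), ncol(L))
  sel <- !is.na(ids) & L > 0L
  L2[sel] <- ids[sel]
  nr <- nrow(L2)
  rois <- do.call(rbind, lapply(seq_along(keep), function(i) {
    ii <- which(L2 == i)
    data.frame(id = i, n_px = length(ii),
               area_um2 = length(ii) * pixelSizeUm^2,
               centroid_row = mean((ii - 1L) %% nr),
               centroid_col = mean((ii - 1L) %/% nr))
  }))
  list(labels = L2, rois = rois)
}

emptyRoiTable <- function() {
  data.frame(id = integer(0), n_px = integer(0), area_um2 = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0))
}

#' Segment amyloid plaques from a DAB optical-density map
#'
#' Thresholds the DAB density raster at \code{dabOdThreshold}, applies a
#' morphological closing (merging dense cores with their coronas), fills
#' holes so pale plaque centres measure as part of the deposit, labels
#' 8-connected components and discards those below the minimum area. Each
#' surviving component is one plaque ROI.
#'
#' @param dab DAB optical-density matrix (from
#'   \code{\link{separateStains}}) or a \linkS4class{StainMaps}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param pixelSizeUm pixel calibration; taken from \code{dab} when it is a
#'   \code{StainMaps}.
#' @return A list with \code{labels} (integer matrix, one id per plaque;
#'   0 = background) and \code{rois} (data.frame: id, n_px, area_um2,
#'   centroid_row, centroid_col; centroids 0-based).
#' @export
segmentPlaques <- function(dab, params = SegmentationParams(),
                           pixelSizeUm = NULL) {
  if (methods::is(dab, "StainMaps")) {
    if (is.null(pixelSizeUm)) pixelSizeUm <- dab@pixelSize
    dab <- stainMap(dab, "dab")
  }
  stopifnot(is.matrix(dab), !is.null(pixelSizeUm))
  componentsFromRaster(dab, params@dabOdThreshold, params@closingRadiusPx,
                       params@minPlaqueAreaUm2, pixelSizeUm)
}

#' Segment blood vessels from a Fast Red optical-density map
#'
#' Thresholds the Fast Red density raster at \code{redOdThreshold}; no
#' minimum size is applied by default (capillary profiles can be tiny).
#'
#' @param fastred Fast Red optical-density matrix or a
#'   \linkS4class{StainMaps}.
#' @param params a \linkS4class{SegmentationParams}.
#' @return Integer matrix, 1 on vessels and 0 elsewhere.
#' @export
segmentVessels <- function(fastred, params = SegmentationParams()) {
  if (methods::is(fastred, "StainMaps")) fastred <- stainMap(fastred, "fastred")
  stopifnot(is.matrix(fastred))
  m <- matrix(0L, nrow(fastred), ncol(fastred))
  m[fastred >= params@redOdThreshold] <- 1L
  m
}

#' Segment thioflavin-S positive deposits
#'
#' Thresholds a ThS fluorescence intensity raster at
#' \code{thsIntensityThreshold} and applies the same closing / hole-fill /
#' 8-connected component / minimum-area logic as plaque segmentation.
#'
#' @param intensity ThS intensity matrix (0-255 scale) or a single-channel
#'   \linkS4class{ImagePlane}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param pixelSizeUm pixel calibration; taken from the image when an
#'   \code{ImagePlane} is given.
#' @return A list with \code{mask} (binary matrix), \code{labels} and
#'   \code{rois} as in \code{\link{segmentPlaques}}.
#' @export
segmentThS <- function(intensity, params = SegmentationParams(),
                       pixelSizeUm = NULL) {
  if (methods::is(intensity, "ImagePlane")) {
    if (is.null(pixelSizeUm)) pixelSizeUm <- pixelSize(intensity)
    intensity <- planeData(intensity)
  }
  stopifnot(is.matrix(intensity), !is.null(pixelSizeUm))
  res <- componentsFromRaster(intensity, params@thsIntensityThreshold,
                              params@closingRadiusPx,
                              params@minPlaqueAreaUm2, pixelSizeUm)
  list(mask = (res$labels > 0L) * 1L, labels = res$labels, rois = res$rois)
}
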