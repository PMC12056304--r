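#' Supra-threshold channel area
#'
#' Expression area of one fluorescence channel: the number of pixels at or
#' above the threshold times the pixel area.
#'
#' @param channel intensity matrix.
#' @param threshold intensity cutoff (>= 0).
#' @param pixelSizeUm micrometres per pixel.
#' @return Area in um^2.
#' @export
channelArea <- function(channel, threshold, pixelSizeUm) {
  stopifnot(threshold >= 0)
  sum(channel >= threshold) * pixelSizeUm^2
}

#' Abeta40/Abeta42 area ratio
#'
#' @param area40,area42 channel areas in consistent units; \code{area42}
#'   must be positive.
#' @return 100 x area40 / area42 (percent).
#' @export
areaRatio4042 <- function(area40, area42) {
  if (any(area42 <= 0))
    stop("Abeta40/Abeta42 ratio is undefined for zero Abeta42 area")
  100 * area40 / area42
}

#' Otsu threshold of an intensity raster
#'
#' Thin wrapper around \code{EBImage::otsu} on the 0-255 intensity scale.
#'
#' @param channel intensity matrix (0-255 scale).
#' @return Threshold on the same scale.
#' @export
otsuThreshold <- function(channel) {
  EBImage::otsu(EBImage::Image(channel / 255), range = c(0, 1),
                levels = 256L) * 255
}

#' Two-colour overlap coefficient
#'
#' Manders-style overlap of two fluorescence channels:
#' \deqn{R = \frac{\sum_i A_i B_i}{\sqrt{\sum_i A_i^2 \sum_i B_i^2}}}
#' computed over pixels supra-threshold in either channel, with
#' sub-threshold values zeroed. Bounded in [0, 1]: 1 for identical
#' channels (Cauchy-Schwarz equality), 0 for disjoint supports. The
#' set-overlap alternative \code{method = "jaccard"}
#' (\eqn{|A \cap B| / |A \cup B|} of the supra-threshold supports) is
#' available for comparison.
#'
#' @param chA,chB intensity matrices of the same shape.
#' @param thresholds length-2 numeric (thresholds for A and B); \code{NULL}
#'   uses Otsu per channel.
#' @param method \code{"manders"} (default) or \code{"jaccard"}.
#' @return The overlap coefficient.
#' @examples
#' overlapCoefficient(matrix(c(1, 0), 1), matrix(c(1, 1), 1),
#'                    thresholds = c(0.5, 0.5))  # 1/sqrt(2)
#' @export
overlapCoefficient <- function(chA, chB, thresholds = NULL,
                               method = c("manders", "jaccard")) {
  method <- match.arg(method)
  stopifnot(identical(dim(chA), dim(chB)))
  if (is.null(thresholds))
    thresholds <- c(otsuThreshold(chA), otsuThreshold(chB))
  A <- ifelse(chA >= thresholds[1L], chA, 0)
  B <- ifelse(chB >= thresholds[2L], chB, 0)
  if (!any(A > 0) || !any(B > 0))
    stop("overlap coefficient undefined: a channel has no supra-threshold pixels")
  if (method == "manders") {
    sum(A * B) / sqrt(sum(A^2) * sum(B^2))
  } else {
    a <- A > 0; b <- B > 0
    sum(a & b) / sum(a | b)
  }
}

#' ThS to immunohistochemistry area ratio
#'
#' Relative percentage of ThS-positive (fibrillar) staining compared to
#' total immunodetected amyloid, computed at the region-per-animal level
#' from consecutive sections.
#'
#' @param thsAreaPerMm2 ThS-positive area density (um^2/mm^2).
#' @param ihcAreaPerMm2 immunostained area density (um^2/mm^2), > 0.
#' @return 100 x ths / ihc (percent).
#' @export
thsToIhcRatio <- function(thsAreaPerMm2, ihcAreaPerMm2) {
  if (any(ihcAreaPerMm2 <= 0))
    stop("ThS/IHC ratio is undefined for zero immunostained area")
  100 * thsAreaPerMm2 / ihcAreaPerMm2
}
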