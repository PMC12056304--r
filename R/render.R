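#' Render a synthetic brightfield image
#'
#' Converts a scene's per-stain density maps into a transmitted-light RGB
#' image by Beer-Lambert optical-density mixing: for each channel,
#' \eqn{I = W \cdot 10^{-\sum_s d_s v_s}} where \eqn{W} is the white level,
#' \eqn{d_s} the stain density and \eqn{v_s} the stain's unit OD vector.
#' Gaussian noise of standard deviation \code{noiseSD} (8-bit units) is then
#' added and intensities are clipped to \code{[0, whiteLevel]}.
#'
#' The returned image carries real-valued intensities on the 0-255 scale;
#' quantization to 8-bit integers happens when the image is written to disk
#' (\code{\link{writeImagePlane}}), so that in-memory analysis is not limited
#' by file bit depth.
#'
#' @param scene a \linkS4class{Scene}.
#' @param profile a \linkS4class{StainProfile} (default
#'   \code{StainProfile()}).
#' @param noiseSD Gaussian noise sd; defaults to the scene spec's value.
#' @param seed RNG seed for the noise; derived from the scene seed by
#'   default so renders are reproducible.
#' @return A 3-channel brightfield \linkS4class{ImagePlane}.
#' @seealso \code{\link{separateStains}} for the inverse operation.
#' @export
renderBrightfield <- function(scene, profile = StainProfile(),
                              noiseSD = scene@spec@noiseSD,
                              seed = childSeed(scene@spec@seed, 1L)) {
  stopifnot(methods::is(scene, "Scene"), methods::is(profile, "StainProfile"))
  v <- stainMatrix(profile)
  W <- whiteLevel(profile)
  d <- scene@densities
  nr <- nrow(d$dab); nc <- ncol(d$dab)
  img <- array(0, dim = c(nr, nc, 3L))
  for (ch in 1:3) {
    od <- d$hematoxylin * v[ch, "hematoxylin"] + d$dab * v[ch, "dab"] +
      d$fastred * v[ch, "fastred"]
    img[, , ch] <- W * 10^(-od)
  }
  if (noiseSD > 0) {
    img <- withSeed(seed, img + array(rnorm(length(img), 0, noiseSD),
                                      dim = dim(img)))
  }
  img <- clip01(img, 0, W)
  ImagePlane(img, pixelSizeUm = pixelSize(scene), modality = "brightfield")
}

#' Render a synthetic two-channel fluorescence image
#'
#' Returns the Abeta40/Abeta42 channel pair of a scene. The Abeta42 channel
#' covers every plaque; the Abeta40 channel was constructed by the scene
#' generator so that the pixelwise overlap coefficient of the noiseless pair
#' equals the spec's \code{ab40Ab42Overlap} and the area ratio equals
#' \code{ab40Ab42AreaRatio}. Additive Gaussian noise is applied per channel.
#'
#' @inheritParams renderBrightfield
#' @return A 2-channel fluorescence \linkS4class{ImagePlane} with channels
#'   \code{ab40}, \code{ab42}.
#' @export
renderFluorescence <- function(scene, noiseSD = scene@spec@noiseSD,
                               seed = childSeed(scene@spec@seed, 2L)) {
  stopifnot(methods::is(scene, "Scene"))
  img <- array(0, dim = c(dim(scene@fluor$ab40), 2L))
  img[, , 1L] <- scene@fluor$ab40
  img[, , 2L] <- scene@fluor$ab42
  if (noiseSD > 0) {
    img <- withSeed(seed, img + array(rnorm(length(img), 0, noiseSD),
                                      dim = dim(img)))
  }
  img <- clip01(img, 0, 255)
  ImagePlane(img, pixelSizeUm = pixelSize(scene), modality = "fluorescence",
             channelNames = c("ab40", "ab42"))
}

#' Render a synthetic thioflavin-S image
#'
#' Single-channel fluorescence image in which the fibrillar cores planted by
#' the generator are bright against a dim background.
#'
#' @inheritParams renderBrightfield
#' @return A single-channel fluorescence \linkS4class{ImagePlane}.
#' @export
renderThS <- function(scene, noiseSD = scene@spec@noiseSD,
                      seed = childSeed(scene@spec@seed, 3L)) {
  stopifnot(methods::is(scene, "Scene"))
  img <- scene@ths
  if (noiseSD > 0) {
    img <- withSeed(seed, img + matrix(rnorm(length(img), 0, noiseSD),
                                       nrow = nrow(img)))
  }
  img <- clip01(img, 0, 255)
  ImagePlane(img, pixelSizeUm = pixelSize(scene), modality = "fluorescence",
             channelNames = "ths")
}
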