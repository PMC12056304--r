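#' @include AllGenerics.R
NULL

#' Pixel calibration of an image-like object
#'
#' @param object an object carrying a spatial calibration.
#' @return Pixel edge length in micrometres per pixel.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' Imaging modality of an object
#'
#' @param object an object carrying a modality tag.
#' @return One of \code{"brightfield"}, \code{"fluorescence"}, \code{"mask"}.
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' Channel names of a multi-channel image
#'
#' @param object an object with named channels.
#' @return Character vector of channel names.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Raw pixel data of an image-like object
#'
#' @param object an object wrapping a pixel array.
#' @return A numeric matrix (single channel) or 3-d array (rows x cols x
#'   channels).
#' @export
setGeneric("planeData", function(object) standardGeneric("planeData"))

#' Ground-truth tables of a synthetic scene
#'
#' @param object a \linkS4class{Scene}.
#' @return A list with elements \code{plaques} (per-plaque truth table),
#'   \code{vessels}, and scene-level truth values.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
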