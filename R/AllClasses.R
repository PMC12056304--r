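#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## ImagePlane
## ---------------------------------------------------------------------------

#' Calibrated raster image
#'
#' An \code{ImagePlane} bundles a pixel array with its spatial calibration
#' (micrometres per pixel) and a modality tag. Single-channel data are stored
#' as a matrix, multi-channel data as a rows x cols x channels array.
#' Coordinates are row/column with origin at the top-left; all areas and
#' distances derived from an \code{ImagePlane} are reported in micrometre
#' units using \code{pixelSize}.
#'
#' @slot data numeric matrix or 3-d array of pixel values.
#' @slot pixelSize positive numeric, micrometres per pixel edge.
#' @slot modality one of \code{"brightfield"}, \code{"fluorescence"},
#'   \code{"mask"}.
#' @slot channelNames character vector, one name per channel.
#'
#' @seealso \code{\link{readImagePlane}}, \code{\link{renderBrightfield}}
#' @export
setClass("ImagePlane",
  representation(
    data = "array",
    pixelSize = "numeric",
    modality = "character",
    channelNames = "character"
  )
)

setValidity("ImagePlane", function(object) {
  msg <- character()
  d <- object@data
  if (!(length(dim(d)) %in% c(2L, 3L)))
    msg <- c(msg, "pixel data must be a matrix or rows x cols x channels array")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (um/px)")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("brightfield", "fluorescence", "mask"))
    msg <- c(msg, "modality must be 'brightfield', 'fluorescence' or 'mask'")
  nch <- if (length(dim(d)) == 3L) dim(d)[3L] else 1L
  if (length(object@channelNames) != nch)
    msg <- c(msg, sprintf("channelNames has length %d but image has %d channel(s)",
                          length(object@channelNames), nch))
  if (length(object@modality) == 1L && object@modality == "mask" &&
      length(d) > 0L && any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
    msg <- c(msg, "mask modality requires binary or integer-labelled pixels")
  if (length(msg)) msg else TRUE
})

#' Construct an ImagePlane
#'
#' @param data matrix or 3-d array of pixel values.
#' @param pixelSizeUm positive numeric, micrometres per pixel.
#' @param modality \code{"brightfield"}, \code{"fluorescence"} or
#'   \code{"mask"}.
#' @param channelNames optional character vector of channel names; defaults to
#'   R/G/B for 3-channel data and \code{"ch1"}, \code{"ch2"}, ... otherwise.
#' @return An \linkS4class{ImagePlane}.
#' @examples
#' img <- ImagePlane(matrix(0, 8, 8), pixelSizeUm = 0.5, modality = "mask")
#' pixelSize(img)
#' @export
ImagePlane <- function(data, pixelSizeUm, modality, channelNames = NULL) {
  if (is.matrix(data)) data <- array(data, dim = dim(data))
  nch <- if (length(dim(data)) == 3L) dim(data)[3L] else 1L
  if (is.null(channelNames)) {
    channelNames <- if (nch == 3L && modality == "brightfield")
      c("R", "G", "B") else paste0("ch", seq_len(nch))
  }
  methods::new("ImagePlane", data = data, pixelSize = as.numeric(pixelSizeUm),
               modality = modality, channelNames = as.character(channelNames))
}

#' @describeIn ImagePlane pixel calibration in um/px.
#' @param object an \code{ImagePlane}.
#' @export
setMethod("pixelSize", "ImagePlane", function(object) object@pixelSize)

#' @describeIn ImagePlane modality tag.
#' @export
setMethod("modality", "ImagePlane", function(object) object@modality)

#' @describeIn ImagePlane channel names.
#' @export
setMethod("channelNames", "ImagePlane", function(object) object@channelNames)

#' @describeIn ImagePlane pixel array (matrix if single channel).
#' @export
setMethod("planeData", "ImagePlane", function(object) {
  d <- object@data
  if (length(dim(d)) == 3L && dim(d)[3L] == 1L) d <- d[, , 1L]
  if (length(dim(d)) == 2L) d <- matrix(d, nrow = dim(d)[1L])
  d
})

setMethod("show", "ImagePlane", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImagePlane: %d x %d px, %d channel(s) [%s], %s, %.4g um/px\n",
              d[1L], d[2L], if (length(d) == 3L) d[3L] else 1L,
              paste(object@channelNames, collapse = ","),
              object@modality, object@pixelSize))
})

## ---------------------------------------------------------------------------
## StainProfile
## ---------------------------------------------------------------------------

#' Chromogen optical-density profile
#'
#' Unit optical-density colour vectors for the three chromogens of a
#' hematoxylin / DAB / Fast Red double immunostain, plus the background white
#' level of the scanner. The vectors are the columns of the stain matrix used
#' both to render synthetic brightfield images (Beer-Lambert mixing) and to
#' unmix real ones (\code{\link{separateStains}}).
#'
#' @slot vectors 3 x 3 numeric matrix; rows R,G,B; columns hematoxylin, dab,
#'   fastred; each column non-negative with unit Euclidean norm.
#' @slot whiteLevel positive numeric, transmitted intensity of unstained
#'   background (255 for 8-bit scans).
#' @export
setClass("StainProfile",
  representation(vectors = "matrix", whiteLevel = "numeric"))

setValidity("StainProfile", function(object) {
  msg <- character()
  v <- object@vectors
  if (!identical(dim(v), c(3L, 3L)))
    msg <- c(msg, "stain matrix must be 3 x 3 (RGB rows, 3 stain columns)")
  else {
    if (any(v < 0)) msg <- c(msg, "stain vectors must be non-negative")
    norms <- sqrt(colSums(v^2))
    if (any(abs(norms - 1) > 1e-6))
      msg <- c(msg, "each stain vector must have unit Euclidean norm")
    if (abs(det(v)) < 1e-8)
      msg <- c(msg, "stain vectors must be linearly independent")
  }
  if (length(object@whiteLevel) != 1L || object@whiteLevel <= 0)
    msg <- c(msg, "whiteLevel must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a StainProfile
#'
#' Defaults are the standard published hematoxylin and DAB unit
#' optical-density vectors plus a Fast Red vector estimated from the
#' chromogen's nominal colour; all overridable.
#'
#' @param hematoxylin,dab,fastred numeric length-3 RGB optical-density
#'   vectors (normalised internally to unit length).
#' @param whiteLevel background transmitted intensity (default 255).
#' @return A \linkS4class{StainProfile}.
#' @examples
#' p <- StainProfile()
#' stainMatrix(p)
#' @export
StainProfile <- function(hematoxylin = c(0.651, 0.701, 0.290),
                         dab = c(0.269, 0.568, 0.778),
                         fastred = c(0.2139, 0.8511, 0.4779),
                         whiteLevel = 255) {
  v <- cbind(hematoxylin = hematoxylin, dab = dab, fastred = fastred)
  v <- sweep(v, 2L, sqrt(colSums(v^2)), "/")
  rownames(v) <- c("R", "G", "B")
  methods::new("StainProfile", vectors = v, whiteLevel = as.numeric(whiteLevel))
}

#' Stain matrix of a StainProfile
#'
#' @param profile a \linkS4class{StainProfile}.
#' @return The 3 x 3 unit-OD stain matrix (RGB rows, stain columns).
#' @export
stainMatrix <- function(profile) {
  stopifnot(methods::is(profile, "StainProfile"))
  profile@vectors
}

#' White level of a StainProfile
#'
#' @param profile a \linkS4class{StainProfile}.
#' @return Background transmitted intensity.
#' @export
whiteLevel <- function(profile) {
  stopifnot(methods::is(profile, "StainProfile"))
  profile@whiteLevel
}

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (unit OD vectors, RGB rows):\n")
  print(round(object@vectors, 4))
  cat(sprintf("white level: %g\n", object@whiteLevel))
})

## ---------------------------------------------------------------------------
## SceneSpec
## ---------------------------------------------------------------------------

#' Synthetic scene specification
#'
#' Parameters of one synthetic histology field: how many plaques of which
#' morphological archetype (diffuse blob, dense deposit, dense-core with
#' corona), their diameter range, the vasculature, the fibrillar (ThS) core
#' fraction, the constructed Abeta40/Abeta42 area ratio and overlap level,
#' the noise level, and the RNG seed. An optional planted contact fraction
#' seeds that proportion of plaques directly on a vessel.
#'
#' @slot fieldSize integer length-2, field size in pixels (rows, cols).
#' @slot pixelSizeUm positive numeric, um/px.
#' @slot nPlaques non-negative integer.
#' @slot typeMix named numeric proportions over diffuse/dense/dense_core,
#'   summing to 1.
#' @slot diameterRangeUm positive length-2 numeric, min/max plaque diameter.
#' @slot vesselCount non-negative integer.
#' @slot vesselRadiusUm positive numeric.
#' @slot fibrillarCoreFraction numeric in [0,1]: fraction of dense and
#'   dense-core plaques carrying a ThS-positive fibrillar core.
#' @slot ab40Ab42Overlap numeric in [0,1], constructed two-channel overlap
#'   coefficient of the noiseless fluorescence render.
#' @slot ab40Ab42AreaRatio positive numeric, constructed Abeta40/Abeta42 area
#'   ratio (1 = equal areas).
#' @slot contactFraction numeric in [0,1], fraction of plaques deliberately
#'   placed in vessel contact (0 = natural placement only).
#' @slot noiseSD non-negative numeric, Gaussian noise sd on the 0-255
#'   intensity scale.
#' @slot regionLayout \code{"single"} (whole field = cortex) or
#'   \code{"quadrants"} (cortex / hippocampus / striatum / thalamus).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(
    fieldSize = "integer", pixelSizeUm = "numeric", nPlaques = "integer",
    typeMix = "numeric", diameterRangeUm = "numeric",
    vesselCount = "integer", vesselRadiusUm = "numeric",
    fibrillarCoreFraction = "numeric", ab40Ab42Overlap = "numeric",
    ab40Ab42AreaRatio = "numeric", contactFraction = "numeric",
    noiseSD = "numeric", regionLayout = "character", seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@fieldSize) != 2L || any(object@fieldSize < 8L))
    msg <- c(msg, "fieldSize must be two integers >= 8")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@nPlaques < 0L) msg <- c(msg, "nPlaques must be >= 0")
  mix <- object@typeMix
  if (!identical(sort(names(mix)), sort(c("diffuse", "dense", "dense_core"))))
    msg <- c(msg, "typeMix must be named over diffuse/dense/dense_core")
  else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    msg <- c(msg, "typeMix proportions must be >= 0 and sum to 1")
  dr <- object@diameterRangeUm
  if (length(dr) != 2L || any(dr <= 0) || dr[1L] > dr[2L])
    msg <- c(msg, "diameterRangeUm must be a non-empty positive interval")
  else {
    ## the field must hold the largest plaque with a placement margin
    maxpx <- dr[2L] / object@pixelSizeUm
    if (maxpx + 4 > min(object@fieldSize))
      msg <- c(msg, sprintf(
        "field too small: max diameter %.1f um needs > %.0f px but field is %d x %d",
        dr[2L], maxpx + 4, object@fieldSize[1L], object@fieldSize[2L]))
  }
  if (object@vesselCount < 0L) msg <- c(msg, "vesselCount must be >= 0")
  if (object@vesselRadiusUm <= 0) msg <- c(msg, "vesselRadiusUm must be > 0")
  for (nm in c("fibrillarCoreFraction", "ab40Ab42Overlap", "contactFraction")) {
    x <- methods::slot(object, nm)
    if (length(x) != 1L || x < 0 || x > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  r <- object@ab40Ab42AreaRatio
  if (r <= 0) msg <- c(msg, "ab40Ab42AreaRatio must be > 0")
  else {
    rhomax <- min(sqrt(r), 1 / sqrt(r))
    if (object@ab40Ab42Overlap > rhomax + 1e-9)
      msg <- c(msg, sprintf(
        "ab40Ab42Overlap %.3f unattainable at area ratio %.3f (max %.3f)",
        object@ab40Ab42Overlap, r, rhomax))
  }
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (!object@regionLayout %in% c("single", "quadrants"))
    msg <- c(msg, "regionLayout must be 'single' or 'quadrants'")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' Defaults emulate a cortical field of an amyloid-depositing transgenic
#' mouse: plaque diameters spanning 10-40 um around the reported cortical
#' means, a mixed population of diffuse, dense and dense-core morphologies,
#' sparse vasculature, half of compact plaques carrying a fibrillar core, and
#' a constructed two-channel overlap in the experimentally observed range.
#'
#' @param fieldSizePx integer length-2, pixels (default \code{c(512, 512)}).
#' @param pixelSizeUm um/px (default 1).
#' @param nPlaques number of plaques (default 25).
#' @param typeMix named proportions over diffuse/dense/dense_core.
#' @param diameterRangeUm plaque max-diameter range in um.
#' @param vesselCount number of vessels (default 5).
#' @param vesselRadiusUm vessel tube radius (default 4).
#' @param fibrillarCoreFraction fraction of dense/dense-core plaques with a
#'   ThS-positive core (default 0.5).
#' @param ab40Ab42Overlap constructed overlap coefficient (default 0.6).
#' @param ab40Ab42AreaRatio constructed Abeta40/Abeta42 area ratio
#'   (default 0.5, i.e. 50 percent).
#' @param contactFraction fraction of plaques planted on vessels (default 0).
#' @param noiseSD Gaussian noise sd in 8-bit units (default 2).
#' @param regionLayout \code{"single"} or \code{"quadrants"}.
#' @param seed RNG seed (default 1).
#' @return A validated \linkS4class{SceneSpec}.
#' @examples
#' spec <- SceneSpec(nPlaques = 5, seed = 42)
#' spec
#' @export
SceneSpec <- function(fieldSizePx = c(512L, 512L), pixelSizeUm = 1,
                      nPlaques = 25,
                      typeMix = c(diffuse = 0.40, dense = 0.35,
                                  dense_core = 0.25),
                      diameterRangeUm = c(10, 40),
                      vesselCount = 5, vesselRadiusUm = 4,
                      fibrillarCoreFraction = 0.5,
                      ab40Ab42Overlap = 0.6, ab40Ab42AreaRatio = 0.5,
                      contactFraction = 0, noiseSD = 2,
                      regionLayout = "single", seed = 1) {
  methods::new("SceneSpec",
    fieldSize = as.integer(fieldSizePx), pixelSizeUm = as.numeric(pixelSizeUm),
    nPlaques = as.integer(nPlaques), typeMix = typeMix,
    diameterRangeUm = as.numeric(diameterRangeUm),
    vesselCount = as.integer(vesselCount),
    vesselRadiusUm = as.numeric(vesselRadiusUm),
    fibrillarCoreFraction = as.numeric(fibrillarCoreFraction),
    ab40Ab42Overlap = as.numeric(ab40Ab42Overlap),
    ab40Ab42AreaRatio = as.numeric(ab40Ab42AreaRatio),
    contactFraction = as.numeric(contactFraction),
    noiseSD = as.numeric(noiseSD), regionLayout = regionLayout,
    seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(paste0(
    "SceneSpec: %d x %d px @ %.3g um/px, %d plaques (%.0f/%.0f/%.0f%% ",
    "diffuse/dense/dense_core), diameters %.3g-%.3g um,\n",
    "  %d vessels r=%.3g um, fibrillar core fraction %.2f, overlap %.2f, ",
    "area ratio %.2f, noise sd %.3g, seed %d\n"),
    object@fieldSize[1L], object@fieldSize[2L], object@pixelSizeUm,
    object@nPlaques, 100 * object@typeMix[["diffuse"]],
    100 * object@typeMix[["dense"]], 100 * object@typeMix[["dense_core"]],
    object@diameterRangeUm[1L], object@diameterRangeUm[2L],
    object@vesselCount, object@vesselRadiusUm, object@fibrillarCoreFraction,
    object@ab40Ab42Overlap, object@ab40Ab42AreaRatio, object@noiseSD,
    object@seed))
})

## ---------------------------------------------------------------------------
## RegionLabelMap
## ---------------------------------------------------------------------------

#' Anatomical region label map
#'
#' Integer label raster (0 = background) naming the anatomical regions of a
#' field, e.g. cortex / hippocampus / striatum / thalamus on sagittal
#' sections, with its pixel calibration so per-region areas can be reported
#' per square millimetre of region rather than of field.
#'
#' @slot labels integer matrix of region labels (0 = background).
#' @slot regionNames character vector named by label (as character).
#' @slot pixelSize positive numeric, um/px.
#' @export
setClass("RegionLabelMap",
  representation(labels = "matrix", regionNames = "character",
                 pixelSize = "numeric"))

setValidity("RegionLabelMap", function(object) {
  msg <- character()
  if (any(object@labels < 0L)) msg <- c(msg, "labels must be >= 0")
  used <- setdiff(sort(unique(as.integer(object@labels))), 0L)
  if (!all(as.character(used) %in% names(object@regionNames)))
    msg <- c(msg, "every nonzero label must be named in regionNames")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a RegionLabelMap
#'
#' @param labels integer matrix, 0 = background.
#' @param regionNames character vector named by label value, e.g.
#'   \code{c("1" = "cortex")}.
#' @param pixelSizeUm um/px.
#' @return A \linkS4class{RegionLabelMap}.
#' @export
RegionLabelMap <- function(labels, regionNames, pixelSizeUm) {
  storage.mode(labels) <- "integer"
  methods::new("RegionLabelMap", labels = labels,
               regionNames = regionNames, pixelSize = as.numeric(pixelSizeUm))
}

#' @describeIn RegionLabelMap pixel calibration in um/px.
#' @param object a \code{RegionLabelMap}.
#' @export
setMethod("pixelSize", "RegionLabelMap", function(object) object@pixelSize)

#' Region areas of a RegionLabelMap
#'
#' @param map a \linkS4class{RegionLabelMap}.
#' @return data.frame with columns \code{label}, \code{region},
#'   \code{area_um2}, \code{area_mm2}.
#' @export
regionAreas <- function(map) {
  stopifnot(methods::is(map, "RegionLabelMap"))
  labs <- as.integer(names(map@regionNames))
  px2 <- map@pixelSize^2
  counts <- vapply(labs, function(l) sum(map@labels == l), numeric(1))
  data.frame(label = labs, region = unname(map@regionNames),
             area_um2 = counts * px2, area_mm2 = counts * px2 / 1e6,
             stringsAsFactors = FALSE)
}

setMethod("show", "RegionLabelMap", function(object) {
  cat(sprintf("RegionLabelMap: %d x %d px, regions: %s\n",
              nrow(object@labels), ncol(object@labels),
              paste(object@regionNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## SegmentationParams
## ---------------------------------------------------------------------------

#' Segmentation parameters
#'
#' The fixed threshold pattern applied to every image of a study: optical
#' density cutoffs for the DAB (amyloid) and Fast Red (endothelium) stain
#' maps, an intensity cutoff for ThS fluorescence, the minimum plaque area,
#' and the radius of the morphological closing that merges a dense core with
#' its corona before connected-component analysis.
#'
#' @slot dabOdThreshold positive numeric, OD units (default 0.15).
#' @slot redOdThreshold positive numeric, OD units (default 0.20).
#' @slot thsIntensityThreshold numeric on the 0-255 scale (default 100).
#' @slot minPlaqueAreaUm2 positive numeric (default 20).
#' @slot closingRadiusPx non-negative integer (default 1).
#' @export
setClass("SegmentationParams",
  representation(dabOdThreshold = "numeric", redOdThreshold = "numeric",
                 thsIntensityThreshold = "numeric",
                 minPlaqueAreaUm2 = "numeric", closingRadiusPx = "integer"))

setValidity("SegmentationParams", function(object) {
  msg <- character()
  if (object@dabOdThreshold <= 0) msg <- c(msg, "dabOdThreshold must be > 0")
  if (object@redOdThreshold <= 0) msg <- c(msg, "redOdThreshold must be > 0")
  if (object@minPlaqueAreaUm2 <= 0)
    msg <- c(msg, "minPlaqueAreaUm2 must be > 0")
  if (object@closingRadiusPx < 0L)
    msg <- c(msg, "closingRadiusPx must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct SegmentationParams
#'
#' @param dabOdThreshold DAB optical-density cutoff (default 0.15).
#' @param redOdThreshold Fast Red optical-density cutoff (default 0.20).
#' @param thsIntensityThreshold ThS intensity cutoff, 0-255 (default 100).
#' @param minPlaqueAreaUm2 minimum plaque area in um^2 (default 20).
#' @param closingRadiusPx morphological closing radius in px (default 1).
#' @return A validated \linkS4class{SegmentationParams}.
#' @export
SegmentationParams <- function(dabOdThreshold = 0.15, redOdThreshold = 0.20,
                               thsIntensityThreshold = 100,
                               minPlaqueAreaUm2 = 20, closingRadiusPx = 1L) {
  methods::new("SegmentationParams",
    dabOdThreshold = as.numeric(dabOdThreshold),
    redOdThreshold = as.numeric(redOdThreshold),
    thsIntensityThreshold = as.numeric(thsIntensityThreshold),
    minPlaqueAreaUm2 = as.numeric(minPlaqueAreaUm2),
    closingRadiusPx = as.integer(closingRadiusPx))
}

setMethod("show", "SegmentationParams", function(object) {
  cat(sprintf(paste0("SegmentationParams: DAB OD >= %.3g, Fast Red OD >= ",
                     "%.3g, ThS >= %g, min area %.3g um^2, closing r = %d px\n"),
              object@dabOdThreshold, object@redOdThreshold,
              object@thsIntensityThreshold, object@minPlaqueAreaUm2,
              object@closingRadiusPx))
})

## ---------------------------------------------------------------------------
## StainMaps
## ---------------------------------------------------------------------------

#' Per-stain optical-density maps
#'
#' Result of optical-density unmixing of a brightfield RGB image: one
#' non-negative density raster per chromogen.
#'
#' @slot hematoxylin,dab,fastred numeric matrices, same shape as the source
#'   image, finite and >= 0.
#' @slot pixelSize um/px carried over from the source image.
#' @export
setClass("StainMaps",
  representation(hematoxylin = "matrix", dab = "matrix", fastred = "matrix",
                 pixelSize = "numeric"))

setValidity("StainMaps", function(object) {
  msg <- character()
  d <- dim(object@hematoxylin)
  if (!identical(d, dim(object@dab)) || !identical(d, dim(object@fastred)))
    msg <- c(msg, "stain maps must share one shape")
  for (nm in c("hematoxylin", "dab", "fastred")) {
    x <- methods::slot(object, nm)
    if (any(!is.finite(x))) msg <- c(msg, sprintf("%s map has non-finite values", nm))
    else if (any(x < 0)) msg <- c(msg, sprintf("%s map has negative densities", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Extract one stain map
#'
#' @param maps a \linkS4class{StainMaps}.
#' @param stain \code{"hematoxylin"}, \code{"dab"} or \code{"fastred"}.
#' @return Numeric matrix of optical densities.
#' @export
stainMap <- function(maps, stain = c("dab", "hematoxylin", "fastred")) {
  stopifnot(methods::is(maps, "StainMaps"))
  methods::slot(maps, match.arg(stain))
}

setMethod("show", "StainMaps", function(object) {
  cat(sprintf("StainMaps: %d x %d px; max OD h=%.3f dab=%.3f fastred=%.3f\n",
              nrow(object@dab), ncol(object@dab),
              max(object@hematoxylin), max(object@dab), max(object@fastred)))
})

## ---------------------------------------------------------------------------
## Scene
## ---------------------------------------------------------------------------

#' Synthetic histology scene
#'
#' A ground-truthed synthetic field: per-stain density maps (DAB on plaques,
#' Fast Red on vessels, hematoxylin counterstain), noiseless fluorescence
#' channels (Abeta40/Abeta42), a ThS intensity layer, the per-plaque label
#' image, the vessel mask, a region label map, and the ground-truth tables
#' against which every downstream measurement can be verified.
#'
#' @slot spec the generating \linkS4class{SceneSpec}.
#' @slot densities list of matrices \code{hematoxylin}, \code{dab},
#'   \code{fastred} (optical densities).
#' @slot fluor list of matrices \code{ab40}, \code{ab42} (0-255 intensities,
#'   noiseless).
#' @slot ths matrix, ThS intensity layer (0-255, noiseless).
#' @slot plaqueLabels integer matrix, plaque id per pixel (0 = none).
#' @slot vesselMask integer matrix, 1 on vessels.
#' @slot regionMap \linkS4class{RegionLabelMap}.
#' @slot truth list: \code{plaques} data.frame (id, type, centroid,
#'   area_um2, max_diameter_um, has_fibrillar_core, nearest_vessel_um,
#'   contact, region), \code{vessels} data.frame, \code{overlap},
#'   \code{area_ratio_40_42}.
#' @seealso \code{\link{generateScene}}
#' @export
setClass("Scene",
  representation(spec = "SceneSpec", densities = "list", fluor = "list",
                 ths = "matrix", plaqueLabels = "matrix",
                 vesselMask = "matrix", regionMap = "RegionLabelMap",
                 truth = "list"))

#' @describeIn Scene ground-truth list (plaque table, vessel table,
#'   scene-level overlap and area ratio).
#' @param object a \code{Scene}.
#' @export
setMethod("groundTruth", "Scene", function(object) object@truth)

#' @describeIn Scene pixel calibration in um/px.
#' @export
setMethod("pixelSize", "Scene", function(object) object@spec@pixelSizeUm)

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d x %d px, %d plaques, %d vessel px, seed %d\n",
              object@spec@fieldSize[1L], object@spec@fieldSize[2L],
              nrow(object@truth$plaques), sum(object@vesselMask),
              object@spec@seed))
})
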