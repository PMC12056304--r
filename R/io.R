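#' Read a calibrated image
#'
#' Loads a TIFF or PNG image and attaches the pixel calibration and modality.
#' Integer bit depth is preserved: 16-bit TIFFs come back as 16-bit integer
#' values, never silently downcast.
#'
#' @param path path to a \code{.tif/.tiff} or \code{.png} file.
#' @param pixelSizeUm pixel calibration in micrometres per pixel. Scanner
#'   exports do not carry a reliable calibration, so this is a required
#'   input.
#' @param modality \code{"brightfield"}, \code{"fluorescence"} or
#'   \code{"mask"}.
#' @param channelNames optional channel names.
#' @return An \linkS4class{ImagePlane}.
#' @export
readImagePlane <- function(path, pixelSizeUm, modality,
                           channelNames = NULL) {
  if (!file.exists(path))
    stop(sprintf("image file does not exist: '%s'", path))
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = {
      x <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
      if (is.list(x)) x <- x[[1L]]
      ## multi-channel reads come back rescaled to [0,1] regardless of
      ## as.is; restore the 8-bit integer scale
      if (is.double(x) && length(x) && max(x) <= 1) x <- round(x * 255)
      x
    },
    png = {
      x <- png::readPNG(path)
      ## png values are scaled to [0,1]; restore the 8-bit integer scale
      round(x * 255)
    },
    stop(sprintf("unsupported image format '.%s' for '%s'", ext, path)))
  if (is.list(a)) a <- a[[1L]]
  storage.mode(a) <- "double"
  ImagePlane(a, pixelSizeUm = pixelSizeUm, modality = modality,
             channelNames = channelNames)
}

#' Write a calibrated image
#'
#' Writes an \linkS4class{ImagePlane} to TIFF (or PNG). Real-valued
#' brightfield/fluorescence intensities on the 0-255 scale are quantized to
#' 8-bit at this point; mask images are written losslessly as 16-bit so
#' integer labels survive a round trip.
#'
#' @param image an \linkS4class{ImagePlane}.
#' @param path output path ending in \code{.tif/.tiff} or \code{.png}.
#' @return Invisibly, \code{path}.
#' @export
writeImagePlane <- function(image, path) {
  stopifnot(methods::is(image, "ImagePlane"))
  d <- image@data
  ext <- tolower(tools::file_ext(path))
  if (modality(image) == "mask") {
    if (max(d) > 65535) stop("mask labels exceed 16-bit range")
    if (ext == "png") png::writePNG(d / 65535, path)
    else tiff::writeTIFF(d / 65535, path, bits.per.sample = 16L)
  } else {
    q <- clip01(round(d), 0, 255) / 255
    if (ext == "png") png::writePNG(q, path)
    else tiff::writeTIFF(q, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write a results table
#'
#' Writes a data.frame as UTF-8 CSV with a header row, '.' decimal
#' separator, stable column order, and 9 significant digits for doubles.
#' Missing optional fields become empty cells, never dropped rows.
#'
#' @param records a data.frame (possibly with zero rows).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMetricsTable <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt <- records
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]]))
      fmt[[j]] <- ifelse(is.na(fmt[[j]]), "",
                         formatC(fmt[[j]], digits = 9, format = "g"))
  }
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read a results table
#'
#' @param path a CSV written by \code{\link{writeMetricsTable}}.
#' @return A data.frame.
#' @export
readMetricsTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("table does not exist: '%s'", path))
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  na.strings = c("NA", ""))
}

#' Write all outputs of a synthetic scene
#'
#' Emits, under \code{dir}: a multi-page TIFF \code{scene.tif} with one page
#' per layer (DAB, Fast Red and hematoxylin densities scaled by 1/2 into
#' [0,1], Abeta40, Abeta42, ThS intensity layers), the rendered brightfield
#' image \code{brightfield.tif}, the label masks \code{plaque_labels.tif}
#' and \code{vessel_mask.tif}, region labels \code{region_labels.tif},
#' ground truth as \code{plaques.csv} and \code{vessels.csv}, and the scene
#' specification as \code{scene_spec.yaml}.
#'
#' @param scene a \linkS4class{Scene}.
#' @param dir output directory (created if missing).
#' @param profile \linkS4class{StainProfile} for the brightfield render.
#' @return Invisibly, the directory path.
#' @export
writeSceneOutputs <- function(scene, dir, profile = StainProfile()) {
  stopifnot(methods::is(scene, "Scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- list(
    dab = clip01(scene@densities$dab / 2, 0, 1),
    fastred = clip01(scene@densities$fastred / 2, 0, 1),
    hematoxylin = clip01(scene@densities$hematoxylin / 2, 0, 1),
    ab40 = scene@fluor$ab40 / 255,
    ab42 = scene@fluor$ab42 / 255,
    ths = scene@ths / 255)
  tiff::writeTIFF(unname(layers), file.path(dir, "scene.tif"),
                  bits.per.sample = 16L)
  writeImagePlane(renderBrightfield(scene, profile),
                  file.path(dir, "brightfield.tif"))
  writeImagePlane(ImagePlane(scene@plaqueLabels, pixelSize(scene), "mask"),
                  file.path(dir, "plaque_labels.tif"))
  writeImagePlane(ImagePlane(scene@vesselMask, pixelSize(scene), "mask"),
                  file.path(dir, "vessel_mask.tif"))
  writeImagePlane(ImagePlane(scene@regionMap@labels, pixelSize(scene),
                             "mask"),
                  file.path(dir, "region_labels.tif"))
  writeMetricsTable(scene@truth$plaques, file.path(dir, "plaques.csv"))
  writeMetricsTable(scene@truth$vessels, file.path(dir, "vessels.csv"))
  yaml::write_yaml(sceneSpecAsList(scene@spec),
                   file.path(dir, "scene_spec.yaml"))
  invisible(dir)
}

## SceneSpec <-> plain list (for YAML round trips)
sceneSpecAsList <- function(spec) {
  list(field_size_px = as.integer(spec@fieldSize),
       pixel_size_um = spec@pixelSizeUm,
       n_plaques = spec@nPlaques,
       type_mix = as.list(spec@typeMix),
       diameter_range_um = spec@diameterRangeUm,
       vessel_count = spec@vesselCount,
       vessel_radius_um = spec@vesselRadiusUm,
       fibrillar_core_fraction = spec@fibrillarCoreFraction,
       ab40_ab42_overlap = spec@ab40Ab42Overlap,
       ab40_ab42_area_ratio = spec@ab40Ab42AreaRatio,
       contact_fraction = spec@contactFraction,
       noise_sd = spec@noiseSD,
       region_layout = spec@regionLayout,
       seed = spec@seed)
}

sceneSpecFromList <- function(x) {
  SceneSpec(fieldSizePx = unlist(x$field_size_px),
            pixelSizeUm = x$pixel_size_um,
            nPlaques = x$n_plaques,
            typeMix = unlist(x$type_mix),
            diameterRangeUm = unlist(x$diameter_range_um),
            vesselCount = x$vessel_count,
            vesselRadiusUm = x$vessel_radius_um,
            fibrillarCoreFraction = x$fibrillar_core_fraction,
            ab40Ab42Overlap = x$ab40_ab42_overlap,
            ab40Ab42AreaRatio = x$ab40_ab42_area_ratio,
            contactFraction = x$contact_fraction,
            noiseSD = x$noise_sd,
            regionLayout = x$region_layout,
            seed = x$seed)
}
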