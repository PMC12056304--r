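## Allowed configuration keys and their defaults. The default cohort is a
## three-group in-silico study: untreated control, clearance facilitator
## (reduced burden, fewer vessel contacts) and clearance inhibitor
## (increased burden), with group-level burden multipliers, planted
## vessel-contact fractions, and channel overlap / area-ratio levels in the
## experimentally reported ranges.
runConfigDefaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    pixel_size_um = 2,
    field_size_px = c(192L, 192L),
    region_layout = "single",
    base_plaque_mean = 10,
    animal_sd = 0.25,
    type_mix = c(diffuse = 0.40, dense = 0.35, dense_core = 0.25),
    diameter_range_um = c(10, 40),
    vessel_count = 2L,
    vessel_radius_um = 4,
    fibrillar_core_fraction = 0.5,
    noise_sd = 2,
    groups = list(
      list(name = "control", n_animals = 3L, burden_multiplier = 1.0,
           contact_fraction = 0.28, ab40_ab42_overlap = 0.62,
           ab40_ab42_area_ratio = 0.476),
      list(name = "facilitator", n_animals = 3L, burden_multiplier = 0.4,
           contact_fraction = 0.18, ab40_ab42_overlap = 0.49,
           ab40_ab42_area_ratio = 0.269),
      list(name = "inhibitor", n_animals = 3L, burden_multiplier = 1.4,
           contact_fraction = 0.26, ab40_ab42_overlap = 0.42,
           ab40_ab42_area_ratio = 0.182)),
    segmentation = list(dab_od_threshold = 0.15, red_od_threshold = 0.20,
                        ths_intensity_threshold = 100,
                        min_plaque_area_um2 = 20, closing_radius_px = 1L),
    coloc_threshold = 90,
    iod_source = "dab_od",
    metrics = c("diameter", "iod", "fd"),
    stages = list(vascular = TRUE, coloc = TRUE, ths = TRUE),
    log_level = "info")
}

#' Validate and normalise a run configuration
#'
#' Accepts a configuration list or the path of a YAML file, fills
#' documented defaults, checks units and value ranges, and rejects unknown
#' keys — reporting every violation at once, before any computation.
#'
#' @param config a named list or a YAML file path; \code{NULL} gives the
#'   default three-group demo configuration.
#' @return The normalised configuration (class \code{"runConfig"}).
#' @examples
#' cfg <- validateConfig(list(seed = 7))
#' cfg$seed
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file does not exist: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (inherits(config, "runConfig")) return(config)
  defaults <- runConfigDefaults()
  errs <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  ## `groups` is an unnamed list of group entries: replace it wholesale
  ## (recursive merging would splice user groups into the defaults)
  userGroups <- config$groups
  cfg <- utils::modifyList(defaults,
                           config[setdiff(names(config),
                                          c(unknown, "groups"))])
  if (!is.null(userGroups)) cfg$groups <- userGroups
  groupDefaults <- list(n_animals = 3L, burden_multiplier = 1,
                        contact_fraction = 0.25, ab40_ab42_overlap = 0.6,
                        ab40_ab42_area_ratio = 0.5)
  cfg$groups <- lapply(cfg$groups, function(g) {
    g <- utils::modifyList(groupDefaults, g[!vapply(g, is.null, logical(1))])
    g$n_animals <- as.integer(g$n_animals)
    g
  })
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    errs <- c(errs, "pixel_size_um must be > 0")
  if (length(cfg$field_size_px) != 2L || any(cfg$field_size_px < 16))
    errs <- c(errs, "field_size_px must be two integers >= 16")
  if (!is.numeric(cfg$base_plaque_mean) || cfg$base_plaque_mean < 0)
    errs <- c(errs, "base_plaque_mean must be >= 0")
  if (!is.numeric(cfg$animal_sd) || cfg$animal_sd < 0)
    errs <- c(errs, "animal_sd must be >= 0")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0)
    errs <- c(errs, "noise_sd must be >= 0")
  if (!cfg$region_layout %in% c("single", "quadrants"))
    errs <- c(errs, "region_layout must be 'single' or 'quadrants'")
  if (!cfg$iod_source %in% c("dab_od", "raw_intensity"))
    errs <- c(errs, "iod_source must be 'dab_od' or 'raw_intensity'")
  groupKeys <- c("name", "n_animals", "burden_multiplier",
                 "contact_fraction", "ab40_ab42_overlap",
                 "ab40_ab42_area_ratio")
  for (i in seq_along(cfg$groups)) {
    g <- cfg$groups[[i]]
    bad <- setdiff(names(g), groupKeys)
    if (length(bad))
      errs <- c(errs, sprintf("group %d: unknown key(s) %s", i,
                              paste(bad, collapse = ", ")))
    if (is.null(g$name)) errs <- c(errs, sprintf("group %d: missing name", i))
    if (!is.null(g$n_animals) && g$n_animals < 1)
      errs <- c(errs, sprintf("group %d: n_animals must be >= 1", i))
    if (!is.null(g$burden_multiplier) && g$burden_multiplier < 0)
      errs <- c(errs, sprintf("group %d: burden_multiplier must be >= 0", i))
    if (!is.null(g$contact_fraction) &&
        (g$contact_fraction < 0 || g$contact_fraction > 1))
      errs <- c(errs, sprintf("group %d: contact_fraction must lie in [0,1]", i))
  }
  segKeys <- names(defaults$segmentation)
  bad <- setdiff(names(cfg$segmentation), segKeys)
  if (length(bad))
    errs <- c(errs, sprintf("segmentation: unknown key(s) %s",
                            paste(bad, collapse = ", ")))
  for (k in c("dab_od_threshold", "red_od_threshold", "min_plaque_area_um2"))
    if (!is.null(cfg$segmentation[[k]]) && cfg$segmentation[[k]] <= 0)
      errs <- c(errs, sprintf("segmentation: %s must be > 0", k))
  if (length(errs))
    stop(paste(c("invalid configuration:", paste(" -", errs)),
               collapse = "\n"))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "runConfig"
  cfg
}

## SegmentationParams from the config sub-list.
segParamsFromConfig <- function(cfg) {
  s <- cfg$segmentation
  SegmentationParams(dabOdThreshold = s$dab_od_threshold,
                     redOdThreshold = s$red_od_threshold,
                     thsIntensityThreshold = s$ths_intensity_threshold,
                     minPlaqueAreaUm2 = s$min_plaque_area_um2,
                     closingRadiusPx = s$closing_radius_px)
}
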