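#' Nearest-vessel distance of one plaque
#'
#' Minimum Euclidean distance (pixel-centre semantics) from any plaque
#' pixel to any vessel pixel, in micrometres. A vessel running through or
#' in direct contact with the deposit — any plaque pixel overlapping or
#' 8-adjacent to a vessel pixel — is deemed to be at 0 um distance and
#' flags the record as a contact.
#'
#' @param plaqueMask logical or 0/1 matrix of the plaque.
#' @param vesselMask logical or 0/1 matrix of the vasculature.
#' @param pixelSizeUm micrometres per pixel.
#' @return list(distance_um, contact). If the vessel mask is empty the
#'   distance is \code{NA} with a warning (record excluded downstream).
#' @examples
#' p <- matrix(0, 16, 16); p[4:6, 4:6] <- 1
#' v <- matrix(0, 16, 16); v[10, 1:16] <- 1
#' nearestVesselDistance(p, v, 0.5)
#' @export
nearestVesselDistance <- function(plaqueMask, vesselMask, pixelSizeUm) {
  stopifnot(identical(dim(plaqueMask), dim(vesselMask)))
  if (!any(vesselMask > 0)) {
    warning("empty vessel mask: nearest-vessel distance is undefined")
    return(list(distance_um = NA_real_, contact = FALSE))
  }
  if (!any(plaqueMask > 0)) stop("empty plaque mask")
  dt <- EBImage::distmap(1 - (vesselMask > 0), metric = "euclidean")
  dmin <- min(dt[plaqueMask > 0])
  contact <- dmin <= sqrt(2) + 1e-9
  list(distance_um = if (contact) 0 else dmin * pixelSizeUm,
       contact = contact)
}

#' Plaque-vessel distance table
#'
#' Computes the nearest-vessel distance and contact flag for every plaque
#' of a label image against one vessel mask, sharing a single distance
#' transform. Optionally merges per-plaque measurements (diameter, region)
#' from a metrics table by ROI id.
#'
#' @param labels plaque label matrix (or the list returned by
#'   \code{\link{segmentPlaques}}).
#' @param vesselMask 0/1 vessel matrix.
#' @param pixelSizeUm micrometres per pixel.
#' @param plaqueTable optional data.frame with an \code{id} column to merge
#'   (e.g. from \code{\link{measurePlaques}}).
#' @return data.frame: id, nearest_distance_um, contact, plus any merged
#'   columns.
#' @export
plaqueVesselTable <- function(labels, vesselMask, pixelSizeUm,
                              plaqueTable = NULL) {
  if (is.list(labels) && !is.matrix(labels)) labels <- labels$labels
  n <- max(labels)
  if (n == 0L) {
    out <- data.frame(id = integer(0), nearest_distance_um = numeric(0),
                      contact = logical(0))
  } else if (!any(vesselMask > 0)) {
    warning("empty vessel mask: plaque-vessel distances are undefined")
    out <- data.frame(id = seq_len(n), nearest_distance_um = NA_real_,
                      contact = FALSE)
  } else {
    dt <- EBImage::distmap(1 - (vesselMask > 0), metric = "euclidean")
    dmin <- vapply(seq_len(n), function(i) min(dt[labels == i]), numeric(1))
    contact <- dmin <= sqrt(2) + 1e-9
    out <- data.frame(id = seq_len(n),
                      nearest_distance_um = ifelse(contact, 0,
                                                   dmin * pixelSizeUm),
                      contact = contact)
  }
  if (!is.null(plaqueTable)) out <- merge(out, plaqueTable, by = "id")
  out
}

#' Vessel-association frequency
#'
#' Percentage of plaques containing a blood vessel or in direct contact
#' with one (contact records) among all plaques.
#'
#' @param records data.frame with a logical \code{contact} column; rows
#'   with undefined distances (\code{NA}) are excluded.
#' @return Percentage in [0, 100].
#' @export
associationFrequency <- function(records) {
  ok <- records[!is.na(records$contact) &
                  (!("nearest_distance_um" %in% names(records)) |
                     !is.na(records$nearest_distance_um)), , drop = FALSE]
  if (!nrow(ok)) stop("association frequency is undefined without records")
  100 * sum(ok$contact) / nrow(ok)
}

#' Mean plaque-vessel distance of non-contact plaques
#'
#' Average nearest-vessel distance over plaques not in vessel contact
#' (plaques at 0 um are disregarded).
#'
#' @param records data.frame with \code{nearest_distance_um} and
#'   \code{contact} columns.
#' @return Mean distance in micrometres.
#' @export
meanNoncontactDistance <- function(records) {
  sub <- records[!is.na(records$nearest_distance_um) & !records$contact, ,
                 drop = FALSE]
  if (!nrow(sub))
    stop("all plaques are in vessel contact: non-contact distance undefined")
  mean(sub$nearest_distance_um)
}

#' Diameter-distance correlation
#'
#' Pearson correlation between plaque maximum diameter and nearest-vessel
#' distance over pooled plaque records. Contact (0 um) plaques can be
#' included or excluded; both conventions are plausible readings of pooled
#' plaque-level correlation analyses, so both are exposed.
#'
#' @param records data.frame with \code{max_diameter_um},
#'   \code{nearest_distance_um} and \code{contact} columns.
#' @param includeContacts include 0-distance contact plaques
#'   (default \code{TRUE}).
#' @return list(r, n, p) from \code{\link{pearsonCorrelation}}.
#' @export
diameterDistanceCorrelation <- function(records, includeContacts = TRUE) {
  sub <- records[!is.na(records$nearest_distance_um), , drop = FALSE]
  if (!includeContacts) sub <- sub[!sub$contact, , drop = FALSE]
  if (nrow(sub) < 4L)
    stop("need at least 4 plaque records for a diameter-distance correlation")
  pearsonCorrelation(sub$max_diameter_um, sub$nearest_distance_um)
}
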