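#' Novel-object discrimination index
#'
#' From novel-object-recognition exploration times: the \code{"fraction"}
#' form is the proportion of the total exploration time spent on the novel
#' object, \eqn{t_n / (t_n + t_f)} (0.5 = chance); the \code{"signed"}
#' form is \eqn{(t_n - t_f) / (t_n + t_f)} (0 = chance). Both are
#' returned; reported preference indices in the literature use either
#' convention, so neither is presumed.
#'
#' @param tNovelS,tFamiliarS exploration times in seconds; their sum must
#'   be positive.
#' @return list(fraction, signed).
#' @examples
#' discriminationIndex(45, 15)  # fraction 0.75, signed 0.5
#' @export
discriminationIndex <- function(tNovelS, tFamiliarS) {
  tot <- tNovelS + tFamiliarS
  if (any(tot <= 0))
    stop("discrimination index undefined: zero total exploration time")
  list(fraction = tNovelS / tot, signed = (tNovelS - tFamiliarS) / tot)
}

#' Time spent in the centre zone of an open field
#'
#' Counts tracked frames whose position falls inside the centre-zone
#' rectangle (inclusive bounds) and multiplies by the frame interval.
#'
#' @param positions n x 2 matrix or data.frame of (x, y) positions.
#' @param zone numeric length-4: xmin, ymin, xmax, ymax of the centre zone.
#' @param frameIntervalS seconds per frame.
#' @return Seconds spent in the zone; 0 with a warning for an empty track.
#' @examples
#' pos <- cbind(x = c(1, 5, 9), y = c(1, 5, 9))
#' timeInCenter(pos, zone = c(3, 3, 7, 7), frameIntervalS = 1)  # 1 s
#' @export
timeInCenter <- function(positions, zone, frameIntervalS) {
  positions <- as.matrix(positions)
  if (!nrow(positions)) {
    warning("empty track: time in centre is 0")
    return(0)
  }
  stopifnot(ncol(positions) == 2L, length(zone) == 4L, frameIntervalS > 0)
  inside <- positions[, 1L] >= zone[1L] & positions[, 1L] <= zone[3L] &
    positions[, 2L] >= zone[2L] & positions[, 2L] <= zone[4L]
  sum(inside) * frameIntervalS
}
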