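#' Hierarchical aggregation of per-object measurements
#'
#' Implements the study's aggregation order: measurements are first
#' averaged (or, for cumulative quantities such as IOD, summed) for each
#' animal and anatomical region, and those animal-level values are then
#' averaged per treatment group. The animal — never the plaque — is the
#' experimental unit: SEM is the n-1 standard deviation of the animal-level
#' values divided by the square root of the number of animals, and is
#' \code{NA} (flagged) for single-animal groups.
#'
#' @param records data.frame of per-object rows carrying \code{group},
#'   \code{animal} and \code{region} keys plus metric columns.
#' @param meanMetrics character, metric columns averaged per animal-region.
#' @param sumMetrics character, metric columns cumulated (summed) per
#'   animal-region.
#' @return list with \code{animalRegion} (one row per group x animal x
#'   region x metric) and \code{group} (group x region x metric with
#'   \code{mean}, \code{sem}, \code{n_animals}).
#' @examples
#' rec <- data.frame(group = "g", animal = c("a", "a", "b", "c"),
#'                   region = "cortex", area = c(2, 4, 4, 6))
#' aggregateMetrics(rec, meanMetrics = "area")$group
#' @export
aggregateMetrics <- function(records, meanMetrics, sumMetrics = character()) {
  need <- c("group", "animal", "region")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop(sprintf("records lack required key column(s): %s",
                 paste(miss, collapse = ", ")))
  metrics <- c(meanMetrics, sumMetrics)
  miss <- setdiff(metrics, names(records))
  if (length(miss))
    stop(sprintf("records lack metric column(s): %s",
                 paste(miss, collapse = ", ")))
  key <- interaction(records$group, records$animal, records$region,
                     drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- records[key == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    vals <- c(
      vapply(meanMetrics, function(m) mean(sub[[m]], na.rm = TRUE), numeric(1)),
      vapply(sumMetrics, function(m) sum(sub[[m]], na.rm = TRUE), numeric(1)))
    data.frame(group = parts[1L], animal = parts[2L], region = parts[3L],
               metric = metrics, value = unname(vals),
               stringsAsFactors = FALSE)
  })
  ar <- do.call(rbind, rows)
  gkey <- interaction(ar$group, ar$region, ar$metric, drop = TRUE, sep = "\r")
  grows <- lapply(levels(gkey), function(k) {
    sub <- ar[gkey == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    n <- nrow(sub)
    data.frame(group = parts[1L], region = parts[2L], metric = parts[3L],
               mean = mean(sub$value),
               sem = if (n > 1L) stats::sd(sub$value) / sqrt(n) else NA_real_,
               n_animals = n, stringsAsFactors = FALSE)
  })
  list(animalRegion = ar, group = do.call(rbind, grows))
}
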