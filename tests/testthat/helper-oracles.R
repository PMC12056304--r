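## Independent oracles used across tests. These deliberately use naive
## brute-force formulations, not the package's algorithms.

## Minimum pairwise pixel-centre distance between two masks, in pixels.
bruteMinDistancePx <- function(maskA, maskB) {
  a <- which(maskA > 0, arr.ind = TRUE)
  b <- which(maskB > 0, arr.ind = TRUE)
  sqrt(min(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
}

## Maximum pairwise pixel-centre distance within one mask, in pixels.
bruteFeretPx <- function(mask) {
  p <- which(mask > 0, arr.ind = TRUE)
  if (nrow(p) < 2L) return(0)
  sqrt(max(outer(p[, 1], p[, 1], "-")^2 + outer(p[, 2], p[, 2], "-")^2))
}

## A small, fast scene spec for unit tests.
smallSpec <- function(...) {
  args <- list(...)
  base <- list(fieldSizePx = c(128L, 128L), nPlaques = 8,
               diameterRangeUm = c(8, 20), vesselCount = 2, noiseSD = 0)
  do.call(SceneSpec, utils::modifyList(base, args))
}

## Simulated plaque records with a given population diameter-distance
## correlation (Gaussian copula on physiologic-looking marginals).
simulateRecords <- function(n, rho, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  data.frame(id = seq_len(n),
             max_diameter_um = 20 + 6 * x,
             nearest_distance_um = pmax(0, 25 + 10 * y),
             contact = FALSE)
}
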