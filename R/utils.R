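## Internal helpers shared across modules.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

## Integer (dr, dc) offsets of a raster disc of radius r (pixel centres).
discOffsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

## Stamp discs of radius r at (rows, cols) into a logical matrix of dim dm.
stampDiscs <- function(rows, cols, r, dm) {
  m <- matrix(FALSE, dm[1L], dm[2L])
  if (!length(rows)) return(m)
  off <- discOffsets(r)
  rr <- rep(rows, each = nrow(off)) + off$dr
  cc <- rep(cols, each = nrow(off)) + off$dc
  keep <- rr >= 1L & rr <= dm[1L] & cc >= 1L & cc <= dm[2L]
  m[cbind(rr[keep], cc[keep])] <- TRUE
  m
}

## Majority nonzero region label over mask indices; 0 if fully background.
majorityLabel <- function(idx, labels) {
  if (!length(idx)) return(0L)
  tab <- table(labels[idx])
  tab <- tab[names(tab) != "0"]
  if (!length(tab)) return(0L)
  as.integer(names(tab)[which.max(tab)])
}

## Derive a child seed from a base seed and an index, staying below 2^31.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(k)) %%
               (.Machine$integer.max - 1) + 1)
}

clip01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
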