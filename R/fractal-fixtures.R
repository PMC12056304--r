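#' Analytic fractal fixtures
#'
#' Deterministic binary masks with known (Hausdorff) dimension, used to
#' validate the box-counting fractal dimension estimator: a straight line
#' (dimension 1), a filled square (dimension 2), the Sierpinski triangle
#' (log2 3 = 1.585) and the Sierpinski carpet (log3 8 = 1.893).
#'
#' \code{line} takes a length in pixels and returns a square mask with that
#' many foreground pixels in its middle row; \code{filled_square} takes the
#' side length; the Sierpinski kinds take a recursion depth (>= 4) and return
#' masks of side \code{2^depth} and \code{3^depth} respectively.
#'
#' @param kind one of \code{"line"}, \code{"filled_square"},
#'   \code{"sierpinski_triangle"}, \code{"sierpinski_carpet"}.
#' @param sizeOrDepth side length in pixels (line, filled_square) or
#'   recursion depth (Sierpinski kinds).
#' @return A logical matrix.
#' @examples
#' sum(generateFractalMask("line", 128))          # 128 foreground px
#' sum(generateFractalMask("sierpinski_triangle", 5)) == 3^5
#' @export
generateFractalMask <- function(kind, sizeOrDepth) {
  kind <- as.character(kind)[1L]
  n <- as.integer(sizeOrDepth)
  switch(kind,
    line = {
      stopifnot(n >= 2L)
      m <- matrix(FALSE, n, n)
      m[(n %/% 2L) + 1L, ] <- TRUE
      m
    },
    filled_square = {
      stopifnot(n >= 2L)
      matrix(TRUE, n, n)
    },
    sierpinski_triangle = {
      if (n < 4L) stop("depth must be >= 4 for fractal kinds")
      side <- 2L^n
      ## pixel (i,j) (0-based) belongs to the Pascal-triangle-mod-2 gasket
      ## iff i AND j == 0 bitwise; foreground count is exactly 3^depth
      i <- matrix(0:(side - 1L), side, side)
      j <- t(i)
      matrix(bitwAnd(i, j) == 0L, side, side)
    },
    sierpinski_carpet = {
      if (n < 4L) stop("depth must be >= 4 for fractal kinds")
      side <- 3L^n
      keep <- rep(TRUE, side)
      m <- matrix(TRUE, side, side)
      idx <- 0:(side - 1L)
      ## drop pixels whose base-3 expansions share a digit '1' at any place
      dig <- matrix(0L, side, n)
      x <- idx
      for (k in seq_len(n)) {
        dig[, k] <- x %% 3L
        x <- x %/% 3L
      }
      one <- dig == 1L
      for (k in seq_len(n)) {
        m[one[, k], one[, k]] <- FALSE
      }
      m
    },
    stop(sprintf("unknown fractal kind '%s'", kind))
  )
}
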