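#' One-way analysis of variance
#'
#' Classical one-way ANOVA across treatment groups (fitted via
#' \code{stats::lm}/\code{stats::anova}): F = MSB/MSW with k-1 and N-k
#' degrees of freedom. When every value is identical the F = 0 path is
#' taken with p = 1.
#'
#' @param groups named list of numeric vectors, one per group (>= 2 groups,
#'   each with >= 2 values).
#' @return list of class \code{"anovaLsd"}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{mse}, \code{means}, \code{n}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))$F  # 3
#' @export
oneWayAnova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("one-way ANOVA needs at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop("every group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), n), levels = names(groups))
  k <- length(groups); N <- length(y)
  if (stats::var(y) < 1e-24) {
    out <- list(F = 0, df_between = k - 1L, df_within = N - k, p = 1,
                mse = 0, means = vapply(groups, mean, numeric(1)), n = n)
    class(out) <- "anovaLsd"
    return(out)
  }
  tab <- stats::anova(stats::lm(y ~ g))
  out <- list(F = tab$`F value`[1L],
              df_between = tab$Df[1L], df_within = tab$Df[2L],
              p = tab$`Pr(>F)`[1L], mse = tab$`Mean Sq`[2L],
              means = vapply(groups, mean, numeric(1)), n = n)
  class(out) <- "anovaLsd"
  out
}

#' @export
print.anovaLsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df_between, x$df_within, x$F, x$p, x$mse))
  invisible(x)
}

#' Fisher's least significant difference post hoc test
#'
#' Unadjusted pairwise comparisons using the ANOVA pooled error:
#' \eqn{t = (m_i - m_j) / \sqrt{MSE (1/n_i + 1/n_j)}} on N-k degrees of
#' freedom, two-sided p, with significance stars at the conventional
#' 0.05 / 0.01 / 0.001 levels. By the LSD definition no multiplicity
#' adjustment is applied. Pairwise results are reported regardless of the
#' omnibus outcome; the omnibus p travels alongside for gating at display
#' time.
#'
#' @param groups named list of numeric vectors (as in
#'   \code{\link{oneWayAnova}}).
#' @param anova result of \code{\link{oneWayAnova}} on the same groups
#'   (recomputed if missing).
#' @return data.frame: group1, group2, mean_diff, t, df, p, stars,
#'   p_omnibus.
#' @export
fisherLsd <- function(groups, anova = oneWayAnova(groups)) {
  if (anova$mse <= 0)
    stop("degenerate variance: LSD undefined with zero pooled MSE")
  nms <- names(anova$means)
  pairs <- utils::combn(nms, 2L)
  df <- anova$df_within
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    diff <- anova$means[[g1]] - anova$means[[g2]]
    se <- sqrt(anova$mse * (1 / anova$n[[g1]] + 1 / anova$n[[g2]]))
    t <- diff / se
    p <- 2 * stats::pt(-abs(t), df)
    data.frame(group1 = g1, group2 = g2, mean_diff = diff, t = t, df = df,
               p = p, stars = significanceStars(p),
               p_omnibus = anova$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Significance stars
#'
#' The conventional annotation: \code{***} p < 0.001, \code{**} p < 0.01,
#' \code{*} p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significanceStars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) "" else if (x < 0.001) "***" else if (x < 0.01) "**"
    else if (x < 0.05) "*" else ""
  }, character(1))
}

#' Pearson correlation with two-sided p
#'
#' Product-moment correlation; the p-value uses
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n-2 degrees of freedom
#' (via \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list(r, n, p).
#' @export
pearsonCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("Pearson correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Fisher Z test for two independent correlations
#'
#' Compares the magnitudes of two independent Pearson correlations via the
#' variance-stabilising transform \eqn{z = \mathrm{atanh}(r)}:
#' \deqn{Z = \frac{z_1 - z_2}{\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a one-tailed p in the stated direction (\code{"greater"} tests
#' r1 > r2) or a two-tailed p.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, >= 4.
#' @param tail \code{"greater"}, \code{"less"} or \code{"two.sided"}.
#' @return list of class \code{"fisherZ"}: r1, n1, r2, n2, Z, p, tail.
#' @examples
#' fisherZTest(0.5, 103, 0.3, 103, tail = "greater")$Z  # about 1.696
#' @export
fisherZTest <- function(r1, n1, r2, n2,
                        tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| = 1 gives an infinite transform; Fisher Z undefined")
  if (n1 < 4 || n2 < 4) stop("Fisher Z needs n >= 4 in both samples")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(tail,
    greater = stats::pnorm(Z, lower.tail = FALSE),
    less = stats::pnorm(Z),
    two.sided = 2 * stats::pnorm(-abs(Z)))
  out <- list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, Z = Z, p = p, tail = tail)
  class(out) <- "fisherZ"
  out
}

#' @export
print.fisherZ <- function(x, ...) {
  cat(sprintf("Fisher Z = %.4g (r1 = %.3f, n1 = %d vs r2 = %.3f, n2 = %d), %s p = %.4g\n",
              x$Z, x$r1, x$n1, x$r2, x$n2, x$tail, x$p))
  invisible(x)
}
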