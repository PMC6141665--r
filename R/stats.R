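#' @include AllClasses.R
NULL

## Rank statistics implemented from the defining formulas on mid-ranks,
## with explicit tie corrections. stats::kruskal.test / cor.test serve
## as independent cross-checks in the test suite, never as the
## implementation.

.asGroups <- function(x, g) {
  if (is.list(x) && missing(g)) {
    lab <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x)
           else as.character(seq_along(x))
    g <- factor(rep(lab, lengths(x)), levels = lab)
    x <- unlist(x, use.names = FALSE)
  } else {
    if (length(x) != length(g)) stop("x and g must have equal length")
    g <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
  }
  if (anyNA(x) || anyNA(g)) stop("observations and group labels must not be NA")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  n <- tabulate(g, nlevels(g))
  if (any(n == 0L)) stop("every group must contain at least one observation")
  if (length(x) < 3L) stop("need at least 3 observations in total")
  list(x = as.numeric(x), g = g, n = n)
}

.tieStats <- function(r) {
  t <- tabulate(match(r, unique(r)))
  sum(t^3 - t)
}

#' Tie-corrected Kruskal-Wallis rank test
#'
#' Computes the Kruskal-Wallis H statistic on mid-ranks,
#' \deqn{H = \frac{12}{N(N+1)} \sum_j R_j^2 / n_j - 3(N+1),}
#' divides by the tie correction
#' \eqn{1 - \sum (t^3 - t) / (N^3 - N)} (t running over tie-group
#' sizes), and takes the p-value from the upper tail of the chi-square
#' distribution with k - 1 degrees of freedom. When every observation
#' is identical the statistic is 0 and p = 1.
#'
#' @param x numeric observations, or a list of k numeric vectors (one
#'   per group).
#' @param g group labels (factor or vector), ignored when \code{x} is a
#'   list.
#' @return a list of class \code{"glycoPAP_test"} with elements
#'   \code{method}, \code{statistic} (tie-corrected H), \code{df},
#'   \code{p.value}, \code{n} and \code{groups}.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$statistic # 7.2
#' @export
kruskalWallis <- function(x, g) {
  gl <- .asGroups(x, g)
  N <- length(gl$x)
  r <- rank(gl$x)
  Rj <- rowsum(r, gl$g)[, 1L]
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / gl$n) - 3 * (N + 1)
  C <- 1 - .tieStats(r) / (N^3 - N)
  if (C <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / C
    p <- stats::pchisq(H, df = nlevels(gl$g) - 1L, lower.tail = FALSE)
  }
  structure(list(method = "Kruskal-Wallis rank sum test (tie-corrected)",
                 statistic = H, df = nlevels(gl$g) - 1L, p.value = p,
                 n = N, groups = levels(gl$g)),
            class = "glycoPAP_test")
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every pair of groups (i, j) computes the Dunn z statistic on the
#' pooled mid-ranks,
#' \deqn{z = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N - 1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}},}
#' with a two-sided p-value from the standard normal, adjusted for the
#' k(k-1)/2 comparisons by the chosen method (Bonferroni by default).
#' The sign convention is \code{group1} minus \code{group2} in the
#' order the group levels appear.
#'
#' @inheritParams kruskalWallis
#' @param adjustment "bonferroni" (default), "sidak" or "none".
#' @return data.frame with one row per pair: \code{group1},
#'   \code{group2}, \code{z}, \code{p_raw}, \code{p_adj},
#'   \code{adjustment}.
#' @export
dunnPosthoc <- function(x, g, adjustment = c("bonferroni", "sidak", "none")) {
  adjustment <- match.arg(adjustment)
  gl <- .asGroups(x, g)
  N <- length(gl$x)
  r <- rank(gl$x)
  Rbar <- rowsum(r, gl$g)[, 1L] / gl$n
  sigma2 <- N * (N + 1) / 12 - .tieStats(r) / (12 * (N - 1))
  lev <- levels(gl$g)
  pairs <- utils::combn(seq_along(lev), 2L)
  m <- ncol(pairs)
  z <- numeric(m); pRaw <- numeric(m)
  for (c in seq_len(m)) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt(sigma2 * (1 / gl$n[i] + 1 / gl$n[j]))
    num <- Rbar[i] - Rbar[j]
    z[c] <- if (se == 0) { if (num == 0) 0 else sign(num) * Inf } else num / se
    pRaw[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  pAdj <- switch(adjustment,
                 bonferroni = pmin(1, pRaw * m),
                 sidak = 1 - (1 - pRaw)^m,
                 none = pRaw)
  data.frame(group1 = lev[pairs[1L, ]], group2 = lev[pairs[2L, ]],
             z = z, p_raw = pRaw, p_adj = pAdj, adjustment = adjustment,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with mid-rank ties
#'
#' Spearman's rho computed as the Pearson correlation of the mid-ranks
#' of the two variables (average ranks for ties), with a two-sided
#' p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length n >= 3; neither may be
#'   constant.
#' @return a list of class \code{"glycoPAP_test"} with elements
#'   \code{method}, \code{estimate} (rho), \code{statistic} (t),
#'   \code{p.value} and \code{n}.
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (1 - rho^2 < .Machine$double.eps) {
    tStat <- sign(rho) * Inf
    p <- 0
  } else {
    tStat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tStat), df = n - 2)
  }
  structure(list(method = "Spearman rank correlation (mid-ranks, t approximation)",
                 estimate = rho, statistic = tStat, p.value = p, n = n),
            class = "glycoPAP_test")
}

#' @export
print.glycoPAP_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$estimate)) cat(sprintf("  rho = %.4f,", x$estimate))
  cat(sprintf("  statistic = %.4f,", x$statistic))
  if (!is.null(x$df)) cat(sprintf(" df = %d,", x$df))
  cat(sprintf(" n = %d, p = %.4g\n", x$n, x$p.value))
  invisible(x)
}
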