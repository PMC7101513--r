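#' Degree distribution over positive degrees
#'
#' Histogram of node degrees, one point per distinct positive degree.
#' Degree-0 nodes are excluded (a log-log fit cannot use them) and absent
#' degrees are not zero-filled.
#'
#' @param table a `centrality_table` (or any data.frame with a `degree`
#'   column).
#' @return data.frame with columns `k` (strictly increasing positive integer
#'   degree) and `count` (number of nodes with that degree, >= 1), of class
#'   `degree_distribution`.
#' @export
degree_distribution <- function(table) {
  if (nrow(table) == 0L) stop("empty centrality table")
  d <- table$degree[table$degree > 0L]
  if (length(d) == 0L) stop("no positive degrees")
  tab <- table(d)
  out <- data.frame(k = as.integer(names(tab)),
                    count = as.integer(tab))
  out <- out[order(out$k), ]
  rownames(out) <- NULL
  class(out) <- c("degree_distribution", "data.frame")
  out
}

#' Power-law fit of a degree distribution
#'
#' Fits `count = a * k^b` by ordinary least squares of `log10(count)` on
#' `log10(k)`, one unweighted point per distinct degree — the simple
#' power-law fit NetworkAnalyzer reports, not a maximum-likelihood
#' (Clauset-style) tail estimate. The returned `correlation` is the Pearson
#' correlation of the log-log points and `r_squared` is its square, so
#' `r_squared == correlation^2` always holds (`NA` for a perfectly flat
#' histogram, whose correlation is undefined). A scale-free network yields
#' `b < 0` with strongly negative correlation.
#'
#' @param dist a `degree_distribution` (>= 3 distinct degree values).
#' @return object of class `power_law_fit`: list with `a` (positive
#'   coefficient), `b` (exponent), `correlation`, `r_squared`, and
#'   `n_points`.
#' @examples
#' pts <- data.frame(k = c(1, 2, 4, 8), count = c(64, 32, 16, 8))
#' fit_power_law(pts)  # recovers a = 64, b = -1 exactly
#' @export
fit_power_law <- function(dist) {
  if (nrow(dist) < 3L) stop("insufficient support for fit: need >= 3 points")
  if (any(dist$count <= 0) || any(dist$k <= 0)) {
    stop("degrees and counts must be positive")
  }
  x <- log10(dist$k)
  y <- log10(dist$count)
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2L])
  a <- 10^unname(stats::coef(fit)[1L])
  # a perfectly flat histogram (every count equal) has slope 0 but an
  # undefined Pearson correlation; report NA rather than warn from cor()
  r <- if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  structure(list(a = a, b = b, correlation = r, r_squared = r^2,
                 n_points = nrow(dist)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit y = a*x^b: a = %.3f, b = %.3f, correlation = %.3f, R^2 = %.3f (%d points)\n",
    x$a, x$b, x$correlation, x$r_squared, x$n_points))
  invisible(x)
}

#' Log-log degree-distribution plot with the fitted power law
#'
#' Cosmetic companion to [fit_power_law()]; the numbers, not the figure, are
#' the contract.
#'
#' @param dist a `degree_distribution`.
#' @param fit optional `power_law_fit` to overlay.
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_degree_distribution <- function(dist, fit = NULL, ...) {
  plot(dist$k, dist$count, log = "xy", xlab = "degree",
       ylab = "number of nodes", pch = 19, ...)
  if (!is.null(fit)) {
    kk <- seq(min(dist$k), max(dist$k), length.out = 100)
    graphics::lines(kk, fit$a * kk^fit$b, lty = 2)
  }
  invisible(NULL)
}
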