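# S3 methods for the central fpa_network class.

#' @export
print.fpa_network <- function(x, ...) {
  cat(sprintf("FPA network: %d nodes, %d edges (m = %s, f = %s%s)\n",
              x$n, nrow(x$edges), format(x$m), format(x$f),
              if (!is.null(x$seed)) paste0(", seed = ", x$seed) else ""))
  cat(sprintf("  degrees: max %d, mean %.3f%s\n",
              max(x$degree), mean(x$degree),
              if (nrow(x$edges) == x$n - 1L) "; tree" else ""))
  invisible(x)
}

#' Summarise an FPA network
#'
#' Computes the full topology summary; see [topology_summary()].
#'
#' @param object An `fpa_network`.
#' @param ... Passed to [topology_summary()].
#' @return An `fpa_topology` object.
#' @export
summary.fpa_network <- function(object, ...) topology_summary(object, ...)

#' Plot FPA network diagnostics
#'
#' Two log-log panels: the cumulative degree distribution P(k) and the mean
#' nearest-neighbour degree curve, with their fitted power laws.
#'
#' @param x An `fpa_network`.
#' @param ... Unused.
#' @export
plot.fpa_network <- function(x, ...) {
  cur <- degree_curves(x)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(cur$k, cur$cdf, log = "xy", pch = 20, cex = 0.5,
                 xlab = "k", ylab = "P(k)",
                 main = sprintf("CCDF (f = %s)", format(x$f)))
  bfit <- tryCatch(fit_ccdf_exponent(x), error = function(e) NULL)
  if (!is.null(bfit))
    graphics::curve(bfit$amplitude * x^(-bfit$exponent), add = TRUE,
                    col = "blue")
  keep <- is.finite(cur$knn)
  graphics::plot(cur$k[keep], cur$knn[keep], log = "xy", pch = 20, cex = 0.5,
                 xlab = "k", ylab = "<knn(k)>", main = "degree correlation")
  afit <- tryCatch(fit_alpha(x), error = function(e) NULL)
  if (!is.null(afit))
    graphics::curve(afit$amplitude * x^(afit$exponent), add = TRUE,
                    col = "blue")
  invisible(x)
}
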