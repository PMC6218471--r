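#' Plot a Bhattacharyya-distance curve
#'
#' BD against noise level (for a [noise_robustness()] report) or against
#' simulation time (for a [response_curve()]).
#'
#' @param x a `robustness_report` or `response_curve`.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot_bd_curve <- function(x, ...) {
  if (inherits(x, "robustness_report")) {
    graphics::plot(x$curve$D, x$curve$BD, type = "b", pch = 16,
                   xlab = "noise level D", ylab = "Bhattacharyya distance",
                   main = paste0(x$circuit, "  (BD at D=1: ",
                                 signif(x$RD, 3), ")"), ...)
    graphics::abline(v = 1, lty = 3)
  } else {
    graphics::plot(x$time, x$BD, type = "l",
                   xlab = "simulation time", ylab = "Bhattacharyya distance",
                   ...)
  }
  invisible(x)
}

#' Scatter plot of a PCA embedding
#'
#' @param embedding a [pca_embed()] result.
#' @param labels optional per-record grouping used for colors.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot_pca <- function(embedding, labels = NULL, ...) {
  ve <- round(100 * embedding$var_explained[1:2], 1)
  col <- if (is.null(labels)) grDevices::rgb(0, 0, 0, 0.3)
         else as.integer(as.factor(labels)) + 1L
  graphics::plot(embedding$scores[, 1], embedding$scores[, 2], col = col,
                 pch = 16, cex = 0.5,
                 xlab = paste0("PC1 (", ve[1], "%)"),
                 ylab = paste0("PC2 (", ve[2], "%)"), ...)
  invisible(embedding)
}

#' Histogram of double-well positions by noise level
#'
#' @param result an `ensemble_result` from a double-well scheme run.
#' @param system the [double_well()] object.
#' @param breaks histogram breaks.
#' @param ... further arguments to [graphics::hist()].
#' @export
plot_dw_histogram <- function(result, system, breaks = 60, ...) {
  graphics::hist(result$expression[, 1], breaks = breaks, freq = FALSE,
                 xlab = "position x",
                 main = paste0("variant ", system$variant, ", ",
                               result$scheme, ", D = ",
                               signif(result$D[1], 3)), ...)
  graphics::abline(v = system$minima, lty = 2)
  invisible(result)
}
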