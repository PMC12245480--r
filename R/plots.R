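# Base-graphics views of a morphological-gap analysis: morphospace scatter,
# ridgeline density profile and tolerance-content curves.

#' @export
plot.ridgeline_profile <- function(x, ...) {
  plot(x$alpha, x$density, type = "l", xlab = expression(alpha),
       ylab = "mixture density", ...)
  invisible(x)
}

#' @export
plot.tolerance_profile <- function(x, ...) {
  plot(x$alpha, x$beta1, type = "l", ylim = c(0, 1),
       xlab = expression(alpha), ylab = expression(beta), ...)
  lines(x$alpha, x$beta2, lty = 2)
  legend("bottom", legend = c("component 1", "component 2"),
         lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Three-panel summary plot of a morphological-gap analysis
#'
#' Panel A: PCA morphospace scatter by group; panel B: mixture density along
#' the ridgeline; panel C: tolerance contents of both components along the
#' ridgeline with the decision threshold band.
#'
#' @param x a [morph_gap()] result.
#' @param ... ignored.
#' @export
plot.morph_gap <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  sc <- x$pca$scores
  grp <- factor(sc$group)
  plot(sc[[3]], sc[[4]], col = as.integer(grp), pch = as.integer(grp),
       xlab = names(sc)[3], ylab = names(sc)[4], main = "morphospace")
  legend("topright", legend = levels(grp), col = 1:2, pch = 1:2, bty = "n")
  plot(x$profile, main = "ridgeline density")
  plot(x$tolerance, main = "tolerance content")
  abline(h = 1 - x$decision$threshold, col = "grey50", lty = 3)
  invisible(x)
}
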