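# S3 methods for fitted "meshreg" registration objects.

#' @export
print.meshreg <- function(x, ...) {
  cat("Nonrigid registration (spring-mesh regularized)\n")
  cat("  grid:               ", paste(dim(x$target), collapse = " x "), "\n")
  cat("  pyramid levels:     ", x$scales_used, "\n")
  cat("  template updates:   ", x$n_template_updates, "\n")
  cat(sprintf("  cross-correlation:   %.4f -> %.4f (target %.4f, %s)\n",
              x$cc0, x$cc_final, x$cc_target,
              if (isTRUE(x$converged)) "reached" else "not reached"))
  cat(sprintf("  negative-Jacobian fraction: %g\n", x$nj_final))
  invisible(x)
}

#' Summarize a fitted registration
#'
#' @param object a [meshreg()] fit.
#' @param ... unused.
#' @return a `summary.meshreg` list with similarity, topology and
#'   displacement-magnitude diagnostics.
#' @export
summary.meshreg <- function(object, ...) {
  d <- field_ndim(object$field)
  mags <- sqrt(rowSums(matrix(object$field, ncol = d)^2))
  jac <- jacobian_determinants(object$field)
  out <- list(
    shape = dim(object$target),
    scales_used = object$scales_used,
    n_template_updates = object$n_template_updates,
    iterations = nrow(object$trace),
    cc0 = object$cc0,
    cc_final = object$cc_final,
    cc_target = object$cc_target,
    converged = object$converged,
    ssd_initial = ssd(object$matched_template, object$target),
    ssd_final = ssd(object$fitted, object$target),
    nj_final = object$nj_final,
    jacobian_range = range(jac),
    displacement = stats::quantile(mags, c(0, 0.5, 0.95, 1)),
    control = object$control)
  class(out) <- "summary.meshreg"
  out
}

#' @export
print.summary.meshreg <- function(x, ...) {
  cat("Nonrigid registration summary\n")
  cat("  grid ", paste(x$shape, collapse = " x "),
      ", ", x$scales_used, " pyramid level(s), ",
      x$iterations, " iterations, ",
      x$n_template_updates, " template update(s)\n", sep = "")
  cat(sprintf("  SSD: %.4g -> %.4g\n", x$ssd_initial, x$ssd_final))
  cat(sprintf("  CC:  %.4f -> %.4f (target %.4f, %s)\n", x$cc0, x$cc_final,
              x$cc_target, if (isTRUE(x$converged)) "reached" else "not reached"))
  cat(sprintf("  Jacobian determinants in [%.3f, %.3f]; negative fraction %g\n",
              x$jacobian_range[1], x$jacobian_range[2], x$nj_final))
  cat(sprintf("  |u| (px): median %.3f, p95 %.3f, max %.3f\n",
              x$displacement[2], x$displacement[3], x$displacement[4]))
  invisible(x)
}

#' @export
coef.meshreg <- function(object, ...) object$field

#' @export
fitted.meshreg <- function(object, ...) object$fitted

#' Residual intensity differences of a registration
#'
#' @param object a [meshreg()] fit.
#' @param ... unused.
#' @return `target - fitted` intensity difference image.
#' @export
residuals.meshreg <- function(object, ...) {
  array(as.vector(object$target) - as.vector(object$fitted),
        dim = dim(object$target))
}

#' Apply a fitted transform to new images or label maps
#'
#' Warps `newdata` through the fitted displacement field: linear interpolation
#' for intensity images, nearest-neighbour label propagation for label maps.
#'
#' @param object a [meshreg()] fit.
#' @param newdata image or label array on the fit's grid; defaults to the
#'   histogram-matched template.
#' @param type `"image"` or `"labels"`.
#' @param ... unused.
#' @return the warped array.
#' @export
predict.meshreg <- function(object, newdata = NULL,
                            type = c("image", "labels"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$matched_template
  if (type == "labels") propagate_labels(newdata, object$field)
  else warp_image(newdata, object$field, "linear")
}

#' Plot registration convergence traces
#'
#' Draws the per-iteration SSD (log scale) and cross-correlation traces,
#' with pyramid-scale boundaries marked.
#'
#' @param x a [meshreg()] fit.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.meshreg <- function(x, ...) {
  tr <- x$trace
  it <- seq_len(nrow(tr))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(it, tr$ssd, type = "l", log = "y", xlab = "iteration",
                 ylab = "SSD", main = "similarity energy", ...)
  brk <- which(diff(tr$scale) != 0 | diff(tr$pass) != 0)
  graphics::abline(v = brk + 0.5, lty = 3, col = "grey50")
  graphics::plot(it, tr$cc, type = "l", xlab = "iteration",
                 ylab = "CC", main = "cross-correlation", ...)
  graphics::abline(h = x$cc_target, lty = 2, col = "red3")
  graphics::abline(v = brk + 0.5, lty = 3, col = "grey50")
  invisible(x)
}
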