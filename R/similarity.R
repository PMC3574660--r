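# Similarity measures and the optical-flow displacement force.

#' Sum of squared intensity differences
#'
#' The similarity energy between two images on the same grid:
#' `sum_p (b(p) - a(p))^2`. Zero if and only if the images are identical.
#'
#' @param a,b images with identical shapes.
#' @return nonnegative scalar.
#' @export
ssd <- function(a, b) {
  check_same_shape(a, b, "images")
  sum((as.vector(b) - as.vector(a))^2)
}

#' Cross-correlation between two images
#'
#' The zero-mean normalized (Pearson) cross-correlation factor of the two
#' intensity vectors over the whole grid, bounded in `[-1, 1]`; 1 means
#' maximum similarity. Undefined when either image is constant.
#'
#' @param a,b images with identical shapes; at least one value must vary.
#' @return scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b) {
  check_same_shape(a, b, "images")
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("cross-correlation is undefined for constant images")
  stats::cor(av, bv)
}

#' Optical-flow displacement force
#'
#' The demons-style per-pixel velocity derived from intensity conservation.
#' With `d(p) = a(p) - b(p)` the difference between the deformed template `a`
#' and the target `b`, and `g = grad b`, the renormalized force is
#' `v(p) = d(p) g(p) / (||g(p)||^2 + d(p)^2)`; without renormalization the
#' denominator is `||g(p)||^2` alone. Where the denominator vanishes the force
#' is set to zero (the unique continuous extension). The displacement
#' increment applied to the template is `u = -v`; the registration driver owns
#' that sign.
#'
#' The renormalized force is bounded: `||v(p)|| <= 1/2` pointwise, by the
#' AM-GM inequality on the denominator.
#'
#' @param deformed_template image `a` (the template warped by the current
#'   field).
#' @param target image `b` whose gradient steers the force.
#' @param renormalized add `d(p)^2` to the denominator (default `TRUE`).
#' @return displacement-field-shaped array `c(dim(target), ndim)`.
#' @export
optical_flow_velocity <- function(deformed_template, target,
                                  renormalized = TRUE) {
  check_same_shape(deformed_template, target, "images")
  shape <- dim(target)
  d <- length(shape)
  flat <- prod(shape)
  diffv <- as.vector(deformed_template) - as.vector(target)
  g <- image_gradient(target)
  gm <- matrix(g, ncol = d)
  gn2 <- rowSums(gm^2)
  denom <- if (renormalized) gn2 + diffv^2 else gn2
  scale <- ifelse(denom == 0, 0, diffv / denom)
  v <- gm * scale
  array(v, dim = c(shape, d))
}

#' Histogram matching by quantile mapping
#'
#' Monotone remapping of the source intensities so that their empirical
#' quantiles agree with the reference image's; the standard intensity
#' normalization step before intensity-based registration. Piecewise-linear
#' interpolation between `n_quantiles` matched quantiles.
#'
#' @param source image to remap.
#' @param reference image providing the target intensity distribution.
#' @param n_quantiles number of quantile anchors (default 256).
#' @return remapped image with the source's shape.
#' @export
histogram_match <- function(source, reference, n_quantiles = 256L) {
  if (n_quantiles < 2L) stop("'n_quantiles' must be at least 2")
  sv <- as.vector(source)
  rv <- as.vector(reference)
  if (max(sv) == min(sv)) {
    warning("constant source image; mapping every value to the reference median")
    out <- array(stats::median(rv), dim = dim(source))
    attr(out, "spacing") <- image_spacing(source)
    return(out)
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  qs <- stats::quantile(sv, probs, names = FALSE)
  qr <- stats::quantile(rv, probs, names = FALSE)
  mapped <- stats::approx(qs, qr, xout = sv, rule = 2, ties = mean)$y
  out <- array(mapped, dim = dim(source))
  attr(out, "spacing") <- image_spacing(source)
  out
}
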