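# Segmentation-transfer evaluation: label propagation and Dice/kappa overlap.

#' Propagate a label image through a displacement field
#'
#' Nearest-neighbour warp of an integer label map through the transform
#' `T(p) = p + u(p)` (linear interpolation of labels would be meaningless).
#' The atlas/template labels are pulled back through the template-to-target
#' field, so the output lives on the target grid.
#'
#' @param labels integer array (0 = background).
#' @param field displacement field over the same grid.
#' @return integer label array of the same shape.
#' @export
propagate_labels <- function(labels, field) {
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers")
  out <- warp_image(array(as.numeric(labels), dim = dim(labels)), field,
                    interpolation = "nearest")
  out <- array(as.integer(round(out)), dim = dim(labels))
  out
}

#' Kappa similarity index (Dice overlap) for one label
#'
#' With `G` the ground-truth mask of `label` and `E` the estimated mask, the
#' index is `2 TP / (2 TP + FN + FP)` where `TP = |G intersect E|`,
#' `FP = |E \\ G|`, `FN = |G \\ E|` - algebraically the Dice coefficient
#' `2|G intersect E| / (|G| + |E|)`. Perfect correspondence gives 1, disjoint
#' nonempty masks give 0; it is undefined (error) when the label is absent
#' from both images.
#'
#' @param ground_truth,estimate integer label arrays of identical shape.
#' @param label the label value to score.
#' @return scalar in `[0, 1]`.
#' @export
kappa_index <- function(ground_truth, estimate, label) {
  check_same_shape(ground_truth, estimate, "label images")
  G <- as.vector(ground_truth) == label
  E <- as.vector(estimate) == label
  if (!any(G) && !any(E))
    stop("label ", label, " absent from both images; overlap undefined")
  tp <- sum(G & E)
  fp <- sum(!G & E)
  fn <- sum(G & !E)
  2 * tp / (2 * tp + fn + fp)
}

#' Per-label overlap table
#'
#' @param ground_truth,estimate integer label arrays.
#' @param labels label values to score; defaults to all nonzero labels present
#'   in either image.
#' @return data frame with columns `label` and `kappa`.
#' @export
kappa_table <- function(ground_truth, estimate, labels = NULL) {
  if (is.null(labels))
    labels <- sort(setdiff(unique(c(as.vector(ground_truth),
                                    as.vector(estimate))), 0L))
  data.frame(label = labels,
             kappa = vapply(labels, function(l)
               kappa_index(ground_truth, estimate, l), numeric(1)))
}

#' Endpoint error between two displacement fields
#'
#' Per-point Euclidean norm of the vector difference between an estimated and
#' a ground-truth field, optionally restricted to a mask.
#'
#' @param estimate,truth displacement fields on the same grid.
#' @param mask optional logical array selecting the points to score.
#' @return numeric vector of per-point errors (over the mask).
#' @export
endpoint_error <- function(estimate, truth, mask = NULL) {
  check_same_shape(estimate, truth, "fields")
  d <- field_ndim(truth)
  err <- sqrt(rowSums((matrix(estimate, ncol = d) - matrix(truth, ncol = d))^2))
  if (!is.null(mask)) err <- err[as.logical(as.vector(mask))]
  err
}

#' Gradient-bearing region of an image
#'
#' Logical mask of grid points whose gradient magnitude exceeds a fraction of
#' the image's maximal gradient magnitude. Displacements are only observable
#' where the intensity varies, so field-recovery error is scored inside this
#' region.
#'
#' @param image numeric array.
#' @param rel_threshold fraction of the maximal gradient magnitude
#'   (default 0.05).
#' @return logical array of the image's shape.
#' @export
gradient_mask <- function(image, rel_threshold = 0.05) {
  g <- image_gradient(image)
  mag <- sqrt(rowSums(matrix(g, ncol = field_ndim(g))^2))
  array(mag > rel_threshold * max(mag), dim = dim(image))
}
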