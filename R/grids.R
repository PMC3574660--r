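# Core grid containers and operators: scalar images, displacement fields,
# interpolation-based warping, finite-difference gradients and discrete
# Jacobian determinants.
#
# Conventions (fixed package-wide):
#   * images are plain numeric matrices (2-D) or 3-D arrays; an optional
#     "spacing" attribute stores the physical size of one grid step per axis;
#   * coordinates are grid-index coordinates and displacements are measured in
#     grid units, so the transform is T(p) = p + u(p) on the pixel grid;
#   * a displacement field over a grid of shape s and dimension d is an array
#     of dim c(s, d), the last margin indexing vector components;
#   * samples falling outside the grid are clamped to the nearest edge
#     (replicate border), which avoids spurious zero-intensity forces.

#' Construct and validate a scalar image
#'
#' A scalar image is a plain numeric matrix (2-D) or 3-D array of finite
#' intensities with an optional per-axis `spacing` attribute (grid step in
#' physical units, default 1 per axis). All package operators accept bare
#' arrays; this constructor only validates and attaches spacing.
#'
#' @param values numeric matrix or 3-D array of finite intensities; every
#'   dimension must have length at least 2.
#' @param spacing numeric vector of positive physical step sizes, one per
#'   axis. Defaults to 1 on every axis.
#' @return the validated array with a `spacing` attribute.
#' @export
#' @examples
#' img <- scalar_image(matrix(rnorm(16), 4, 4))
#' attr(img, "spacing")
scalar_image <- function(values, spacing = NULL) {
  if (is.null(dim(values))) stop("'values' must be a matrix or array")
  d <- length(dim(values))
  if (!(d %in% c(2L, 3L))) stop("images must be 2-D or 3-D, got ", d, " dims")
  if (any(dim(values) < 2L)) stop("every image dimension must be >= 2")
  if (!all(is.finite(values))) stop("image intensities must all be finite")
  if (is.null(spacing)) spacing <- image_spacing(values)
  if (length(spacing) != d || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must hold one positive finite value per axis")
  storage.mode(values) <- "double"
  attr(values, "spacing") <- as.numeric(spacing)
  values
}

#' @rdname scalar_image
#' @param image an image array.
#' @export
image_spacing <- function(image) {
  sp <- attr(image, "spacing")
  if (is.null(sp)) rep(1, length(dim(image))) else as.numeric(sp)
}

#' Construct a displacement field
#'
#' A displacement field assigns one d-component vector (in grid units) to each
#' point of a d-dimensional grid; it is stored as an array of dim
#' `c(shape, d)` whose last margin indexes vector components. The associated
#' spatial transform is `T(p) = p + u(p)`.
#'
#' @param vectors array of dim `c(shape, d)` with finite entries, or `NULL`
#'   to create a zero field.
#' @param shape grid dimensions (required when `vectors` is `NULL`).
#' @return the validated field array.
#' @export
displacement_field <- function(vectors = NULL, shape = NULL) {
  if (is.null(vectors)) {
    if (is.null(shape)) stop("either 'vectors' or 'shape' is required")
    shape <- as.integer(shape)
    return(array(0, dim = c(shape, length(shape))))
  }
  dm <- dim(vectors)
  if (is.null(dm) || length(dm) < 3L)
    stop("'vectors' must be an array of dim c(shape, ndim)")
  d <- dm[length(dm)]
  if (d != length(dm) - 1L)
    stop("last margin (", d, " components) must match grid dimension (",
         length(dm) - 1L, ")")
  if (!all(is.finite(vectors))) stop("field components must all be finite")
  storage.mode(vectors) <- "double"
  vectors
}

field_shape <- function(field) {
  dm <- dim(field)
  dm[-length(dm)]
}

field_ndim <- function(field) {
  dm <- dim(field)
  dm[length(dm)]
}

#' @keywords internal
check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[seq_along(dim(a))], dim(b)[seq_along(dim(b))]) ||
      length(dim(a)) != length(dim(b)) || any(dim(a) != dim(b)))
    stop(what, " must have identical shapes (got ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
  invisible(TRUE)
}

# Grid coordinate arrays (1-based), one matrix column per axis.
grid_coords <- function(shape) {
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  storage.mode(idx) <- "double"
  idx
}

# Multilinear interpolation of 'arr' at continuous 1-based coordinates
# (n x d matrix). Out-of-range coordinates are clamped to the domain.
interp_linear <- function(arr, coords) {
  dm <- dim(arr)
  d <- length(dm)
  n <- nrow(coords)
  base <- matrix(0L, n, d)
  frac <- matrix(0, n, d)
  for (k in seq_len(d)) {
    x <- pmin(pmax(coords[, k], 1), dm[k])
    b <- floor(x)
    b <- pmin(b, dm[k] - 1L)  # dm[k] >= 2 by container invariant
    base[, k] <- as.integer(b)
    frac[, k] <- x - b
  }
  strides <- cumprod(c(1, dm[-d]))
  out <- numeric(n)
  # accumulate over the 2^d corners of the surrounding cell
  for (corner in 0:(2^d - 1)) {
    off <- bitwAnd(corner, 2^(seq_len(d) - 1L)) > 0
    idx <- 1
    w <- rep(1, n)
    for (k in seq_len(d)) {
      ik <- base[, k] + if (off[k]) 1L else 0L
      idx <- idx + (ik - 1L) * strides[k]
      w <- w * if (off[k]) frac[, k] else 1 - frac[, k]
    }
    out <- out + w * arr[idx]
  }
  out
}

# Nearest-neighbour sampling at continuous 1-based coordinates, clamped.
interp_nearest <- function(arr, coords) {
  dm <- dim(arr)
  d <- length(dm)
  strides <- cumprod(c(1, dm[-d]))
  idx <- 1
  for (k in seq_len(d)) {
    ik <- pmin(pmax(round(coords[, k]), 1), dm[k])
    idx <- idx + (as.integer(ik) - 1L) * strides[k]
  }
  arr[idx]
}

#' Warp an image through a displacement field
#'
#' Resamples `image` at the pulled-back positions `p + u(p)`: the output value
#' at grid point `p` is the input sampled at `p + u(p)`. Samples outside the
#' grid are clamped to the nearest border pixel.
#'
#' @param image numeric matrix or 3-D array.
#' @param field displacement field of dim `c(dim(image), ndim)` in grid units.
#' @param interpolation `"linear"` (multilinear) or `"nearest"`.
#' @return warped image with the same shape (and spacing) as the input.
#' @export
#' @examples
#' img <- matrix(seq_len(16), 4, 4)
#' u <- displacement_field(shape = dim(img))
#' identical(warp_image(img, u, "nearest"), img + 0)
warp_image <- function(image, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  shape <- dim(image)
  if (!identical(as.integer(field_shape(field)), as.integer(shape)))
    stop("image and field shapes differ (",
         paste(shape, collapse = "x"), " vs ",
         paste(field_shape(field), collapse = "x"), ")")
  d <- length(shape)
  coords <- grid_coords(shape)
  u <- matrix(field, ncol = d)
  coords <- coords + u
  vals <- switch(interpolation,
                 linear = interp_linear(image, coords),
                 nearest = interp_nearest(image, coords))
  out <- array(vals, dim = shape)
  attr(out, "spacing") <- image_spacing(image)
  out
}

# Extract a shifted copy of 'a' along 'axis' with replicate-border clamping;
# shift = +1 picks a[i+1], shift = -1 picks a[i-1].
shift_clamped <- function(a, axis, shift) {
  dm <- dim(a)
  idx <- lapply(seq_along(dm), function(k) {
    if (k == axis) pmin(pmax(seq_len(dm[k]) + shift, 1L), dm[k])
    else seq_len(dm[k])
  })
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

# Finite-difference derivative along one axis: central differences in the
# interior, one-sided at the two boundary slices; divided by the grid step.
axis_derivative <- function(a, axis, step = 1) {
  dm <- dim(a)
  up <- shift_clamped(a, axis, 1L)
  dn <- shift_clamped(a, axis, -1L)
  si <- slice.index(a, axis)
  denom <- ifelse(si == 1L | si == dm[axis], 1, 2)
  (up - dn) / (denom * step)
}

#' Image gradient by finite differences
#'
#' Central differences in the interior and one-sided differences at the
#' boundary, per axis; units are intensity per physical step (grid step times
#' spacing). Returned as a displacement-field-shaped array `c(dim(image), d)`.
#'
#' @param image numeric matrix or 3-D array.
#' @return gradient array of dim `c(dim(image), length(dim(image)))`.
#' @export
image_gradient <- function(image) {
  shape <- dim(image)
  d <- length(shape)
  sp <- image_spacing(image)
  out <- array(0, dim = c(shape, d))
  flat <- prod(shape)
  for (k in seq_len(d))
    out[seq_len(flat) + (k - 1L) * flat] <- axis_derivative(image, k, sp[k])
  out
}

#' Discrete Jacobian determinants of a deformation
#'
#' For the transform `T(p) = p + u(p)` the Jacobian at each grid point is
#' `det(I + Du)` with the displacement derivatives `Du` taken by central
#' differences (one-sided at boundaries) in grid units. The identity field
#' yields exactly 1 everywhere; negative values flag folding of the grid.
#'
#' @param field displacement field array of dim `c(shape, d)`.
#' @return array of per-point determinants with the grid's shape.
#' @export
#' @examples
#' u <- displacement_field(shape = c(8, 8))
#' all(jacobian_determinants(u) == 1)
jacobian_determinants <- function(field) {
  shape <- field_shape(field)
  d <- field_ndim(field)
  flat <- prod(shape)
  # J[[k]][[l]] = d u_k / d x_l  (+ identity on the diagonal), flattened
  J <- vector("list", d)
  for (k in seq_len(d)) {
    comp <- array(field[seq_len(flat) + (k - 1L) * flat], dim = shape)
    J[[k]] <- vector("list", d)
    for (l in seq_len(d)) {
      der <- as.vector(axis_derivative(comp, l, 1))
      if (k == l) der <- der + 1
      J[[k]][[l]] <- der
    }
  }
  det_flat <-
    if (d == 2L) {
      J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
    } else {
      J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
      J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
      J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
    }
  array(det_flat, dim = shape)
}

#' Fraction of grid points with a negative Jacobian determinant
#'
#' The standard topology diagnostic: the share of grid points at which the
#' deformation folds over itself (determinant < 0). Zero means the discrete
#' transform is topology preserving.
#'
#' @param jac array of Jacobian determinants (from [jacobian_determinants()]).
#' @return fraction in `[0, 1]`.
#' @export
negative_jacobian_fraction <- function(jac) {
  if (!all(is.finite(jac))) stop("Jacobian determinants must be finite")
  mean(jac < 0)
}

#' Read and write images and displacement fields as NIfTI
#'
#' Thin wrappers around the RNifti reader/writer. Images round-trip as plain
#' arrays with a `spacing` attribute taken from the NIfTI pixel dimensions.
#' Displacement fields are stored as multi-component volumes whose last
#' dimension indexes vector components.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_image` returns an image array; `read_field` a field array.
#' @export
read_image <- function(path) {
  nii <- RNifti::readNifti(path)
  a <- array(as.numeric(nii), dim = dim(nii))
  sp <- tryCatch(RNifti::pixdim(nii)[seq_along(dim(a))],
                 error = function(e) rep(1, length(dim(a))))
  if (length(sp) == length(dim(a)) && all(is.finite(sp)) && all(sp > 0))
    attr(a, "spacing") <- as.numeric(sp)
  a
}

#' @rdname read_image
#' @param image image array to write.
#' @export
write_image <- function(image, path) {
  a <- array(as.numeric(image), dim = dim(image))
  nii <- RNifti::asNifti(a)
  RNifti::pixdim(nii) <- image_spacing(image)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_field <- function(path) {
  nii <- RNifti::readNifti(path)
  a <- array(as.numeric(nii), dim = dim(nii))
  displacement_field(a)
}

#' @rdname read_image
#' @param field displacement field array to write.
#' @export
write_field <- function(field, path) {
  a <- array(as.numeric(field), dim = dim(field))
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}
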