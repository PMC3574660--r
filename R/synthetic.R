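# Synthetic phantoms, ground-truth smooth warps and registration pairs.
#
# The generators stand in for skull-stripped, affinely normalized brain MRI:
# nested smooth structures with distinct intensity plateaus (a head-like
# outline with subcortical-like inner blobs), plus smooth random ground-truth
# deformations against which a recovered field can be scored. They do not
# emulate bias fields, Rician noise or partial-volume effects.

# Evaluate 'code' under a temporary RNG state seeded with 'seed', restoring
# the caller's stream afterwards, so all generators are pure in their spec.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Parameters of the synthetic "brain-like" phantom: nested smooth blobs
#' (ellipses perturbed by low-order radial harmonics) with one intensity
#' plateau per structure, edge smoothing so the image bears gradients, and
#' optional additive Gaussian noise.
#'
#' @param shape grid dimensions (2-D), default `c(64, 64)`.
#' @param n_structures number of nested structures (default 3).
#' @param intensity_levels one intensity per structure, outermost first;
#'   background is 0. Default `c(0.4, 0.7, 1.0)` on a unit scale.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   unit intensity scale (default 0.01, a mild acquisition-noise level).
#' @param edge_sigma Gaussian smoothing of the piecewise-constant image so
#'   that structure borders carry gradients (default 1 px).
#' @param seed integer RNG seed.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(64L, 64L), n_structures = 3L,
                         intensity_levels = NULL, noise_sigma = 0.01,
                         edge_sigma = 1.0, seed = 0L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 16L))
    stop("phantoms are 2-D with every dimension >= 16")
  if (is.null(intensity_levels))
    intensity_levels <- seq(0.4, 1.0, length.out = n_structures)
  if (length(intensity_levels) != n_structures)
    stop("'intensity_levels' must have one entry per structure")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  structure(list(shape = shape, n_structures = as.integer(n_structures),
                 intensity_levels = as.numeric(intensity_levels),
                 noise_sigma = noise_sigma, edge_sigma = edge_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Ground-truth warp specification
#'
#' Parameters of the smooth random deformation: a white-noise vector field
#' smoothed by a Gaussian of standard deviation `smoothness_sigma_px` and
#' rescaled so the maximal vector magnitude equals `amplitude_px`. Requiring
#' `amplitude_px <= smoothness_sigma_px` keeps the field's spatial derivatives
#' well below 1, so generated warps have everywhere-positive Jacobians.
#'
#' @param shape grid dimensions.
#' @param amplitude_px maximal displacement magnitude in pixels (default 3).
#' @param smoothness_sigma_px Gaussian smoothing scale in pixels (default 8).
#' @param seed integer RNG seed.
#' @return list of class `"warp_spec"`.
#' @export
warp_spec <- function(shape = c(64L, 64L), amplitude_px = 3,
                      smoothness_sigma_px = 8, seed = 0L) {
  shape <- as.integer(shape)
  if (amplitude_px < 0) stop("'amplitude_px' must be >= 0")
  if (smoothness_sigma_px <= 0) stop("'smoothness_sigma_px' must be > 0")
  if (amplitude_px > smoothness_sigma_px)
    stop("'amplitude_px' must not exceed 'smoothness_sigma_px' ",
         "(keeps Jacobian determinants positive)")
  structure(list(shape = shape, amplitude_px = amplitude_px,
                 smoothness_sigma_px = smoothness_sigma_px,
                 seed = as.integer(seed)),
            class = "warp_spec")
}

#' Generate a brain-like phantom and its label map
#'
#' Builds `n_structures` nested blobs around the grid centre. Each structure
#' boundary is an anisotropic ellipse whose radius is modulated by random
#' low-order angular harmonics (orders 2-4, relative amplitude <= 12%);
#' nesting is enforced by capping each boundary at 88% of its parent. The
#' image assigns `intensity_levels[k]` inside structure k (deepest structure
#' wins), smooths edges with `edge_sigma` and adds Gaussian noise. Labels
#' 1..n mark the (unsmoothed) structures, 0 the background. Deterministic
#' given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (numeric array) and `labels` (integer array).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    n <- spec$n_structures
    centre <- (shape + 1) / 2
    coords <- grid_coords(shape)
    dx <- coords[, 1] - centre[1]
    dy <- coords[, 2] - centre[2]
    base_r <- 0.42 * min(shape) * seq(1, 0.35, length.out = n)
    if (min(base_r) < 3)
      stop("innermost structure would not fit the grid; reduce n_structures")
    theta <- atan2(dy, dx)
    labels <- integer(prod(shape))
    prev_boundary <- NULL
    for (k in seq_len(n)) {
      aniso <- stats::runif(2, 0.85, 1.15)
      harm <- rep(0, length(theta))
      for (m in 2:4)
        harm <- harm + stats::runif(1, -0.04, 0.04) *
          cos(m * theta + stats::runif(1, 0, 2 * pi))
      r_eff <- sqrt((dx / aniso[1])^2 + (dy / aniso[2])^2)
      boundary <- base_r[k] * (1 + 3 * harm)
      if (!is.null(prev_boundary)) boundary <- pmin(boundary, 0.88 * prev_boundary)
      inside <- r_eff <= boundary
      labels[inside] <- k
      prev_boundary <- boundary
    }
    img <- numeric(prod(shape))
    for (k in seq_len(n)) img[labels >= k] <- spec$intensity_levels[k]
    img <- array(img, dim = shape)
    img <- gaussian_smooth(img, spec$edge_sigma)
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(prod(shape), 0, spec$noise_sigma),
                         dim = shape)
    list(image = img, labels = array(as.integer(labels), dim = shape))
  })
}

#' Generate a smooth random displacement field
#'
#' White-noise components smoothed with a Gaussian of the spec's smoothness
#' scale, then rescaled so the maximal vector magnitude equals the spec's
#' amplitude (a zero amplitude yields the zero field). Deterministic given
#' the seed.
#'
#' @param spec a [warp_spec()].
#' @return displacement field of dim `c(shape, length(shape))`.
#' @export
make_smooth_warp <- function(spec = warp_spec()) {
  stopifnot(inherits(spec, "warp_spec"))
  with_seed(spec$seed, {
    shape <- spec$shape
    d <- length(shape)
    flat <- prod(shape)
    u <- array(stats::rnorm(flat * d), dim = c(shape, d))
    for (k in seq_len(d)) {
      comp <- array(u[seq_len(flat) + (k - 1L) * flat], dim = shape)
      u[seq_len(flat) + (k - 1L) * flat] <-
        gaussian_smooth(comp, spec$smoothness_sigma_px)
    }
    mags <- sqrt(rowSums(matrix(u, ncol = d)^2))
    m <- max(mags)
    if (spec$amplitude_px == 0 || m == 0) return(array(0, dim = c(shape, d)))
    u * (spec$amplitude_px / m)
  })
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `w` with `w(p) = -u(p + w(p))`, so that warping first by `w` and then
#' by `u` returns (approximately) to the start. Converges for smooth fields
#' whose spatial derivatives are below 1 in magnitude, which the synthetic
#' warp generator guarantees.
#'
#' @param field displacement field.
#' @param n_iter fixed-point iterations (default 30).
#' @return the approximate inverse field.
#' @export
invert_field <- function(field, n_iter = 30L) {
  shape <- field_shape(field)
  d <- field_ndim(field)
  flat <- prod(shape)
  base <- grid_coords(shape)
  w <- array(0, dim = dim(field))
  comps <- lapply(seq_len(d), function(k)
    array(field[seq_len(flat) + (k - 1L) * flat], dim = shape))
  for (it in seq_len(n_iter)) {
    coords <- base + matrix(w, ncol = d)
    for (k in seq_len(d))
      w[seq_len(flat) + (k - 1L) * flat] <- -interp_linear(comps[[k]], coords)
  }
  w
}

#' Generate a template/target pair with known ground truth
#'
#' The target is the phantom itself; the ground-truth field is a smooth random
#' warp; the template is the phantom resampled through the (fixed-point)
#' inverse of the truth field, so that warping the template by the truth field
#' reproduces the target: the field recovered by [meshreg()] should match the
#' returned `truth_field` directly. Labels are returned in both spaces:
#' `target_labels` are the phantom's labels and `template_labels` their
#' pull-back onto the template grid.
#'
#' @param phantom a [phantom_spec()].
#' @param warp a [warp_spec()] on the same grid.
#' @return list with `template`, `target`, `truth_field`, `template_labels`,
#'   `target_labels`.
#' @export
make_registration_pair <- function(phantom = phantom_spec(),
                                   warp = warp_spec()) {
  if (!identical(as.integer(phantom$shape), as.integer(warp$shape)))
    stop("phantom and warp shapes must agree")
  ph <- make_phantom(phantom)
  truth <- make_smooth_warp(warp)
  inv <- invert_field(truth)
  template <- warp_image(ph$image, inv)
  template_labels <- propagate_labels(ph$labels, inv)
  list(template = template, target = ph$image, truth_field = truth,
       template_labels = template_labels, target_labels = ph$labels)
}
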