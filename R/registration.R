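# Multiresolution registration driver.
#
# The energy being minimized decomposes into an intensity similarity term
# (sum of squared differences) and a spring regularization term; the two are
# minimized alternately. Within each pyramid level the loop is:
#   (a) warp the template with the current field,
#   (b) compute the renormalized optical-flow force v against the target and
#       accumulate the rough field u <- u - v,
#   (c) relax u with a few Jacobi spring sweeps,
# until the SSD stops decreasing or the per-scale iteration cap is hit. The
# field is upsampled (vectors scaled by the resampling factor) between
# levels. After the finest level any residual negative-Jacobian points are
# removed by extra spring sweeps, and if the cross-correlation target is not
# reached the template is re-warped through the current transform and the
# whole pass repeats, composing fields.

#' Registration control parameters
#'
#' Collects every tunable of [meshreg()] with its default. Defaults follow
#' the method's standard operating point: resampling factor 2 between
#' pyramid levels, ten iterations per scale, three spring sweeps per
#' iteration, stopping parameter `alpha = 1.2`, and at most three template
#' updates.
#'
#' @param resample_factor integer pyramid downsampling factor (>= 2).
#' @param min_coarse_dim smallest allowed dimension at the coarsest pyramid
#'   level.
#' @param iters_per_scale iteration cap within one pyramid level.
#' @param relax_iters spring (Jacobi) sweeps per iteration, in `[1, 10]`.
#' @param alpha stopping-rule parameter of the cross-correlation target.
#' @param max_template_updates upper limit on template re-warping passes.
#' @param cc_rule `"literal"` applies the affine rule
#'   `(1 - cc0) * alpha + cc0` clamped at 0.999 (unclamped it exceeds 1 for
#'   any `cc0 < 1` when `alpha > 1`); `"fractional_gap"` closes `1/alpha` of
#'   the remaining gap: `cc0 + (1 - cc0)/alpha`.
#' @param renormalized_force use the renormalized optical-flow denominator
#'   (default `TRUE`).
#' @param ssd_rel_tol relative SSD decrease below which a scale is declared
#'   converged.
#' @param posthoc_sweeps spring sweeps per post-hoc Jacobian-correction round.
#' @param posthoc_rounds maximal number of correction rounds.
#' @param seed integer recorded in reports; the registration itself is
#'   deterministic.
#' @return a list of class `"meshreg_control"`.
#' @export
meshreg_control <- function(resample_factor = 2L,
                            min_coarse_dim = 32L,
                            iters_per_scale = 10L,
                            relax_iters = 3L,
                            alpha = 1.2,
                            max_template_updates = 3L,
                            cc_rule = c("literal", "fractional_gap"),
                            renormalized_force = TRUE,
                            ssd_rel_tol = 1e-4,
                            posthoc_sweeps = 3L,
                            posthoc_rounds = 3L,
                            seed = 0L) {
  cc_rule <- match.arg(cc_rule)
  if (resample_factor < 2L) stop("'resample_factor' must be >= 2")
  if (iters_per_scale < 1L) stop("'iters_per_scale' must be >= 1")
  if (relax_iters < 1L || relax_iters > 10L)
    stop("'relax_iters' must be in [1, 10]")
  if (alpha <= 0) stop("'alpha' must be positive")
  if (max_template_updates < 0L) stop("'max_template_updates' must be >= 0")
  structure(list(resample_factor = as.integer(resample_factor),
                 min_coarse_dim = as.integer(min_coarse_dim),
                 iters_per_scale = as.integer(iters_per_scale),
                 relax_iters = as.integer(relax_iters),
                 alpha = alpha,
                 max_template_updates = as.integer(max_template_updates),
                 cc_rule = cc_rule,
                 renormalized_force = isTRUE(renormalized_force),
                 ssd_rel_tol = ssd_rel_tol,
                 posthoc_sweeps = as.integer(posthoc_sweeps),
                 posthoc_rounds = as.integer(posthoc_rounds),
                 seed = as.integer(seed)),
            class = "meshreg_control")
}

#' Separable Gaussian smoothing with replicate borders
#'
#' @param a numeric array.
#' @param sigma kernel standard deviation in grid units; `sigma <= 0` returns
#'   the input unchanged.
#' @return smoothed array of the same shape.
#' @export
gaussian_smooth <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  out <- a
  for (axis in seq_along(dim(a))) {
    acc <- array(0, dim = dim(a))
    for (s in seq(-r, r))
      acc <- acc + w[s + r + 1L] * shift_clamped(out, axis, s)
    out <- acc
  }
  out
}

# Smooth (anti-alias) then subsample every factor-th grid point.
downsample_image <- function(image, factor) {
  sm <- gaussian_smooth(image, 0.5 * factor)
  idx <- lapply(dim(image), function(n) seq(1L, n, by = factor))
  out <- do.call(`[`, c(list(sm), idx, list(drop = FALSE)))
  attr(out, "spacing") <- image_spacing(image) * factor
  out
}

#' Multiresolution image pyramid
#'
#' Repeatedly Gaussian-smooths (sigma = half the factor) and subsamples the
#' image until any dimension of the next level would fall below
#' `min_coarse_dim`. The finest level is the original image; levels are
#' ordered coarse to fine.
#'
#' @param image numeric matrix or 3-D array.
#' @param control a [meshreg_control()] (only `resample_factor` and
#'   `min_coarse_dim` are used).
#' @return list of images, coarsest first.
#' @export
#' @examples
#' length(build_pyramid(matrix(0, 256, 256)))  # levels 32, 64, 128, 256
build_pyramid <- function(image, control = meshreg_control()) {
  f <- control$resample_factor
  levels <- list(image)
  cur <- image
  repeat {
    next_dims <- ceiling(dim(cur) / f)
    if (any(next_dims < control$min_coarse_dim)) break
    cur <- downsample_image(cur, f)
    levels <- c(list(cur), levels)
  }
  levels
}

#' Cross-correlation stopping threshold
#'
#' Converts the initial cross-correlation `cc0` between the images into the
#' target value the deformed template must reach. The `"literal"` rule is
#' the affine form `(1 - cc0) * alpha + cc0`, clamped at 0.999
#' because for `alpha > 1` the raw value exceeds 1 whenever `cc0 < 1`;
#' `"fractional_gap"` instead closes a `1/alpha` fraction of the remaining
#' gap to perfect correlation: `cc0 + (1 - cc0)/alpha`.
#'
#' @param cc0 initial cross-correlation in `[-1, 1]`.
#' @param alpha positive rule parameter (default 1.2).
#' @param rule `"literal"` or `"fractional_gap"`.
#' @return the target correlation.
#' @export
cc_threshold <- function(cc0, alpha = 1.2,
                         rule = c("literal", "fractional_gap")) {
  rule <- match.arg(rule)
  if (alpha <= 0) stop("'alpha' must be positive")
  switch(rule,
         literal = min((1 - cc0) * alpha + cc0, 0.999),
         fractional_gap = cc0 + (1 - cc0) / alpha)
}

#' Upsample a displacement field to a finer grid
#'
#' Vector components are multiplied by the resampling factor (a displacement
#' of c grid units at the coarse scale spans `factor * c` fine grid units) and
#' each component is linearly interpolated onto the fine grid, sampling the
#' coarse field at `fine_coordinate / factor` (0-based), clamped at the
#' domain border.
#'
#' @param field coarse displacement field.
#' @param new_shape fine grid dimensions.
#' @param factor resampling factor between the grids.
#' @return field of dim `c(new_shape, d)`.
#' @export
upsample_field <- function(field, new_shape, factor) {
  new_shape <- as.integer(new_shape)
  d <- field_ndim(field)
  shape <- field_shape(field)
  coords <- grid_coords(new_shape)       # 1-based fine coordinates
  coarse <- (coords - 1) / factor + 1    # 0-based scaling, back to 1-based
  flat <- prod(shape)
  out <- array(0, dim = c(new_shape, d))
  nflat <- prod(new_shape)
  for (k in seq_len(d)) {
    comp <- array(field[seq_len(flat) + (k - 1L) * flat], dim = shape)
    out[seq_len(nflat) + (k - 1L) * nflat] <-
      factor * interp_linear(comp, coarse)
  }
  out
}

#' Compose two displacement fields
#'
#' Returns the field of the composite transform "apply inner, then outer" in
#' the pull-back convention used by [warp_image()]:
#' `u(p) = u_outer(p) + u_inner(p + u_outer(p))`, with linear interpolation of
#' the inner field. Used when a template updated through `u_inner` is
#' registered again, producing `u_outer`.
#'
#' @param field_outer,field_inner displacement fields on the same grid.
#' @return composed field.
#' @export
compose_fields <- function(field_outer, field_inner) {
  check_same_shape(field_outer, field_inner, "fields")
  shape <- field_shape(field_outer)
  d <- field_ndim(field_outer)
  coords <- grid_coords(shape) + matrix(field_outer, ncol = d)
  flat <- prod(shape)
  out <- array(0, dim = dim(field_outer))
  for (k in seq_len(d)) {
    comp <- array(field_inner[seq_len(flat) + (k - 1L) * flat], dim = shape)
    out[seq_len(flat) + (k - 1L) * flat] <-
      field_outer[seq_len(flat) + (k - 1L) * flat] + interp_linear(comp, coords)
  }
  out
}

#' Single-scale alternating minimization
#'
#' Runs the similarity/regularization loop at one pyramid level: warp the
#' template with the current field, add the negated optical-flow force, relax
#' with spring sweeps, and stop when the relative SSD decrease falls below
#' `control$ssd_rel_tol` or `control$iters_per_scale` is reached. An update
#' that increases the SSD is rolled back (the previous field is kept), so the
#' recorded per-scale SSD trace is non-increasing.
#'
#' @param template,target images at this level (same shape).
#' @param init_field starting displacement field for this level.
#' @param mesh [spring_mesh()] over this level's grid.
#' @param control a [meshreg_control()].
#' @return list with `field`, and the per-iteration `ssd` and `cc` traces.
#' @export
register_one_scale <- function(template, target, init_field, mesh,
                               control = meshreg_control()) {
  check_same_shape(template, target, "images")
  u <- init_field
  u_prev <- u
  ssd_trace <- numeric(0)
  cc_trace <- numeric(0)
  prev_ssd <- Inf
  for (it in seq_len(control$iters_per_scale)) {
    warped <- warp_image(template, u)
    cur_ssd <- ssd(warped, target)
    if (!is.finite(cur_ssd))
      stop("non-finite similarity encountered at iteration ", it,
           "; the force field has diverged")
    if (cur_ssd > prev_ssd) {      # overshoot: keep the previous (best) field
      u <- u_prev
      break
    }
    ssd_trace <- c(ssd_trace, cur_ssd)
    cc_trace <- c(cc_trace, tryCatch(cross_correlation(warped, target),
                                     error = function(e) NA_real_))
    if (is.finite(prev_ssd) &&
        (prev_ssd - cur_ssd) < control$ssd_rel_tol * max(prev_ssd, .Machine$double.eps))
      break
    prev_ssd <- cur_ssd
    u_prev <- u
    v <- optical_flow_velocity(warped, target, control$renormalized_force)
    u <- u - v                              # displacement increment is -v
    u <- spring_relax(u, mesh, n_iter = control$relax_iters)
  }
  list(field = u, ssd = ssd_trace, cc = cc_trace)
}

# One full coarse-to-fine pass over the pyramids; returns the pass field and
# the concatenated traces.
run_pyramid_pass <- function(pyr_template, pyr_target, control, pass_id) {
  n_levels <- length(pyr_template)
  u <- NULL
  trace <- list()
  for (lev in seq_len(n_levels)) {
    tpl <- pyr_template[[lev]]
    tgt <- pyr_target[[lev]]
    shape <- dim(tgt)
    u <- if (is.null(u)) displacement_field(shape = shape)
         else upsample_field(u, shape, control$resample_factor)
    mesh <- build_mesh(shape)
    res <- register_one_scale(tpl, tgt, u, mesh, control)
    u <- res$field
    trace[[lev]] <- data.frame(pass = pass_id, scale = lev,
                               iteration = seq_along(res$ssd),
                               ssd = res$ssd, cc = res$cc)
  }
  list(field = u, trace = do.call(rbind, trace))
}

#' Topology-preserving nonrigid registration
#'
#' Estimates the dense displacement field `u` (transform `T(p) = p + u(p)`)
#' that deforms `template` onto `target` by alternating a renormalized
#' optical-flow similarity force with spring-analogy mesh regularization in a
#' coarse-to-fine multiresolution scheme. After the finest level, residual
#' grid folds (negative Jacobian determinants) are removed by additional
#' spring sweeps; if the deformed template's cross-correlation with the
#' target still falls short of the [cc_threshold()] target, the template is
#' re-warped through the current transform and registration restarts, the
#' fields being composed (up to `max_template_updates` times).
#'
#' The template's intensities are first remapped onto the target's by
#' histogram matching. Inputs are assumed spatially pre-aligned (rigid or
#' affine normalization is upstream of this package).
#'
#' @param template moving image (matrix or 3-D array).
#' @param target fixed image of the same shape.
#' @param control a [meshreg_control()].
#' @return an object of class `"meshreg"`: a list with the displacement
#'   `field`, `fitted` (deformed matched template), `trace` (per-iteration
#'   SSD/CC data frame), `cc0`, `cc_final`, `cc_target`, `nj_final`,
#'   `n_template_updates`, `scales_used`, `converged`, the matched template,
#'   inputs, `control` and the call. Supports `print`, `summary`, `coef`,
#'   `fitted`, `residuals`, `predict` and `plot`.
#' @seealso [meshreg_control()], [predict.meshreg()], [make_registration_pair()]
#' @export
#' @examples
#' pair <- make_registration_pair(phantom_spec(shape = c(48, 48)),
#'                                warp_spec(shape = c(48, 48), amplitude_px = 2))
#' fit <- meshreg(pair$template, pair$target,
#'                meshreg_control(min_coarse_dim = 24, max_template_updates = 1))
#' fit$nj_final
meshreg <- function(template, target, control = meshreg_control()) {
  if (length(dim(template)) != length(dim(target)))
    stop("template and target dimensionality differ")
  check_same_shape(template, target, "template and target")
  cl <- match.call()
  shape <- dim(target)

  matched <- histogram_match(template, target)
  cc0 <- tryCatch(cross_correlation(matched, target), error = function(e) NA_real_)
  cc_tgt <- if (is.na(cc0)) NA_real_ else
    cc_threshold(cc0, control$alpha, control$cc_rule)

  pyr_target <- build_pyramid(target, control)
  mesh_full <- build_mesh(shape)
  total_u <- NULL
  traces <- list()
  n_updates <- 0L
  repeat {
    cur_template <- if (is.null(total_u)) matched else warp_image(matched, total_u)
    pass <- run_pyramid_pass(build_pyramid(cur_template, control), pyr_target,
                             control, pass_id = n_updates + 1L)
    traces[[length(traces) + 1L]] <- pass$trace
    total_u <- if (is.null(total_u)) pass$field
               else compose_fields(pass$field, total_u)
    # post-hoc topology correction
    round <- 0L
    while (negative_jacobian_fraction(jacobian_determinants(total_u)) > 0 &&
           round < control$posthoc_rounds) {
      total_u <- spring_relax(total_u, mesh_full, n_iter = control$posthoc_sweeps)
      round <- round + 1L
    }
    deformed <- warp_image(matched, total_u)
    cc_final <- tryCatch(cross_correlation(deformed, target),
                         error = function(e) NA_real_)
    reached <- !is.na(cc_final) && !is.na(cc_tgt) && cc_final >= cc_tgt
    if (reached || n_updates >= control$max_template_updates) break
    n_updates <- n_updates + 1L
  }

  structure(list(
    field = total_u,
    fitted = deformed,
    trace = do.call(rbind, traces),
    cc0 = cc0,
    cc_final = cc_final,
    cc_target = cc_tgt,
    nj_final = negative_jacobian_fraction(jacobian_determinants(total_u)),
    n_template_updates = n_updates,
    scales_used = length(pyr_target),
    converged = reached,
    template = template,
    matched_template = matched,
    target = target,
    control = control,
    call = cl), class = "meshreg")
}
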