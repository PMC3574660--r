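test_that("pyramid level arithmetic follows the halving rule", {
  ctrl <- meshreg_control()
  pyr <- build_pyramid(matrix(0, 256, 256), ctrl)
  expect_identical(length(pyr), 4L)
  expect_identical(lapply(pyr, dim),
                   list(c(32L, 32L), c(64L, 64L), c(128L, 128L), c(256L, 256L)))
  expect_identical(length(build_pyramid(matrix(0, 32, 32), ctrl)), 1L)
  expect_identical(length(build_pyramid(matrix(0, 48, 48), ctrl)), 1L)
  expect_identical(length(build_pyramid(matrix(0, 16, 16), ctrl)), 1L)
})

test_that("downsampling anti-aliases but preserves constants", {
  img <- matrix(4.2, 64, 64)
  pyr <- build_pyramid(img, meshreg_control())
  expect_true(all(abs(pyr[[1]] - 4.2) < 1e-12))
})

test_that("cross-correlation stopping threshold implements both rules", {
  expect_identical(cc_threshold(1, 1.2, "literal"), 0.999)
  expect_identical(cc_threshold(1, 1.2, "fractional_gap"), 1.0)
  # the affine form exceeds 1 before the clamp: (1-0.9)*1.2+0.9 = 1.02
  expect_identical((1 - 0.9) * 1.2 + 0.9, 1.02)
  expect_identical(cc_threshold(0.9, 1.2, "literal"), 0.999)
  expect_equal(cc_threshold(0.9, 1.2, "fractional_gap"), 0.9 + 0.1 / 1.2,
               tolerance = 1e-15)
  expect_equal(cc_threshold(0.5, 0.8, "literal"), 0.9)
  expect_error(cc_threshold(0.5, 0), "positive")
})

test_that("upsampling scales vectors by the resampling factor", {
  u <- constant_field(c(8, 8), c(1.5, -2))
  up <- upsample_field(u, c(16, 16), 2)
  expect_equal(as.vector(up[, , 1]), rep(3, 256), tolerance = 1e-12)
  expect_equal(as.vector(up[, , 2]), rep(-4, 256), tolerance = 1e-12)
})

test_that("field composition handles identities and translations", {
  set.seed(14)
  u <- array(rnorm(6 * 7 * 2, sd = 0.5), c(6, 7, 2))
  z <- displacement_field(shape = c(6, 7))
  expect_equal(compose_fields(u, z), u, tolerance = 1e-12)
  expect_equal(as.vector(compose_fields(z, u)), as.vector(u), tolerance = 1e-12)
  a <- constant_field(c(6, 7), c(0.5, 1))
  b <- constant_field(c(6, 7), c(1, -0.25))
  # interior points compose to the exact sum; border samples are clamped
  comp <- compose_fields(a, b)
  expect_equal(c(comp[3, 3, 1], comp[3, 3, 2]), c(1.5, 0.75), tolerance = 1e-12)
})

test_that("registering an image onto itself returns the zero field", {
  set.seed(15)
  img <- blob_image(c(24, 24)) + matrix(rnorm(24 * 24, sd = 0.01), 24, 24)
  mesh <- build_mesh(c(24, 24))
  res <- register_one_scale(img, img, displacement_field(shape = c(24, 24)),
                            mesh, meshreg_control(min_coarse_dim = 24))
  expect_true(all(res$field == 0))
  expect_true(all(res$ssd == 0))
})

test_that("a one-pixel translation is recovered on a smooth ramp phantom", {
  shape <- c(48, 48)
  target <- array(rep(seq(0, 1, length.out = 48), 48), dim = shape)  # I = x
  template <- warp_image(target, constant_field(shape, c(1, 0)))
  # template(p) = target(p + 1_x), so the minimizing field is u = (-1, 0)
  mesh <- build_mesh(shape)
  res <- register_one_scale(template, target,
                            displacement_field(shape = shape), mesh,
                            meshreg_control(iters_per_scale = 30))
  interior <- array(FALSE, shape); interior[5:44, 5:44] <- TRUE
  u1 <- res$field[, , 1][interior]
  expect_lt(abs(mean(u1) - (-1)), 0.25)
  expect_lt(abs(mean(res$field[, , 2][interior])), 0.25)
  # SSD trace is non-increasing on this fixture
  expect_true(all(diff(res$ssd) <= 0.01 * head(res$ssd, -1)))
})

test_that("pyramid transfer preserves a pure translation", {
  shape <- c(64, 64)
  target <- array(rep(seq(0, 1, length.out = 64), 64), dim = shape)
  template <- warp_image(target, constant_field(shape, c(2, 0)))
  half_t <- meshreg:::downsample_image(template, 2)
  half_b <- meshreg:::downsample_image(target, 2)
  res <- register_one_scale(half_t, half_b,
                            displacement_field(shape = dim(half_b)),
                            build_mesh(dim(half_b)),
                            meshreg_control(iters_per_scale = 30))
  up <- upsample_field(res$field, shape, 2)
  interior <- array(FALSE, shape); interior[9:56, 9:56] <- TRUE
  expect_lt(abs(mean(up[, , 1][interior]) - (-2)), 0.5)
})

test_that("the full driver handles identical inputs and synthetic warps", {
  pair0 <- make_registration_pair(phantom_spec(shape = c(48, 48), seed = 2),
                                  warp_spec(shape = c(48, 48),
                                            amplitude_px = 0, seed = 3))
  fit0 <- meshreg(pair0$template, pair0$target)
  expect_equal(fit0$cc_final, 1.0, tolerance = 1e-12)
  expect_identical(fit0$nj_final, 0)
  expect_identical(fit0$n_template_updates, 0L)
  expect_true(fit0$converged)

  pair <- make_registration_pair(phantom_spec(shape = c(64, 64), seed = 4),
                                 warp_spec(amplitude_px = 3, seed = 5))
  fit <- meshreg(pair$template, pair$target)
  expect_gt(fit$cc_final, fit$cc0)
  expect_identical(fit$nj_final, 0)
  expect_identical(fit$scales_used, 2L)
  expect_s3_class(fit, "meshreg")
})

test_that("registration is deterministic for identical inputs and config", {
  pair <- make_registration_pair(phantom_spec(shape = c(48, 48), seed = 6),
                                 warp_spec(shape = c(48, 48), seed = 7))
  f1 <- meshreg(pair$template, pair$target)
  f2 <- meshreg(pair$template, pair$target)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$trace, f2$trace)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("fit methods expose field, fitted image, residuals and predictions", {
  pair <- make_registration_pair(phantom_spec(shape = c(48, 48), seed = 8),
                                 warp_spec(shape = c(48, 48),
                                           amplitude_px = 2, seed = 9))
  fit <- meshreg(pair$template, pair$target,
                 meshreg_control(max_template_updates = 1))
  expect_identical(dim(coef(fit)), c(48L, 48L, 2L))
  expect_equal(residuals(fit),
               array(pair$target - fitted(fit), dim = c(48, 48)),
               tolerance = 1e-12)
  pred <- predict(fit)
  expect_equal(as.vector(pred), as.vector(fitted(fit)), tolerance = 1e-12)
  lab <- predict(fit, pair$template_labels, type = "labels")
  expect_true(all(lab %in% unique(as.vector(pair$template_labels))))
  expect_output(print(fit), "Nonrigid registration")
  expect_output(print(summary(fit)), "Jacobian")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("control parameters are validated", {
  expect_error(meshreg_control(resample_factor = 1), ">= 2")
  expect_error(meshreg_control(relax_iters = 11), "relax_iters")
  expect_error(meshreg_control(alpha = -1), "positive")
  expect_error(meshreg(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})
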