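test_that("grid meshes have the enumerated vertex/edge/triangle counts", {
  m2 <- build_mesh(c(2, 2))
  expect_identical(nrow(m2$positions), 4L)
  expect_identical(nrow(m2$edges), 5L)   # 4 sides + 1 diagonal
  expect_identical(m2$n_triangles, 2L)
  m3 <- build_mesh(c(3, 3))
  expect_identical(nrow(m3$positions), 9L)
  expect_identical(nrow(m3$edges), 16L)  # 12 axis edges + 4 cell diagonals
  expect_identical(m3$n_triangles, 8L)
  # combinatorial formula: axis edges + one diagonal per cell
  for (shape in list(c(2, 5), c(4, 3), c(7, 6))) {
    m <- build_mesh(shape)
    nr <- shape[1]; nc <- shape[2]
    expect_identical(nrow(m$edges),
                     as.integer((nr - 1) * nc + nr * (nc - 1) +
                                (nr - 1) * (nc - 1)))
    expect_identical(m$n_triangles, as.integer(2 * (nr - 1) * (nc - 1)))
    expect_true(all(m$edges[, 1] != m$edges[, 2]))
  }
  expect_error(build_mesh(c(1, 5)), ">= 2")
})

test_that("interior vertices of a 2-D grid mesh have degree 6", {
  m <- build_mesh(c(5, 6))
  deg <- tabulate(c(m$edges[, 1], m$edges[, 2]), nbins = nrow(m$positions))
  interior <- !grid_boundary_mask(c(5, 6))
  expect_true(all(deg[interior] == 6L))
})

test_that("undeformed stiffness is exactly 1 on axis edges, 1/sqrt(2) on diagonals", {
  m <- build_mesh(c(4, 4))
  len <- sqrt(rowSums((m$positions[m$edges[, 1], ] -
                       m$positions[m$edges[, 2], ])^2))
  expect_identical(unique(m$stiffness[len == 1]), 1)
  expect_identical(unique(m$stiffness[len > 1]), 1 / sqrt(2))
  expect_identical(sort(unique(m$stiffness)), c(1 / sqrt(2), 1))
  # reciprocal-length rule on a stretched edge
  k <- spring_stiffness(rbind(c(0, 0), c(2, 0)), rbind(c(1, 2)))
  expect_identical(k, 0.5)
  expect_warning(spring_stiffness(rbind(c(0, 0), c(0, 0)), rbind(c(1, 2))),
                 "clamped")
})

test_that("constant fields are fixed points of spring relaxation", {
  m <- build_mesh(c(6, 5))
  u <- constant_field(c(6, 5), c(1.7, -0.4))
  out <- spring_relax(u, m, n_iter = 5)
  expect_equal(as.vector(out), as.vector(u), tolerance = 1e-12)
})

test_that("a vertex whose neighbours are fixed at zero relaxes to zero", {
  m <- build_mesh(c(5, 5))
  u <- array(0, c(5, 5, 2))
  u[3, 3, ] <- c(2, -1)
  fixed <- rep(TRUE, 25)
  fixed[3 + 2 * 5] <- FALSE            # only the perturbed vertex is free
  out <- spring_relax(u, m, n_iter = 1, fixed = fixed,
                      dynamic_stiffness = FALSE)
  expect_equal(c(out[3, 3, 1], out[3, 3, 2]), c(0, 0))
  expect_equal(as.vector(out)[-c(13, 38)], as.vector(u)[-c(13, 38)])
})

test_that("a fixed-end chain relaxes to the tridiagonal equilibrium solution", {
  pos <- cbind(0:4, rep(0, 5))
  edges <- cbind(1:4, 2:5)
  chain <- spring_mesh(pos, edges)
  u <- matrix(0, 5, 2)
  u[5, 1] <- 4
  fixed <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  out <- spring_relax(u, chain, n_iter = 500, fixed = fixed,
                      dynamic_stiffness = FALSE)
  direct <- oracle_spring_solve(chain, u, fixed)
  expect_equal(out, direct, tolerance = 1e-8)
  expect_equal(out[, 1], c(0, 1, 2, 3, 4), tolerance = 1e-8)
  # and the converged chain satisfies equilibrium at every free vertex
  res <- equilibrium_residual(out, chain)
  expect_lt(max(res$per_vertex[!fixed]), 1e-8)
})

test_that("frozen-stiffness relaxation converges to the direct linear solve", {
  set.seed(10)
  for (shape in list(c(4, 4), c(6, 5), c(8, 8))) {
    m <- build_mesh(shape)
    u <- array(rnorm(prod(shape) * 2), c(shape, 2))
    fixed <- grid_boundary_mask(shape)
    relaxed <- spring_relax(u, m, n_iter = 3000, fixed = fixed,
                            dynamic_stiffness = FALSE)
    direct <- oracle_spring_solve(m, matrix(u, ncol = 2), fixed)
    expect_lt(max(abs(matrix(relaxed, ncol = 2) - direct)), 1e-6)
  }
})

test_that("frozen-stiffness sweeps obey the discrete maximum principle", {
  set.seed(12)
  m <- build_mesh(c(7, 7))
  for (rep in 1:10) {
    u <- array(rnorm(49 * 2, sd = 3), c(7, 7, 2))
    cur <- u
    for (s in 1:5) {
      nxt <- spring_relax(cur, m, n_iter = 1, dynamic_stiffness = FALSE)
      for (k in 1:2) {
        expect_gte(min(nxt[, , k]), min(cur[, , k]) - 1e-12)
        expect_lte(max(nxt[, , k]), max(cur[, , k]) + 1e-12)
      }
      cur <- nxt
    }
  }
})

test_that("regularization energy is non-increasing across frozen sweeps", {
  m <- build_mesh(c(6, 6))
  fixed <- grid_boundary_mask(c(6, 6))
  for (seed in 1:20) {
    set.seed(seed)
    u <- array(rnorm(36 * 2), c(6, 6, 2))
    e0 <- regularization_energy(u, m)
    cur <- u
    for (s in 1:4) {
      cur <- spring_relax(cur, m, n_iter = 1, fixed = fixed,
                          dynamic_stiffness = FALSE)
      e1 <- regularization_energy(cur, m)
      expect_lte(e1, e0 + 1e-9)
      e0 <- e1
    }
  }
})

test_that("equilibrium residual expands as the hand formula for a point perturbation", {
  m <- build_mesh(c(5, 5))
  delta <- 1.3
  v <- 3 + 2 * 5                        # interior vertex (3, 3)
  u <- matrix(0, 25, 2)
  u[v, 1] <- delta
  res <- equilibrium_residual(u, m)
  nb_edges <- which(m$edges[, 1] == v | m$edges[, 2] == v)
  ksum <- sum(m$stiffness[nb_edges])
  expect_equal(res$per_vertex[v], delta * ksum, tolerance = 1e-12)
  for (e in nb_edges) {
    other <- setdiff(m$edges[e, ], v)
    expect_equal(res$per_vertex[other], m$stiffness[e] * delta,
                 tolerance = 1e-12)
  }
  untouched <- setdiff(seq_len(25), c(v, m$edges[nb_edges, ]))
  expect_true(all(res$per_vertex[untouched] == 0))
  # the energy is the sum of the residual magnitudes by definition
  expect_equal(regularization_energy(u, m), sum(res$per_vertex))
  expect_identical(regularization_energy(matrix(2, 25, 2), m), 0)
})

test_that("3-D grid meshes carry axis edges plus three face diagonals per cell", {
  m <- build_mesh(c(3, 3, 3))
  expect_identical(nrow(m$positions), 27L)
  n <- 3
  axis_edges <- 3 * (n - 1) * n * n
  diag_edges <- 3 * (n - 1) * (n - 1) * n
  expect_identical(nrow(m$edges), as.integer(axis_edges + diag_edges))
  u <- constant_field(c(3, 3, 3), c(1, 0, -2))
  expect_equal(as.vector(spring_relax(u, m, 2)), as.vector(u),
               tolerance = 1e-12)
})
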