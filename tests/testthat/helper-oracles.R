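# Independent brute-force oracles used by the tests. These deliberately use
# naive per-pixel loops so they share no code path with the package.

# Bilinear interpolation of a 2-D image at (x, y), 1-based, edge-clamped.
oracle_bilinear_at <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- min(max(x, 1), nr); y <- min(max(y, 1), nc)
  x0 <- min(floor(x), nr - 1); y0 <- min(floor(y), nc - 1)
  fx <- x - x0; fy <- y - y0
  (1 - fx) * (1 - fy) * img[x0, y0] +
    fx * (1 - fy) * img[x0 + 1, y0] +
    (1 - fx) * fy * img[x0, y0 + 1] +
    fx * fy * img[x0 + 1, y0 + 1]
}

# Per-pixel warp of a 2-D image through a field, bilinear, edge-clamped.
oracle_warp2d <- function(img, field) {
  out <- img * 0
  for (i in seq_len(nrow(img)))
    for (j in seq_len(ncol(img)))
      out[i, j] <- oracle_bilinear_at(img, i + field[i, j, 1], j + field[i, j, 2])
  out
}

# Central/one-sided finite-difference gradient of a 2-D image, per-pixel.
oracle_gradient2d <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  g <- array(0, c(nr, nc, 2))
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      g[i, j, 1] <- if (i == 1) img[2, j] - img[1, j]
                    else if (i == nr) img[nr, j] - img[nr - 1, j]
                    else (img[i + 1, j] - img[i - 1, j]) / 2
      g[i, j, 2] <- if (j == 1) img[i, 2] - img[i, 1]
                    else if (j == nc) img[i, nc] - img[i, nc - 1]
                    else (img[i, j + 1] - img[i, j - 1]) / 2
    }
  g
}

# Per-pixel 2-D Jacobian determinant of T(p) = p + u(p), central/one-sided.
oracle_jacobian2d <- function(field) {
  nr <- dim(field)[1]; nc <- dim(field)[2]
  d1 <- oracle_gradient2d(field[, , 1])
  d2 <- oracle_gradient2d(field[, , 2])
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- (1 + d1[i, j, 1]) * (1 + d2[i, j, 2]) -
                   d1[i, j, 2] * d2[i, j, 1]
  out
}

# Direct dense solve of the spring equilibrium system with fixed vertices and
# frozen stiffness: for free vertices, deg_i u_i - sum_j k_ij u_j = boundary.
oracle_spring_solve <- function(mesh, u_matrix, fixed) {
  nv <- nrow(mesh$positions)
  W <- matrix(0, nv, nv)
  for (e in seq_len(nrow(mesh$edges))) {
    a <- mesh$edges[e, 1]; b <- mesh$edges[e, 2]
    W[a, b] <- W[a, b] + mesh$stiffness[e]
    W[b, a] <- W[b, a] + mesh$stiffness[e]
  }
  deg <- rowSums(W)
  free <- !fixed
  L <- diag(deg[free], sum(free)) - W[free, free, drop = FALSE]
  rhs <- W[free, fixed, drop = FALSE] %*% u_matrix[fixed, , drop = FALSE]
  out <- u_matrix
  out[free, ] <- solve(L, rhs)
  out
}

# Count 4-connected components of a logical 2-D mask (BFS flood fill).
oracle_components2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- !mask
  n <- 0L
  for (start in which(mask)) {
    if (seen[start]) next
    n <- n + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      i <- (p - 1) %% nr + 1; j <- (p - 1) %/% nr + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > nr || nb[2] < 1 || nb[2] > nc) next
        q <- nb[1] + (nb[2] - 1) * nr
        if (!seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  n
}

# Boundary-vertex mask for a grid mesh.
grid_boundary_mask <- function(shape) {
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  apply(idx, 1, function(p) any(p == 1 | p == shape))
}

# A smooth radially symmetric blob image bearing gradients everywhere inside.
blob_image <- function(shape, radius_frac = 0.35) {
  centre <- (shape + 1) / 2
  co <- arrayInd(seq_len(prod(shape)), .dim = shape)
  r <- sqrt((co[, 1] - centre[1])^2 + (co[, 2] - centre[2])^2)
  array(exp(-(r / (radius_frac * min(shape)))^2), dim = shape)
}

# Constant displacement field over a grid.
constant_field <- function(shape, vec) {
  d <- length(vec)
  u <- array(0, dim = c(shape, d))
  for (k in seq_len(d)) u[slice.index(u, d + 1) == k] <- vec[k]
  u
}
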