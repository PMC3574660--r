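# Spring-analogy mesh regularization.
#
# The pixel grid is covered by a triangular mesh with one vertex per grid
# point: every unit cell is split into two triangles along the same diagonal,
# so interior 2-D vertices have degree 6 (4 axis + 2 diagonal neighbours).
# Each edge is a linear spring with Batina stiffness k_ij = 1 / |x_j - x_i|
# (inversely proportional to edge length), which penalizes vertex collision.
# Regularization relaxes a displacement field toward spring equilibrium
# F_i = sum_j k_ij (u_j - u_i) = 0 by Jacobi sweeps
# u_i <- sum_j k_ij u_j / sum_j k_ij: each vertex moves to the
# stiffness-weighted average of its neighbours' displacements.

#' Construct a spring mesh from explicit vertices and edges
#'
#' @param positions numeric matrix of vertex coordinates (grid units), one
#'   row per vertex.
#' @param edges two-column integer matrix of undirected edges (vertex row
#'   indices); no self-edges.
#' @param shape optional grid dimensions when vertices correspond one-to-one
#'   (column-major) with grid points.
#' @param n_triangles optional triangle count (bookkeeping only).
#' @return object of class `"spring_mesh"` with elements `positions`,
#'   `edges`, `stiffness`, `shape`, `n_triangles`.
#' @export
spring_mesh <- function(positions, edges, shape = NULL, n_triangles = NA_integer_) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) == 0L) stop("mesh must have at least one edge")
  if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
  if (any(edges < 1L) || any(edges > nrow(positions)))
    stop("edge indices out of range")
  if (!is.null(shape) && prod(shape) != nrow(positions))
    stop("vertex count must equal the grid point count")
  structure(
    list(positions = positions, edges = edges,
         stiffness = spring_stiffness(positions, edges),
         shape = if (is.null(shape)) NULL else as.integer(shape),
         n_triangles = as.integer(n_triangles)),
    class = "spring_mesh")
}

#' @export
print.spring_mesh <- function(x, ...) {
  cat("Spring mesh:", nrow(x$positions), "vertices,", nrow(x$edges), "edges")
  if (!is.na(x$n_triangles)) cat(",", x$n_triangles, "triangles")
  if (!is.null(x$shape)) cat(" on a ", paste(x$shape, collapse = "x"), " grid", sep = "")
  cat("\n")
  invisible(x)
}

#' Triangular mesh over a pixel grid
#'
#' One vertex per grid point at integer (0-based) coordinates. In 2-D every
#' unit cell is split into two triangles along the `(i,j) - (i+1,j+1)`
#' diagonal, so the edge set is all axis edges plus one diagonal per cell and
#' interior vertices have degree 6. In 3-D the edge set is the 6-connected
#' axis graph plus the three analogous face diagonals per cell, in fixed
#' orientation. Stiffness is initialized from the undeformed edge lengths.
#'
#' @param shape grid dimensions (each entry at least 2), length 2 or 3.
#' @return a [spring_mesh()] object.
#' @export
#' @examples
#' m <- build_mesh(c(3, 3))
#' nrow(m$edges)  # 16: 12 axis edges + 4 cell diagonals
build_mesh <- function(shape) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (!(d %in% c(2L, 3L))) stop("mesh grids must be 2-D or 3-D")
  if (any(shape < 2L)) stop("every grid dimension must be >= 2")
  nv <- prod(shape)
  positions <- grid_coords(shape) - 1  # 0-based grid coordinates
  strides <- cumprod(c(1L, shape[-d]))
  idx <- array(seq_len(nv), dim = shape)

  sub_block <- function(drop_axes) {
    # linear indices of vertices with room for +1 along each axis in drop_axes
    keep <- lapply(seq_len(d), function(k)
      if (k %in% drop_axes) seq_len(shape[k] - 1L) else seq_len(shape[k]))
    as.vector(do.call(`[`, c(list(idx), keep, list(drop = FALSE))))
  }

  edge_list <- list()
  for (k in seq_len(d)) {                 # axis edges
    a <- sub_block(k)
    edge_list[[length(edge_list) + 1L]] <- cbind(a, a + strides[k])
  }
  pairs <- utils::combn(d, 2)             # one fixed diagonal per cell face
  for (c_ in seq_len(ncol(pairs))) {
    ax <- pairs[, c_]
    a <- sub_block(ax)
    edge_list[[length(edge_list) + 1L]] <-
      cbind(a, a + strides[ax[1]] + strides[ax[2]])
  }
  edges <- do.call(rbind, edge_list)
  n_tri <- if (d == 2L) 2L * prod(shape - 1L) else NA_integer_
  spring_mesh(positions, edges, shape = shape, n_triangles = n_tri)
}

#' Batina spring stiffness
#'
#' Per-edge stiffness inversely proportional to edge length:
#' `k_ij = 1 / max(|x_j - x_i|, eps)`. Unit axis edges get stiffness 1,
#' unit-cell diagonals `1/sqrt(2)`. Near-coincident adjacent vertices are
#' clamped at `eps` with a warning.
#'
#' @param positions vertex coordinate matrix.
#' @param edges two-column edge matrix.
#' @param eps minimal edge length before clamping (grid units).
#' @return numeric vector of positive stiffnesses, one per edge.
#' @export
spring_stiffness <- function(positions, edges, eps = 1e-6) {
  dvec <- positions[edges[, 1], , drop = FALSE] -
          positions[edges[, 2], , drop = FALSE]
  len <- sqrt(rowSums(dvec^2))
  if (any(len < eps))
    warning(sum(len < eps), " edge(s) shorter than ", eps,
            " grid units; stiffness clamped")
  1 / pmax(len, eps)
}

# Internal: coerce a grid-shaped field or an nv x d matrix to nv x d.
field_as_matrix <- function(field, mesh) {
  nv <- nrow(mesh$positions)
  if (is.matrix(field) && nrow(field) == nv &&
      ncol(field) == ncol(mesh$positions)) return(field)
  if (is.null(mesh$shape))
    stop("grid-shaped fields need a mesh built over a grid")
  if (!identical(as.integer(field_shape(field)), mesh$shape))
    stop("field shape does not match the mesh grid")
  matrix(field, ncol = field_ndim(field))
}

# Sparse symmetric weight matrix of the mesh for a given stiffness vector.
mesh_weights <- function(mesh, stiffness) {
  nv <- nrow(mesh$positions)
  Matrix::sparseMatrix(i = c(mesh$edges[, 1], mesh$edges[, 2]),
                       j = c(mesh$edges[, 2], mesh$edges[, 1]),
                       x = c(stiffness, stiffness), dims = c(nv, nv))
}

#' Jacobi spring relaxation of a displacement field
#'
#' Runs `n_iter` simultaneous (Jacobi) sweeps of the spring equilibrium
#' update: every non-fixed vertex's displacement is replaced by the
#' stiffness-weighted average of its neighbours' displacements from the
#' previous sweep. By default the stiffness is recomputed before each sweep
#' from the current vertex positions `x0 + u` (the mesh moves with the
#' deformation); `dynamic_stiffness = FALSE` freezes the stiffness at the
#' mesh's stored values, in which case each sweep is one Jacobi iteration of
#' the linear equilibrium system.
#'
#' With frozen stiffness every sweep is a convex combination per vertex, so
#' componentwise min/max bounds of the field never expand.
#'
#' @param field displacement field array over the mesh grid (or an
#'   `n_vertices x d` matrix for hand-built meshes).
#' @param mesh a [spring_mesh()].
#' @param n_iter number of sweeps (>= 1).
#' @param fixed optional logical mask (grid-shaped array, or vector of length
#'   `n_vertices`) of vertices that keep their input displacement.
#' @param dynamic_stiffness recompute stiffness from deformed positions
#'   before each sweep (default `TRUE`).
#' @return relaxed field in the same form as the input.
#' @export
spring_relax <- function(field, mesh, n_iter = 3L, fixed = NULL,
                         dynamic_stiffness = TRUE) {
  if (n_iter < 1L) stop("'n_iter' must be >= 1")
  grid_input <- is.array(field) && length(dim(field)) > 2L
  u <- field_as_matrix(field, mesh)
  nv <- nrow(u)
  if (!is.null(fixed)) {
    fixed <- as.logical(as.vector(fixed))
    if (length(fixed) != nv) stop("'fixed' mask length must equal vertex count")
  }
  u_fix <- if (!is.null(fixed) && any(fixed)) u[fixed, , drop = FALSE]
  W <- NULL
  if (!dynamic_stiffness) {
    W <- mesh_weights(mesh, mesh$stiffness)
    deg <- Matrix::rowSums(W)
  }
  for (it in seq_len(n_iter)) {
    if (dynamic_stiffness) {
      k <- spring_stiffness(mesh$positions + u, mesh$edges)
      W <- mesh_weights(mesh, k)
      deg <- Matrix::rowSums(W)
    }
    u <- as.matrix(W %*% u) / deg
    if (!is.null(u_fix)) u[fixed, ] <- u_fix
  }
  if (grid_input) return(array(u, dim = dim(field)))
  dimnames(u) <- NULL
  u
}

#' Spring equilibrium residual
#'
#' The net spring force at each vertex, `F_i = sum_j k_ij (u_j - u_i)`, using
#' the mesh's stored stiffness. Zero everywhere exactly when the field
#' satisfies the spring equilibrium equations.
#'
#' @inheritParams spring_relax
#' @return list with `per_vertex` (force magnitudes `||F_i||`) and `max_norm`.
#' @export
equilibrium_residual <- function(field, mesh) {
  u <- field_as_matrix(field, mesh)
  W <- mesh_weights(mesh, mesh$stiffness)
  deg <- Matrix::rowSums(W)
  Fm <- as.matrix(W %*% u) - deg * u
  per_vertex <- sqrt(rowSums(Fm^2))
  list(per_vertex = per_vertex, max_norm = max(per_vertex))
}

#' Spring regularization energy
#'
#' Sum over vertices of the magnitude of the net spring force,
#' `sum_i || sum_j k_ij (u_j - u_i) ||`; zero exactly at spring equilibrium
#' (in particular for any constant field).
#'
#' @inheritParams spring_relax
#' @return nonnegative scalar.
#' @export
regularization_energy <- function(field, mesh) {
  sum(equilibrium_residual(field, mesh)$per_vertex)
}
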