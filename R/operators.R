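# Sparse finite-difference operators for the reaction-diffusion solves.
#
# All elliptic problems in the package have the form
#   -div(D grad c) + r c = s          on free nodes,
#   c = g                             on Dirichlet nodes,
# discretized with the standard five-point stencil and face diffusivities
# taken as the arithmetic mean of the two adjacent nodes. Dirichlet nodes
# are eliminated so the free-node system is symmetric positive definite
# (an M-matrix, hence a discrete maximum principle holds).

.pdacrf_cache <- new.env(parent = emptyenv())

# internal: edge index lists for a grid, cached by dimension
grid_edge_index <- function(grid) {
  key <- paste0("edges_", grid$ny, "x", grid$nx)
  cached <- .pdacrf_cache[[key]]
  if (!is.null(cached)) return(cached)
  ny <- grid$ny; nx <- grid$nx
  id <- matrix(seq_len(ny * nx), ny, nx)
  # horizontal edges: (iy, ix) -- (iy, ix+1); vertical: (iy, ix) -- (iy+1, ix)
  ea <- c(id[, -nx], id[-ny, ])
  eb <- c(id[, -1],  id[-1, ])
  out <- list(a = as.integer(ea), b = as.integer(eb))
  .pdacrf_cache[[key]] <- out
  out
}

# internal: assemble the eliminated free-node system.
#   D: diffusivity field (matrix, um^2/h); r: reaction field (>= 0, 1/h)
#   dirichlet: logical matrix; value: matrix or scalar of boundary values
# Returns list(A, b0, free, dims): A is dsCMatrix over free nodes, b0 the
# rhs contribution from Dirichlet neighbors, free the free-node indices.
assemble_operator <- function(grid, D, r, dirichlet, value = 0) {
  check_field(D, grid); check_field(r, grid)
  n <- grid$ny * grid$nx
  eg <- grid_edge_index(grid)
  w <- (D[eg$a] + D[eg$b]) / (2 * grid$h^2)
  fixed <- as.logical(dirichlet)
  if (length(value) == 1) value <- rep(as.numeric(value), n)
  value <- as.numeric(value)

  afree <- !fixed[eg$a]; bfree <- !fixed[eg$b]
  # diagonal gets every incident face weight (including faces to Dirichlet
  # neighbors), which is what elimination requires
  diagv <- as.numeric(r)
  dsum <- numeric(n)
  tmp <- rowsum(c(w, w), c(eg$a, eg$b))
  dsum[as.integer(rownames(tmp))] <- tmp[, 1]
  diagv <- diagv + dsum

  free <- which(!fixed)
  map <- integer(n); map[free] <- seq_along(free)

  both <- afree & bfree
  ii <- c(map[eg$a[both]], map[eg$b[both]], seq_along(free))
  jj <- c(map[eg$b[both]], map[eg$a[both]], seq_along(free))
  xx <- c(-w[both], -w[both], diagv[free])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(free), length(free)))
  A <- Matrix::forceSymmetric(A)

  b0 <- numeric(length(free))
  mixed_af <- afree & !bfree
  if (any(mixed_af))
    b0 <- b0 + as.numeric(rowsum_into(map[eg$a[mixed_af]],
                                      w[mixed_af] * value[eg$b[mixed_af]],
                                      length(free)))
  mixed_bf <- !afree & bfree
  if (any(mixed_bf))
    b0 <- b0 + as.numeric(rowsum_into(map[eg$b[mixed_bf]],
                                      w[mixed_bf] * value[eg$a[mixed_bf]],
                                      length(free)))
  list(A = A, b0 = b0, free = free, fixed_value = value, fixed = fixed,
       dims = c(grid$ny, grid$nx))
}

# internal: scatter-add `vals` at integer positions `idx` into a vector of length n
rowsum_into <- function(idx, vals, n) {
  out <- numeric(n)
  tmp <- rowsum(vals, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1]
  out
}

# internal: factorize the free-node system (supernodal Cholesky)
factor_operator <- function(op) Matrix::Cholesky(op$A, LDL = FALSE, super = TRUE)

# internal: solve for a full field given volumetric source s (matrix)
solve_operator <- function(op, s, ch = NULL) {
  rhs <- as.numeric(s)[op$free] + op$b0
  if (is.null(ch)) ch <- factor_operator(op)
  x <- as.numeric(Matrix::solve(ch, rhs))
  full <- numeric(prod(op$dims))
  full[op$free] <- x
  full[op$fixed] <- op$fixed_value[op$fixed]
  matrix(full, op$dims[1], op$dims[2])
}

# internal: five-point Laplacian of a field with variable diffusivity and
# zero-flux closure at the domain edge (used by the explicit drug stepper,
# whose far field is handled by the caller through Dirichlet framing)
laplacian_varcoef <- function(f, D, h) {
  ny <- nrow(f); nx <- ncol(f)
  out <- matrix(0, ny, nx)
  # x direction
  wr <- (D[, -nx] + D[, -1]) / 2
  fluxr <- wr * (f[, -1] - f[, -nx]) / h   # flux across right faces
  out[, -nx] <- out[, -nx] + fluxr / h
  out[, -1]  <- out[, -1]  - fluxr / h
  # y direction
  wd <- (D[-ny, ] + D[-1, ]) / 2
  fluxd <- wd * (f[-1, ] - f[-ny, ]) / h
  out[-ny, ] <- out[-ny, ] + fluxd / h
  out[-1, ]  <- out[-1, ]  - fluxd / h
  out
}
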