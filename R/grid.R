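#' Create a simulation grid
#'
#' Defines the regular node-centered 2D grid on which all fields live.
#' Lengths are in micrometers, times in hours throughout the package.
#'
#' @param nx,ny Number of nodes in x and y (at least 16 each).
#' @param h Node spacing in micrometers (> 0).
#' @return An object of class `sim_grid` with elements `nx`, `ny`, `h`.
#'   Fields on this grid are plain numeric matrices of dimension
#'   `c(ny, nx)`; rows index y, columns index x, both 1-based.
#' @examples
#' g <- sim_grid(64, 64, h = 10)
#' @export
sim_grid <- function(nx, ny, h) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 16 || ny < 16)
    stop("sim_grid: nx and ny must be >= 16")
  if (!is.numeric(h) || h <= 0) stop("sim_grid: h must be > 0")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), h = as.numeric(h)),
            class = "sim_grid")
}

#' @export
print.sim_grid <- function(x, ...) {
  cat(sprintf("<sim_grid %d x %d nodes, h = %g um (%g x %g um)>\n",
              x$nx, x$ny, x$h, (x$nx - 1) * x$h, (x$ny - 1) * x$h))
  invisible(x)
}

#' Create a scalar field on a grid
#'
#' @param grid A [sim_grid()].
#' @param value Scalar or matrix of dimension `c(ny, nx)`.
#' @return A numeric matrix of dimension `c(ny, nx)`.
#' @export
scalar_field <- function(grid, value = 0) {
  if (is.matrix(value)) {
    check_field(value, grid)
    return(value)
  }
  matrix(as.numeric(value), grid$ny, grid$nx)
}

# internal: stop unless `f` is a finite field on `grid`
check_field <- function(f, grid, name = deparse(substitute(f))) {
  if (!is.matrix(f) || nrow(f) != grid$ny || ncol(f) != grid$nx)
    stop(sprintf("field '%s' must be a %d x %d matrix matching the grid",
                 name, grid$ny, grid$nx))
  if (!all(is.finite(f))) stop(sprintf("field '%s' contains non-finite values", name))
  invisible(TRUE)
}

# internal: x/y coordinates (um) of every node as matrices
grid_coords <- function(grid) {
  list(x = matrix(rep((seq_len(grid$nx) - 1) * grid$h, each = grid$ny),
                  grid$ny, grid$nx),
       y = matrix(rep((seq_len(grid$ny) - 1) * grid$h, grid$nx),
                  grid$ny, grid$nx))
}

# internal: logical matrix marking the outermost ring of nodes
boundary_mask <- function(grid) {
  m <- matrix(FALSE, grid$ny, grid$nx)
  m[1, ] <- TRUE; m[grid$ny, ] <- TRUE; m[, 1] <- TRUE; m[, grid$nx] <- TRUE
  m
}

# internal: disk indicator centered at (cx, cy) um with radius r um
disk_mask <- function(grid, cx, cy, r) {
  co <- grid_coords(grid)
  (co$x - cx)^2 + (co$y - cy)^2 <= r^2
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Write a scalar field as a node-list CSV
#'
#' One row per node with 1-based indices: `i` (x column), `j` (y row), and
#' the field value.
#'
#' @param f Field matrix.
#' @param path Output file path.
#' @export
write_field_csv <- function(f, path) {
  df <- data.frame(i = rep(seq_len(ncol(f)), each = nrow(f)),
                   j = rep(seq_len(nrow(f)), ncol(f)),
                   value = as.numeric(f))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
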