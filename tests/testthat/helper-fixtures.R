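# Small shared builders used across test files.

tiny_grid <- function(n = 24, h = 10) sim_grid(n, n, h)

disk_lesion <- function(grid, r_um, phi = 0.8) {
  cx <- (grid$nx - 1) * grid$h / 2
  cy <- (grid$ny - 1) * grid$h / 2
  phi_f <- matrix(0, grid$ny, grid$nx)
  phi_f[disk_mask_test(grid, cx, cy, r_um)] <- phi
  lesion_state(grid, phi = phi_f)
}

disk_mask_test <- function(grid, cx, cy, r) {
  xs <- matrix(rep((seq_len(grid$nx) - 1) * grid$h, each = grid$ny),
               grid$ny, grid$nx)
  ys <- matrix(rep((seq_len(grid$ny) - 1) * grid$h, grid$nx),
               grid$ny, grid$nx)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

zero_field <- function(grid) matrix(0, grid$ny, grid$nx)

# network with a single active tip and no segments (for step-law tests)
new_test_net <- function(grid, x, y) {
  segs <- data.frame(x1 = integer(), y1 = integer(), x2 = integer(),
                     y2 = integer(), perfused = logical(),
                     sprout_id = integer(), engulf_checked = logical(),
                     fused = logical())
  net <- pdacRF:::new_vessel_network(
    segs, data.frame(id = 1L, x = as.integer(x), y = as.integer(y), age_h = 0),
    grid)
  net$lineage[["1"]] <- 1L
  net$visited[["1"]] <- (as.integer(x) - 1L) * grid$ny + as.integer(y)
  net
}
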