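# Tissue mechanics: proliferation-driven pressure, Darcy velocity,
# conservative upwind advection of the volume fractions, and necrosis.
#
# Single-phase Darcy closure: net volume production S drives an oncotic
# pressure field mobility * lap(P) = -S with far-field P = 0, and tissue
# moves with u = -mobility * grad(P), so div(u) = S.

#' Growth parameters
#'
#' @param lambda_mit Mitosis rate scale (1/h); the effective proliferation
#'   rate is `lambda_mit * sigma` in proliferating tissue.
#' @param lambda_apop Background apoptosis rate (1/h).
#' @param lambda_nec Viable-to-necrotic conversion rate below the necrosis
#'   threshold (1/h).
#' @param lambda_lys Necrotic lysis (clearance) rate (1/h).
#' @param mobility Darcy mobility (relative units).
#' @export
growth_params <- function(lambda_mit = 0.030, lambda_apop = 0.002,
                          lambda_nec = 0.05, lambda_lys = 0.08,
                          mobility = 1) {
  vals <- c(lambda_mit, lambda_apop, lambda_nec, lambda_lys, mobility)
  if (any(vals < 0)) stop("growth_params: rates must be >= 0")
  if (lambda_mit <= lambda_apop)
    stop("growth_params: need lambda_mit > lambda_apop for growth to be possible")
  structure(list(lambda_mit = lambda_mit, lambda_apop = lambda_apop,
                 lambda_nec = lambda_nec, lambda_lys = lambda_lys,
                 mobility = mobility), class = "growth_params")
}

#' Net volumetric source of tumor tissue
#'
#' `S = lambda_mit * sigma * phi * [proliferating] - lambda_apop * phi
#'  - kill_rate * phi - lambda_lys * nec`.
#'
#' @param sigma Oxygen field.
#' @param lesion A classified [lesion_state()].
#' @param gp A [growth_params()].
#' @param kill_rate Drug kill-rate field (1/h; 0 if untreated).
#' @return Source field (1/h).
#' @export
proliferation_source <- function(sigma, lesion, gp,
                                 kill_rate = scalar_field(lesion$grid)) {
  check_field(sigma, lesion$grid, "sigma")
  if (any(kill_rate < 0)) stop("proliferation_source: kill_rate must be >= 0")
  prolif <- lesion$labels == REGION_PROLIF
  gp$lambda_mit * sigma * lesion$phi * prolif -
    gp$lambda_apop * lesion$phi -
    kill_rate * lesion$phi -
    gp$lambda_lys * lesion$nec
}

#' Solve the oncotic pressure field
#'
#' Solves `mobility * lap(P) = -S` with `P = 0` on the far boundary. The
#' (constant-coefficient) operator factorization is cached per grid.
#'
#' @param S Volumetric source field (1/h).
#' @param gp A [growth_params()].
#' @param grid A [sim_grid()].
#' @return Pressure field.
#' @export
solve_pressure <- function(S, gp, grid) {
  check_field(S, grid, "S")
  key <- sprintf("pressure_%d_%d_%g_%g", grid$ny, grid$nx, grid$h, gp$mobility)
  ctx <- .pdacrf_cache[[key]]
  if (is.null(ctx)) {
    op <- assemble_operator(grid, scalar_field(grid, gp$mobility),
                            scalar_field(grid, 0), boundary_mask(grid), 0)
    ctx <- list(op = op, ch = factor_operator(op))
    .pdacrf_cache[[key]] <- ctx
  }
  solve_operator(ctx$op, S, ctx$ch)
}

#' Darcy velocity from the pressure field
#'
#' `u = -mobility * grad(P)` with central differences in the interior and
#' one-sided differences at the boundary.
#'
#' @param P Pressure field.
#' @param gp A [growth_params()].
#' @param grid A [sim_grid()].
#' @return List with component fields `ux`, `uy` (um/h).
#' @export
velocity_from_pressure <- function(P, gp, grid) {
  check_field(P, grid, "P")
  h <- grid$h; nx <- grid$nx; ny <- grid$ny
  ux <- matrix(0, ny, nx); uy <- matrix(0, ny, nx)
  ux[, 2:(nx - 1)] <- (P[, 3:nx] - P[, 1:(nx - 2)]) / (2 * h)
  ux[, 1] <- (P[, 2] - P[, 1]) / h
  ux[, nx] <- (P[, nx] - P[, nx - 1]) / h
  uy[2:(ny - 1), ] <- (P[3:ny, ] - P[1:(ny - 2), ]) / (2 * h)
  uy[1, ] <- (P[2, ] - P[1, ]) / h
  uy[ny, ] <- (P[ny, ] - P[ny - 1, ]) / h
  list(ux = -gp$mobility * ux, uy = -gp$mobility * uy)
}

# internal: conservative first-order upwind divergence of (u * f)
upwind_div_flux <- function(f, ux, uy, h) {
  ny <- nrow(f); nx <- ncol(f)
  # right-face velocities (average of adjacent nodes)
  ufr <- (ux[, -nx] + ux[, -1]) / 2
  Fr <- ifelse(ufr > 0, ufr * f[, -nx], ufr * f[, -1])
  ufd <- (uy[-ny, ] + uy[-1, ]) / 2
  Fd <- ifelse(ufd > 0, ufd * f[-ny, ], ufd * f[-1, ])
  div <- matrix(0, ny, nx)
  div[, -nx] <- div[, -nx] + Fr / h
  div[, -1]  <- div[, -1]  - Fr / h
  div[-ny, ] <- div[-ny, ] + Fd / h
  div[-1, ]  <- div[-1, ]  - Fd / h
  # div holds net outflow per node: d f/dt (advective) = -div
  div
}

#' Advect the tumor volume fractions
#'
#' First-order conservative upwind advection of `phi` and `nec` by the
#' tissue velocity plus explicit source terms. Fractions are clipped to
#' `[0, 1]` and rescaled proportionally where `phi + nec` would exceed 1.
#' Requires the CFL condition `dt * max|u| / h <= 1`.
#'
#' @param lesion A [lesion_state()].
#' @param u Velocity list from [velocity_from_pressure()].
#' @param S_viable,S_nec Source fields for `phi` and `nec` (1/h).
#' @param dt Time step (h).
#' @return Updated [lesion_state()] with `t` advanced by `dt`.
#' @export
advect_update <- function(lesion, u, S_viable, S_nec, dt) {
  grid <- lesion$grid
  umax <- max(abs(u$ux), abs(u$uy))
  if (dt * umax / grid$h > 1)
    stop(sprintf("advect_update: CFL violated; need dt <= %g h for max|u| = %g um/h",
                 grid$h / umax, umax))
  phi <- lesion$phi - dt * upwind_div_flux(lesion$phi, u$ux, u$uy, grid$h) +
    dt * S_viable
  nec <- lesion$nec - dt * upwind_div_flux(lesion$nec, u$ux, u$uy, grid$h) +
    dt * S_nec
  phi <- pmin(pmax(phi, 0), 1)
  nec <- pmin(pmax(nec, 0), 1)
  tot <- phi + nec
  over <- tot > 1
  if (any(over)) {
    phi[over] <- phi[over] / tot[over]
    nec[over] <- nec[over] / tot[over]
  }
  lesion$phi <- phi; lesion$nec <- nec; lesion$t <- lesion$t + dt
  lesion
}

#' Hypoxia-driven necrosis and necrotic lysis
#'
#' Where oxygen falls below the necrosis threshold, viable tissue converts
#' to necrotic at rate `lambda_nec` (capped at the available `phi`);
#' necrotic debris is cleared at rate `lambda_lys` (lysed volume leaves the
#' tissue budget).
#'
#' @param lesion A [lesion_state()].
#' @param sigma Oxygen field.
#' @param thr A [tissue_thresholds()].
#' @param gp A [growth_params()].
#' @param dt Time step (h).
#' @export
necrosis_transfer <- function(lesion, sigma, thr, gp, dt) {
  check_field(sigma, lesion$grid, "sigma")
  if (dt <= 0) stop("necrosis_transfer: dt must be > 0")
  low <- sigma < thr$sigma_N
  delta <- pmin(lesion$phi, gp$lambda_nec * lesion$phi * dt) * low
  lesion$phi <- lesion$phi - delta
  lesion$nec <- lesion$nec + delta
  lesion$nec <- lesion$nec - gp$lambda_lys * lesion$nec * dt
  lesion
}
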