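# Reaction-diffusion transport of diffusible species.
#
# Species are parameterized the way the simulated therapy comparisons vary
# them: by a relative diffusive penetration P_rel (oxygen = 1.00) and a
# vascular extravasation transfer rate TR (oxygen = 5 /h). The absolute
# diffusivity is derived from the oxygen reference so that the 1D
# penetration length L = sqrt(D / lambda_u) scales exactly as
# L = P_rel * L_O2. The oxygen reference length is 100 um, which puts the
# baseline drug (P_rel = 0.2) at the experimentally measured ~20 um.

#' Transport reference scales
#'
#' Oxygen reference used to convert relative penetrations into absolute
#' diffusivities: penetration length `L_ref` = 100 um, uptake
#' `lambda_ref` = 1 /h, hence `D_ref` = L_ref^2 * lambda_ref = 1e4 um^2/h.
#' @return Named list with `D_ref`, `lambda_ref`, `L_ref`.
#' @export
transport_reference <- function() list(D_ref = 1e4, lambda_ref = 1, L_ref = 100)

#' Per-species transport parameters
#'
#' @param name Species name.
#' @param P_rel Relative diffusive penetration (dimensionless; oxygen = 1.00).
#' @param TR Vascular extravasation transfer rate (1/h; oxygen = 5).
#' @param lambda_u Uptake rate by viable tumor (1/h).
#' @param lambda_d Background decay rate (1/h).
#' @param follows_plasma Whether the vessel-side concentration tracks the
#'   plasma pharmacokinetics (TRUE for drug) or is constant (TRUE oxygen
#'   vessel level is 1).
#' @param uptake_includes_debris Whether necrotic debris also takes the
#'   species up (TRUE for nucleic-acid-binding drugs, whose targets persist
#'   in dead cells; FALSE for oxygen, which only live cells consume).
#' @return Object of class `species_params`.
#' @export
species_params <- function(name, P_rel, TR, lambda_u, lambda_d = 0,
                           follows_plasma = FALSE,
                           uptake_includes_debris = FALSE) {
  if (P_rel <= 0) stop("species_params: P_rel must be > 0")
  if (TR < 0 || lambda_u < 0 || lambda_d < 0)
    stop("species_params: rates must be >= 0")
  structure(list(name = name, P_rel = P_rel, TR = TR, lambda_u = lambda_u,
                 lambda_d = lambda_d, follows_plasma = follows_plasma,
                 uptake_includes_debris = uptake_includes_debris),
            class = "species_params")
}

#' ECM parameters
#'
#' @param lambda_deg Degradation rate of ECM by matrix-degrading enzymes (1/h).
#' @param alpha Diffusivity-hindrance coefficient: effective diffusivity is
#'   `D / (1 + alpha * E)` where `E` is ECM density in `[0, 1]`.
#' @export
ecm_params <- function(lambda_deg = 0.005, alpha = 0.5) {
  if (lambda_deg < 0 || alpha < 0) stop("ecm_params: parameters must be >= 0")
  structure(list(lambda_deg = lambda_deg, alpha = alpha), class = "ecm_params")
}

#' Derive absolute diffusivity from relative penetration
#'
#' Computes `D = P_rel^2 * ref_diffusivity * (lambda_u / ref_uptake)` so that
#' the 1D penetration length `L = sqrt(D / lambda_u)` satisfies
#' `L = P_rel * L_ref` regardless of the species' own uptake rate.
#'
#' @param sp A [species_params()].
#' @param ref_diffusivity,ref_uptake Oxygen reference diffusivity (um^2/h)
#'   and uptake (1/h); default [transport_reference()].
#' @return Diffusivity in um^2/h.
#' @export
derive_diffusivity <- function(sp,
                               ref_diffusivity = transport_reference()$D_ref,
                               ref_uptake = transport_reference()$lambda_ref) {
  if (ref_diffusivity <= 0 || ref_uptake <= 0)
    stop("derive_diffusivity: reference quantities must be > 0")
  if (sp$lambda_u == 0)
    stop("derive_diffusivity: zero uptake with finite P_rel leaves the penetration length undefined")
  sp$P_rel^2 * ref_diffusivity * (sp$lambda_u / ref_uptake)
}

#' ECM-hindered diffusivity field
#'
#' @param D0 Free diffusivity (um^2/h).
#' @param E ECM density field in `[0, 1]`.
#' @param p An [ecm_params()].
#' @return Field `D0 / (1 + alpha * E)`.
#' @export
ecm_hindered_diffusivity <- function(D0, E, p) {
  if (any(E < -1e-12) || any(E > 1 + 1e-12))
    stop("ecm_hindered_diffusivity: E must lie in [0, 1]")
  D0 / (1 + p$alpha * E)
}

# internal: reaction field TR*vessels + lambda_u*(absorbing tissue) + lambda_d
reaction_field <- function(sp, vessels, lesion) {
  absorber <- lesion$phi
  if (isTRUE(sp$uptake_includes_debris)) absorber <- absorber + lesion$nec
  sp$TR * vessels + sp$lambda_u * absorber + sp$lambda_d
}

#' Quasi-steady concentration of a vessel-delivered species
#'
#' Solves `0 = div(D_eff grad c) + TR*vessels*(vessel_level - c)
#' - lambda_u*phi*c - lambda_d*c` with Dirichlet far-field boundary.
#' Uptake acts on the viable tumor fraction `phi`.
#'
#' @param sp A [species_params()].
#' @param vessels Perfused-vessel indicator field (>= 0).
#' @param lesion A [lesion_state()] (supplies `phi` and the grid).
#' @param E ECM density field (hindrance); pass 0 field for none.
#' @param vessel_level Vessel-side concentration (plasma level for drug).
#' @param ecm An [ecm_params()].
#' @param boundary_value Dirichlet value on the domain edge (default 0; the
#'   oxygen solve passes the host value).
#' @param dirichlet Optional extra logical matrix of clamped nodes (merged
#'   with the domain edge), with values `boundary_value`; used e.g. to hold a
#'   bath concentration around an avascular spheroid.
#' @return Concentration field in `[0, max(vessel_level, boundary_value)]`.
#' @export
solve_quasi_steady <- function(sp, vessels, lesion, E, vessel_level,
                               ecm = ecm_params(), boundary_value = 0,
                               dirichlet = NULL) {
  grid <- lesion$grid
  check_field(vessels, grid, "vessels"); check_field(E, grid, "E")
  if (vessel_level < 0) stop("solve_quasi_steady: vessel_level must be >= 0")
  D0 <- derive_diffusivity(sp)
  Deff <- ecm_hindered_diffusivity(scalar_field(grid, D0), E, ecm)
  r <- reaction_field(sp, vessels, lesion)
  fixed <- boundary_mask(grid)
  if (!is.null(dirichlet)) fixed <- fixed | dirichlet
  if (all(r == 0) && !any(fixed))
    stop("solve_quasi_steady: all rates zero, system is singular")
  op <- assemble_operator(grid, Deff, r, fixed, boundary_value)
  s <- sp$TR * vessels * vessel_level
  out <- solve_operator(op, s)
  pmax(out, 0)
}

#' One explicit time step of drug transport
#'
#' Advances `dc/dt = div(D_eff grad c) + TR*vessels*(plasma - c)
#' - lambda_u*phi*c - lambda_d*c` by `dt` with an exponential-Euler step:
#' diffusion is explicit (five-point stencil) while the local reaction is
#' integrated exactly, and long-time stepping converges to the
#' [solve_quasi_steady()] field. `dt` must satisfy the diffusive stability
#' bound `dt <= h^2 / (4 max(D_eff))`; the far boundary is held drug-free.
#'
#' @param c Current concentration field.
#' @inheritParams solve_quasi_steady
#' @param plasma_level Vessel-side (plasma) concentration during the step.
#' @param dt Time step (h).
#' @return Updated concentration field.
#' @export
step_drug <- function(c, sp, vessels, lesion, E, plasma_level, dt,
                      ecm = ecm_params()) {
  grid <- lesion$grid
  check_field(c, grid, "c"); check_field(vessels, grid, "vessels")
  if (dt <= 0) stop("step_drug: dt must be > 0")
  D0 <- derive_diffusivity(sp)
  Deff <- ecm_hindered_diffusivity(scalar_field(grid, D0), E, ecm)
  dt_max <- grid$h^2 / (4 * max(Deff))
  if (dt > dt_max)
    stop(sprintf("step_drug: dt = %g h violates the diffusive stability bound; need dt <= %g h",
                 dt, dt_max))
  r <- reaction_field(sp, vessels, lesion)
  s <- sp$TR * vessels * plasma_level
  # exponential Euler: the local reaction is integrated exactly and the
  # diffusive flux enters through the averaged integrating factor, so the
  # scheme's fixed point is exactly the discrete quasi-steady solution
  lap <- laplacian_varcoef(c, Deff, grid$h)
  ef <- exp(-r * dt)
  w <- ifelse(r > 0, (1 - ef) / pmax(r, .Machine$double.eps), dt)
  out <- c * ef + w * (s + lap)
  # far-field Dirichlet: the domain edge stays drug-free, matching the
  # quasi-steady operator
  out[1, ] <- 0; out[nrow(out), ] <- 0; out[, 1] <- 0; out[, ncol(out)] <- 0
  pmax(out, 0)
}

#' Default parameters of the angiogenic-factor and enzyme fields
#'
#' TAF: produced by hypoxic tissue, decays slowly, bound by vessels;
#' diffusivity gives a signaling range of a few hundred micrometers.
#' MDE: produced by viable tumor, decays faster, short range.
#' @return Nested list with `taf` and `mde` blocks.
#' @export
field_params <- function() {
  list(taf = list(D = 1000, production = 0.05, decay = 0.01, vessel_sink = 0.25),
       mde = list(D = 500, production = 0.1, decay = 0.1))
}

#' Quasi-steady tumor angiogenic factor field
#'
#' Production in hypoxic lesion nodes, decay everywhere, binding sink on
#' perfused vessels, zero-Dirichlet far field; result clipped to `[0, 1]`.
#'
#' @param T_field Current TAF field (unused by the quasi-steady solve except
#'   for shape checking; kept for a uniform update signature).
#' @param lesion A classified [lesion_state()].
#' @param vessels Perfused-vessel indicator field.
#' @param params `field_params()$taf`-style list.
#' @param E Optional ECM field hindering TAF diffusion.
#' @param ecm An [ecm_params()].
#' @export
update_taf <- function(T_field, lesion, vessels, params = field_params()$taf,
                       E = NULL, ecm = ecm_params()) {
  grid <- lesion$grid
  check_field(vessels, grid, "vessels")
  D <- scalar_field(grid, params$D)
  if (!is.null(E)) D <- ecm_hindered_diffusivity(D, E, ecm)
  r <- scalar_field(grid, params$decay) + params$vessel_sink * vessels
  s <- params$production * (lesion$labels == REGION_HYPOXIC)
  if (!any(s > 0)) return(scalar_field(grid, 0))
  op <- assemble_operator(grid, D, r, boundary_mask(grid), 0)
  clip01(solve_operator(op, s))
}

#' Update matrix-degrading enzymes and degrade ECM
#'
#' MDE is quasi-steady (production by viable tumor, diffusion, decay, zero
#' far field); ECM then decays as `E <- E * exp(-lambda_deg * M * dt)`,
#' clipped to `[0, 1]`. ECM never increases under this operation.
#'
#' @param M Current MDE field (shape only).
#' @param E ECM density field.
#' @param lesion A [lesion_state()].
#' @param p An [ecm_params()].
#' @param dt Time step (h).
#' @param params `field_params()$mde`-style list.
#' @return List with updated `M` and `E`.
#' @export
update_mde_ecm <- function(M, E, lesion, p, dt, params = field_params()$mde) {
  grid <- lesion$grid
  check_field(E, grid, "E")
  if (dt <= 0) stop("update_mde_ecm: dt must be > 0")
  D <- scalar_field(grid, params$D)
  r <- scalar_field(grid, params$decay)
  s <- params$production * lesion$phi
  if (any(s > 0)) {
    op <- assemble_operator(grid, D, r, boundary_mask(grid), 0)
    M <- clip01(solve_operator(op, s))
  } else {
    M <- scalar_field(grid, 0)
  }
  E2 <- clip01(E * exp(-p$lambda_deg * M * dt))
  list(M = M, E = E2)
}

#' Measure the 1D penetration length of a species
#'
#' Solves the quasi-steady profile on a thin strip with the species held at
#' concentration 1 on one face (a vessel plane) and uptake by uniformly
#' viable tissue elsewhere, then reports the depth at which the
#' concentration falls to `1/e` of the face value. For a semi-infinite
#' domain the analytic profile is `exp(-x / L)` with
#' `L = P_rel * L_ref`.
#'
#' @param sp A [species_params()].
#' @param h Node spacing (um).
#' @param depth Strip depth (um); should be several penetration lengths.
#' @param phi Viable fraction of the absorbing tissue.
#' @return Penetration depth in um.
#' @export
penetration_length_1d <- function(sp, h = 2.5, depth = 800, phi = 1) {
  nx <- max(16, round(depth / h) + 1)
  grid <- sim_grid(nx, 16, h)
  lesion <- lesion_state(grid, phi = matrix(phi, grid$ny, grid$nx))
  E <- scalar_field(grid, 0)
  vessels <- scalar_field(grid, 0)
  fixed <- matrix(FALSE, grid$ny, grid$nx)
  fixed[, 1] <- TRUE
  D0 <- derive_diffusivity(sp)
  # strip: no-flux top/bottom handled by not fixing those rows; only the
  # inlet face (x = 0) and the far face are Dirichlet (1 and 0)
  val <- matrix(0, grid$ny, grid$nx); val[, 1] <- 1
  fixed[, grid$nx] <- TRUE
  r <- reaction_field(sp, vessels, lesion)
  op <- assemble_operator(grid, scalar_field(grid, D0), r, fixed, as.numeric(val))
  cfield <- solve_operator(op, scalar_field(grid, 0))
  prof <- cfield[8, ] / cfield[8, 1]
  x <- (seq_len(nx) - 1) * h
  idx <- which(prof < exp(-1))[1]
  if (is.na(idx)) return(Inf)
  x0 <- x[idx - 1]; x1 <- x[idx]
  p0 <- prof[idx - 1]; p1 <- prof[idx]
  x0 + (p0 - exp(-1)) / (p0 - p1) * (x1 - x0)
}
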