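# The treatment main loop: oxygen quasi-steady solve -> tissue
# classification -> TAF / angiogenesis / MDE-ECM updates -> drug transport
# and exposure integration during active doses -> pharmacodynamic kill
# (viable -> necrotic) -> Darcy growth mechanics -> hypoxic necrosis and
# lysis, with the trajectory sampled every macro step.

#' Bundle of model parameters for the tissue-scale simulation
#'
#' Collects every parameter block the main loop needs. Defaults encode the
#' baseline study conditions: oxygen penetration 100 um (TR = 5), drug
#' penetration 20% of oxygen's at the same TR, plasma washout 1.5 h, and a
#' PD kill calibrated to the EC70 spheroid datum.
#'
#' @param o2,gem [species_params()] for oxygen and drug.
#' @param growth A [growth_params()].
#' @param angio An [angiogenesis_params()].
#' @param ecm An [ecm_params()].
#' @param fields TAF/MDE parameter list from [field_params()].
#' @param pk A [pk_params()].
#' @param pd A [pd_params()] (calibrate with [calibrate_kill()]).
#' @param resistance An [rf_resistance()] or NULL to disable resistance.
#' @param thresholds A [tissue_thresholds()].
#' @param vasc List: `p_prune`, the probability that a pre-existing
#'   capillary collapses when engulfed by the growing lesion (matching the
#'   initial intratumoral pruning).
#' @param numerics List: `dt` macro step (h), `angio_every` (h) cadence of
#'   TAF/angiogenesis/ECM updates, `dose_window` (h) during which plasma
#'   drug is tracked after a dose, `drug_substeps` per macro step within a
#'   window.
#' @export
sim_params <- function(o2 = species_params("O2", 1, 5, 1.0, 0.05),
                       gem = species_params("Gem", 0.2, 5, 5, 0.2, TRUE,
                                            uptake_includes_debris = TRUE),
                       growth = growth_params(),
                       angio = angiogenesis_params(),
                       ecm = ecm_params(),
                       fields = field_params(),
                       pk = pk_params(),
                       pd = pd_params(),
                       resistance = NULL,
                       thresholds = tissue_thresholds(),
                       vasc = list(p_prune = 0.8),
                       numerics = list(dt = 1, angio_every = 4,
                                       dose_window = 12, drug_substeps = 4)) {
  structure(list(o2 = o2, gem = gem, growth = growth, angio = angio,
                 ecm = ecm, fields = fields, pk = pk, pd = pd,
                 resistance = resistance, thresholds = thresholds,
                 vasc = vasc, numerics = numerics), class = "sim_params")
}

# internal: host-side oxygen level used as the far-field Dirichlet value
host_oxygen_level <- function(o2) o2$TR / (o2$TR + o2$lambda_d)

# internal: one macro step of the coupled model; `state` carries
# lesion, net, E (ECM), u_exposure, taf, and the active-dose context
sim_step <- function(state, params, dose_ctx = NULL) {
  grid <- state$lesion$grid
  dt <- params$numerics$dt
  vessels <- vessel_indicator(state$net, grid)

  sigma <- solve_quasi_steady(params$o2, vessels, state$lesion, state$E,
                              vessel_level = 1, ecm = params$ecm,
                              boundary_value = host_oxygen_level(params$o2))
  state$sigma <- sigma
  state$lesion <- classify_tissue(sigma, state$lesion, params$thresholds)

  # angiogenesis + stroma remodeling on a slower cadence
  if (state$step %% max(1L, round(params$numerics$angio_every / dt)) == 0L) {
    state$net <- engulf_prune(state$net, state$lesion,
                              params$vasc$p_prune %||% 0.8)
    state$taf <- update_taf(state$taf, state$lesion, vessels,
                            params$fields$taf, E = state$E, ecm = params$ecm)
    state$net <- spawn_sprouts(state$net, state$taf, params$angio)
    nsub <- max(1L, round(params$angio$step_h * params$numerics$angio_every))
    for (i in seq_len(nsub))
      state$net <- sprout_step(state$net, state$taf, state$E, params$angio,
                               dt_h = params$numerics$angio_every / nsub)
    state$net <- mark_perfusion_connectivity(state$net, state$lesion)
    me <- update_mde_ecm(state$mde, state$E, state$lesion, params$ecm,
                         params$numerics$angio_every, params$fields$mde)
    state$mde <- me$M; state$E <- me$E
  }

  # drug transport during an active dose window
  if (!is.null(dose_ctx)) {
    ns <- max(1L, params$numerics$drug_substeps)
    sp <- dose_ctx$sp
    D0 <- derive_diffusivity(sp)
    Deff <- ecm_hindered_diffusivity(scalar_field(grid, D0), state$E,
                                     params$ecm)
    r <- reaction_field(sp, vessels, state$lesion)
    op <- assemble_operator(grid, Deff, r, boundary_mask(grid), 0)
    ch <- factor_operator(op)
    for (i in seq_len(ns)) {
      tsub <- state$t + (i - 0.5) * dt / ns
      plasma <- plasma_concentration(tsub, dose_ctx$ev, params$pk)
      cfield <- solve_operator(op, sp$TR * vessels * plasma, ch)
      state$u_exposure <- state$u_exposure * exp(-(dt / ns) / params$pd$tau_ret) +
        pmax(cfield, 0) * ((dt / ns) / params$pd$tau_load)
    }
    state$drug <- cfield
  } else {
    state$u_exposure <- state$u_exposure * exp(-dt / params$pd$tau_ret)
    state$drug <- NULL
  }

  # pharmacodynamic kill (cell-cycle weighted, with a re-entry lag so
  # newly re-oxygenated tissue takes ~a cycle time to become vulnerable):
  # viable tissue joins the necrotic pool
  w_now <- cycle_kill_weight(state$lesion$labels, params$pd)
  if (is.null(state$w_cycle)) state$w_cycle <- w_now
  else if (params$pd$tau_cycle > 0)
    state$w_cycle <- state$w_cycle + (w_now - state$w_cycle) *
      (1 - exp(-dt / params$pd$tau_cycle))
  else state$w_cycle <- w_now
  kill <- drug_kill_rate(state$u_exposure, params$pd) * state$w_cycle
  if (any(kill > 0)) {
    dphi <- state$lesion$phi * (1 - exp(-kill * dt))
    state$lesion$phi <- state$lesion$phi - dphi
    state$lesion$nec <- pmin(state$lesion$nec + dphi, 1)
  }

  # growth mechanics: volume sources (kill is a conversion, not a volume
  # source, so it is excluded here), pressure, Darcy velocity, advection
  S_press <- proliferation_source(sigma, state$lesion, params$growth)
  P <- solve_pressure(S_press, params$growth, grid)
  u <- velocity_from_pressure(P, params$growth, grid)
  gp <- params$growth
  prolif <- state$lesion$labels == REGION_PROLIF
  S_viable <- gp$lambda_mit * sigma * state$lesion$phi * prolif -
    gp$lambda_apop * state$lesion$phi
  S_nec <- scalar_field(grid, 0)
  umax <- max(abs(u$ux), abs(u$uy))
  nadv <- max(1L, ceiling(dt * umax / (0.8 * grid$h)))
  for (i in seq_len(nadv))
    state$lesion <- advect_update(state$lesion, u, S_viable, S_nec, dt / nadv)
  state$lesion <- necrosis_transfer(state$lesion, sigma, params$thresholds,
                                    gp, dt)

  state$t <- state$t + dt
  state$step <- state$step + 1L
  state
}

# internal: initial engine state
sim_init <- function(lesion, net, params, E = NULL) {
  grid <- lesion$grid
  if (is.null(E)) E <- scalar_field(grid, 0.6)
  list(lesion = lesion, net = net, E = E,
       taf = scalar_field(grid, 0), mde = scalar_field(grid, 0),
       u_exposure = scalar_field(grid, 0), sigma = scalar_field(grid, 1),
       w_cycle = NULL, drug = NULL, t = lesion$t, step = 0L)
}

# internal: one trajectory row
trajectory_row <- function(state, plasma) {
  lesion <- state$lesion
  n <- sum(tumor_mask(lesion))
  fr <- if (n > 0) tissue_fractions(lesion) else c(fP = NA_real_,
                                                   fH = NA_real_, fN = NA_real_)
  data.frame(t_h = state$t, radius_um = effective_radius(lesion),
             fP = fr[["fP"]], fH = fr[["fH"]], fN = fr[["fN"]],
             plasma = plasma, viable_mass = sum(lesion$phi),
             necrotic_mass = sum(lesion$nec))
}

#' Run a therapy schedule on a lesion
#'
#' Executes the coupled tissue-scale model under an ordered schedule of
#' bolus doses (possibly RF-enhanced) and returns the sampled trajectory.
#' Deterministic for a fixed seed.
#'
#' @param initial A [lesion_state()] (e.g. from [gen_pretreatment_lesion()]).
#' @param net The matching `vessel_network`.
#' @param schedule A [therapy_schedule()] (empty for an untreated control).
#' @param params A [sim_params()] bundle.
#' @param t_end Simulation end time (h).
#' @param seed Integer RNG seed.
#' @param E Initial ECM density field (default uniform 0.6).
#' @param stop_radius Optional radius (um); the run stops early once the
#'   effective radius reaches it (used when growing lesions to size).
#' @return A `trajectory` data frame with columns `t_h`, `radius_um`, `fP`,
#'   `fH`, `fN`, `plasma`, `viable_mass`, `necrotic_mass`; the final engine
#'   state is attached as attribute `final_state`.
#' @export
run_schedule <- function(initial, net, schedule = therapy_schedule(),
                         params = sim_params(), t_end = 168, seed = 1,
                         E = NULL, stop_radius = NULL) {
  stopifnot(inherits(initial, "lesion_state"))
  initial$t <- 0 # each run carries its own clock (doses are relative to it)
  events <- schedule$events
  withr::with_seed(seed, {
    state <- sim_init(initial, net, params, E)
    rows <- vector("list", ceiling((t_end - state$t) / params$numerics$dt) + 1)
    rows[[1]] <- trajectory_row(state, 0)
    ri <- 1
    n_rf <- 0L
    dose_sp <- vector("list", length(events))
    while (state$t < t_end - 1e-9) {
      # active dose: latest event whose window covers the current step
      dose_ctx <- NULL
      plasma_now <- 0
      if (length(events) > 0) {
        t0s <- vapply(events, `[[`, numeric(1), "t0")
        active <- which(t0s <= state$t + 1e-9 &
                        state$t < t0s + params$numerics$dose_window)
        if (length(active) > 0) {
          a <- active[length(active)]
          if (is.null(dose_sp[[a]])) {
            if (isTRUE(events[[a]]$rf)) n_rf <- n_rf + 1L
            dose_sp[[a]] <- apply_rf(params$gem, events[[a]],
                                     params$resistance, max(n_rf, 1L))
          }
          dose_ctx <- list(ev = events[[a]], sp = dose_sp[[a]])
          plasma_now <- plasma_concentration(state$t, events[[a]], params$pk)
        }
      }
      state <- sim_step(state, params, dose_ctx)
      ri <- ri + 1
      rows[[ri]] <- trajectory_row(state, plasma_now)
      if (!is.null(stop_radius) &&
          rows[[ri]]$radius_um >= stop_radius) break
      if (rows[[ri]]$radius_um == 0 && is.null(stop_radius) &&
          state$t < t_end - 1e-9) {
        # lesion eradicated: pad the trajectory to t_end and stop
        ri <- ri + 1
        rows[[ri]] <- rows[[ri - 1]]
        rows[[ri]]$t_h <- t_end
        break
      }
    }
    traj <- do.call(rbind, rows[seq_len(ri)])
    class(traj) <- c("trajectory", "data.frame")
    attr(traj, "dose_times") <- if (length(events) > 0)
      vapply(events, `[[`, numeric(1), "t0") else numeric()
    attr(traj, "final_state") <- state
    traj
  })
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d samples, t = [%.1f, %.1f] h, radius %.1f -> %.1f um>\n",
              nrow(x), x$t_h[1], x$t_h[nrow(x)], x$radius_um[1],
              x$radius_um[nrow(x)]))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj A trajectory from [run_schedule()].
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$t_h <- round(df$t_h, 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
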