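# Pharmacokinetics, RF modulation, pharmacodynamic kill, and the
# treatment main loop.
#
# A bolus dose produces an exponentially washing-out plasma concentration
# (tau = 1.5 h, so >90% is gone within 3.6 h). Interstitial drug follows
# vessel extravasation (rate TR) and ECM-hindered diffusion. The kill is
# driven by a cell-associated drug exposure field: gemcitabine's active
# metabolite is retained intracellularly far longer than the plasma
# washout, so cells keep dying for ~2 days after a bolus, which is what
# places the radius minimum near 48 h post dose. The maximal kill rate is
# calibrated against the EC70 datum (70% viable-mass reduction of an
# avascular spheroid after 72 h in a 100 uM bath).

#' Plasma pharmacokinetic parameters
#'
#' @param tau Plasma washout time constant (h).
#' @param dose_peak Peak plasma concentration, normalized so 1.0 = 100 uM.
#' @export
pk_params <- function(tau = 1.5, dose_peak = 1) {
  if (tau <= 0) stop("pk_params: tau must be > 0")
  if (dose_peak < 0) stop("pk_params: dose_peak must be >= 0")
  structure(list(tau = tau, dose_peak = dose_peak), class = "pk_params")
}

#' Pharmacodynamic kill parameters
#'
#' Saturating (Michaelis-type) kill driven by the retained cellular drug
#' exposure `u`: kill rate = `k_kill * u / (c50 + u)`. The exposure field
#' loads from the interstitial concentration at rate `1/tau_load` and
#' clears at rate `1/tau_ret`.
#'
#' @param k_kill Maximal kill rate (1/h); calibrated by [calibrate_kill()].
#' @param c50 Half-effect exposure (normalized 100 uM * h units).
#' @param tau_load Exposure loading time constant (h).
#' @param tau_ret Intracellular retention time constant (h).
#' @param quiescent_frac Kill-rate multiplier for hypoxic (quiescent)
#'   tissue relative to proliferating tissue. The drug is S-phase specific:
#'   it kills cycling cells at the full rate and quiescent cells only
#'   marginally; quiescent cells become vulnerable when peripheral death
#'   re-oxygenates them and they resume cycling.
#' @param tau_cycle Cell-cycle re-entry time constant (h): newly
#'   re-oxygenated tissue approaches its full cycling kill weight with this
#'   first-order lag rather than instantaneously.
#' @param model Kill law; `"saturating"` (default) or `"linear"`
#'   (`k_kill * u`, no saturation).
#' @export
pd_params <- function(k_kill = 0.05, c50 = 0.2, tau_load = 1, tau_ret = 24,
                      quiescent_frac = 0.1, tau_cycle = 0,
                      model = c("saturating", "linear")) {
  if (k_kill < 0) stop("pd_params: k_kill must be >= 0")
  if (c50 <= 0) stop("pd_params: c50 must be > 0")
  if (quiescent_frac < 0 || quiescent_frac > 1)
    stop("pd_params: quiescent_frac must be in [0, 1]")
  if (tau_cycle < 0) stop("pd_params: tau_cycle must be >= 0")
  structure(list(k_kill = k_kill, c50 = c50, tau_load = tau_load,
                 tau_ret = tau_ret, quiescent_frac = quiescent_frac,
                 tau_cycle = tau_cycle, model = match.arg(model)),
            class = "pd_params")
}

#' Cell-cycle weighting of the kill rate by tissue region
#'
#' Full kill in proliferating tissue, `quiescent_frac` of it in hypoxic
#' tissue, none in necrotic or host regions.
#'
#' @param labels Region-label matrix from [classify_tissue()].
#' @param pd A [pd_params()].
#' @return Weight field in `[0, 1]`.
#' @export
cycle_kill_weight <- function(labels, pd) {
  (labels == REGION_PROLIF) + pd$quiescent_frac * (labels == REGION_HYPOXIC)
}

#' A single dose event
#'
#' @param t0 Administration time (h, >= 0).
#' @param dose_peak Peak plasma concentration (normalized; 1.0 = 100 uM).
#' @param rf Whether the dose follows non-invasive RF exposure.
#' @param f_D,f_TR RF enhancement multipliers applied to the drug's relative
#'   penetration and vascular transfer rate (default 1.75 each, i.e. +75%).
#' @export
dose_event <- function(t0, dose_peak = 1, rf = FALSE, f_D = 1.75, f_TR = 1.75) {
  if (t0 < 0) stop("dose_event: t0 must be >= 0")
  if (rf && (f_D < 1 || f_TR < 1))
    stop("dose_event: f_D and f_TR must be >= 1 when rf is TRUE")
  structure(list(t0 = t0, dose_peak = dose_peak, rf = rf,
                 f_D = f_D, f_TR = f_TR), class = "dose_event")
}

#' An ordered therapy schedule
#'
#' @param ... [dose_event()] objects (or a single list of them) with
#'   strictly increasing `t0`.
#' @export
therapy_schedule <- function(...) {
  evs <- list(...)
  if (length(evs) == 1 && !inherits(evs[[1]], "dose_event")) evs <- evs[[1]]
  if (length(evs) > 1) {
    t0s <- vapply(evs, `[[`, numeric(1), "t0")
    if (any(diff(t0s) <= 0))
      stop("therapy_schedule: dose times must be strictly increasing")
  }
  structure(list(events = evs), class = "therapy_schedule")
}

#' RF resistance buildup
#'
#' Susceptibility to the k-th RF exposure is
#' `s_k = max(floor, 1 - delta * (k - 1))`: a 10% decline after four
#' treatments corresponds to `delta = 0.025` per exposure.
#'
#' @param delta Per-exposure susceptibility decrement.
#' @param floor Lower bound on susceptibility.
#' @export
rf_resistance <- function(delta = 0.025, floor = 0) {
  if (delta < 0 || delta > 1) stop("rf_resistance: delta must be in [0,1]")
  structure(list(delta = delta, floor = floor), class = "rf_resistance")
}

#' RF susceptibility at the k-th exposure
#' @param res An [rf_resistance()] (or NULL for full susceptibility).
#' @param k Exposure index (1-based).
#' @export
rf_susceptibility <- function(res, k) {
  if (is.null(res)) return(1)
  max(res$floor, 1 - res$delta * (k - 1))
}

#' Plasma concentration after a bolus
#'
#' 0 before the dose; `dose_peak * exp(-(t - t0) / tau)` afterwards.
#'
#' @param t Time (h); vectorized.
#' @param ev A [dose_event()].
#' @param pk A [pk_params()].
#' @export
plasma_concentration <- function(t, ev, pk) {
  peak <- ev$dose_peak * pk$dose_peak
  ifelse(t < ev$t0, 0, peak * exp(-(t - ev$t0) / pk$tau))
}

#' Apply RF modulation to a species' transport parameters
#'
#' For an RF dose, penetration and transfer rate are scaled by
#' `1 + s_k * (f - 1)` where `s_k` is the current RF susceptibility;
#' unchanged when the event carries no RF flag.
#'
#' @param sp A [species_params()].
#' @param ev A [dose_event()].
#' @param res An [rf_resistance()] or NULL (no resistance).
#' @param k RF exposure index (>= 1).
#' @export
apply_rf <- function(sp, ev, res = NULL, k = 1) {
  if (k < 1) stop("apply_rf: exposure index k must be >= 1")
  if (!isTRUE(ev$rf)) return(sp)
  s <- rf_susceptibility(res, k)
  sp$P_rel <- sp$P_rel * (1 + s * (ev$f_D - 1))
  sp$TR <- sp$TR * (1 + s * (ev$f_TR - 1))
  sp
}

#' Pharmacodynamic kill-rate field
#'
#' `k_kill * c / (c50 + c)` elementwise (or `k_kill * c` for the linear
#' model), applied to whatever concentration-like field drives the kill.
#'
#' @param c Non-negative concentration/exposure field.
#' @param pd A [pd_params()].
#' @return Kill-rate field in `[0, k_kill)` (1/h).
#' @export
drug_kill_rate <- function(c, pd) {
  if (any(c < 0)) stop("drug_kill_rate: concentrations must be >= 0")
  if (pd$model == "linear") return(pd$k_kill * c)
  pd$k_kill * c / (pd$c50 + c)
}

#' Default avascular-spheroid configuration for PD calibration
#'
#' A 550 x 550 um domain at 5 um resolution holding a 200 um-radius
#' spheroid (viable fraction 0.8, uniform ECM 0.6) bathed in drug held at
#' the boundary.
#' @export
avascular_config <- function() {
  list(grid = sim_grid(110, 110, 5), radius = 200, phi0 = 0.8,
       ecm_density = 0.6, dt = 2, lambda_lys = growth_params()$lambda_lys)
}

#' Simulate drug exposure of an avascular spheroid
#'
#' Bath drug (boundary Dirichlet at `conc`) diffuses into an avascular
#' spheroid; the interstitial profile is re-solved quasi-steadily as viable
#' tissue dies, the retained-exposure field integrates it, and viable
#' tissue is killed at the PD rate. Killed cells enter a necrotic-debris
#' pool that still absorbs the drug (nucleic-acid binding) until slowly
#' lysed, so the kill front cannot race ahead of debris clearance. Growth
#' is disabled to isolate the drug effect. Returns the fractional
#' viable-mass reduction at `duration`.
#'
#' @param config An [avascular_config()]-style list.
#' @param sp Drug [species_params()].
#' @param pd A [pd_params()].
#' @param conc Bath concentration (normalized; 1.0 = 100 uM).
#' @param duration Exposure duration (h).
#' @param ecm An [ecm_params()].
#' @return Viable-mass reduction in `[0, 1]`.
#' @export
simulate_spheroid_exposure <- function(config, sp, pd, conc = 1, duration = 72,
                                       ecm = ecm_params(),
                                       o2 = species_params("O2", 1, 5, 1.0, 0.05),
                                       thresholds = tissue_thresholds()) {
  grid <- config$grid
  cx <- (grid$nx - 1) * grid$h / 2; cy <- (grid$ny - 1) * grid$h / 2
  phi <- matrix(0, grid$ny, grid$nx)
  phi[disk_mask(grid, cx, cy, config$radius)] <- config$phi0
  lesion <- lesion_state(grid, phi = phi)
  E <- scalar_field(grid, config$ecm_density)
  vessels <- scalar_field(grid, 0)
  m0 <- sum(lesion$phi)
  u <- scalar_field(grid, 0)
  nsteps <- ceiling(duration / config$dt)
  dt <- duration / nsteps
  lys <- config$lambda_lys %||% growth_params()$lambda_lys
  w_cyc <- NULL
  for (i in seq_len(nsteps)) {
    # oxygen from the well-oxygenated culture medium sets which cells cycle
    sigma <- solve_quasi_steady(o2, vessels, lesion, E, vessel_level = 0,
                                ecm = ecm, boundary_value = 1)
    lesion <- classify_tissue(sigma, lesion, thresholds)
    cfield <- solve_quasi_steady(sp, vessels, lesion, E, vessel_level = 0,
                                 ecm = ecm, boundary_value = conc)
    u <- u * exp(-dt / pd$tau_ret) + cfield * (dt / pd$tau_load)
    w_now <- cycle_kill_weight(lesion$labels, pd)
    if (is.null(w_cyc)) w_cyc <- w_now
    else if (pd$tau_cycle > 0)
      w_cyc <- w_cyc + (w_now - w_cyc) * (1 - exp(-dt / pd$tau_cycle))
    else w_cyc <- w_now
    k <- drug_kill_rate(u, pd) * w_cyc
    dphi <- lesion$phi * (1 - exp(-k * dt))
    lesion$phi <- lesion$phi - dphi
    # killed cells become debris, which keeps binding the drug until lysed;
    # as the debris clears, oxygen reaches deeper and recruits quiescent
    # cells into the cycle, where the retained drug can kill them
    lesion$nec <- pmin((lesion$nec + dphi) * exp(-lys * dt), 1)
  }
  1 - sum(lesion$phi) / m0
}

#' Calibrate the maximal kill rate against the EC70 datum
#'
#' Bisects `k_kill` until the avascular spheroid simulation reproduces the
#' target viable-mass reduction (default 70% at 100 uM for 72 h) to within
#' +/- 0.01.
#'
#' @param config An [avascular_config()]-style list.
#' @param sp Drug [species_params()].
#' @param pd Template [pd_params()] supplying `c50` and retention constants.
#' @param target_effect Target fractional reduction (default 0.70).
#' @param conc Calibration concentration (1.0 = 100 uM).
#' @param duration Exposure duration (h).
#' @param tol Acceptable |reduction - target| (default 0.005).
#' @return Calibrated [pd_params()] with attributes `reduction` (achieved)
#'   and `iterations`.
#' @export
calibrate_kill <- function(config = avascular_config(),
                           sp = species_params("Gem", 0.2, 5, 5, 0.2, TRUE,
                                               uptake_includes_debris = TRUE),
                           pd = pd_params(), target_effect = 0.70,
                           conc = 1, duration = 72, tol = 0.005) {
  eval_k <- function(k) {
    pd$k_kill <- k
    simulate_spheroid_exposure(config, sp, pd, conc, duration)
  }
  lo <- 0; red_lo <- 0
  hi <- 0.05; red_hi <- eval_k(hi)
  tries <- 0
  while (red_hi < target_effect && tries < 10) {
    lo <- hi; red_lo <- red_hi
    hi <- hi * 2; red_hi <- eval_k(hi); tries <- tries + 1
  }
  if (red_hi < target_effect)
    stop(sprintf("calibrate_kill: target %.2f unreachable (max reduction %.3f at k_kill = %g)",
                 target_effect, red_hi, hi))
  it <- tries + 1; mid <- hi; red <- red_hi
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    red <- eval_k(mid); it <- it + 1
    if (abs(red - target_effect) <= tol) break
    if (red < target_effect) lo <- mid else hi <- mid
  }
  if (abs(red - target_effect) > 2 * tol)
    stop(sprintf("calibrate_kill: did not converge (reduction %.3f)", red))
  pd$k_kill <- mid
  attr(pd, "reduction") <- red
  attr(pd, "iterations") <- it
  pd
}
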