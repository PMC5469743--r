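# Configuration handling and the experiment-level runners: single
# simulated treatments, the five-case transport-parameter sweep, and the
# weekly dosing protocol for advanced disease.

#' Default run configuration
#'
#' Nested list of every tunable block; YAML files with the same structure
#' can be loaded with [read_config()]. Unknown keys are rejected by
#' [validate_config()].
#' @export
default_config <- function() {
  list(
    grid = list(nx = 140, ny = 140, h = 10),
    species = list(
      o2 = list(P_rel = 1.0, TR = 5, lambda_u = 1.0, lambda_d = 0.05),
      gem = list(P_rel = 0.2, TR = 5, lambda_u = 5, lambda_d = 0.2,
                 uptake_includes_debris = TRUE)),
    fields = field_params(),
    ecm = list(lambda_deg = 0.005, alpha = 0.5),
    vasculature = list(spacing_nodes = 10, p_prune = 0.8,
                       angio = list(taf_threshold = 0.3, beta = 30,
                                    p_branch = 0.03, p_sprout = 0.01,
                                    step_h = 0.5,
                                    perfuse_on_anastomosis = TRUE,
                                    ecm_drag = 1, max_age_h = 150,
                                    max_tips = 40)),
    growth = list(lambda_mit = 0.030, lambda_apop = 0.002, lambda_nec = 0.05,
                  lambda_lys = 0.08, mobility = 1),
    pk = list(tau = 1.5, dose_peak = 1),
    pd = list(k_kill = NULL, c50 = 0.2, tau_load = 1, tau_ret = 24,
              quiescent_frac = 0.1, tau_cycle = 0, model = "saturating"),
    resistance = list(enabled = FALSE, delta = 0.025, floor = 0),
    thresholds = list(sigma_P = 0.35, sigma_N = 0.08),
    lesion = list(init_radius = 300, target_radius = 400, phi0 = 0.75,
                  ecm_mean = 0.6, ecm_sd = 0.15, smooth_sigma = 3,
                  max_hours = 600),
    schedule = list(),
    numerics = list(dt = 1, angio_every = 4, dose_window = 12,
                    drug_substeps = 4),
    t_end_h = 120,
    seed = 1)
}

#' Validate a run configuration
#'
#' Recursively checks the configuration against the [default_config()]
#' schema and rejects unknown keys; schedule entries are checked against
#' the dose-event schema (`t0_h`, `dose_uM`, `rf`, `f_D`, `f_TR`).
#'
#' @param config Nested configuration list.
#' @return The configuration merged over the defaults (invisibly usable).
#' @export
validate_config <- function(config) {
  ref <- default_config()
  bad <- character()
  walk <- function(cfg, ref, path) {
    for (k in names(cfg)) {
      if (!k %in% names(ref)) {
        bad <<- c(bad, paste0(path, k))
      } else if (is.list(cfg[[k]]) && is.list(ref[[k]]) &&
                 !is.null(names(ref[[k]]))) {
        walk(cfg[[k]], ref[[k]], paste0(path, k, "."))
      }
    }
  }
  cfg_nosched <- config[setdiff(names(config), "schedule")]
  walk(cfg_nosched, ref, "")
  dose_schema <- c("t0_h", "dose_uM", "rf", "f_D", "f_TR")
  for (i in seq_along(config$schedule)) {
    extra <- setdiff(names(config$schedule[[i]]), dose_schema)
    if (length(extra) > 0)
      bad <- c(bad, paste0("schedule[", i, "].", extra))
  }
  if (length(bad) > 0)
    stop("validate_config: unknown configuration keys: ",
         paste(bad, collapse = ", "))
  merged <- utils::modifyList(ref, cfg_nosched)
  merged$schedule <- config$schedule %||% list()
  if (length(merged$schedule) > 1) {
    t0s <- vapply(merged$schedule, function(d) d$t0_h, numeric(1))
    if (any(diff(t0s) <= 0))
      stop("validate_config: schedule dose times must be strictly increasing")
  }
  merged
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a YAML run configuration
#'
#' @param path YAML file with the [default_config()] structure.
#' @return Validated configuration list.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' Build typed model parameters from a configuration
#'
#' @param config Validated configuration list.
#' @return A [sim_params()] bundle.
#' @export
config_to_params <- function(config) {
  sp <- config$species
  pd_cfg <- config$pd
  k_kill <- pd_cfg$k_kill %||% default_k_kill()
  sim_params(
    o2 = species_params("O2", sp$o2$P_rel, sp$o2$TR, sp$o2$lambda_u,
                        sp$o2$lambda_d),
    gem = species_params("Gem", sp$gem$P_rel, sp$gem$TR, sp$gem$lambda_u,
                         sp$gem$lambda_d, follows_plasma = TRUE,
                         uptake_includes_debris =
                           isTRUE(sp$gem$uptake_includes_debris)),
    growth = do.call(growth_params, config$growth),
    angio = do.call(angiogenesis_params, config$vasculature$angio),
    ecm = do.call(ecm_params, config$ecm),
    fields = config$fields,
    pk = do.call(pk_params, config$pk),
    pd = pd_params(k_kill, pd_cfg$c50, pd_cfg$tau_load, pd_cfg$tau_ret,
                   pd_cfg$quiescent_frac %||% 0.1, pd_cfg$tau_cycle %||% 0,
                   pd_cfg$model),
    resistance = if (isTRUE(config$resistance$enabled))
      rf_resistance(config$resistance$delta, config$resistance$floor) else NULL,
    thresholds = tissue_thresholds(config$thresholds$sigma_P,
                                   config$thresholds$sigma_N),
    vasc = list(p_prune = config$vasculature$p_prune),
    numerics = config$numerics)
}

#' Shipped default maximal kill rate
#'
#' The PD kill rate obtained by running [calibrate_kill()] with the default
#' avascular-spheroid configuration (EC70: 70% viable-mass reduction at
#' 100 uM for 72 h). Re-run the calibration to regenerate it.
#' @export
default_k_kill <- function() 0.3

# internal: schedule list-of-blocks -> therapy_schedule
config_schedule <- function(config) {
  evs <- lapply(config$schedule, function(d)
    dose_event(t0 = d$t0_h, dose_peak = (d$dose_uM %||% 100) / 100,
               rf = isTRUE(d$rf), f_D = d$f_D %||% 1.75,
               f_TR = d$f_TR %||% 1.75))
  therapy_schedule(evs)
}

#' Run a configured treatment experiment
#'
#' Generates (or reuses) the pre-treatment reference lesion, runs the
#' configured schedule, and writes `trajectory.csv`, `summary.json` and a
#' reproducibility manifest to the output directory.
#'
#' @param config Configuration list (validated against the schema) or a
#'   YAML path.
#' @param out_dir Output directory (created); NULL to skip writing.
#' @param reference Optional precomputed result of
#'   [gen_pretreatment_lesion()] to reuse across runs.
#' @return List with `trajectory`, `summary`, `reference` (invisibly).
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           reference = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  params <- config_to_params(config)
  if (is.null(reference))
    reference <- gen_pretreatment_lesion(
      c(list(grid = sim_grid(config$grid$nx, config$grid$ny, config$grid$h)),
        config$lesion), seed = config$seed, params = params)
  params$thresholds <- reference$thresholds
  sched <- config_schedule(config)
  traj <- run_schedule(reference$lesion, reference$net, sched, params,
                       t_end = config$t_end_h, seed = config$seed + 1L,
                       E = reference$E)
  summ <- summarize_trajectory(traj)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("pdacRF")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(trajectory = traj, summary = summ, reference = reference))
}

# internal: standard summary block for a trajectory
summarize_trajectory <- function(traj) {
  doses <- attr(traj, "dose_times")
  ms <- minimal_size(traj)
  out <- list(
    radius_initial_um = traj$radius_um[1],
    radius_final_um = traj$radius_um[nrow(traj)],
    radius_final_fraction = traj$radius_um[nrow(traj)] / traj$radius_um[1],
    minimal_size_fraction = ms$fraction,
    minimal_size_t_h = ms$t_h)
  if (length(doses) > 0) {
    t48 <- doses[1] + 48
    if (t48 <= max(traj$t_h))
      out$regression_48h_pct <- regression_percent(traj, t48, doses[1])
  }
  out
}

#' The five-case transport sweep
#'
#' Packaged preset of the single-treatment comparisons: drug alone, doubled
#' vascular transfer, RF enhancement of both parameters by 75%, penetration
#' maximized to oxygen's, and penetration maximized with doubled transfer.
#' Multipliers apply to the baseline drug parameters (P_rel = 0.2, TR = 5).
#' @export
sweep_preset <- function() {
  list(list(name = "gem_only", P_mult = 1, TR_mult = 1),
       list(name = "tr_x2", P_mult = 1, TR_mult = 2),
       list(name = "rf_175", P_mult = 1.75, TR_mult = 1.75),
       list(name = "d_max", P_mult = 5, TR_mult = 1),
       list(name = "both_max", P_mult = 5, TR_mult = 2))
}

#' Run a transport-parameter sweep
#'
#' Runs one single-bolus treatment per case on a shared pre-treatment
#' lesion, varying the drug's relative penetration and vascular transfer
#' rate. Per-case RNG streams are derived from the master seed by case
#' index, so results are order-independent.
#'
#' @param base_config Base configuration (single dose at `t0_h = 0` is
#'   imposed; `t_end_h` sets the per-case duration).
#' @param cases List of case lists (`name`, `P_mult`, `TR_mult`); default
#'   [sweep_preset()].
#' @param reference Optional precomputed reference lesion.
#' @return Data frame: name, P_rel, TR, regression at 48 h (%), minimal
#'   size fraction, time of minimum (h). Per-case failures are recorded as
#'   NA rows and the sweep continues.
#' @export
run_sweep <- function(base_config = default_config(), cases = sweep_preset(),
                      reference = NULL) {
  if (length(cases) < 1) stop("run_sweep: need at least one case")
  config <- validate_config(base_config)
  params0 <- config_to_params(config)
  if (is.null(reference))
    reference <- gen_pretreatment_lesion(
      c(list(grid = sim_grid(config$grid$nx, config$grid$ny, config$grid$h)),
        config$lesion), seed = config$seed, params = params0)
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    res <- tryCatch({
      params <- params0
      params$thresholds <- reference$thresholds
      params$gem$P_rel <- params0$gem$P_rel * cs$P_mult
      params$gem$TR <- params0$gem$TR * cs$TR_mult
      sched <- therapy_schedule(dose_event(t0 = 0))
      traj <- run_schedule(reference$lesion, reference$net, sched, params,
                           t_end = config$t_end_h,
                           seed = config$seed + 100L + i, E = reference$E)
      ms <- minimal_size(traj)
      data.frame(name = cs$name, P_rel = params$gem$P_rel, TR = params$gem$TR,
                 regression_48h_pct = regression_percent(traj, 48, 0),
                 minimal_size = ms$fraction, t_min_h = ms$t_h)
    }, error = function(e) {
      warning(sprintf("sweep case '%s' failed: %s", cs$name, conditionMessage(e)))
      data.frame(name = cs$name, P_rel = NA, TR = NA,
                 regression_48h_pct = NA, minimal_size = NA, t_min_h = NA)
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}

#' Run the weekly dosing protocol
#'
#' Builds a once-weekly schedule (`n_weeks` doses at 168 h intervals,
#' optionally RF-enhanced) and runs it on the reference lesion.
#'
#' @param base_config Base configuration.
#' @param n_weeks Number of weekly doses.
#' @param rf Whether each dose follows RF exposure.
#' @param f_D,f_TR RF enhancement multipliers.
#' @param weeks_simulated Simulated duration in weeks (default `n_weeks`).
#' @param reference Optional precomputed reference lesion.
#' @param resistance Optional [rf_resistance()]; NULL uses the config.
#' @return List: `trajectory`, `weekly` (data frame of week, radius, and
#'   radius as fraction of initial), `summary`.
#' @export
run_weekly_protocol <- function(base_config = default_config(), n_weeks = 7,
                                rf = FALSE, f_D = 1.75, f_TR = 1.75,
                                weeks_simulated = n_weeks, reference = NULL,
                                resistance = NULL) {
  config <- validate_config(base_config)
  config$t_end_h <- weeks_simulated * 168
  config$schedule <- lapply(seq_len(n_weeks), function(k)
    list(t0_h = (k - 1) * 168, dose_uM = 100, rf = rf, f_D = f_D, f_TR = f_TR))
  params <- config_to_params(config)
  if (!is.null(resistance)) params$resistance <- resistance
  if (is.null(reference))
    reference <- gen_pretreatment_lesion(
      c(list(grid = sim_grid(config$grid$nx, config$grid$ny, config$grid$h)),
        config$lesion), seed = config$seed, params = params)
  params$thresholds <- reference$thresholds
  traj <- run_schedule(reference$lesion, reference$net,
                       config_schedule(config), params,
                       t_end = config$t_end_h, seed = config$seed + 1L,
                       E = reference$E)
  wk <- seq_len(weeks_simulated)
  weekly <- data.frame(
    week = wk,
    radius_um = vapply(wk * 168, function(t) traj_radius_at(traj, t),
                       numeric(1)))
  weekly$fraction_of_initial <- weekly$radius_um / traj$radius_um[1]
  list(trajectory = traj, weekly = weekly,
       summary = summarize_trajectory(traj), reference = reference)
}
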