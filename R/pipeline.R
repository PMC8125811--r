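#' Campaign configuration
#'
#' Describes a simulation campaign: one row per condition (ionic strength x
#' linker regime), trials per condition, the base seed (trial seeds are
#' `base_seed + trial_index` over a campaign-global trial counter) and
#' shared simulator/analysis settings.
#'
#' @param conditions Data frame with columns `ionic_strength` (mol/L) and
#'   `linker_regime` (`"WT"`/`"labile"`); non-empty.
#' @param n_trials Trials per condition (>= 1; the emulated campaign uses
#'   200).
#' @param base_seed Integer base seed.
#' @param box_side,t_max,dt,stride See [simulation_config()].
#' @param bind_threshold,contact_cutoff Bound-state definition.
#' @param min_placement_distance Initial-placement exclusion radius in
#'   Angstrom.
#' @param native_well_depth,native_well_width Native-site well (kcal/mol,
#'   Angstrom).
#' @param timescale_factor CG-to-all-atom clock factor applied to mean FPTs.
#' @param n_boot Bootstrap resamples for the rate estimate.
#' @param record_frames Retain coordinates (needed for landscape/RG
#'   analyses; off by default to keep memory flat).
#' @param receptor_args,ligand_args Extra arguments for [build_receptor()] /
#'   [build_ligand()].
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(conditions, n_trials = 200, base_seed = 1,
                            box_side = 150, t_max = 2000, dt = 0.01,
                            stride = 100, bind_threshold = 50,
                            contact_cutoff = 5.5,
                            min_placement_distance = 40,
                            native_well_depth = 12,
                            native_well_width = 7, timescale_factor = 4,
                            n_boot = 1000, record_frames = FALSE,
                            receptor_args = list(), ligand_args = list()) {
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0) stop("`conditions` must be non-empty")
  if (!all(c("ionic_strength", "linker_regime") %in% names(conditions))) {
    stop("`conditions` needs columns ionic_strength and linker_regime")
  }
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  structure(as.list(environment()), class = "campaign_config")
}

#' @export
print.campaign_config <- function(x, ...) {
  cat(sprintf("campaign_config: %d condition(s) x %d trials, base seed %d\n",
              nrow(x$conditions), x$n_trials, x$base_seed))
  invisible(x)
}

#' Run a full simulation + analysis campaign
#'
#' For each condition, builds the regime's topology, runs `n_trials`
#' Brownian-dynamics trials, extracts first passage times, and produces the
#' bootstrap rate estimate plus an exponential fit of the FPT distribution.
#' A failing condition is logged and marked failed; the campaign continues.
#' Fully reproducible from `base_seed`.
#'
#' @param config A [campaign_config()].
#' @param verbose Print per-condition progress.
#' @return A list with `rates` (one data-frame row per condition: n,
#'   censored count, mean Tfp ns with sd, ka with sd in 1/M/s), `samples`
#'   (per-condition `fpt_sample`), `fits` (exponential fits), `trial_log`
#'   (per-trial seed, FPT, censored flag) and `trajectories` (when
#'   `record_frames = TRUE`).
#' @export
run_campaign <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "campaign_config"))
  conds <- config$conditions
  rates <- NULL
  samples <- list()
  fits <- list()
  trajs <- list()
  log_rows <- list()
  trial_counter <- 0L
  for (ci in seq_len(nrow(conds))) {
    regime <- as.character(conds$linker_regime[ci])
    ionic <- conds$ionic_strength[ci]
    label <- sprintf("%s_%gM", regime, ionic)
    row <- tryCatch({
      receptor <- do.call(build_receptor, c(
        list(linker = linker_spec(regime_tag = regime)),
        config$receptor_args))
      ligand <- do.call(build_ligand, config$ligand_args)
      topo <- assemble_system(receptor, ligand, box_side = config$box_side)
      inter <- interaction_model(ionic_strength = ionic,
                           native_well_depth = config$native_well_depth,
                           native_well_width = config$native_well_width,
                           cutoff = config$box_side / 2)
      times <- numeric(config$n_trials)
      cens <- logical(config$n_trials)
      cond_trajs <- if (config$record_frames) {
        vector("list", config$n_trials)
      } else NULL
      for (tr in seq_len(config$n_trials)) {
        trial_counter <- trial_counter + 1L
        seed <- config$base_seed + trial_counter
        sc <- simulation_config(
          ionic_strength = ionic, box_side = config$box_side,
          dt = config$dt, t_max = config$t_max, stride = config$stride,
          seed = seed, linker_regime = regime,
          min_placement_distance = config$min_placement_distance,
          bind_mode = "contacts", bind_threshold = config$bind_threshold,
          contact_cutoff = config$contact_cutoff,
          stop_on_bind = !config$record_frames,
          record_frames = config$record_frames)
        t0 <- Sys.time()
        traj <- simulate_trial(topo, sc, inter)
        times[tr] <- ifelse(traj$censored, NA_real_, traj$fpt)
        cens[tr] <- traj$censored
        if (config$record_frames) cond_trajs[[tr]] <- traj
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          condition = label, trial = tr, seed = seed,
          fpt = times[tr], censored = cens[tr],
          wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      }
      samp <- fpt_sample(times, cens, t_max = config$t_max)
      est <- rate_estimate(samp, box_volume = config$box_side^3 * 1e-27,
                           timescale_factor = config$timescale_factor,
                           n_boot = config$n_boot,
                           seed = config$base_seed + ci)
      fit <- if (sum(!cens) >= 10) {
        fit_exponential(samp$times[!samp$censored])
      } else NULL
      list(sample = samp, est = est, fit = fit, trajs = cond_trajs,
           df = data.frame(
             condition = label, ionic_strength = ionic,
             linker_regime = regime, n = config$n_trials,
             n_censored = sum(cens),
             mean_tfp_ns = est$mean_tfp, tfp_sd_ns = est$tfp_sd,
             ka = est$ka, ka_sd = est$ka_sd, failed = FALSE))
    }, error = function(e) {
      warning("condition ", label, " failed: ", conditionMessage(e))
      list(sample = NULL, est = NULL, fit = NULL, trajs = NULL,
           df = data.frame(
             condition = label, ionic_strength = ionic,
             linker_regime = regime, n = config$n_trials,
             n_censored = NA_integer_, mean_tfp_ns = NA_real_,
             tfp_sd_ns = NA_real_, ka = NA_real_, ka_sd = NA_real_,
             failed = TRUE))
    })
    rates <- rbind(rates, row$df)
    samples[[label]] <- row$sample
    fits[[label]] <- row$fit
    if (config$record_frames) trajs[[label]] <- row$trajs
    if (verbose) {
      message(sprintf("[%s] mean Tfp %.4g ns, ka %.3g /M/s (%s censored)",
                      label, row$df$mean_tfp_ns, row$df$ka,
                      row$df$n_censored))
    }
  }
  list(rates = rates,
       samples = samples,
       fits = fits,
       trial_log = do.call(rbind, log_rows),
       trajectories = if (config$record_frames) trajs else NULL)
}

#' Reproduce the rate-table arithmetic from printed mean FPTs
#'
#' Applies [ka_from_mean_fpt()] to each mean first passage time (all-atom
#' clock, ns) and reports the association rates in units of 1e8 /M/s
#' rounded to two decimals.
#'
#' @param tfp_values Mean first passage times in ns (all-atom clock).
#' @param box_volume Box volume in litres (default 3.375e-21).
#' @return Numeric vector of ka values in 1e8 /M/s, 2 decimals.
#' @examples
#' reproduce_table1(c(1247.78, 1708.28, 2326.98)) # 16.29 11.90 8.73
#' @export
reproduce_table1 <- function(tfp_values, box_volume = 3.375e-21) {
  if (length(tfp_values) == 0) return(numeric(0))
  round(ka_from_mean_fpt(tfp_values, box_volume) / 1e8, 2)
}

#' Write a campaign rates table to CSV and JSON
#'
#' @param rates The `rates` data frame from [run_campaign()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the rates table.
#' @export
write_rates_table <- function(rates, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(rates, csv_path,
                                           row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(rates, json_path, digits = NA, dataframe = "rows")
  }
  invisible(rates)
}
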