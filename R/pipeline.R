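#' Run the full synthetic calibration-to-hybrid workflow
#'
#' End-to-end orchestration on synthetic experiments:
#' generate (two train replicates + one shifted test run) -> densify ->
#' calibrate by GWO with bound refinement -> identifiability screening
#' with sequential fixing -> re-calibrate the retained free set ->
#' Monte Carlo uncertainty bands -> residuals -> TPE-tuned LSTM ->
#' hybrid blending -> RMSE evaluation. Every stage's artifact is
#' returned, and a machine-readable manifest records seeds and stage
#' fingerprints so identical configurations reproduce identical runs.
#'
#' @param true_params generating [kinetic_params()] for the synthetic
#'   experiments.
#' @param model_params parameters used by the mechanistic model being
#'   evaluated (defaults to `start_params` after calibration; pass the
#'   truth and `calibrate = FALSE` for an identity check).
#' @param start_params calibration starting values.
#' @param do_calibration run the calibration stages (disable to
#'   evaluate `model_params` as-is).
#' @param noise [noise_model()] for the generator.
#' @param sched [sampling_schedule()].
#' @param spec [ic_spec()].
#' @param free parameters searched in the first calibration pass.
#' @param pop,round_epochs,total_epochs GWO settings.
#' @param tpe_trials TPE trials for the LSTM stage.
#' @param lstm_space TPE search space.
#' @param max_epochs LSTM training-epoch cap.
#' @param weights [hybrid_weights()].
#' @param mc_n,mc_rel_sd Monte Carlo settings.
#' @param rollout hybrid roll-out policy.
#' @param rng_seed master seed; every stage derives its own seed from it.
#' @param out_dir optional directory: when given, every intermediate
#'   artifact (CSV/JSON) plus the manifest is written there.
#' @param cfg,opts model configuration.
#' @return A `ferm_pipeline` list: `datasets`, `densified`,
#'   `calibration`, `fixing`, `recalibration`, `params_final`, `bands`,
#'   `residuals`, `tpe`, `hybrid` (per dataset), `rmse`, `manifest`.
#' @export
run_pipeline <- function(true_params = default_params(),
                         model_params = NULL,
                         start_params = initial_params(),
                         do_calibration = TRUE,
                         noise = noise_model(),
                         sched = sampling_schedule(),
                         spec = ic_spec(),
                         free = param_names(),
                         pop = 30L, round_epochs = 20L, total_epochs = 160L,
                         tpe_trials = 10L,
                         lstm_space = .tpe_space_default(),
                         max_epochs = 300L,
                         weights = hybrid_weights(),
                         mc_n = 100L, mc_rel_sd = 0.05,
                         rollout = "teacher",
                         rng_seed = 1L, out_dir = NULL,
                         cfg = gating_config(), opts = model_options()) {
  seeds <- rng_seed + c(gen1 = 11L, gen2 = 23L, gen_test = 37L,
                        calib = 41L, recal = 43L, mc = 53L, tpe = 59L)

  # --- experiments -----------------------------------------------------
  train1 <- generate_experiment(true_params, role = "train", spec = spec,
                                sched = sched, noise = noise,
                                rng_seed = seeds[["gen1"]], cfg = cfg,
                                opts = opts)
  train2 <- generate_experiment(true_params, role = "train", spec = spec,
                                sched = sched, noise = noise,
                                rng_seed = seeds[["gen2"]], cfg = cfg,
                                opts = opts)
  test <- generate_experiment(true_params, role = "test", spec = spec,
                              sched = sched, noise = noise,
                              rng_seed = seeds[["gen_test"]], cfg = cfg,
                              opts = opts)
  datasets <- list(train1 = train1, train2 = train2, test = test)

  # --- densification (each train replicate separately) -----------------
  densified <- lapply(datasets[1:2], densify, n_free_params = length(free))

  # --- calibration + identifiability ----------------------------------
  calib <- fixing <- recal <- NULL
  if (do_calibration) {
    calib <- calibrate(densified, free = free, start = start_params,
                       pop = pop, round_epochs = round_epochs,
                       total_epochs = total_epochs,
                       rng_seed = seeds[["calib"]], cfg = cfg, opts = opts)
    fixing <- sequential_fixing(calib$params, datasets[1:2],
                                free = free, cfg = cfg, opts = opts)
    densified_free <- lapply(datasets[1:2], densify,
                             n_free_params = length(fixing$free))
    recal <- calibrate(densified_free, free = fixing$free,
                       start = calib$params, pop = pop,
                       round_epochs = round_epochs,
                       total_epochs = total_epochs,
                       rng_seed = seeds[["recal"]], cfg = cfg, opts = opts)
    params_final <- recal$params
  } else {
    params_final <- kinetic_params(
      .values = if (is.null(model_params)) start_params else model_params)
  }

  # --- uncertainty -----------------------------------------------------
  bands <- monte_carlo_bands(params_final, attr(test, "ic"),
                             t_grid = test$time_h, rel_sd = mc_rel_sd,
                             n = mc_n, rng_seed = seeds[["mc"]],
                             cfg = cfg, opts = opts)

  # --- residual learning ----------------------------------------------
  res_train <- lapply(datasets[1:2], compute_residuals, p = params_final,
                      cfg = cfg, opts = opts)
  # shared scaler fitted on pooled training residuals
  pooled <- do.call(rbind, lapply(res_train, `[[`, "residuals"))
  scaler <- fit_minmax_scaler(pooled)
  res_train <- lapply(datasets[1:2], compute_residuals, p = params_final,
                      scaler = scaler, cfg = cfg, opts = opts)
  res_test <- compute_residuals(test, params_final, scaler = scaler,
                                cfg = cfg, opts = opts)
  wins <- lapply(res_train, make_windows)
  wd <- list(inputs = abind_first(lapply(wins, `[[`, "inputs")),
             targets = do.call(rbind, lapply(wins, `[[`, "targets")),
             look_back = wins[[1]]$look_back, scaler = scaler,
             times = unlist(lapply(wins, `[[`, "times")))
  class(wd) <- "ferm_windows"
  tpe <- tpe_search(wd, trials = tpe_trials, rng_seed = seeds[["tpe"]],
                    space = lstm_space, max_epochs = max_epochs)

  # --- hybrid + evaluation --------------------------------------------
  all_res <- c(res_train, list(test = res_test))
  hybrids <- lapply(all_res, hybrid_predict, model = tpe$best_model,
                    weights = weights, rollout = rollout)
  evals <- list()
  for (nm in names(datasets)) {
    role <- attr(datasets[[nm]], "role")
    evals <- c(evals,
               list(list(model = "mechanistic", role = role,
                         pred = all_res[[nm]]$pheno, obs = datasets[[nm]]),
                    list(model = "hybrid", role = role,
                         pred = hybrids[[nm]], obs = datasets[[nm]])))
  }
  rmse_tab <- rmse_table(evals)

  manifest <- list(
    seed = rng_seed, stage_seeds = as.list(seeds),
    n_free_initial = length(free),
    free_after_fixing = if (do_calibration) fixing$free else free,
    tpe_trials = tpe_trials, mc_n = mc_n, mc_rel_sd = mc_rel_sd,
    weights = unclass(weights), rollout = rollout,
    params_final = as.list(unclass(params_final)),
    rmse = as.data.frame(rmse_tab)
  )
  out <- structure(list(datasets = datasets, densified = densified,
                        calibration = calib, fixing = fixing,
                        recalibration = recal,
                        params_final = params_final, bands = bands,
                        residuals = all_res, tpe = tpe, hybrid = hybrids,
                        rmse = rmse_tab, manifest = manifest),
                   class = "ferm_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(datasets)) {
      write_dataset_csv(datasets[[nm]], file.path(out_dir,
                                                  paste0(nm, ".csv")))
      write_trajectory_csv(hybrids[[nm]],
                           file.path(out_dir, paste0("hybrid_", nm, ".csv")))
    }
    utils::write.csv(as.data.frame(rmse_tab),
                     file.path(out_dir, "rmse.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

# bind 3-d arrays along the first dimension
abind_first <- function(arrays) {
  d <- dim(arrays[[1]])
  n <- sum(vapply(arrays, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 0
  for (a in arrays) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.ferm_pipeline <- function(x, ...) {
  cat("<ferm_pipeline>\n")
  print(x$rmse)
  invisible(x)
}
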