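#' Initial-condition specification for synthetic batch experiments
#'
#' Defaults reproduce the study design the generator emulates: two
#' train-like biological replicates drawn around
#' sucrose 32.7 +/- 3.9, glucose 27.3 +/- 3.8, fructose 27.1 +/- 4.1,
#' biomass 0.5 +/- 0.1, urea 2.6 +/- 0.7 g/L, and a single shifted
#' test run at 39.6 / 27.5 / 25.8 / 1.2 / 2.3 g/L. Ethanol starts at 0;
#' working volume is 0.3 or 0.4 L.
#'
#' @param mean named numeric: train-role means (g/L) for S, G, R, X, U.
#' @param sd named numeric: train-role SDs (g/L).
#' @param test named numeric: fixed test-role values (g/L).
#' @param volume working volume, L.
#' @return Named list with class `ic_spec`.
#' @export
ic_spec <- function(mean = c(S = 32.7, G = 27.3, R = 27.1, X = 0.5, U = 2.6),
                    sd = c(S = 3.9, G = 3.8, R = 4.1, X = 0.1, U = 0.7),
                    test = c(S = 39.6, G = 27.5, R = 25.8, X = 1.2, U = 2.3),
                    volume = 0.4) {
  keys <- c("S", "G", "R", "X", "U")
  stopifnot(all(keys %in% names(mean)), all(keys %in% names(sd)),
            all(keys %in% names(test)), volume %in% c(0.3, 0.4))
  structure(list(mean = mean[keys], sd = sd[keys], test = test[keys],
                 volume = volume), class = "ic_spec")
}

#' Draw an initial condition
#'
#' Train role: each concentration is drawn from a Normal truncated at 0
#' around the replicate mean/SD. Test role: the fixed shifted values.
#' Ethanol is always 0 at inoculation.
#'
#' @param spec an [ic_spec()].
#' @param role `"train"` or `"test"`.
#' @param rng_seed integer seed (ignored for the deterministic test role).
#' @return A [state_vector()].
#' @export
draw_initial_conditions <- function(spec = ic_spec(),
                                    role = c("train", "test"),
                                    rng_seed = 1L) {
  role <- match.arg(role)
  vals <- if (role == "test") {
    spec$test
  } else {
    withr::with_seed(rng_seed, {
      v <- stats::rnorm(5, spec$mean, spec$sd)
      while (any(v < 0)) {                 # truncate at 0 by redraw
        i <- v < 0
        v[i] <- stats::rnorm(sum(i), spec$mean[i], spec$sd[i])
      }
      stats::setNames(v, names(spec$mean))
    })
  }
  state_vector(X = vals[["X"]], G = vals[["G"]], R = vals[["R"]],
               S = vals[["S"]], U = vals[["U"]], Et = 0, V = spec$volume)
}

#' Sampling schedule
#'
#' Emulates the study cadence: dense sampling every 1.5-3 h up to ~30 h
#' while sugars are being consumed, then sparser samples (default every
#' 6 h) as growth slows on ethanol, up to the horizon.
#'
#' @param dense_range length-2 numeric, h: interval range in the dense phase.
#' @param dense_end end of the dense phase, h.
#' @param sparse_interval interval after `dense_end`, h.
#' @param horizon final time, h.
#' @return Named list with class `sampling_schedule`.
#' @export
sampling_schedule <- function(dense_range = c(1.5, 3), dense_end = 30,
                              sparse_interval = 6, horizon = 48) {
  stopifnot(length(dense_range) == 2, dense_range[1] > 0,
            diff(dense_range) >= 0, dense_end > 0, horizon >= dense_end,
            sparse_interval > 0)
  structure(list(dense_range = dense_range, dense_end = dense_end,
                 sparse_interval = sparse_interval, horizon = horizon),
            class = "sampling_schedule")
}

# Draw the actual sample times for one run (first sample at t = 0,
# strictly increasing).
.draw_sample_times <- function(sched, rng_seed) {
  withr::with_seed(rng_seed, {
    t <- 0
    times <- 0
    while (t < sched$dense_end) {
      t <- t + stats::runif(1, sched$dense_range[1], sched$dense_range[2])
      if (t <= sched$horizon) times <- c(times, t)
    }
    while (t < sched$horizon) {
      t <- min(t + sched$sparse_interval, sched$horizon)
      times <- c(times, t)
    }
    round(times, 3)
  })
}

#' Measurement-noise model
#'
#' Gaussian noise truncated at 0, with standard deviation
#' `max(rel_sd * value, abs_sd)` per observation. `noise_model(0, 0)`
#' reproduces the model output exactly.
#'
#' @param rel_sd relative SD (default 0.05).
#' @param abs_sd absolute SD floor, g/L (default 0.02).
#' @return Named list with class `noise_model`.
#' @export
noise_model <- function(rel_sd = 0.05, abs_sd = 0.02) {
  stopifnot(rel_sd >= 0, abs_sd >= 0)
  structure(list(rel_sd = rel_sd, abs_sd = abs_sd), class = "noise_model")
}

#' Generate one synthetic batch experiment
#'
#' Simulates the kinetic model at schedule-drawn sample times, applies
#' truncated Gaussian measurement noise, and records the generating
#' parameters and seed so recovery tests can compare against truth.
#' Deterministic given `rng_seed`.
#'
#' @param p generating [kinetic_params()].
#' @param ic initial [state_vector()]; if `NULL`, drawn from `spec`.
#' @param role `"train"` or `"test"`.
#' @param spec [ic_spec()] used when `ic` is `NULL`.
#' @param sched [sampling_schedule()].
#' @param noise [noise_model()].
#' @param rng_seed integer seed.
#' @inheritParams simulate_fermentation
#' @return A tibble (class `ferm_dataset`) with columns `time_h` and the
#'   six concentration channels; attributes `role`, `ic`, `true_params`,
#'   `seed`, `volume`.
#' @export
generate_experiment <- function(p = default_params(), ic = NULL,
                                role = c("train", "test"),
                                spec = ic_spec(),
                                sched = sampling_schedule(),
                                noise = noise_model(),
                                rng_seed = 1L,
                                cfg = gating_config(),
                                opts = model_options()) {
  role <- match.arg(role)
  if (is.null(ic)) {
    ic <- draw_initial_conditions(spec, role, rng_seed = rng_seed)
  }
  times <- .draw_sample_times(sched, rng_seed + 1L)
  traj <- simulate_fermentation(ic, p, t_grid = times, cfg = cfg,
                                opts = opts)
  vals <- as.matrix(traj[, .channel_names])
  if (noise$rel_sd > 0 || noise$abs_sd > 0) {
    vals <- withr::with_seed(rng_seed + 2L, {
      sd <- pmax(noise$rel_sd * vals, noise$abs_sd)
      noisy <- vals + stats::rnorm(length(vals), 0, sd)
      pmax(noisy, 0)
    })
  }
  out <- tibble::as_tibble(cbind(time_h = times, as.data.frame(vals)))
  structure(out, class = c("ferm_dataset", class(out)),
            role = role, ic = ic, true_params = p, seed = rng_seed,
            volume = ic[["V"]])
}

#' Polynomial densification of a sparse dataset
#'
#' Regression preprocessing that turns sparse, noisy measurements into a
#' dense fitting grid: per channel, polynomials in standardized time of
#' degree 2..`max_degree` are fit by least squares and the degree with
#' the highest adjusted R-squared is kept (the adjustment guards against
#' oscillatory overfit); the fit is evaluated on an even grid of
#' `10 * n_free_params` points over the sampled window and negative
#' values are clamped to 0. A constant channel is fit with degree 0 and
#' its R-squared is defined as 1.
#'
#' @param ds a `ferm_dataset` (or data frame with `time_h` + channels).
#' @param n_free_params number of free model parameters (grid size is
#'   10 per free parameter).
#' @param max_degree maximum polynomial degree considered.
#' @return A tibble (class `ferm_densified`) with `time_h` + channels;
#'   attributes `degree` and `r_squared` (named per channel), and `role`
#'   carried over when present.
#' @export
densify <- function(ds, n_free_params = 22L, max_degree = 6L) {
  stopifnot(nrow(ds) >= 6, n_free_params >= 1)
  t_raw <- ds$time_h
  t_sc <- scale(t_raw)            # standardized time for conditioning
  grid_raw <- seq(0, max(t_raw), length.out = 10L * n_free_params)
  grid_sc <- (grid_raw - attr(t_sc, "scaled:center")) /
    attr(t_sc, "scaled:scale")
  degrees <- integer(0); r2s <- numeric(0)
  fitted <- list()
  for (ch in .channel_names) {
    y <- ds[[ch]]
    if (max(y) - min(y) < .Machine$double.eps^0.5) {
      fitted[[ch]] <- rep(mean(y), length(grid_raw))
      degrees[ch] <- 0L; r2s[ch] <- 1
      next
    }
    best <- NULL; best_adj <- -Inf
    for (d in 2:min(max_degree, nrow(ds) - 1L)) {
      fit <- stats::lm(y ~ stats::poly(as.numeric(t_sc), d, raw = TRUE))
      # summary.lm warns on an exactly polynomial (perfect) fit
      adj <- suppressWarnings(summary(fit)$adj.r.squared)
      if (is.finite(adj) && adj > best_adj) {
        best_adj <- adj; best <- fit; degrees[ch] <- d
      }
    }
    co <- stats::coef(best)
    co[is.na(co)] <- 0
    yhat <- drop(outer(grid_sc, 0:degrees[ch], `^`) %*% co)
    fitted[[ch]] <- pmax(yhat, 0)
    r2s[ch] <- suppressWarnings(summary(best)$r.squared)
  }
  out <- tibble::as_tibble(c(list(time_h = grid_raw), fitted))
  structure(out, class = c("ferm_densified", class(out)),
            degree = degrees, r_squared = r2s,
            role = attr(ds, "role"), ic = attr(ds, "ic"),
            source_times = t_raw)
}

#' Write / read a dataset CSV with a JSON metadata sidecar
#'
#' The CSV uses the shared column convention; `<path>.json` stores role,
#' seed and the generating parameters when known.
#'
#' @param ds `ferm_dataset` or `ferm_densified`.
#' @param path CSV file path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` a tibble with restored attributes if the
#'   sidecar exists.
#' @export
write_dataset_csv <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE)
  meta <- list(role = attr(ds, "role"), seed = attr(ds, "seed"))
  if (!is.null(attr(ds, "true_params"))) {
    meta$true_params <- as.list(unclass(attr(ds, "true_params")))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(out, "role") <- meta$role
    attr(out, "seed") <- meta$seed
    if (!is.null(meta$true_params)) {
      attr(out, "true_params") <- kinetic_params(.values = meta$true_params)
    }
  }
  class(out) <- c("ferm_dataset", class(out))
  out
}
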