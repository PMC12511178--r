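# Tree-structured Parzen estimator for LSTM hyper-parameter tuning.
# Per-dimension densities: after a random startup phase the observed
# trials are split at the gamma quantile of the loss into "good" (l) and
# "bad" (g) sets; numeric dimensions get Gaussian kernel densities,
# categorical ones smoothed count probabilities. Candidates are sampled
# from l and ranked by l/g.

.tpe_space_default <- function() {
  list(
    units1 = list(type = "choice", values = c(32, 64, 128, 256)),
    units2 = list(type = "choice", values = c(32, 64, 128, 256)),
    activation = list(type = "choice",
                      values = c("relu", "elu", "tanh", "sigmoid",
                                 "leakyrelu")),
    leaky_alpha = list(type = "uniform", low = 0.01, high = 0.3),
    dropout = list(type = "uniform", low = 0, high = 0.5),
    recurrent_dropout = list(type = "uniform", low = 0, high = 0.5),
    learning_rate = list(type = "loguniform", low = 1e-5, high = 1e-2),
    batch_size = list(type = "choice", values = c(16, 32, 64, 128)),
    optimizer = list(type = "choice",
                     values = c("adam", "rmsprop", "nadam"))
  )
}

.tpe_sample_prior <- function(space) {
  lapply(space, function(dim) {
    switch(dim$type,
           choice = sample(dim$values, 1),
           uniform = stats::runif(1, dim$low, dim$high),
           loguniform = exp(stats::runif(1, log(dim$low), log(dim$high))))
  })
}

# density of value x under kernel estimate over points xs (numeric dims)
.tpe_kde <- function(x, xs, low, high) {
  if (length(xs) == 0) return(1 / (high - low))
  bw <- max(1.06 * stats::sd(xs) * length(xs)^(-0.2),
            (high - low) / 50)
  if (!is.finite(bw) || bw <= 0) bw <- (high - low) / 10
  mean(stats::dnorm(x, xs, bw))
}

.tpe_cat_prob <- function(x, xs, values) {
  counts <- table(factor(xs, levels = values)) + 1  # +1 smoothing
  as.numeric(counts[as.character(x)] / sum(counts))
}

#' Tune the residual LSTM with a tree-structured Parzen estimator
#'
#' Runs `trials` configurations: a random startup phase followed by
#' TPE-guided proposals (candidates sampled from the density of
#' good-performing trials and ranked by the good/bad density ratio).
#' Every trial trains on the same chronological split and is scored by
#' validation MSE; the best configuration and its trained model are
#' returned along with the full trial log.
#'
#' @param wd a `ferm_windows` object.
#' @param trials number of configurations to evaluate.
#' @param rng_seed integer seed (controls both the sampler and each
#'   trial's training seed).
#' @param space search-space definition (see `.tpe_space_default`;
#'   override to narrow the space).
#' @param gamma quantile splitting good from bad trials.
#' @param n_candidates candidate proposals scored per TPE step.
#' @param n_startup random trials before TPE kicks in.
#' @param max_epochs,patience,split passed to [train_lstm()].
#' @return A `ferm_tpe` object: `best_config` ([lstm_config()]),
#'   `best_model` (`ferm_lstm`), `best_mse`, `trials` (tibble log).
#' @export
tpe_search <- function(wd, trials = 100L, rng_seed = 1L,
                       space = .tpe_space_default(), gamma = 0.25,
                       n_candidates = 24L, n_startup = 10L,
                       max_epochs = 500L, patience = 15L, split = 0.8) {
  stopifnot(trials >= 1)
  log_rows <- list()
  losses <- numeric(0)
  configs <- list()
  best <- list(mse = Inf, model = NULL, config = NULL)
  n_fail <- 0L
  for (tr in seq_len(trials)) {
    cand <- withr::with_seed(rng_seed * 1000L + tr, {
      if (tr <= n_startup || sum(is.finite(losses)) < 4) {
        .tpe_sample_prior(space)
      } else {
        ok <- is.finite(losses)
        cut <- stats::quantile(losses[ok], gamma, names = FALSE)
        good_idx <- which(ok & losses <= cut)
        bad_idx <- which(ok & losses > cut)
        cands <- lapply(seq_len(n_candidates), function(i) {
          lapply(names(space), function(nm) {
            dim <- space[[nm]]
            goods <- vapply(configs[good_idx], function(cf) cf[[nm]],
                            configs[[1]][[nm]])
            if (dim$type == "choice") {
              counts <- table(factor(goods, levels = dim$values)) + 1
              dim$values[sample.int(length(dim$values), 1,
                                    prob = as.numeric(counts))]
            } else {
              lo <- if (dim$type == "loguniform") log(dim$low) else dim$low
              hi <- if (dim$type == "loguniform") log(dim$high) else dim$high
              g <- if (dim$type == "loguniform") log(as.numeric(goods)) else
                as.numeric(goods)
              bw <- max(1.06 * stats::sd(g) * length(g)^(-0.2),
                        (hi - lo) / 50)
              if (!is.finite(bw) || bw <= 0) bw <- (hi - lo) / 10
              x <- stats::rnorm(1, sample(g, 1), bw)
              x <- min(max(x, lo), hi)
              if (dim$type == "loguniform") exp(x) else x
            }
          }) -> vals
          stats::setNames(vals, names(space))
        })
        score <- vapply(cands, function(cf) {
          s <- 0
          for (nm in names(space)) {
            dim <- space[[nm]]
            goods <- vapply(configs[good_idx], function(c2) c2[[nm]],
                            configs[[1]][[nm]])
            bads <- vapply(configs[bad_idx], function(c2) c2[[nm]],
                           configs[[1]][[nm]])
            if (dim$type == "choice") {
              s <- s + log(.tpe_cat_prob(cf[[nm]], goods, dim$values)) -
                log(.tpe_cat_prob(cf[[nm]], bads, dim$values))
            } else {
              tf <- if (dim$type == "loguniform") log else identity
              lo <- tf(dim$low); hi <- tf(dim$high)
              s <- s +
                log(.tpe_kde(tf(cf[[nm]]), tf(as.numeric(goods)), lo, hi) +
                      1e-12) -
                log(.tpe_kde(tf(cf[[nm]]), tf(as.numeric(bads)), lo, hi) +
                      1e-12)
            }
          }
          s
        }, numeric(1))
        score[!is.finite(score)] <- -Inf
        if (all(score == -Inf)) cands[[1]] else cands[[which.max(score)]]
      }
    })
    cfg <- lstm_config(units = c(cand$units1, cand$units2),
                       activation = cand$activation,
                       leaky_alpha = cand$leaky_alpha,
                       dropout = cand$dropout,
                       recurrent_dropout = cand$recurrent_dropout,
                       learning_rate = cand$learning_rate,
                       batch_size = cand$batch_size,
                       optimizer = cand$optimizer)
    fit <- try(train_lstm(wd, cfg, split = split, patience = patience,
                          max_epochs = max_epochs,
                          rng_seed = rng_seed * 100L + tr),
               silent = TRUE)
    loss <- if (inherits(fit, "try-error")) {
      n_fail <- n_fail + 1L
      NA_real_
    } else {
      fit$mse_val
    }
    losses <- c(losses, ifelse(is.na(loss), Inf, loss))
    configs <- c(configs, list(cand))
    log_rows[[tr]] <- tibble::tibble(
      trial = tr, mse_val = loss,
      units1 = cand$units1, units2 = cand$units2,
      activation = cand$activation, dropout = cand$dropout,
      recurrent_dropout = cand$recurrent_dropout,
      learning_rate = cand$learning_rate, batch_size = cand$batch_size,
      optimizer = cand$optimizer,
      failed = inherits(fit, "try-error"))
    if (!inherits(fit, "try-error") && loss < best$mse) {
      best <- list(mse = loss, model = fit, config = cfg)
    }
  }
  if (is.null(best$model)) {
    stop("all ", trials, " TPE trials failed; see the trial log")
  }
  structure(list(best_config = best$config, best_model = best$model,
                 best_mse = best$mse,
                 trials = dplyr::bind_rows(log_rows), n_failed = n_fail),
            class = "ferm_tpe")
}

#' @export
print.ferm_tpe <- function(x, ...) {
  cat("<ferm_tpe>", nrow(x$trials), "trials | best val MSE",
      format(x$best_mse, digits = 5), "\n")
  print(x$best_config$units)
  invisible(x)
}
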