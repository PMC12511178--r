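test_that("LSTM cell reproduces the hand-computed single-unit recurrence", {
  # single unit, single channel, all weights 1, biases 0, one input = 1:
  # i = f = o = sigma(1), chat = tanh(1), c = sigma(1) * tanh(1),
  # h = sigma(1) * tanh(c); dense (W = 1, b = 0) passes h through
  w <- list(layers = list(list(W = matrix(1, 1, 4), Uh = matrix(1, 1, 4),
                               b = rep(0, 4))),
            dense = list(W = matrix(1, 1, 1), b = 0))
  cfg <- list(units = 1L, activation = "tanh", leaky_alpha = 0.1)
  out <- lstm_forward(list(weights = w, config = cfg), matrix(1, 1, 1))
  sig1 <- 1 / (1 + exp(-1))
  c1 <- sig1 * tanh(1)
  expect_equal(c1, 0.5568, tolerance = 1e-4)
  expect_equal(out, sig1 * tanh(c1), tolerance = 1e-9)
  expect_equal(out, 0.3696, tolerance = 1e-3)
})

test_that("zero weights give zero output regardless of the input", {
  cfg <- lstm_config(units = c(3, 2))
  w <- hybridferm:::.lstm_init_weights(cfg, 4, 6, 1)
  w0 <- rapply(w, function(x) x * 0, how = "replace")
  win <- matrix(rnorm(20), 5, 4)
  expect_equal(unname(lstm_forward(list(weights = w0, config = cfg), win)),
               rep(0, 6))
})

test_that("matrix implementation matches an independent scalar reference", {
  # plain scalar-loop LSTM written from the gate equations, independent
  # of the package's vectorized code path
  scalar_lstm <- function(w, cfg, win) {
    sig <- function(z) 1 / (1 + exp(-z))
    x_seq <- win
    for (l in seq_along(w$layers)) {
      W <- w$layers[[l]]$W; Uh <- w$layers[[l]]$Uh; b <- w$layers[[l]]$b
      U <- nrow(Uh)
      h <- rep(0, U); cc <- rep(0, U)
      outs <- matrix(0, nrow(x_seq), U)
      for (k in seq_len(nrow(x_seq))) {
        z <- as.numeric(t(W) %*% x_seq[k, ] + t(Uh) %*% h + b)
        i <- sig(z[1:U]); f <- sig(z[(U + 1):(2 * U)])
        g <- tanh(z[(2 * U + 1):(3 * U)]); o <- sig(z[(3 * U + 1):(4 * U)])
        cc <- f * cc + i * g
        h <- o * tanh(cc)
        outs[k, ] <- h
      }
      x_seq <- outs
    }
    as.numeric(t(w$dense$W) %*% x_seq[nrow(x_seq), ] + w$dense$b)
  }
  cfg <- lstm_config(units = c(4, 3), activation = "tanh")
  w <- hybridferm:::.lstm_init_weights(cfg, 2, 2, 11)
  withr::with_seed(12, {
    for (rep in 1:5) {
      win <- matrix(rnorm(10), 5, 2)
      expect_equal(unname(lstm_forward(list(weights = w, config = cfg), win)),
                   scalar_lstm(w, cfg, win), tolerance = 1e-6)
    }
  })
})

test_that("backpropagation matches numerical gradients", {
  cfg <- lstm_config(units = c(4, 3), activation = "elu")
  w <- hybridferm:::.lstm_init_weights(cfg, 2, 2, 7)
  withr::with_seed(42, {
    X <- array(rnorm(3 * 5 * 2), dim = c(3, 5, 2))
    Y <- matrix(rnorm(6), 3, 2)
  })
  fw <- hybridferm:::.lstm_forward_pass(w, cfg, X, keep = TRUE)
  gr <- unlist(hybridferm:::.lstm_backward_pass(
    w, cfg, fw, 2 * (fw$pred - Y) / length(Y)))
  v0 <- unlist(w)
  restore <- function(tpl, fl) {
    if (is.list(tpl)) {
      for (n in seq_along(tpl)) fl[[n]] <- restore(tpl[[n]], fl[[n]])
      fl
    } else {
      dim(fl) <- dim(tpl); fl
    }
  }
  loss_flat <- function(v) {
    wr <- restore(w, utils::relist(v, w))
    mean((hybridferm:::.lstm_forward_pass(wr, cfg, X) - Y)^2)
  }
  idx <- withr::with_seed(1, sample(length(v0), 25))
  num <- vapply(idx, function(i) {
    h <- 1e-6
    vp <- v0; vp[i] <- vp[i] + h
    vm <- v0; vm[i] <- vm[i] - h
    (loss_flat(vp) - loss_flat(vm)) / (2 * h)
  }, numeric(1))
  expect_equal(num, unname(gr[idx]), tolerance = 1e-6)
})

test_that("windowing bookkeeping is exact", {
  M <- matrix(seq_len(60), 20, 3)
  wd <- make_windows(M / 60, p = 5)
  expect_equal(dim(wd$inputs), c(15, 5, 3))
  expect_equal(dim(wd$targets), c(15, 3))
  # targets reproduce rows p+1..N exactly
  expect_equal(wd$targets, (M / 60)[6:20, ])
  # consecutive windows share p-1 rows
  expect_equal(wd$inputs[2, 1:4, ], wd$inputs[1, 2:5, ])
  # N = 6, p = 5: exactly one pair
  w1 <- make_windows(M[1:6, ] / 60, p = 5)
  expect_equal(dim(w1$inputs)[1], 1)
  expect_equal(w1$inputs[1, , ], (M / 60)[1:5, ])
  expect_equal(w1$targets[1, ], (M / 60)[6, ])
  expect_error(make_windows(M[1:5, ], p = 5), "minimum series length is 6")
})

test_that("min-max scaling round-trips and handles degenerate channels", {
  withr::with_seed(8, {
    R <- cbind(rnorm(30), rnorm(30, 5, 2), rep(1.5, 30))
  })
  sc <- fit_minmax_scaler(R)
  S <- apply_minmax_scaler(R, sc)
  expect_true(all(S[, 1:2] >= 0 & S[, 1:2] <= 1))
  expect_true(all(S[, 3] == 0))
  back <- invert_minmax_scaler(S, sc)
  expect_lt(max(abs(back[, 1:2] - R[, 1:2])), 1e-10)
  # degenerate channel inverts onto its constant minimum by convention
  expect_true(all(back[, 3] == 1.5))
})

test_that("training learns an AR(1) residual and beats the naive baseline", {
  r <- ar1_matrix(n = 300, m = 1)
  sc <- fit_minmax_scaler(r)
  wd <- make_windows(apply_minmax_scaler(r, sc), p = 5)
  fit <- train_lstm(wd, lstm_config(units = c(8, 8), learning_rate = 1e-2,
                                    batch_size = 32),
                    max_epochs = 400, rng_seed = 1)
  n <- dim(wd$inputs)[1]
  idx_val <- (floor(0.8 * n) + 1):n
  naive <- mean((wd$inputs[idx_val, 5, 1] - wd$targets[idx_val, 1])^2)
  expect_lt(fit$mse_val, naive)
  # loss history is recorded and the best epoch's weights are restored
  expect_equal(min(fit$history$val), fit$mse_val)
})

test_that("early stopping halts within the patience window", {
  r <- ar1_matrix(n = 40, m = 2)
  wd <- make_windows(apply_minmax_scaler(r, fit_minmax_scaler(r)), p = 5)
  fit <- train_lstm(wd, lstm_config(units = c(4, 4), learning_rate = 1e-3),
                    patience = 5, max_epochs = 200, rng_seed = 2)
  best_epoch <- which.min(fit$history$val)
  expect_lte(fit$epochs_run - best_epoch, 5)
})

test_that("training is reproducible per seed and validates the split", {
  r <- ar1_matrix(n = 50, m = 2)
  wd <- make_windows(apply_minmax_scaler(r, fit_minmax_scaler(r)), p = 5)
  a <- train_lstm(wd, lstm_config(units = c(4, 4)), max_epochs = 10,
                  rng_seed = 3)
  b <- train_lstm(wd, lstm_config(units = c(4, 4)), max_epochs = 10,
                  rng_seed = 3)
  expect_identical(a$weights, b$weights)
  expect_identical(a$mse_val, b$mse_val)
  expect_error(train_lstm(make_windows(r[1:7, ], p = 5),
                          lstm_config()), "validation")
})

test_that("dropout training still converges on constant targets", {
  r <- matrix(0.5, 40, 2) + ar1_matrix(40, 2, rho = 0, sd = 1e-4)
  wd <- make_windows(r, p = 5)
  fit <- train_lstm(wd, lstm_config(units = c(4, 4), dropout = 0.2,
                                    recurrent_dropout = 0.2,
                                    learning_rate = 5e-3),
                    max_epochs = 120, rng_seed = 4)
  expect_lt(fit$mse_val, 0.01)
})

test_that("TPE search returns the best-scoring trial and logs all", {
  r <- ar1_matrix(n = 120, m = 2)
  wd <- make_windows(apply_minmax_scaler(r, fit_minmax_scaler(r)), p = 5)
  small_space <- list(
    units1 = list(type = "choice", values = c(4, 8)),
    units2 = list(type = "choice", values = c(4, 8)),
    activation = list(type = "choice", values = c("tanh", "relu")),
    leaky_alpha = list(type = "uniform", low = 0.01, high = 0.3),
    dropout = list(type = "uniform", low = 0, high = 0.2),
    recurrent_dropout = list(type = "uniform", low = 0, high = 0.2),
    learning_rate = list(type = "loguniform", low = 1e-4, high = 1e-2),
    batch_size = list(type = "choice", values = c(16, 32)),
    optimizer = list(type = "choice", values = c("adam", "rmsprop"))
  )
  res <- tpe_search(wd, trials = 8, rng_seed = 5, space = small_space,
                    max_epochs = 40, n_startup = 4)
  expect_equal(nrow(res$trials), 8)
  expect_equal(res$best_mse, min(res$trials$mse_val, na.rm = TRUE))
  expect_lte(res$best_mse, stats::median(res$trials$mse_val, na.rm = TRUE))
  # single-trial search returns that sampled configuration
  one <- tpe_search(wd, trials = 1, rng_seed = 6, space = small_space,
                    max_epochs = 5)
  expect_equal(nrow(one$trials), 1)
  expect_equal(one$best_mse, one$trials$mse_val[1])
  # reproducibility
  res2 <- tpe_search(wd, trials = 8, rng_seed = 5, space = small_space,
                     max_epochs = 40, n_startup = 4)
  expect_identical(res$trials, res2$trials)
})

test_that("optimizer variants all reduce the training loss", {
  r <- ar1_matrix(n = 80, m = 2)
  wd <- make_windows(apply_minmax_scaler(r, fit_minmax_scaler(r)), p = 5)
  for (opt in c("adam", "rmsprop", "nadam")) {
    fit <- train_lstm(wd, lstm_config(units = c(4, 4), optimizer = opt,
                                      learning_rate = 3e-3),
                      max_epochs = 60, rng_seed = 8)
    expect_lt(fit$history$train[fit$epochs_run],
              fit$history$train[1] + 1e-12, label = opt)
  }
})
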