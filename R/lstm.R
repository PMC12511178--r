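# Hand-rolled two-layer LSTM used as the residual learner. The cell
# follows the standard gate recurrence exactly (sigmoid input/forget/
# output gates, configurable candidate/output activation, h0 = c0 = 0),
# with backpropagation through time and Adam/RMSprop/Nadam updates.

.act_fun <- function(z, type, alpha = 0.1) {
  switch(type,
         tanh = tanh(z),
         sigmoid = 1 / (1 + exp(-z)),
         relu = pmax(z, 0),
         elu = ifelse(z > 0, z, expm1(z)),
         leakyrelu = ifelse(z > 0, z, alpha * z),
         stop("unknown activation: ", type))
}

.act_grad <- function(z, a, type, alpha = 0.1) {
  # derivative of act at pre-activation z (a = act(z), reused when cheap)
  switch(type,
         tanh = 1 - a^2,
         sigmoid = a * (1 - a),
         relu = (z > 0) * 1,
         elu = ifelse(z > 0, 1, a + 1),
         leakyrelu = ifelse(z > 0, 1, alpha))
}

.sigm <- function(z) 1 / (1 + exp(-z))

#' LSTM configuration
#'
#' Hyper-parameters of the two-layer residual LSTM. The search domains
#' mirror the tuning space: units per layer in 32/64/128/256,
#' activation among relu, elu, tanh, sigmoid, leakyrelu (alpha between
#' 0.01 and 0.3), dropout and recurrent dropout between 0 and 0.5,
#' learning rate between 1e-5 and 1e-2 (log scale), batch size
#' 16/32/64/128, optimizer among adam, rmsprop, nadam.
#'
#' @param units integer vector of length 2 (units per layer).
#' @param activation candidate/output activation.
#' @param leaky_alpha slope for `"leakyrelu"`.
#' @param dropout,recurrent_dropout dropout rates between 0 and 0.5.
#' @param learning_rate step size.
#' @param batch_size minibatch size.
#' @param optimizer `"adam"`, `"rmsprop"` or `"nadam"`.
#' @return Named list with class `lstm_config`.
#' @export
lstm_config <- function(units = c(64, 64),
                        activation = c("tanh", "relu", "elu", "sigmoid",
                                       "leakyrelu"),
                        leaky_alpha = 0.1,
                        dropout = 0, recurrent_dropout = 0,
                        learning_rate = 1e-3, batch_size = 32L,
                        optimizer = c("adam", "rmsprop", "nadam")) {
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  units <- rep_len(as.integer(units), 2)
  stopifnot(all(units >= 1), dropout >= 0, dropout <= 0.5,
            recurrent_dropout >= 0, recurrent_dropout <= 0.5,
            learning_rate > 0, batch_size >= 1)
  structure(list(units = units, activation = activation,
                 leaky_alpha = leaky_alpha, dropout = dropout,
                 recurrent_dropout = recurrent_dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer),
            class = "lstm_config")
}

# Glorot-uniform initialization; forget-gate bias starts at 1.
.lstm_init_weights <- function(cfg, input_dim, output_dim, rng_seed) {
  withr::with_seed(rng_seed, {
    glorot <- function(nin, nout) {
      lim <- sqrt(6 / (nin + nout))
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    layers <- list()
    d_in <- input_dim
    for (l in seq_along(cfg$units)) {
      U <- cfg$units[l]
      b <- rep(0, 4 * U)
      b[(U + 1):(2 * U)] <- 1
      layers[[l]] <- list(W = glorot(d_in, 4 * U), Uh = glorot(U, 4 * U),
                          b = b)
      d_in <- U
    }
    list(layers = layers,
         dense = list(W = glorot(cfg$units[2], output_dim),
                      b = rep(0, output_dim)))
  })
}

# Forward pass over a batch of windows.
# X: array (batch, p, input_dim). Returns prediction (batch, output_dim)
# and, if keep = TRUE, the caches needed by backprop. Dropout masks
# (one per layer, fixed across time steps) are applied only when given.
.lstm_forward_pass <- function(weights, cfg, X, keep = FALSE,
                               masks = NULL) {
  B <- dim(X)[1]; p <- dim(X)[2]
  caches <- list()
  layer_in <- X
  for (l in seq_along(weights$layers)) {
    W <- weights$layers[[l]]$W
    Uh <- weights$layers[[l]]$Uh
    b <- weights$layers[[l]]$b
    U <- nrow(Uh)
    h <- matrix(0, B, U); cc <- matrix(0, B, U)
    mx <- if (is.null(masks)) NULL else masks$x[[l]]
    mh <- if (is.null(masks)) NULL else masks$h[[l]]
    steps <- vector("list", p)
    H_out <- array(0, dim = c(B, p, U))
    for (k in 1:p) {
      x_k <- matrix(layer_in[, k, ], nrow = B)
      x_t <- if (is.null(mx)) x_k else x_k * mx
      h_t <- if (is.null(mh)) h else h * mh
      Z <- x_t %*% W + h_t %*% Uh + matrix(b, B, 4 * U, byrow = TRUE)
      zi <- Z[, 1:U, drop = FALSE]
      zf <- Z[, (U + 1):(2 * U), drop = FALSE]
      zg <- Z[, (2 * U + 1):(3 * U), drop = FALSE]
      zo <- Z[, (3 * U + 1):(4 * U), drop = FALSE]
      ig <- .sigm(zi); fg <- .sigm(zf); og <- .sigm(zo)
      gg <- .act_fun(zg, cfg$activation, cfg$leaky_alpha)
      c_prev <- cc
      cc <- fg * c_prev + ig * gg
      ac <- .act_fun(cc, cfg$activation, cfg$leaky_alpha)
      h <- og * ac
      H_out[, k, ] <- h
      if (keep) {
        steps[[k]] <- list(x_t = x_t, h_t = h_t, i = ig, f = fg, o = og,
                           g = gg, zg = zg, c = cc, c_prev = c_prev,
                           ac = ac)
      }
    }
    if (keep) caches[[l]] <- steps
    layer_in <- H_out
  }
  h_final <- matrix(layer_in[, p, ], nrow = B)
  pred <- h_final %*% weights$dense$W +
    matrix(weights$dense$b, B, ncol(weights$dense$W), byrow = TRUE)
  if (!keep) return(pred)
  list(pred = pred, h_final = h_final, caches = caches, p = p, B = B)
}

# Backward pass: returns gradients with the same structure as weights.
.lstm_backward_pass <- function(weights, cfg, fw, d_pred, masks = NULL) {
  B <- fw$B; p <- fw$p
  grads <- list(layers = list(), dense = list())
  grads$dense$W <- crossprod(fw$h_final, d_pred)
  grads$dense$b <- colSums(d_pred)
  # gradient flowing into each layer's h sequence from above
  n_layers <- length(weights$layers)
  dH_top <- array(0, dim = c(B, p, nrow(weights$dense$W)))
  dH_top[, p, ] <- d_pred %*% t(weights$dense$W)
  dH_above <- dH_top
  for (l in rev(seq_len(n_layers))) {
    U <- nrow(weights$layers[[l]]$Uh)
    W <- weights$layers[[l]]$W
    Uh <- weights$layers[[l]]$Uh
    steps <- fw$caches[[l]]
    mx <- if (is.null(masks)) NULL else masks$x[[l]]
    mh <- if (is.null(masks)) NULL else masks$h[[l]]
    dW <- matrix(0, nrow(W), ncol(W))
    dU <- matrix(0, U, 4 * U)
    db <- rep(0, 4 * U)
    d_in <- array(0, dim = c(B, p, nrow(W)))
    dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
    for (k in p:1) {
      st <- steps[[k]]
      dh <- matrix(dH_above[, k, ], nrow = B) + dh_next
      d_o <- dh * st$ac
      dzo <- d_o * st$o * (1 - st$o)
      dc <- dh * st$o *
        .act_grad(st$c, st$ac, cfg$activation, cfg$leaky_alpha) + dc_next
      d_i <- dc * st$g
      dzi <- d_i * st$i * (1 - st$i)
      d_f <- dc * st$c_prev
      dzf <- d_f * st$f * (1 - st$f)
      d_g <- dc * st$i
      dzg <- d_g * .act_grad(st$zg, st$g, cfg$activation, cfg$leaky_alpha)
      dZ <- cbind(dzi, dzf, dzg, dzo)
      dW <- dW + crossprod(st$x_t, dZ)
      dU <- dU + crossprod(st$h_t, dZ)
      db <- db + colSums(dZ)
      dx <- dZ %*% t(W)
      if (!is.null(mx)) dx <- dx * mx
      d_in[, k, ] <- dx
      dh_next <- dZ %*% t(Uh)
      if (!is.null(mh)) dh_next <- dh_next * mh
      dc_next <- dc * st$f
    }
    grads$layers[[l]] <- list(W = dW, Uh = dU, b = db)
    dH_above <- d_in
  }
  grads
}

# Optimizer state + update (Adam / RMSprop / Nadam).
.opt_init <- function(weights) {
  zeros <- function(w) rapply(w, function(x) x * 0, how = "replace")
  list(m = zeros(weights), v = zeros(weights), t = 0L)
}

.opt_update <- function(weights, grads, state, cfg) {
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; rho <- 0.9
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, g, m, v) {
    if (cfg$optimizer == "rmsprop") {
      v2 <- rho * v + (1 - rho) * g^2
      list(w = w - lr * g / (sqrt(v2) + eps), m = m, v = v2)
    } else {
      m2 <- b1 * m + (1 - b1) * g
      v2 <- b2 * v + (1 - b2) * g^2
      vhat <- v2 / (1 - b2^t)
      mhat <- if (cfg$optimizer == "nadam") {
        (b1 * m2 + (1 - b1) * g) / (1 - b1^t)
      } else {
        m2 / (1 - b1^t)
      }
      list(w = w - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  walk <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- list(w = w, m = m, v = v)
      for (nm in seq_along(w)) {
        r <- walk(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$w[[nm]] <- r$w; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      upd(w, g, m, v)
    }
  }
  r <- walk(weights, grads, state$m, state$v)
  list(weights = r$w, state = list(m = r$m, v = r$v, t = t))
}

#' Single-window LSTM forward evaluation
#'
#' Runs the exact gate recurrence over one look-back window with
#' `h0 = c0 = 0` and applies the linear dense output layer. Dropout is
#' off (inference mode); the result is deterministic.
#'
#' @param model a trained `ferm_lstm` (or a bare list with `weights` and
#'   `config`).
#' @param window numeric matrix, p x m (rows = time steps).
#' @return Numeric vector of length m (next-step residual prediction, in
#'   the scaled space the model was trained in).
#' @export
lstm_forward <- function(model, window) {
  window <- as.matrix(window)
  if (ncol(window) != nrow(model$weights$layers[[1]]$W)) {
    stop("window has ", ncol(window), " channels; model expects ",
         nrow(model$weights$layers[[1]]$W))
  }
  X <- aperm(array(window, dim = c(nrow(window), ncol(window), 1)),
             c(3, 1, 2))
  drop(.lstm_forward_pass(model$weights, model$config, X))
}

#' Train the residual LSTM
#'
#' Chronological 80/20 split of the windowed pairs, minibatch training
#' with the configured optimizer on one-step mean squared error, early
#' stopping on the validation MSE (patience 15 epochs by default) with
#' best-validation weights restored. Reproducible for a given seed.
#'
#' @param wd a `ferm_windows` object from [make_windows()].
#' @param config an [lstm_config()].
#' @param split fraction of pairs used for fitting (rest validates).
#' @param patience early-stopping patience, epochs.
#' @param max_epochs training-epoch cap.
#' @param rng_seed integer seed.
#' @return A `ferm_lstm` object: `weights`, `config`, `mse_val` (best
#'   validation MSE), `history` (per-epoch train/val loss tibble),
#'   `epochs_run`, `scaler` (carried from `wd`), `seed`.
#' @export
train_lstm <- function(wd, config = lstm_config(), split = 0.8,
                       patience = 15L, max_epochs = 500L, rng_seed = 1L) {
  X <- wd$inputs; Y <- wd$targets
  n <- dim(X)[1]
  n_fit <- floor(split * n)
  if (n_fit < 1 || n - n_fit < 2) {
    stop("need at least 2 validation pairs after the chronological split ",
         "(got ", n - n_fit, " from ", n, " pairs)")
  }
  idx_fit <- seq_len(n_fit)
  idx_val <- (n_fit + 1):n
  m <- dim(X)[3]
  weights <- .lstm_init_weights(config, m, ncol(Y), rng_seed)
  state <- .opt_init(weights)
  mse <- function(w, idx) {
    pred <- .lstm_forward_pass(w, config,
                               X[idx, , , drop = FALSE])
    mean((pred - Y[idx, , drop = FALSE])^2)
  }
  best <- list(w = weights, val = mse(weights, idx_val), epoch = 0L)
  hist_tr <- hist_val <- numeric(0)
  use_dropout <- config$dropout > 0 || config$recurrent_dropout > 0
  withr::with_seed(rng_seed + 1L, {
    for (ep in seq_len(max_epochs)) {
      ord <- sample(idx_fit)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bt in batches) {
        Xb <- X[bt, , , drop = FALSE]
        Yb <- Y[bt, , drop = FALSE]
        masks <- NULL
        if (use_dropout) {
          keepx <- 1 - config$dropout
          keeph <- 1 - config$recurrent_dropout
          masks <- list(x = list(), h = list())
          d_in <- m
          for (l in 1:2) {
            masks$x[[l]] <- matrix(
              stats::rbinom(length(bt) * d_in, 1, keepx) / keepx,
              length(bt), d_in)
            masks$h[[l]] <- matrix(
              stats::rbinom(length(bt) * config$units[l], 1, keeph) / keeph,
              length(bt), config$units[l])
            d_in <- config$units[l]
          }
        }
        fw <- .lstm_forward_pass(weights, config, Xb, keep = TRUE,
                                 masks = masks)
        d_pred <- 2 * (fw$pred - Yb) / length(Yb)
        grads <- .lstm_backward_pass(weights, config, fw, d_pred, masks)
        r <- .opt_update(weights, grads, state, config)
        weights <- r$weights; state <- r$state
      }
      tr <- mse(weights, idx_fit)
      vl <- mse(weights, idx_val)
      hist_tr <- c(hist_tr, tr); hist_val <- c(hist_val, vl)
      if (vl < best$val - 1e-12) {
        best <- list(w = weights, val = vl, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        break
      }
    }
  })
  structure(list(weights = best$w, config = config, mse_val = best$val,
                 history = tibble::tibble(epoch = seq_along(hist_tr),
                                          train = hist_tr, val = hist_val),
                 epochs_run = length(hist_tr),
                 scaler = wd$scaler, look_back = wd$look_back,
                 seed = rng_seed),
            class = "ferm_lstm")
}

#' @export
print.ferm_lstm <- function(x, ...) {
  cat("<ferm_lstm> units", paste(x$config$units, collapse = "/"),
      "| activation", x$config$activation,
      "| optimizer", x$config$optimizer,
      "| val MSE", format(x$mse_val, digits = 5),
      "|", x$epochs_run, "epochs\n")
  invisible(x)
}

# Batched inference on a ferm_windows object (or 3-d array).
.lstm_predict <- function(model, X) {
  if (inherits(X, "ferm_windows")) X <- X$inputs
  .lstm_forward_pass(model$weights, model$config, X)
}
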