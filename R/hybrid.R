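#' Mechanistic-model residuals at the observation times
#'
#' Simulates the mechanistic model at the dataset's sample times and
#' returns the pointwise residual `r(t_i) = y_exp(t_i) - y_pheno(t_i)`
#' for the six concentration channels, together with the feature-wise
#' min-max scaling bounds fitted on these residuals (fit on training
#' data and reuse on test data via the `scaler` argument).
#'
#' @param ds a `ferm_dataset` with an `ic` attribute.
#' @param p calibrated [kinetic_params()].
#' @param scaler optional scaler from a previous (training) call; when
#'   supplied, its bounds are stored instead of refitting.
#' @param cfg,opts model configuration.
#' @return A `ferm_residuals` object: `times`, `residuals` (N x 6
#'   matrix), `scaled` (N x 6, channels mapped to the unit interval; a degenerate
#'   channel with min = max maps to all zeros), `scaler` (list of `min`,
#'   `max` per channel), `pheno` (the mechanistic trajectory tibble).
#' @export
compute_residuals <- function(ds, p, scaler = NULL,
                              cfg = gating_config(),
                              opts = model_options()) {
  ic <- attr(ds, "ic")
  if (is.null(ic)) stop("dataset carries no `ic` attribute")
  traj <- simulate_fermentation(ic, p, t_grid = ds$time_h, cfg = cfg,
                                opts = opts)
  obs <- as.matrix(ds[, .channel_names])
  mod <- as.matrix(traj[, .channel_names])
  R <- obs - mod
  if (is.null(scaler)) scaler <- fit_minmax_scaler(R)
  structure(list(times = ds$time_h, residuals = R,
                 scaled = apply_minmax_scaler(R, scaler),
                 scaler = scaler, pheno = traj),
            class = "ferm_residuals")
}

#' Feature-wise min-max scaler
#'
#' `fit_minmax_scaler()` records per-channel min/max;
#' `apply_minmax_scaler()` maps each channel to the unit interval (values
#' outside the fitted range, e.g. test residuals, may leave the unit
#' interval); a degenerate channel (range zero up to a 1e-8 relative
#' tolerance, e.g. a residual constant to solver precision) maps to all
#' zeros by convention. `invert_minmax_scaler()` recovers raw values to
#' better than 1e-10 for non-degenerate channels (degenerate ones invert
#' onto their constant minimum).
#'
#' @param R numeric matrix (rows = times, cols = channels).
#' @param scaler list with `min` and `max` vectors.
#' @return `fit_minmax_scaler()`: the scaler list; the others: a matrix
#'   shaped like `R`.
#' @export
fit_minmax_scaler <- function(R) {
  list(min = apply(R, 2, min), max = apply(R, 2, max))
}

.scaler_degenerate <- function(scaler) {
  rng <- scaler$max - scaler$min
  rng <= 1e-8 * pmax(1, abs(scaler$min), abs(scaler$max))
}

#' @rdname fit_minmax_scaler
#' @export
apply_minmax_scaler <- function(R, scaler) {
  deg <- .scaler_degenerate(scaler)
  rng <- scaler$max - scaler$min
  out <- sweep(R, 2, scaler$min)
  out <- sweep(out, 2, ifelse(deg, 1, rng), `/`)
  out[, deg] <- 0
  out
}

#' @rdname fit_minmax_scaler
#' @export
invert_minmax_scaler <- function(R, scaler) {
  deg <- .scaler_degenerate(scaler)
  rng <- scaler$max - scaler$min
  out <- sweep(R, 2, ifelse(deg, 0, rng), `*`)
  sweep(out, 2, scaler$min, `+`)
}

#' Look-back windows from a residual series
#'
#' Builds the (input, target) pairs for one-step-ahead residual
#' forecasting: pair `i` has input rows `r(t_i) ... r(t_{i+p-1})` and
#' target `r(t_{i+p})`, all in the scaled space; an N-point series
#' yields `N - p` pairs in chronological order.
#'
#' @param rs a `ferm_residuals` object (or a plain numeric matrix,
#'   treated as already scaled).
#' @param p look-back window length (default 5).
#' @return A `ferm_windows` object: `inputs` (array (N-p) x p x m),
#'   `targets` ((N-p) x m), `look_back`, `scaler`, `times` (target
#'   times).
#' @export
make_windows <- function(rs, p = 5L) {
  M <- if (inherits(rs, "ferm_residuals")) rs$scaled else as.matrix(rs)
  n <- nrow(M)
  if (n <= p) {
    stop("need more than ", p, " residual points to build windows ",
         "(minimum series length is ", p + 1, "; got ", n, ")")
  }
  n_pairs <- n - p
  inputs <- array(0, dim = c(n_pairs, p, ncol(M)))
  for (i in seq_len(n_pairs)) {
    inputs[i, , ] <- M[i:(i + p - 1), , drop = FALSE]
  }
  targets <- M[(p + 1):n, , drop = FALSE]
  structure(list(inputs = inputs, targets = targets, look_back = p,
                 scaler = if (inherits(rs, "ferm_residuals")) rs$scaler,
                 times = if (inherits(rs, "ferm_residuals")) {
                   rs$times[(p + 1):n]
                 }),
            class = "ferm_windows")
}

#' Hybrid weights
#'
#' Weighting factors of the blended prediction
#' `y_hybrid = lambda_pheno * y_pheno + lambda_ml * y_ml`. The defaults
#' (0.3 mechanistic, 0.7 data-driven) balance train/test performance.
#'
#' @param lambda_pheno,lambda_ml non-negative weights.
#' @return Named list with class `hybrid_weights`.
#' @export
hybrid_weights <- function(lambda_pheno = 0.3, lambda_ml = 0.7) {
  stopifnot(lambda_pheno >= 0, lambda_ml >= 0)
  structure(list(lambda_pheno = lambda_pheno, lambda_ml = lambda_ml),
            class = "hybrid_weights")
}

#' Blend mechanistic and LSTM predictions
#'
#' Produces the hybrid trajectory at the residual-series times. The
#' data-driven prediction is defined as mechanistic + predicted
#' residual, so `weights = hybrid_weights(1, 0)` reduces exactly to the
#' mechanistic model. For the first `p` points no window exists and the
#' hybrid equals the mechanistic prediction. Two roll-out policies are
#' available: `"teacher"` builds every window from the measured
#' residuals (requires observations at all times), `"recursive"` feeds
#' the model's own scaled predictions back into subsequent windows after
#' the first window.
#'
#' @param rs a `ferm_residuals` for the run being predicted (its
#'   `pheno` trajectory and, under teacher forcing, its measured
#'   residuals are used).
#' @param model a trained `ferm_lstm`; its stored (training) scaler is
#'   used for inverse scaling.
#' @param weights a [hybrid_weights()].
#' @param rollout `"teacher"` or `"recursive"`.
#' @return A tibble (class `ferm_hybrid`) in long-friendly wide format:
#'   `time_h`, six hybrid channel columns; attributes `y_ml`
#'   (matrix), `pheno`, `weights`, `rollout`.
#' @export
hybrid_predict <- function(rs, model, weights = hybrid_weights(),
                           rollout = c("teacher", "recursive")) {
  rollout <- match.arg(rollout)
  if (is.null(model$scaler)) stop("model carries no scaler")
  p <- model$look_back
  scaler <- model$scaler
  n <- length(rs$times)
  if (n <= p) stop("residual series shorter than the look-back window")
  pheno <- as.matrix(rs$pheno[, .channel_names])
  scaled_obs <- apply_minmax_scaler(rs$residuals, scaler)
  pred_scaled <- matrix(NA_real_, n, 6)
  if (rollout == "teacher") {
    wins <- array(0, dim = c(n - p, p, 6))
    for (i in seq_len(n - p)) wins[i, , ] <- scaled_obs[i:(i + p - 1), ]
    pred_scaled[(p + 1):n, ] <- .lstm_predict(model, wins)
  } else {
    buf <- scaled_obs[1:p, , drop = FALSE]
    for (i in (p + 1):n) {
      win <- aperm(array(buf, dim = c(p, 6, 1)), c(3, 1, 2))
      pr <- drop(.lstm_forward_pass(model$weights, model$config, win))
      pred_scaled[i, ] <- pr
      buf <- rbind(buf[-1, , drop = FALSE], pr)
    }
  }
  resid_hat <- invert_minmax_scaler(pred_scaled[(p + 1):n, , drop = FALSE],
                                    scaler)
  y_ml <- pheno
  y_ml[(p + 1):n, ] <- pheno[(p + 1):n, ] + resid_hat
  hyb <- weights$lambda_pheno * pheno + weights$lambda_ml * y_ml
  hyb[1:p, ] <- pheno[1:p, ]          # no window available yet
  hyb <- pmax(hyb, 0)
  out <- tibble::as_tibble(cbind(time_h = rs$times, as.data.frame(hyb)))
  names(out) <- c("time_h", .channel_names)
  structure(out, class = c("ferm_hybrid", class(out)),
            y_ml = y_ml, pheno = rs$pheno, weights = weights,
            rollout = rollout)
}
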