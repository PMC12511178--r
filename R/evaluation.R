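#' Root-mean-square error of a prediction against observations
#'
#' @param pred data frame with `time_h` and channel columns (trajectory
#'   or hybrid prediction).
#' @param obs a `ferm_dataset` (or data frame with the same columns).
#' @param variable channel name (one of biomass, glucose, fructose,
#'   sucrose, urea, ethanol); `NULL` returns all six as a named vector.
#' @param tol time-matching tolerance, h.
#' @return RMSE in g/L (scalar, or named vector when `variable` is
#'   `NULL`).
#' @export
rmse <- function(pred, obs, variable = NULL, tol = 1e-6) {
  m <- outer(obs$time_h, pred$time_h, function(a, b) abs(a - b) <= tol)
  take <- apply(m, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  keep <- !is.na(take)
  if (!any(keep)) stop("no overlapping observation/prediction times")
  chans <- if (is.null(variable)) .channel_names else variable
  out <- vapply(chans, function(ch) {
    sqrt(mean((pred[[ch]][take[keep]] - obs[[ch]][keep])^2))
  }, numeric(1))
  if (is.null(variable)) out else unname(out)
}

#' Total RMSE across the six state variables
#'
#' The reported "Total" is the arithmetic mean of the six per-variable
#' RMSEs (this convention reproduces published totals from their row
#' values). A pooled alternative, the RMSE over all channels'
#' observations jointly, sqrt(mean of the six mean-squared errors), is
#' available behind `mode = "pooled"`.
#'
#' @param per_variable numeric vector of exactly six per-variable RMSEs
#'   (g/L).
#' @param mode `"mean"` (default) or `"pooled"`.
#' @return Scalar total RMSE, g/L.
#' @export
total_rmse <- function(per_variable, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  per_variable <- unlist(per_variable)
  if (length(per_variable) != 6 || anyNA(per_variable)) {
    stop("total_rmse needs exactly six non-missing per-variable RMSEs")
  }
  if (mode == "mean") mean(per_variable) else sqrt(mean(per_variable^2))
}

#' Fold reduction in total error
#'
#' Ratio of the mechanistic total RMSE to the hybrid total RMSE
#' (> 1 means the hybrid is better), conventionally reported to one
#' decimal.
#'
#' @param total_mech,total_hybrid total RMSEs, g/L.
#' @return Unitless ratio.
#' @export
fold_reduction <- function(total_mech, total_hybrid) {
  if (total_hybrid <= 0) stop("hybrid total RMSE must be positive")
  total_mech / total_hybrid
}

#' RMSE table for mechanistic and hybrid predictions
#'
#' Evaluates both models against one or more datasets and assembles the
#' per-variable and total RMSEs, one row per (model, role).
#'
#' @param evals a list of entries, each a list with fields `model`
#'   (`"mechanistic"`/`"hybrid"`), `role` (`"train"`/`"test"`), `pred`
#'   (trajectory/hybrid tibble) and `obs` (dataset).
#' @param mode total aggregation mode (see [total_rmse()]).
#' @return A tibble: `model`, `role`, the six channels, `total`.
#' @export
rmse_table <- function(evals, mode = "mean") {
  rows <- lapply(evals, function(e) {
    per <- rmse(e$pred, e$obs)
    tibble::tibble(model = e$model, role = e$role,
                   !!!as.list(per), total = total_rmse(per, mode))
  })
  dplyr::bind_rows(rows)
}

#' Published worked-example RMSE values
#'
#' Per-variable RMSEs (g/L) reported for a mechanistic model and its
#' LSTM-residual hybrid on train and test batches of an aerated
#' mixed-sugar yeast fermentation, shipped for worked examples and
#' consistency checks of the aggregation conventions.
#'
#' @return A tibble: `model`, `role`, six channel columns.
#' @export
published_rmse <- function() {
  path <- system.file("extdata", "published_rmse.csv",
                      package = "hybridferm", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
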