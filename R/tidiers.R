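#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration result
#'
#' One row per free parameter: the estimate, the starting value, and the
#' final search bounds.
#'
#' @param x a `ferm_calibration`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.ferm_calibration <- function(x, ...) {
  final_bounds <- x$bound_history |>
    dplyr::group_by(.data$parameter) |>
    dplyr::slice_max(.data$round, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tibble::tibble(parameter = x$free, estimate = unname(x$estimate)) |>
    dplyr::left_join(final_bounds[, c("parameter", "lower", "upper")],
                     by = "parameter")
}

#' @rdname tidy.ferm_calibration
#' @export
glance.ferm_calibration <- function(x, ...) {
  tibble::tibble(objective = x$value, start_objective = x$start_value,
                 n_free = length(x$free), epochs_run = x$epochs_run,
                 rounds = x$rounds, seed = x$seed)
}

#' Tidy an identifiability report
#'
#' @param x a `ferm_pra`.
#' @param ... unused.
#' @return The per-parameter metrics tibble (estimate, sd, %sd, t-value,
#'   confidence bounds, max sensitivity, classification).
#' @export
tidy.ferm_pra <- function(x, ...) x$table

#' @rdname tidy.ferm_pra
#' @export
glance.ferm_pra <- function(x, ...) {
  tibble::tibble(
    n_parameters = nrow(x$table),
    n_significant = sum(x$table$classification == "significant"),
    n_non_significant = sum(x$table$classification == "non-significant"),
    n_non_identifiable = sum(x$table$classification == "non-identifiable"),
    s2 = x$s2, ci_mult = x$ci_mult
  )
}

#' Tidy a trained residual LSTM
#'
#' @param x a `ferm_lstm`.
#' @param ... unused.
#' @return `tidy()`: the per-epoch loss history; `glance()`: a one-row
#'   summary (configuration and best validation MSE).
#' @export
tidy.ferm_lstm <- function(x, ...) x$history

#' @rdname tidy.ferm_lstm
#' @export
glance.ferm_lstm <- function(x, ...) {
  tibble::tibble(units1 = x$config$units[1], units2 = x$config$units[2],
                 activation = x$config$activation,
                 optimizer = x$config$optimizer,
                 learning_rate = x$config$learning_rate,
                 mse_val = x$mse_val, epochs_run = x$epochs_run,
                 seed = x$seed)
}

#' Long-format view of a trajectory
#'
#' @param x a `ferm_trajectory` (or `ferm_hybrid`).
#' @param ... unused.
#' @return Tibble with `time_h`, `channel`, `value`.
#' @export
tidy.ferm_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("time_h", .channel_names)],
                      -"time_h", names_to = "channel", values_to = "value")
}

#' @export
tidy.ferm_hybrid <- tidy.ferm_trajectory

#' Plot a simulated trajectory
#'
#' Faceted concentration profiles over time, one panel per state
#' variable.
#'
#' @param object a `ferm_trajectory`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ferm_trajectory <- function(object, ...) {
  ggplot2::ggplot(tidy.ferm_trajectory(object),
                  ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)")
}

#' Plot Monte Carlo uncertainty bands
#'
#' @param object a `ferm_bands` from [monte_carlo_bands()].
#' @param ... unused.
#' @return A ggplot object: nominal trajectory with min/max envelope,
#'   faceted per channel.
#' @export
autoplot.ferm_bands <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$nominal)) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)")
}

#' Plot a hybrid prediction against its mechanistic core
#'
#' @param object a `ferm_hybrid` from [hybrid_predict()].
#' @param obs optional observation dataset to overlay as points.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ferm_hybrid <- function(object, obs = NULL, ...) {
  hy <- tidy.ferm_trajectory(object)
  hy$model <- "hybrid"
  ph <- tidy.ferm_trajectory(attr(object, "pheno"))
  ph$model <- "mechanistic"
  dat <- dplyr::bind_rows(hy, ph)
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h,
                                          y = .data$value,
                                          colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (g/L)")
  if (!is.null(obs)) {
    od <- tidyr::pivot_longer(
      tibble::as_tibble(obs)[, c("time_h", .channel_names)],
      -"time_h", names_to = "channel", values_to = "value")
    gg <- gg + ggplot2::geom_point(data = od, colour = "black",
                                   size = 1)
  }
  gg
}

#' Plot identifiability metrics
#'
#' t-values on a log scale with the significance cutoff at 2, colored by
#' classification.
#'
#' @param object a `ferm_pra`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ferm_pra <- function(object, ...) {
  tab <- object$table
  tab$parameter <- stats::reorder(tab$parameter, tab$t_value)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$t_value,
                                    y = .data$parameter,
                                    colour = .data$classification)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 2, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "t-value", y = NULL)
}
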