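#' Calibration objective: normalized sum of squared errors
#'
#' For each dataset the model is simulated at the observation times and
#' the squared residuals are summed over channels and times after
#' normalization:
#' \deqn{J(\theta) = \sum_d \sum_v w_v \sum_t
#'       \left(\frac{x^{model}_{v,t} - x^{exp}_{v,t}}{N_v}\right)^2}
#' with `N_v = max_t x_exp` per channel (default, `"max"` mode) or the
#' pointwise experimental value (`"pointwise"` mode; singular where the
#' data hit 0, kept behind the flag for completeness). Solver failures
#' return the penalty value so a global optimizer can continue.
#'
#' @param params `ferm_params` (full 22-vector) to evaluate.
#' @param datasets list of `ferm_dataset`/`ferm_densified` tibbles; each
#'   must carry its initial condition in the `ic` attribute (or supply
#'   `ics`).
#' @param ics optional list of initial states overriding the attributes.
#' @param normalization `"max"` or `"pointwise"`.
#' @param weights channel weights, recycled over the six channels.
#' @param penalty value returned on solver failure.
#' @param cfg,opts gating configuration and model options.
#' @return Scalar J >= 0.
#' @export
objective_value <- function(params, datasets, ics = NULL,
                            normalization = c("max", "pointwise"),
                            weights = rep(1, 6), penalty = 1e9,
                            cfg = gating_config(), opts = model_options()) {
  normalization <- match.arg(normalization)
  if (!is.list(datasets) || tibble::is_tibble(datasets)) {
    datasets <- list(datasets)
  }
  weights <- rep_len(weights, 6)
  if (any(weights < 0) || all(weights == 0)) {
    stop("channel weights must be >= 0 with at least one positive")
  }
  total <- 0
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    ic <- if (!is.null(ics)) ics[[k]] else attr(ds, "ic")
    if (is.null(ic)) stop("dataset ", k, " carries no initial condition")
    traj <- try(simulate_fermentation(ic, params, t_grid = ds$time_h,
                                      cfg = cfg, opts = opts),
                silent = TRUE)
    if (inherits(traj, "try-error")) {
      warning("solver failure during objective evaluation; penalty applied")
      return(penalty)
    }
    for (v in seq_along(.channel_names)) {
      ch <- .channel_names[v]
      obs <- ds[[ch]]
      mod <- traj[[ch]]
      nv <- if (normalization == "max") {
        rep(max(obs), length(obs))
      } else {
        obs
      }
      resid2 <- ((mod - obs) / nv)^2
      resid2[!is.finite(resid2)] <- 0   # pointwise mode at exact zeros
      total <- total + weights[v] * sum(resid2)
    }
  }
  total
}

# Builds a closure over the free-parameter subset for the optimizer.
.make_objective <- function(datasets, free, base, ...) {
  base <- kinetic_params(.values = base)
  force(free)
  function(theta) {
    p <- base
    p[free] <- theta
    objective_value(p, datasets, ...)
  }
}

#' Grey wolf optimization
#'
#' Canonical grey wolf optimizer: a pack of candidate solutions moves
#' toward the three best wolves (alpha, beta, delta) with coefficient
#' vectors `A = 2 a r1 - a` and `C = 2 r2`, where `a` decays linearly
#' from 2 to 0 over the epochs; positions are clipped to the bounds.
#' The best-so-far solution never worsens. Fully reproducible per seed.
#'
#' @param f objective function of a numeric vector, returning a scalar.
#' @param lower,upper bound vectors (equal length >= 1).
#' @param pop pack size (>= 4).
#' @param epochs number of epochs (0 returns the best of the random
#'   initial pack).
#' @param rng_seed integer seed.
#' @param init optional matrix (rows = wolves) or vector of initial
#'   positions injected into the pack.
#' @param pack optional warm-start state (the `pack` element of a
#'   previous result): resumes the same pack instead of sampling a new
#'   one.
#' @param a_range coefficient decay window: `a` moves linearly from
#'   `a_range[1]` to `a_range[2]` across the epochs. The canonical
#'   schedule is 2 -> 0; block-wise callers pass intermediate windows so
#'   a segmented run follows the same global decay.
#' @return List with `par`, `value`, `history` (best J per epoch),
#'   `evals`, `pack` (resumable state).
#' @export
gwo_minimize <- function(f, lower, upper, pop = 30L, epochs = 100L,
                         rng_seed = 1L, init = NULL, pack = NULL,
                         a_range = c(2, 0)) {
  d <- length(lower)
  if (length(upper) != d || any(lower >= upper)) {
    stop("invalid bounds: need lower < upper componentwise")
  }
  if (pop < 4) stop("pack size must be at least 4 (alpha/beta/delta/omega)")
  withr::with_seed(rng_seed, {
    clip <- function(M) {
      pmin(pmax(M, rep(lower, each = nrow(M))), rep(upper, each = nrow(M)))
    }
    evals <- 0L
    if (is.null(pack)) {
      X <- matrix(stats::runif(pop * d, rep(lower, each = pop),
                               rep(upper, each = pop)), nrow = pop)
      if (!is.null(init)) {
        init <- matrix(init, ncol = d)
        take <- min(nrow(init), pop)
        X[seq_len(take), ] <- init[seq_len(take), , drop = FALSE]
        X <- clip(X)
      }
      J <- apply(X, 1, f)
      evals <- pop
      ord <- order(J)
      alpha <- X[ord[1], ]; beta <- X[ord[2], ]; delta <- X[ord[3], ]
      J_abc <- J[ord[1:3]]
    } else {
      X <- clip(pack$X)
      alpha <- pmin(pmax(pack$alpha, lower), upper)
      beta <- pmin(pmax(pack$beta, lower), upper)
      delta <- pmin(pmax(pack$delta, lower), upper)
      J_abc <- pack$J_abc
      # leaders displaced by new bounds must be re-scored
      moved <- c(!isTRUE(all.equal(alpha, pack$alpha)),
                 !isTRUE(all.equal(beta, pack$beta)),
                 !isTRUE(all.equal(delta, pack$delta)))
      if (moved[1]) J_abc[1] <- f(alpha)
      if (moved[2]) J_abc[2] <- f(beta)
      if (moved[3]) J_abc[3] <- f(delta)
      evals <- evals + sum(moved)
    }
    history <- numeric(0)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        a <- a_range[1] + (a_range[2] - a_range[1]) *
          (ep - 1) / max(epochs - 1, 1)
        for (i in seq_len(pop)) {
          x_new <- numeric(d)
          for (leader in list(alpha, beta, delta)) {
            A <- 2 * a * stats::runif(d) - a
            C <- 2 * stats::runif(d)
            D <- abs(C * leader - X[i, ])
            x_new <- x_new + (leader - A * D) / 3
          }
          X[i, ] <- pmin(pmax(x_new, lower), upper)
        }
        J <- apply(X, 1, f)
        evals <- evals + pop
        for (i in seq_len(pop)) {
          if (J[i] < J_abc[1]) {
            J_abc <- c(J[i], J_abc[1:2])
            delta <- beta; beta <- alpha; alpha <- X[i, ]
          } else if (J[i] < J_abc[2]) {
            J_abc[2:3] <- c(J[i], J_abc[2])
            delta <- beta; beta <- X[i, ]
          } else if (J[i] < J_abc[3]) {
            J_abc[3] <- J[i]
            delta <- X[i, ]
          }
        }
        history <- c(history, J_abc[1])
      }
    }
    list(par = alpha, value = J_abc[1], history = history, evals = evals,
         pack = list(X = X, alpha = alpha, beta = beta, delta = delta,
                     J_abc = J_abc))
  })
}

#' Calibrate kinetic parameters by GWO with iterative bound refinement
#'
#' Runs the grey wolf optimizer in rounds (default 20 epochs each, 160
#' epochs total). The first round searches a +/- `initial_halfwidth`
#' (default 30%) box around the starting values. After every round, any
#' parameter within relative `touch_tol` of a bound has its box
#' recalibrated to +/- 10% around the current estimate, intersected with
#' `[literature_lower / 10, literature_upper * 10]` so the moving box
#' can never drift more than an order of magnitude from the
#' literature-based range. Refinement stops early once a round brings
#' neither an improvement nor a bound recalibration.
#'
#' @param datasets list of (densified) datasets with `ic` attributes.
#' @param free names of the free parameters (others fixed at `start`).
#' @param start full starting `ferm_params` (default: the literature
#'   initial values).
#' @param bounds literature bounds tibble as from [param_bounds()].
#' @param round_epochs,total_epochs epochs per round / in total
#'   (`total_epochs` must be a multiple of `round_epochs`).
#' @param pop pack size.
#' @param initial_halfwidth half-width of the first-round box (fraction).
#' @param refine_halfwidth half-width after a bound touch (fraction).
#' @param touch_tol relative proximity to a bound that triggers
#'   recalibration.
#' @param rng_seed integer seed.
#' @param ... passed to [objective_value()] (normalization, weights, ...).
#' @return A `ferm_calibration` object: list with `params` (full
#'   calibrated set), `estimate` (free subset), `value`, `start_value`,
#'   `free`, `bound_history`, `epochs_run`, `rounds`, `seed`,
#'   `convergence` (best J per epoch).
#' @export
calibrate <- function(datasets, free = param_names(),
                      start = initial_params(), bounds = param_bounds(),
                      round_epochs = 20L, total_epochs = 160L,
                      pop = 30L, initial_halfwidth = 0.30,
                      refine_halfwidth = 0.10, touch_tol = 1e-6,
                      rng_seed = 1L, ...) {
  if (total_epochs %% round_epochs != 0) {
    stop("total_epochs must be a multiple of round_epochs")
  }
  start <- kinetic_params(.values = start)
  free <- match.arg(free, param_names(), several.ok = TRUE)
  f <- .make_objective(datasets, free, start, ...)
  lit <- bounds[match(free, bounds$parameter), ]
  if (anyNA(lit$lower)) stop("bounds table is missing free parameters")
  # order-of-magnitude clamp around the literature box; a zero literature
  # lower bound clamps to 0
  clamp_lo <- lit$lower / 10
  clamp_hi <- lit$upper * 10

  theta0 <- unclass(start)[free]
  lower <- pmax(theta0 * (1 - initial_halfwidth), clamp_lo)
  upper <- pmin(theta0 * (1 + initial_halfwidth), clamp_hi)
  # guard degenerate boxes around ~0 starting values
  tiny <- upper - lower <= 0
  if (any(tiny)) {
    lower[tiny] <- clamp_lo[tiny]
    upper[tiny] <- pmax(clamp_hi[tiny] * 1e-3, lower[tiny] + 1e-12)
  }

  J0 <- f(theta0)
  best_par <- theta0
  best_J <- J0
  bound_history <- list(tibble::tibble(parameter = free, round = 0L,
                                       lower = lower, upper = upper))
  convergence <- numeric(0)
  rounds <- total_epochs %/% round_epochs
  rounds_run <- 0L
  pack <- NULL
  for (r in seq_len(rounds)) {
    # one pack persists across rounds; `a` follows the global 2 -> 0 decay
    a_hi <- 2 - 2 * (r - 1) / rounds
    a_lo <- 2 - 2 * r / rounds
    res <- gwo_minimize(f, lower, upper, pop = pop, epochs = round_epochs,
                        rng_seed = rng_seed + r, init = best_par,
                        pack = pack, a_range = c(a_hi, a_lo))
    pack <- res$pack
    rounds_run <- r
    convergence <- c(convergence, res$history)
    improved <- res$value < best_J - .Machine$double.eps
    if (res$value <= best_J) {
      best_J <- res$value
      best_par <- res$par
    }
    # recalibrate boxes touched by the current estimate
    width <- upper - lower
    touched <- (best_par - lower) <= touch_tol * pmax(abs(best_par), width) |
      (upper - best_par) <= touch_tol * pmax(abs(best_par), width)
    if (any(touched)) {
      lower[touched] <- pmax(best_par[touched] * (1 - refine_halfwidth),
                             clamp_lo[touched])
      upper[touched] <- pmin(best_par[touched] * (1 + refine_halfwidth),
                             clamp_hi[touched])
      bad <- upper <= lower
      if (any(bad)) {      # collapsed box (estimate pinned at a clamp)
        upper[bad] <- lower[bad] + pmax(1e-9, 1e-6 * abs(lower[bad]))
      }
      bound_history <- c(bound_history,
                         list(tibble::tibble(parameter = free[touched],
                                             round = r,
                                             lower = lower[touched],
                                             upper = upper[touched])))
    }
    if (!improved && !any(touched)) break
  }
  params <- start
  params[free] <- best_par
  structure(list(
    params = params,
    estimate = stats::setNames(best_par, free),
    value = best_J, start_value = J0, free = free,
    bound_history = dplyr::bind_rows(bound_history),
    epochs_run = rounds_run * round_epochs, rounds = rounds_run,
    seed = rng_seed, convergence = convergence
  ), class = "ferm_calibration")
}

#' @export
print.ferm_calibration <- function(x, ...) {
  cat("<ferm_calibration>\n",
      " free parameters: ", length(x$free), "\n",
      " J(theta_hat) = ", format(x$value, digits = 6),
      " (start ", format(x$start_value, digits = 6), ")\n",
      " epochs run: ", x$epochs_run, "\n", sep = "")
  invisible(x)
}
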