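#' Forward sensitivity trajectories
#'
#' Integrates the augmented system `dS/dt = (df/dx) S + df/dtheta`
#' alongside the states, with S(0) = 0 (initial conditions do not depend
#' on the parameters). The Jacobians of the smooth gated right-hand side
#' are evaluated in compiled code by central differences at each solver
#' call; the augmented (non-stiff) system is integrated with an Adams
#' predictor-corrector, falling back to BDF (`vode`) at tightened
#' tolerance before raising a structured error.
#'
#' @param p [kinetic_params()] at which to linearize.
#' @param ic initial [state_vector()].
#' @param t_grid output times, h, starting at 0.
#' @param parameters subset of [param_names()] to differentiate with
#'   respect to (default: all 22).
#' @param cfg,opts gating configuration and model options.
#' @param atol,rtol integration tolerances for the augmented system.
#' @return A list of class `ferm_sensitivity`: `times`, `states` (matrix
#'   length(t_grid) x 7), `sens` (array length(t_grid) x 6 channels x
#'   n_parameters, units: g/L per parameter unit), `parameters`.
#' @export
forward_sensitivities <- function(p, ic, t_grid = seq(0, 48, by = 1),
                                  parameters = param_names(),
                                  cfg = gating_config(),
                                  opts = model_options(),
                                  atol = 1e-8, rtol = 1e-8) {
  p <- kinetic_params(.values = p)
  parameters <- match.arg(parameters, param_names(), several.ok = TRUE)
  idx <- match(parameters, param_names())
  parms <- .ferm_parms_vector(p, cfg, feed_inputs(), opts)
  n_th <- length(idx)
  ic <- ic[state_names()]

  aug_rhs <- function(t, y, ignored) {
    st <- y[1:7]
    S <- matrix(y[-(1:7)], nrow = 7)
    core <- .ferm_rhs_c(st, parms)
    J <- .ferm_jac_c(st, parms)
    dS <- J$Jx %*% S + J$Jp[, idx, drop = FALSE]
    list(c(core$dy, as.vector(dS)))
  }
  y0 <- c(ic, rep(0, 7 * n_th))
  run <- function(method, at, rt) {
    try(suppressWarnings(
      deSolve::ode(y = y0, times = t_grid, func = aug_rhs, parms = NULL,
                   method = method, atol = at, rtol = rt,
                   maxsteps = 50000)), silent = TRUE)
  }
  sol <- run("adams", atol, rtol)
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid) ||
        anyNA(sol)) {
    sol <- run("vode", atol / 10, rtol / 10)
  }
  if (inherits(sol, "try-error") || nrow(sol) < length(t_grid)) {
    stop("sensitivity integration failed, including at tightened tolerance")
  }
  states <- sol[, 2:8, drop = FALSE]
  colnames(states) <- state_names()
  sens <- array(sol[, -(1:8), drop = FALSE],
                dim = c(length(t_grid), 7, n_th))
  # report the six concentration channels (drop volume)
  sens <- sens[, 1:6, , drop = FALSE]
  dimnames(sens) <- list(NULL, .channel_names, parameters)
  structure(list(times = t_grid, states = states, sens = sens,
                 parameters = parameters, params = p),
            class = "ferm_sensitivity")
}

#' Practical-identifiability metrics (pre/post-regression analysis)
#'
#' From forward sensitivities evaluated at the data times, builds the
#' scaled sensitivity matrix (each entry `(dx_v/dtheta_j) * theta_j / N_v`
#' with `N_v` the per-channel maximum, mirroring the objective's
#' normalization), then computes the parameter covariance
#' `s^2 (S'S)^{-1}`, standard deviations, t-values, the correlation
#' matrix K, the per-channel average absolute scaled sensitivity
#' `G_prom`, and a classification:
#' * `non-significant` if t <= 2;
#' * `non-identifiable` if involved in a correlation with |K| >= 0.95
#'   (or flagged when S'S is numerically singular);
#' * `low-sensitivity-flagged` if max-over-channel G_prom is below
#'   1e-3 of the global maximum (reported, never auto-fixed: such
#'   parameters can still be phenomenologically necessary);
#' * `significant` otherwise.
#' Confidence bounds are `estimate +/- ci_mult * sd` with `ci_mult = 1`
#' by default (the reporting convention used here; set 1.96 for
#' asymptotic 95% intervals).
#'
#' @param sens a `ferm_sensitivity` evaluated at the observation times.
#' @param residual_variance scalar s^2: weighted residual mean square of
#'   the fit (normalized residuals, denominator n_obs - n_free).
#' @param norms optional named per-channel normalization constants
#'   (default: max absolute model value per channel from `sens$states`).
#' @param ci_mult CI half-width in units of sigma.
#' @param cor_cutoff |K| threshold for non-identifiability.
#' @return A `ferm_pra` object: list with `table` (tibble: parameter,
#'   estimate, sd, pct_sd, t_value, ci_lower, ci_upper, g_prom_max,
#'   classification), `correlation` (K matrix), `g_prom`
#'   (parameter x channel), `s2`.
#' @export
pra_metrics <- function(sens, residual_variance = 1, norms = NULL,
                        ci_mult = 1, cor_cutoff = 0.95) {
  pars <- sens$parameters
  theta <- unclass(sens$params)[pars]
  n_t <- length(sens$times)
  if (is.null(norms)) {
    mod <- sens$states[, 1:6, drop = FALSE]
    colnames(mod) <- .channel_names
    norms <- apply(abs(mod), 2, max)
  }
  norms <- pmax(norms[.channel_names], .Machine$double.eps)

  # stacked scaled sensitivity matrix: rows = (channel, time), cols = params
  S <- do.call(rbind, lapply(seq_along(.channel_names), function(v) {
    Sv <- matrix(sens$sens[, v, ], nrow = n_t)
    sweep(Sv, 2, theta, `*`) / norms[v]
  }))
  colnames(S) <- pars

  # parameters the data carry no information on (zero sensitivity
  # columns) get infinite variance, not the near-zero variance a
  # pseudo-inverse would report for a null-space direction
  col_norm <- sqrt(colSums(S^2))
  dead <- col_norm <= 1e-10 * max(col_norm, .Machine$double.eps)
  live <- which(!dead)
  cov_u <- matrix(0, length(pars), length(pars),
                  dimnames = list(pars, pars))
  cov_u[dead, ] <- cov_u[, dead] <- NA_real_
  sing <- FALSE
  if (length(live)) {
    StS <- crossprod(S[, live, drop = FALSE])
    inv <- tryCatch(solve(StS), error = function(e) NULL)
    if (is.null(inv)) {
      sing <- TRUE
      sv <- svd(StS)
      pos <- sv$d > max(sv$d) * 1e-12
      inv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      warning("S'S numerically singular: pseudo-inverse used; ",
              "affected parameters flagged non-identifiable")
    }
    cov_u[live, live] <- inv
  }
  covm <- residual_variance * cov_u
  # covariance of the *scaled* parameters (theta_j / theta_j = 1), so the
  # relative sd of theta_j is sqrt(diag); absolute sd scales by |theta_j|
  rel_sd <- sqrt(pmax(diag(covm), 0))
  rel_sd[dead] <- Inf
  sd_abs <- rel_sd * abs(theta)
  t_val <- ifelse(rel_sd > 0, 1 / rel_sd, Inf)
  # correlation structure does not depend on s^2: use the unscaled inverse
  sdu <- sqrt(pmax(diag(cov_u), 0))
  denom <- outer(sdu, sdu)
  K <- cov_u / ifelse(is.finite(denom) & denom > 0, denom, 1)
  K[!is.finite(K)] <- 0
  diag(K) <- 1
  dimnames(K) <- list(pars, pars)

  g_prom <- t(vapply(seq_along(pars), function(j) {
    vapply(seq_along(.channel_names), function(v) {
      mean(abs(sens$sens[, v, j] * theta[j] / norms[v]))
    }, numeric(1))
  }, numeric(6)))
  dimnames(g_prom) <- list(pars, .channel_names)
  g_max <- apply(g_prom, 1, max)

  correlated <- vapply(seq_along(pars), function(j) {
    any(abs(K[j, -j]) >= cor_cutoff)
  }, logical(1))
  low_sens <- g_max < 1e-3 * max(g_max)
  classification <- dplyr::case_when(
    t_val <= 2 ~ "non-significant",
    sing | correlated ~ "non-identifiable",
    low_sens ~ "low-sensitivity-flagged",
    TRUE ~ "significant"
  )
  tab <- tibble::tibble(
    parameter = pars,
    estimate = unname(theta),
    sd = unname(sd_abs),
    pct_sd = unname(rel_sd) * 100,
    t_value = unname(t_val),
    ci_lower = unname(theta - ci_mult * sd_abs),
    ci_upper = unname(theta + ci_mult * sd_abs),
    g_prom_max = unname(g_max),
    classification = classification
  )
  structure(list(table = tab, correlation = K, g_prom = g_prom,
                 s2 = residual_variance, ci_mult = ci_mult),
            class = "ferm_pra")
}

#' @export
print.ferm_pra <- function(x, ...) {
  cat("<ferm_pra> identifiability report,", nrow(x$table), "parameters\n")
  print(x$table, n = nrow(x$table))
  invisible(x)
}

# Residual mean square of a fit: max-normalized residuals over all
# datasets/channels, denominator n_obs - n_free.
.residual_mean_square <- function(params, datasets, n_free,
                                  cfg = gating_config(),
                                  opts = model_options()) {
  ss <- 0; n <- 0
  for (ds in datasets) {
    ic <- attr(ds, "ic")
    traj <- simulate_fermentation(ic, params, t_grid = ds$time_h,
                                  cfg = cfg, opts = opts)
    for (ch in .channel_names) {
      nv <- max(ds[[ch]], .Machine$double.eps)
      ss <- ss + sum(((traj[[ch]] - ds[[ch]]) / nv)^2)
      n <- n + length(ds[[ch]])
    }
  }
  ss / max(n - n_free, 1)
}

#' Sequential parameter fixing driven by identifiability
#'
#' Applies the screening criteria in sequence, refitting the metrics
#' after each stage: (1) fix every parameter with t <= 2 at its current
#' estimate; (2) while any pair has |K| >= 0.95, fix the member with the
#' smaller t-value (ties: smaller mean G_prom) and recompute; (3) report
#' (but never auto-fix) parameters whose max G_prom falls below 1e-3 of
#' the global maximum. Errors if the procedure would fix everything.
#'
#' @param params calibrated `ferm_params` (current estimates).
#' @param datasets list of datasets with `ic` attributes (observation
#'   times and values; used for normalization and residual variance).
#' @param free names of the initially free parameters.
#' @param cfg,opts model configuration.
#' @param t_grid_pool optional times at which sensitivities are
#'   evaluated; default: union of dataset times.
#' @return A list of class `ferm_fixing`: `free`, `fixed` (named stages),
#'   `report` (final `ferm_pra`), `stages` (tibble log).
#' @export
sequential_fixing <- function(params, datasets, free = param_names(),
                              cfg = gating_config(),
                              opts = model_options(),
                              t_grid_pool = NULL) {
  params <- kinetic_params(.values = params)
  datasets <- if (tibble::is_tibble(datasets)) list(datasets) else datasets
  ics <- lapply(datasets, attr, "ic")
  if (any(vapply(ics, is.null, logical(1)))) {
    stop("every dataset must carry an `ic` attribute")
  }
  norms <- apply(do.call(rbind, lapply(datasets, function(d) {
    apply(abs(as.matrix(d[, .channel_names])), 2, max)
  })), 2, max)

  compute_pra <- function(cur_free) {
    s2 <- .residual_mean_square(params, datasets, length(cur_free), cfg, opts)
    s2 <- max(s2, .Machine$double.eps)
    sens_list <- lapply(seq_along(datasets), function(k) {
      forward_sensitivities(params, ics[[k]],
                            t_grid = datasets[[k]]$time_h,
                            parameters = cur_free, cfg = cfg, opts = opts)
    })
    # pool replicate sensitivities by stacking times
    pooled <- sens_list[[1]]
    if (length(sens_list) > 1) {
      pooled$times <- unlist(lapply(sens_list, `[[`, "times"))
      pooled$states <- do.call(rbind, lapply(sens_list, `[[`, "states"))
      pooled$sens <- do.call(function(...) {
        arrays <- list(...)
        out <- array(NA_real_, dim = c(sum(vapply(arrays, function(a)
          dim(a)[1], numeric(1))), 6, length(cur_free)))
        at <- 0
        for (a in arrays) {
          out[at + seq_len(dim(a)[1]), , ] <- a
          at <- at + dim(a)[1]
        }
        dimnames(out) <- dimnames(arrays[[1]])
        out
      }, lapply(sens_list, `[[`, "sens"))
    }
    pra_metrics(pooled, residual_variance = s2, norms = norms)
  }

  cur_free <- free
  fixed <- list()
  stages <- list()

  # stage 1: significance
  rep1 <- compute_pra(cur_free)
  ns <- rep1$table$parameter[rep1$table$t_value <= 2]
  if (length(ns) >= length(cur_free)) {
    stop("sequential fixing would leave no free parameters")
  }
  fixed$non_significant <- ns
  cur_free <- setdiff(cur_free, ns)
  stages <- c(stages, list(tibble::tibble(stage = "significance",
                                          fixed = list(ns))))

  # stage 2: identifiability (iterate until no |K| >= 0.95 pair remains)
  repeat {
    rep2 <- compute_pra(cur_free)
    K <- rep2$correlation
    off <- abs(K); diag(off) <- 0
    if (all(off < 0.95) || length(cur_free) <= 1) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    pair <- rownames(K)[worst]
    tv <- rep2$table$t_value[match(pair, rep2$table$parameter)]
    drop_par <- if (tv[1] == tv[2]) {
      gm <- rowMeans(rep2$g_prom[pair, , drop = FALSE])
      pair[which.min(gm)]
    } else {
      pair[which.min(tv)]
    }
    if (length(cur_free) - 1 < 1) {
      stop("sequential fixing would leave no free parameters")
    }
    fixed$non_identifiable <- c(fixed$non_identifiable, drop_par)
    cur_free <- setdiff(cur_free, drop_par)
    stages <- c(stages, list(tibble::tibble(stage = "identifiability",
                                            fixed = list(drop_par))))
  }

  # stage 3: sensitivity screening (reported only)
  final <- compute_pra(cur_free)
  low <- final$table$parameter[final$table$classification ==
                                 "low-sensitivity-flagged"]
  stages <- c(stages, list(tibble::tibble(stage = "sensitivity",
                                          fixed = list(character(0)),
                                          flagged = list(low))))
  structure(list(free = cur_free, fixed = fixed, report = final,
                 low_sensitivity = low,
                 stages = dplyr::bind_rows(stages)),
            class = "ferm_fixing")
}

#' Monte Carlo uncertainty bands
#'
#' Runs `n` simulations with every parameter independently perturbed as
#' `theta_j ~ Normal(theta_j, rel_sd * theta_j)` (truncated at the
#' literature order-of-magnitude box), and returns the pointwise
#' min/max envelope across successful runs together with the nominal
#' (unperturbed) trajectory. At least 80% of runs must integrate;
#' failures are dropped with a warning.
#'
#' @param p nominal [kinetic_params()].
#' @param ic initial [state_vector()].
#' @param t_grid output times, h.
#' @param rel_sd relative SD of the parameter perturbation (default 5%).
#' @param n number of Monte Carlo iterations (default 100).
#' @param rng_seed integer seed.
#' @param cfg,opts model configuration.
#' @return A tibble (class `ferm_bands`) in long format: `time_h`,
#'   `channel`, `nominal`, `lower`, `upper`; attributes `n_effective`,
#'   `rel_sd`.
#' @export
monte_carlo_bands <- function(p, ic, t_grid = seq(0, 48, by = 1),
                              rel_sd = 0.05, n = 100L, rng_seed = 1L,
                              cfg = gating_config(),
                              opts = model_options()) {
  stopifnot(n >= 2)
  p <- kinetic_params(.values = p)
  nominal <- simulate_fermentation(ic, p, t_grid = t_grid, cfg = cfg,
                                   opts = opts)
  theta <- unclass(p)
  draws <- withr::with_seed(rng_seed, {
    matrix(stats::rnorm(n * length(theta), rep(theta, each = n),
                        rep(abs(theta) * rel_sd, each = n)),
           nrow = n)
  })
  # truncate at an order of magnitude around the nominal value
  draws <- pmin(pmax(draws, rep(theta / 10, each = n)),
                rep(theta * 10, each = n))
  lo <- hi <- as.matrix(nominal[, .channel_names])
  n_ok <- 0L
  for (i in seq_len(n)) {
    pi <- kinetic_params(.values = stats::setNames(draws[i, ], names(theta)))
    traj <- try(simulate_fermentation(ic, pi, t_grid = t_grid, cfg = cfg,
                                      opts = opts), silent = TRUE)
    if (inherits(traj, "try-error")) next
    m <- as.matrix(traj[, .channel_names])
    lo <- pmin(lo, m); hi <- pmax(hi, m)
    n_ok <- n_ok + 1L
  }
  if (n_ok < n) warning(n - n_ok, " Monte Carlo run(s) failed and were dropped")
  if (n_ok < 0.8 * n) stop("fewer than 80% of Monte Carlo runs succeeded")
  out <- tidyr::pivot_longer(nominal[, c("time_h", .channel_names)],
                             -"time_h", names_to = "channel",
                             values_to = "nominal")
  out$lower <- as.vector(t(lo))
  out$upper <- as.vector(t(hi))
  structure(out, class = c("ferm_bands", class(out)),
            n_effective = n_ok, rel_sd = rel_sd)
}
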