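#' Smooth depletion/appearance gate
#'
#' Leaky-ReLU-style switch normalized by its own argument:
#' `max(gamma * z, z) / sqrt(z^2 + epsilon)` with
#' `z = c - threshold` (direction `"deplete"`: the gate shuts a rate down
#' as the pool `c` empties) or `z = threshold - c` (direction `"appear"`:
#' the gate turns on as the pool empties, used for post-glucose switching).
#' The gate runs continuously in (-gamma * threshold / sqrt(epsilon), 1)
#' and is differentiable everywhere except the kink of `max` itself, which
#' the normalization keeps bounded.
#'
#' @param c concentration, g/L (vectorized).
#' @param direction `"deplete"` or `"appear"`.
#' @param cfg a [gating_config()].
#' @return Unitless gate value(s) in (-gamma*threshold/sqrt(epsilon), 1).
#' @export
#' @examples
#' smooth_gate(10, "deplete")     # ~1: pool abundant
#' smooth_gate(0.001, "deplete")  # 0 exactly at the threshold
smooth_gate <- function(c, direction = c("deplete", "appear"),
                        cfg = gating_config()) {
  direction <- match.arg(direction)
  if (any(!is.finite(c))) stop("smooth_gate: non-finite concentration")
  z <- if (direction == "deplete") c - cfg$threshold else cfg$threshold - c
  pmax(cfg$gamma * z, z) / sqrt(z^2 + cfg$epsilon)
}

#' Effective fructose parameters under catabolite repression
#'
#' Glucose represses fructose uptake; once glucose is depleted the
#' fructose maximum growth rate and affinity constant relax to their
#' post-glucose values. The switch is the appearance gate evaluated on
#' instantaneous glucose (a pure function of state, no accumulation):
#' `mu_max_R_eff = mu_max_R + s * (mu_max_postG - mu_max_R)`,
#' `K_R_eff = K_R + s * (K_R_postG - K_R)` with
#' `s = smooth_gate(G, "appear")`.
#'
#' @param G glucose, g/L.
#' @param p [kinetic_params()].
#' @param cfg [gating_config()].
#' @return Named list `mu_max_R_eff`, `K_R_eff` (g/(g h), g/L).
#' @export
effective_fructose_params <- function(G, p = default_params(),
                                      cfg = gating_config()) {
  s <- smooth_gate(G, "appear", cfg)
  list(
    mu_max_R_eff = p[["mu_max_R"]] + s * (p[["mu_max_postG"]] - p[["mu_max_R"]]),
    K_R_eff      = p[["K_R"]] + s * (p[["K_R_postG"]] - p[["K_R"]])
  )
}

#' Specific rates
#'
#' Monod growth on glucose and fructose with non-competitive ethanol
#' inhibition, respiratory growth on ethanol inhibited by fermentable
#' monosaccharides (AF = G + R, the Crabtree-style repression of ethanol
#' respiration), and their sum as the total specific growth rate:
#' \deqn{\mu_G = \mu_{max,G} \frac{G}{K_G+G} \frac{K_{i,Et}}{K_{i,Et}+Et}}
#' \deqn{\mu_{Et} = \mu_{max,Et} \frac{Et}{K_{Et}+Et}
#'                  \frac{K_{inh,AF}}{K_{inh,AF}+AF}}
#' \deqn{\mu_X = \mu_G + \mu_R + \mu_{Et}}
#'
#' @param state named state vector (see [state_vector()]).
#' @param p [kinetic_params()]. @param cfg [gating_config()].
#' @return Named list `mu_G`, `mu_R`, `mu_Et`, `mu_X`, all g/(g h).
#' @export
specific_rates <- function(state, p = default_params(),
                           cfg = gating_config()) {
  G <- state[["G"]]; R <- state[["R"]]; Et <- state[["Et"]]
  eff <- effective_fructose_params(G, p, cfg)
  inh <- p[["K_i_Et"]] / (p[["K_i_Et"]] + Et)
  mu_G <- p[["mu_max_G"]] * G / (p[["K_G"]] + G) * inh
  mu_R <- eff$mu_max_R_eff * R / (eff$K_R_eff + R) * inh
  AF <- G + R
  mu_Et <- p[["mu_max_Et"]] * Et / (p[["K_Et"]] + Et) *
    p[["K_inh_AF"]] / (p[["K_inh_AF"]] + AF)
  list(mu_G = mu_G, mu_R = mu_R, mu_Et = mu_Et,
       mu_X = mu_G + mu_R + mu_Et)
}

#' Volumetric reaction rates
#'
#' All nine volumetric rates of the model, g/(L h): biomass growth
#' `r_X`, glucose/fructose consumption `r_G`/`r_R` (growth-linked +
#' maintenance + ethanol-linked, each shut down by the depletion gate on
#' its own sugar), sucrose uptake `r_S` (Monod, invertase hydrolysis),
#' the monosaccharide release rates `r_gG = r_gR = r_S * Y_AF_S`, urea
#' uptake `r_Ur` (growth-proportional, gated on urea), ethanol
#' production `r_Et` and consumption `r_Et_c`. Consumption rates are
#' multiplied by `1{c > 0}` exactly when a pool is at or below zero so
#' the gate leak can never drive a concentration negative.
#'
#' @inheritParams specific_rates
#' @param opts [model_options()].
#' @return Named list of the nine rates plus the four specific rates.
#' @export
reaction_rates <- function(state, p = default_params(),
                           cfg = gating_config(), opts = model_options()) {
  X <- state[["X"]]; G <- state[["G"]]; R <- state[["R"]]
  S <- state[["S"]]; U <- state[["U"]]; Et <- state[["Et"]]
  mu <- specific_rates(state, p, cfg)

  gate_G <- smooth_gate(G, "deplete", cfg)
  gate_R <- smooth_gate(R, "deplete", cfg)
  gate_U <- smooth_gate(U, "deplete", cfg)
  gate_Et <- if (opts$ethanol_production_gate == "G+R") {
    smooth_gate(G + R, "deplete", cfg)
  } else {
    gate_R
  }
  eth_den <- if (opts$fructose_ethanol_yield_denominator == "R") {
    p[["Y_Et_R"]]
  } else {
    p[["Y_Et_G"]]
  }

  r_X <- mu$mu_X * X
  r_S <- p[["alpha_S"]] * S / (S + p[["K_S"]]) * X
  r_G <- (p[["Y_G_X"]] * mu$mu_G * X + p[["m_G"]] * X +
            mu$mu_X * X * p[["Y_Et_X"]] / p[["Y_Et_G"]]) * gate_G
  r_R <- (p[["Y_R_X"]] * mu$mu_R * X + p[["m_R"]] * X +
            mu$mu_X * X * p[["Y_Et_X"]] / eth_den) * gate_R
  r_Ur <- mu$mu_X / p[["Y_X_Ur"]] * X * gate_U
  r_Et <- p[["Y_Et_X"]] * mu$mu_X * X * gate_Et
  r_Et_c <- p[["Y_cEt_X"]] * mu$mu_Et * X

  if (G <= 0) r_G <- 0
  if (R <= 0) r_R <- 0
  if (S <= 0) r_S <- 0
  if (U <= 0) r_Ur <- 0
  if (Et <= 0) r_Et_c <- 0

  c(list(r_X = r_X, r_G = r_G, r_R = r_R, r_S = r_S,
         r_gG = r_S * p[["Y_AF_S"]], r_gR = r_S * p[["Y_AF_S"]],
         r_Ur = r_Ur, r_Et = r_Et, r_Et_c = r_Et_c), mu)
}

#' Mass-balance right-hand side
#'
#' Time derivative of the seven-component state (six concentrations plus
#' volume) from the volumetric rates and (optional) feed terms. For a
#' batch run every feed field is zero and the balances reduce to
#' `dX/dt = r_X`, `dG/dt = r_gG - r_G`, and so on; the dilution term
#' `-c * dV/dt / V` is retained for generality (subtracted in every
#' balance, including urea).
#'
#' @param t time, h (unused: the system is autonomous; kept for solver
#'   compatibility).
#' @inheritParams reaction_rates
#' @param feed [feed_inputs()].
#' @return Named numeric vector of derivatives, g/(L h) (and L/h for V).
#' @export
fermentation_rhs <- function(t, state, p = default_params(),
                             feed = feed_inputs(), cfg = gating_config(),
                             opts = model_options()) {
  V <- state[["V"]]
  if (!is.finite(V) || V <= 0) {
    stop("fermentation_rhs: non-positive culture volume (V = ", V, ")")
  }
  r <- reaction_rates(state, p, cfg, opts)
  dV <- feed$dVdt
  c(
    X = (r$r_X * V - state[["X"]] * dV) / V,
    G = (feed$F_i * feed$G_i + V * (r$r_gG - r$r_G) - state[["G"]] * dV) / V,
    R = (feed$F_i * feed$R_i + V * (r$r_gR - r$r_R) - state[["R"]] * dV) / V,
    S = (feed$F_i * feed$S_i - V * r$r_S - state[["S"]] * dV) / V,
    U = (feed$F_i * feed$U_i - V * r$r_Ur - state[["U"]] * dV) / V,
    Et = (V * (r$r_Et - r$r_Et_c) - state[["Et"]] * dV) / V,
    V = dV
  )
}

# Compiled mirrors of the RHS (used by the solver and sensitivity system).
.ferm_rhs_c <- function(state, parms33) {
  out <- .Call(C_ferm_rhs, as.double(state), as.double(parms33))
  list(dy = stats::setNames(out[1:7], state_names()),
       rates = stats::setNames(out[8:20],
                               c("r_X", "r_G", "r_R", "r_S", "r_gG", "r_gR",
                                 "r_Ur", "r_Et", "r_Et_c",
                                 "mu_G", "mu_R", "mu_Et", "mu_X")))
}

.ferm_jac_c <- function(state, parms33) {
  .Call(C_ferm_jac, as.double(state), as.double(parms33))
}

#' Simulate a batch fermentation
#'
#' Integrates the kinetic model over `t_grid` with an explicit
#' 8th-order Dormand-Prince method (`atol = rtol = 1e-6` by default).
#' Solver output concentrations in `(-1e-6, 0)` (possible overshoot at
#' the integration tolerance around depleted pools) are clamped to 0;
#' anything more negative raises a warning.
#'
#' @param ic initial state, a [state_vector()] or a named numeric vector
#'   with components X, G, R, S, U, Et, V.
#' @param p [kinetic_params()].
#' @param t_grid strictly increasing times (h) starting at 0.
#' @param cfg [gating_config()]. @param feed [feed_inputs()].
#' @param opts [model_options()].
#' @param method solver method: `"rk78dp"` (default) or any
#'   [deSolve::ode()] method name.
#' @param atol,rtol absolute/relative integration tolerances.
#' @return A tibble (class `ferm_trajectory`) with columns `time_h`,
#'   `biomass`, `glucose`, `fructose`, `sucrose`, `urea`, `ethanol`,
#'   `volume`; solver metadata in attributes `method`, `atol`, `rtol`,
#'   `success`.
#' @export
#' @examples
#' traj <- simulate_fermentation(
#'   state_vector(X = 1.2, G = 27.5, R = 25.8, S = 39.6, U = 2.3),
#'   t_grid = seq(0, 10, by = 1))
#' traj
simulate_fermentation <- function(ic, p = default_params(),
                                  t_grid = seq(0, 48, by = 0.5),
                                  cfg = gating_config(),
                                  feed = feed_inputs(),
                                  opts = model_options(),
                                  method = "rk78dp",
                                  atol = 1e-6, rtol = 1e-6) {
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing with at least two points")
  }
  if (t_grid[1] != 0) stop("t_grid must start at 0 (inoculation)")
  ic <- ic[state_names()]
  if (anyNA(ic)) stop("initial condition must name all of ",
                      paste(state_names(), collapse = ", "))
  parms <- .ferm_parms_vector(p, cfg, feed, opts)
  meth <- if (identical(method, "rk78dp")) deSolve::rkMethod("rk78dp") else method
  sol <- try(deSolve::ode(
    y = ic, times = t_grid, parms = parms,
    func = "hybridferm_derivs", initfunc = "hybridferm_initparms",
    dllname = "hybridferm", method = meth, atol = atol, rtol = rtol
  ), silent = TRUE)
  ok <- !inherits(sol, "try-error") && nrow(sol) == length(t_grid) &&
    !anyNA(sol)
  if (!ok) {
    last_t <- if (inherits(sol, "try-error")) NA_real_ else
      max(sol[stats::complete.cases(sol), 1])
    stop("ODE integration failed (last successful time: ", last_t, " h)")
  }
  conc <- sol[, 2:7, drop = FALSE]
  if (any(conc < -1e-3)) {
    warning("solver produced concentrations below -1e-3 g/L; clamped to 0")
  }
  conc <- pmax(conc, 0)
  out <- tibble::tibble(
    time_h = sol[, 1],
    biomass = conc[, 1], glucose = conc[, 2], fructose = conc[, 3],
    sucrose = conc[, 4], urea = conc[, 5], ethanol = conc[, 6],
    volume = sol[, 8]
  )
  # first row is the supplied initial condition exactly
  out[1, 2:8] <- as.list(unname(ic))
  structure(out, class = c("ferm_trajectory", class(out)),
            method = if (is.character(method)) method else "custom",
            atol = atol, rtol = rtol, success = TRUE)
}

#' Write / read a trajectory CSV
#'
#' Plain CSV with the shared column convention
#' `time_h,biomass,glucose,fructose,sucrose,urea,ethanol,volume`.
#'
#' @param traj a `ferm_trajectory` (or any data frame with the columns).
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a tibble.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
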