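test_that("specific rates follow Monod kinetics with ethanol inhibition", {
  p <- default_params()
  # no substrates, no ethanol: everything zero
  st0 <- state_vector(X = 1, G = 0, R = 0, S = 0, U = 0, Et = 0)
  mu0 <- specific_rates(st0, p)
  expect_equal(mu0$mu_X, 0)
  # saturating glucose, no ethanol: mu_G -> mu_max_G
  st_sat <- state_vector(X = 1, G = 1000 * p[["K_G"]], R = 0, S = 0, U = 0)
  expect_equal(specific_rates(st_sat, p)$mu_G, p[["mu_max_G"]],
               tolerance = 1.1e-3)
  # half-saturation in G and in the ethanol inhibition simultaneously
  st_half <- state_vector(X = 1, G = p[["K_G"]], R = 0, S = 0, U = 0,
                          Et = p[["K_i_Et"]])
  expect_equal(specific_rates(st_half, p)$mu_G,
               0.149 * 0.5 * 0.5, tolerance = 1e-12)
  # ethanol consumption inhibited by fermentable monosaccharides (AF = G+R)
  st_et <- state_vector(X = 1, G = 0, R = 0, S = 0, U = 0, Et = 5)
  st_et_af <- state_vector(X = 1, G = 5, R = 5, S = 0, U = 0, Et = 5)
  mu_et_free <- specific_rates(st_et, p)$mu_Et
  mu_et_inh <- specific_rates(st_et_af, p)$mu_Et
  expect_equal(mu_et_inh / mu_et_free,
               p[["K_inh_AF"]] / (p[["K_inh_AF"]] + 10))
  expect_lt(mu_et_inh, 0.05 * mu_et_free)
})

test_that("reaction rates reproduce hand-evaluated sucrose kinetics", {
  p <- default_params()
  st <- test_ic()
  r <- reaction_rates(st, p)
  # alpha_S * S/(S + K_S) * X with the shifted-run initial condition
  expect_equal(r$r_S, 7.645 * 39.6 / (39.6 + 29.935) * 1.2,
               tolerance = 1e-12)
  expect_equal(r$r_S, 5.2246, tolerance = 1e-4)
  # hydrolysis feeds both monosaccharide pools equally
  expect_identical(r$r_gG, r$r_gR)
  expect_equal(r$r_gG, r$r_S * 0.520)
  expect_equal(r$r_gG, 2.7168, tolerance = 1e-4)
})

test_that("all rates vanish (up to gate leak) when the culture is empty", {
  p <- default_params()
  st <- state_vector(X = 1, G = 0, R = 0, S = 0, U = 0, Et = 0)
  r <- reaction_rates(st, p)
  for (nm in c("r_X", "r_G", "r_R", "r_S", "r_gG", "r_gR", "r_Ur",
               "r_Et", "r_Et_c")) {
    expect_lt(abs(r[[nm]]), 1e-5, label = nm)
  }
  # consumption rates are clamped exactly to zero at c <= 0
  expect_identical(r$r_G, 0)
  expect_identical(r$r_S, 0)
  expect_identical(r$r_Ur, 0)
  expect_identical(r$r_Et_c, 0)
})

test_that("mass-balance RHS matches the rate laws in batch mode", {
  p <- default_params()
  st <- test_ic()
  d <- fermentation_rhs(0, st, p)
  r <- reaction_rates(st, p)
  expect_equal(d[["X"]], r$r_X)
  expect_equal(d[["G"]], r$r_gG - r$r_G)
  expect_equal(d[["R"]], r$r_gR - r$r_R)
  expect_equal(d[["S"]], -r$r_S)
  expect_equal(d[["U"]], -r$r_Ur)
  expect_equal(d[["Et"]], r$r_Et - r$r_Et_c)
  expect_equal(d[["V"]], 0)
  # sucrose depletion rate from the worked example above
  expect_equal(d[["S"]], -5.2246, tolerance = 1e-4)
  # empty culture: zero vector
  st0 <- state_vector(X = 0, G = 0, R = 0, S = 0, U = 0, Et = 0)
  expect_true(all(abs(fermentation_rhs(0, st0, p)) == 0))
  # glucose below threshold: dG/dt reduces to the hydrolysis inflow
  st_g0 <- state_vector(X = 1, G = 0, R = 10, S = 20, U = 1, Et = 0)
  r_g0 <- reaction_rates(st_g0, p)
  d_g0 <- fermentation_rhs(0, st_g0, p)
  expect_equal(d_g0[["G"]], r_g0$r_gG)
  expect_error(fermentation_rhs(0, c(st[1:6], V = -1), p), "volume")
})

test_that("compiled RHS mirrors the reference R implementation", {
  p <- default_params()
  parms <- hybridferm:::.ferm_parms_vector(p)
  withr::with_seed(99, {
    for (i in 1:25) {
      st <- state_vector(X = runif(1, 0, 10), G = runif(1, 0, 40),
                         R = runif(1, 0, 40), S = runif(1, 0, 50),
                         U = runif(1, 0, 3), Et = runif(1, 0, 25),
                         V = 0.4)
      expect_equal(unname(hybridferm:::.ferm_rhs_c(st, parms)$dy),
                   unname(fermentation_rhs(0, st, p)), tolerance = 1e-12)
    }
  })
  # model structure flags propagate identically
  opts <- model_options(fructose_ethanol_yield_denominator = "R",
                        ethanol_production_gate = "G+R")
  parms2 <- hybridferm:::.ferm_parms_vector(p, opts = opts)
  st <- test_ic()
  expect_equal(unname(hybridferm:::.ferm_rhs_c(st, parms2)$dy),
               unname(fermentation_rhs(0, st, p, opts = opts)),
               tolerance = 1e-12)
})

test_that("simulated batch culture shows the expected two-phase dynamics", {
  traj <- simulate_fermentation(test_ic(), t_grid = seq(0, 50, by = 0.5))
  # first state equals the initial condition exactly
  expect_identical(unname(unlist(traj[1, 2:8])), unname(test_ic()))
  # all concentrations non-negative
  expect_true(all(as.matrix(traj[, 2:7]) >= 0))
  # sugars monotonically depleted below 0.01 g/L and stay there
  late <- traj$time_h >= 40
  expect_true(all(traj$sucrose[late] < 0.01))
  expect_true(all(traj$glucose[late] < 0.01))
  expect_true(all(traj$fructose[late] < 0.01))
  expect_true(all(diff(traj$sucrose) <= 1e-8))
  # ethanol rises then falls (unimodal up to solver tolerance)
  pk <- which.max(traj$ethanol)
  expect_gt(traj$ethanol[pk], 5)
  expect_true(all(diff(traj$ethanol[1:pk]) > -1e-4))
  expect_true(all(diff(traj$ethanol[pk:nrow(traj)]) < 1e-4))
  # biomass grows in both phases
  expect_true(all(diff(traj$biomass) > -1e-6))
})

test_that("zero-inoculum and constant trajectories are preserved", {
  ic <- state_vector(X = 0, G = 10, R = 10, S = 10, U = 1, Et = 0)
  traj <- simulate_fermentation(ic, t_grid = seq(0, 10, by = 1))
  for (ch in c("glucose", "fructose", "sucrose", "urea", "ethanol")) {
    expect_equal(diff(range(traj[[ch]])), 0, tolerance = 1e-9)
  }
})

test_that("solution is converged with respect to the solver tolerance", {
  # gate crossings amplify tolerance differences; the default 1e-6 run
  # is accurate to ~1e-3 g/L against a tight reference, and a 1e-8 run
  # to better than 1e-4 g/L
  tg <- seq(0, 50, by = 2)
  ref <- simulate_fermentation(test_ic(), t_grid = tg,
                               atol = 1e-9, rtol = 1e-9)
  t6 <- simulate_fermentation(test_ic(), t_grid = tg)
  t8 <- simulate_fermentation(test_ic(), t_grid = tg,
                              atol = 1e-8, rtol = 1e-8)
  expect_lt(max(abs(as.matrix(t6[, 2:7]) - as.matrix(ref[, 2:7]))), 5e-3)
  expect_lt(max(abs(as.matrix(t8[, 2:7]) - as.matrix(ref[, 2:7]))), 1e-4)
})

test_that("adaptive solver agrees with an independent fixed-step RK4", {
  p <- default_params()
  parms <- hybridferm:::.ferm_parms_vector(p)
  f <- function(y) hybridferm:::.ferm_rhs_c(y, parms)$dy
  h <- 1e-3
  y <- test_ic()
  keep <- list(y)
  for (i in seq_len(10 / h)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i %% (2 / h) == 0) keep <- c(keep, list(y))
  }
  rk4 <- do.call(rbind, keep)
  traj <- simulate_fermentation(test_ic(), t_grid = seq(0, 10, by = 2))
  expect_lt(max(abs(as.matrix(traj[, 2:8]) - rk4)), 1e-4)
})

test_that("simulate validates its time grid and initial state", {
  expect_error(simulate_fermentation(test_ic(), t_grid = c(1, 2)),
               "start at 0")
  expect_error(simulate_fermentation(test_ic(), t_grid = c(0, 2, 2)),
               "strictly increasing")
  expect_error(simulate_fermentation(c(X = 1), t_grid = c(0, 1)), "name")
})

test_that("trajectory CSV round-trips through the shared column format", {
  traj <- simulate_fermentation(test_ic(), t_grid = seq(0, 6, by = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- read_trajectory_csv(path)
  expect_named(back, c("time_h", "biomass", "glucose", "fructose",
                       "sucrose", "urea", "ethanol", "volume"))
  expect_equal(as.data.frame(back), as.data.frame(traj),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("model configuration YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ferm_config(path, params = kinetic_params(mu_max_G = 0.2),
                    gating = gating_config(gamma = 0.02))
  cfg <- read_ferm_config(path)
  expect_equal(cfg$params[["mu_max_G"]], 0.2)
  expect_equal(cfg$gating$gamma, 0.02)
  expect_equal(cfg$solver$atol, 1e-6)
})
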