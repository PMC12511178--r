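test_that("forward sensitivities start at zero and flag absent parameters", {
  sens <- forward_sensitivities(default_params(), test_ic(),
                                t_grid = seq(0, 6, by = 2),
                                parameters = c("alpha_S", "Y_Et_R"))
  # initial conditions are parameter-independent
  expect_true(all(sens$sens[1, , ] == 0))
  # under the as-printed rate laws Y_Et_R never enters the RHS
  expect_true(all(abs(sens$sens[, , "Y_Et_R"]) < 1e-10))
  expect_true(any(abs(sens$sens[, , "alpha_S"]) > 1e-3))
})

test_that("forward sensitivities match trajectory finite differences", {
  p <- default_params()
  tg <- seq(0, 10, by = 2.5)
  sens <- forward_sensitivities(p, test_ic(), t_grid = tg)
  for (nm in c("mu_max_G", "alpha_S", "K_S", "Y_X_Ur")) {
    h <- 1e-5 * p[[nm]]
    pp <- kinetic_params(.values = p); pp[nm] <- p[[nm]] + h
    pm <- kinetic_params(.values = p); pm[nm] <- p[[nm]] - h
    tp <- simulate_fermentation(test_ic(), pp, t_grid = tg,
                                atol = 1e-10, rtol = 1e-10)
    tm <- simulate_fermentation(test_ic(), pm, t_grid = tg,
                                atol = 1e-10, rtol = 1e-10)
    fd <- (as.matrix(tp[, 2:7]) - as.matrix(tm[, 2:7])) / (2 * h)
    rel <- max(abs(fd - sens$sens[, , nm])) / max(abs(fd))
    expect_lt(rel, 1e-3)
  }
})

test_that("identifiability metrics reproduce the CI and t-value conventions", {
  # synthetic single-parameter sensitivity scaled so that the relative
  # sd equals 19.68%: CI must come out as estimate +/- 1 sigma
  theta <- 29.935
  p <- kinetic_params(K_S = theta)
  n_t <- 8
  sens_val <- matrix(0.02, n_t, 1)   # arbitrary nonzero sensitivity
  fake <- structure(list(
    times = seq_len(n_t), states = matrix(1, n_t, 7,
                                          dimnames = list(NULL, state_names())),
    sens = array(sens_val / theta,
                 dim = c(n_t, 6, 1),
                 dimnames = list(NULL,
                                 c("biomass", "glucose", "fructose",
                                   "sucrose", "urea", "ethanol"), "K_S")),
    parameters = "K_S", params = p), class = "ferm_sensitivity")
  # scaled sensitivity entries all equal 0.02 -> S'S = 48 * 4e-4
  StS <- 6 * n_t * 0.02^2
  s2 <- 0.1968^2 * StS
  rep <- pra_metrics(fake, residual_variance = s2,
                     norms = stats::setNames(rep(1, 6),
                                             c("biomass", "glucose",
                                               "fructose", "sucrose",
                                               "urea", "ethanol")))
  expect_equal(rep$table$pct_sd, 19.68, tolerance = 1e-6)
  expect_equal(rep$table$ci_lower, 24.043, tolerance = 1e-3)
  expect_equal(rep$table$ci_upper, 35.826, tolerance = 1e-3)
  # t-value is the inverse relative sd: 1/0.1968 ~ 5.08 > 2
  expect_equal(rep$table$t_value, 1 / 0.1968, tolerance = 1e-6)
  expect_identical(rep$table$classification, "significant")
  # the published mu_max_G row convention: %sd 1.83 -> t ~ 54.6
  expect_equal(1 / 0.0183, 54.6, tolerance = 1e-2)
})

test_that("perfectly confounded parameters are flagged non-identifiable", {
  # two parameters whose sensitivity columns are proportional (theta1 *
  # theta2 observed only through their product)
  n_t <- 10
  base <- sin(seq(0, 3, length.out = n_t))
  p <- kinetic_params(alpha_S = 2, K_S = 3)
  sens <- array(0, dim = c(n_t, 6, 2),
                dimnames = list(NULL, c("biomass", "glucose", "fructose",
                                        "sucrose", "urea", "ethanol"),
                                c("alpha_S", "K_S")))
  sens[, 1, 1] <- base * 3 / 2   # dx/dt1 = t2 * base/...
  sens[, 1, 2] <- base
  fake <- structure(list(times = seq_len(n_t),
                         states = matrix(1, n_t, 7,
                                         dimnames = list(NULL, state_names())),
                         sens = sens, parameters = c("alpha_S", "K_S"),
                         params = p), class = "ferm_sensitivity")
  rep <- suppressWarnings(pra_metrics(fake, residual_variance = 0.01))
  expect_equal(abs(rep$correlation["alpha_S", "K_S"]), 1, tolerance = 1e-6)
  expect_true(all(rep$table$classification %in%
                    c("non-identifiable", "non-significant")))
})

test_that("correlation matrix is a valid correlation matrix", {
  sens <- forward_sensitivities(default_params(), test_ic(),
                                t_grid = seq(0, 20, by = 4),
                                parameters = c("mu_max_G", "alpha_S",
                                               "K_S", "Y_X_Ur", "Y_Et_X"))
  rep <- pra_metrics(sens, residual_variance = 1e-4)
  K <- rep$correlation
  expect_equal(K, t(K))
  expect_equal(unname(diag(K)), rep(1, 5))
  expect_true(all(K >= -1 - 1e-9 & K <= 1 + 1e-9))
})

test_that("noiseless single-parameter fit is sharply identifiable", {
  ds <- noiseless_dataset(seed = 41, horizon = 30)
  fix <- sequential_fixing(default_params(), list(ds),
                           free = c("alpha_S", "mu_max_G", "Y_X_Ur"))
  # residual variance ~ 0 on noiseless data at truth: t -> large
  tab <- fix$report$table
  expect_true(all(tab$t_value > 100))
  expect_identical(sort(fix$free), sort(c("alpha_S", "mu_max_G", "Y_X_Ur")))
  expect_length(fix$fixed$non_significant, 0)
})

test_that("strong-excitation screening keeps the core kinetic parameters", {
  opts <- model_options(fructose_ethanol_yield_denominator = "R")
  ds1 <- noiseless_dataset(seed = 42, opts = opts)
  # moderate noise so the residual variance is realistic
  ds1n <- generate_experiment(default_params(), role = "train",
                              noise = noise_model(0.03, 0.01),
                              sched = sampling_schedule(),
                              rng_seed = 43, opts = opts)
  fix <- sequential_fixing(default_params(), list(ds1n),
                           free = c("mu_max_G", "alpha_S", "K_S",
                                    "Y_X_Ur", "Y_Et_X", "K_R_postG"),
                           opts = opts)
  expect_true(all(c("mu_max_G", "alpha_S", "Y_X_Ur") %in% fix$free))
  # uptake rate and its half-saturation constant are confounded in a
  # single batch run: at most one of the pair survives stage 2
  expect_lte(sum(c("alpha_S", "K_S") %in% fix$free), 1)
  # the post-glucose affinity constant at ~7e-9 g/L cannot matter
  expect_false("K_R_postG" %in% fix$free)
  expect_true("K_R_postG" %in% fix$fixed$non_significant)
  expect_error(sequential_fixing(default_params(), list(ds1n),
                                 free = "K_R_postG", opts = opts),
               "no free parameters")
})

test_that("Monte Carlo bands contain the nominal trajectory", {
  bands <- monte_carlo_bands(default_params(), test_ic(),
                             t_grid = seq(0, 36, by = 3),
                             rel_sd = 0.05, n = 20, rng_seed = 3)
  expect_true(all(bands$lower <= bands$nominal + 1e-9))
  expect_true(all(bands$upper >= bands$nominal - 1e-9))
  expect_gte(attr(bands, "n_effective"), 16)
})

test_that("bands collapse at zero spread and widen with it", {
  tg <- seq(0, 24, by = 6)
  b0 <- monte_carlo_bands(default_params(), test_ic(), t_grid = tg,
                          rel_sd = 0, n = 5, rng_seed = 2)
  expect_equal(b0$lower, b0$nominal, tolerance = 1e-12)
  expect_equal(b0$upper, b0$nominal, tolerance = 1e-12)
  widths <- vapply(c(0.01, 0.05, 0.10), function(sd) {
    b <- monte_carlo_bands(default_params(), test_ic(), t_grid = tg,
                           rel_sd = sd, n = 25, rng_seed = 7)
    mean(b$upper - b$lower)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("monte_carlo_bands is deterministic per seed", {
  tg <- seq(0, 12, by = 6)
  a <- monte_carlo_bands(default_params(), test_ic(), t_grid = tg,
                         rel_sd = 0.05, n = 8, rng_seed = 5)
  b <- monte_carlo_bands(default_params(), test_ic(), t_grid = tg,
                         rel_sd = 0.05, n = 8, rng_seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
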