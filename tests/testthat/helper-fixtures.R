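# Shared fixtures: kept tiny so the default run stays fast.

test_ic <- function() {
  state_vector(X = 1.2, G = 27.5, R = 25.8, S = 39.6, U = 2.3)
}

# short noiseless dataset on a coarse schedule
noiseless_dataset <- function(p = default_params(), seed = 101,
                              role = "train", horizon = 36,
                              opts = model_options()) {
  generate_experiment(p, role = role, noise = noise_model(0, 0),
                      sched = sampling_schedule(dense_range = c(2, 3),
                                                dense_end = 24,
                                                sparse_interval = 6,
                                                horizon = horizon),
                      rng_seed = seed, opts = opts)
}

# small scaled residual matrix with temporal structure (AR(1) channels)
ar1_matrix <- function(n = 60, m = 3, rho = 0.9, sd = 0.01, seed = 3) {
  withr::with_seed(seed, {
    r <- matrix(0, n, m)
    for (i in 2:n) r[i, ] <- rho * r[i - 1, ] + stats::rnorm(m, 0, sd)
    r
  })
}
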