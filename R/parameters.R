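#' Kinetic parameters of the mixed-sugar fermentation model
#'
#' Constructs the full 22-parameter set of the six-state kinetic model.
#' Defaults are the calibrated estimates shipped with the package
#' (see [default_params()]); any subset can be overridden by name.
#'
#' Units: maximum specific rates and maintenance coefficients in g/(g h),
#' half-saturation and inhibition constants in g/L, yields in g/g.
#'
#' @param ... named scalar overrides, e.g. `mu_max_G = 0.2`.
#' @param .values optional named numeric vector/list used as the base set
#'   instead of the calibrated defaults.
#' @return A named numeric vector of length 22 with class `ferm_params`.
#' @export
#' @examples
#' p <- kinetic_params(mu_max_G = 0.2)
#' p[["mu_max_G"]]
kinetic_params <- function(..., .values = NULL) {
  base <- if (is.null(.values)) .default_estimates else unlist(.values)
  base <- base[param_names()]
  if (anyNA(base)) {
    stop("missing kinetic parameters: ",
         paste(param_names()[is.na(base)], collapse = ", "))
  }
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), param_names())
    if (length(bad)) stop("unknown kinetic parameters: ",
                          paste(bad, collapse = ", "))
    base[names(over)] <- unlist(over)
  }
  if (any(!is.finite(base))) stop("kinetic parameters must be finite")
  structure(base, class = "ferm_params")
}

#' @export
print.ferm_params <- function(x, ...) {
  cat("<ferm_params> 22 kinetic parameters\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Canonical parameter order
#'
#' Names of the 22 kinetic parameters, in the fixed order used throughout
#' the package (calibration vectors, sensitivity columns, bounds tables).
#'
#' @return Character vector of length 22.
#' @export
param_names <- function() names(.default_estimates)

# Calibrated estimates used as package defaults (growth rates and
# maintenance in g/(g h), K's in g/L, yields in g/g).
.default_estimates <- c(
  mu_max_Et    = 0.007,
  mu_max_G     = 0.149,
  mu_max_R     = 0.011,
  mu_max_postG = 0.047,
  m_G          = 0.037,
  m_R          = 0.128,
  alpha_S      = 7.645,
  K_G          = 0.035,
  K_R          = 1.666,
  K_R_postG    = 6.768e-09,
  K_S          = 29.935,
  K_Et         = 0.092,
  K_i_Et       = 7.920,
  K_inh_AF     = 0.203,
  Y_AF_S       = 0.520,
  Y_Et_G       = 0.451,
  Y_Et_R       = 0.740,
  Y_Et_X       = 3.126,
  Y_cEt_X      = 10.907,
  Y_G_X        = 5.417,
  Y_R_X        = 7.488,
  Y_X_Ur       = 2.794
)

# Literature-style starting values used to seed calibration.
.default_initial_values <- c(
  mu_max_Et    = 0.090,
  mu_max_G     = 0.098,
  mu_max_R     = 0.096,
  mu_max_postG = 0.265,
  m_G          = 0.047,
  m_R          = 0.057,
  alpha_S      = 11.815,
  K_G          = 0.057,
  K_R          = 10.548,
  K_R_postG    = 0.001,
  K_S          = 38.983,
  K_Et         = 0.108,
  K_i_Et       = 12.836,
  K_inh_AF     = 0.186,
  Y_AF_S       = 0.563,
  Y_Et_G       = 0.891,
  Y_Et_R       = 0.900,
  Y_Et_X       = 5.409,
  Y_cEt_X      = 5.603,
  Y_G_X        = 5.000,
  Y_R_X        = 3.000,
  Y_X_Ur       = 3.590
)

# Parameters retained as free after identifiability screening of the
# calibrated model (the "significant" set).
.significant_params <- c(
  "mu_max_G", "m_R", "alpha_S", "K_inh_AF", "K_i_Et", "K_G", "K_S",
  "Y_AF_S", "Y_Et_G", "Y_Et_R", "Y_Et_X", "Y_X_Ur",
  # significant but mutually involved in ethanol turnover
  "mu_max_Et", "Y_cEt_X"
)

#' Calibrated default parameter set
#'
#' The calibrated estimate for each kinetic parameter, shipped as the
#' package default (used by [kinetic_params()] when no override is given).
#'
#' @return `ferm_params` vector.
#' @export
default_params <- function() kinetic_params()

#' Literature-based starting values for calibration
#'
#' @return `ferm_params` vector of the pre-calibration initial guesses.
#' @export
initial_params <- function() kinetic_params(.values = .default_initial_values)

#' Names of the parameters classified significant by identifiability
#' screening of the calibrated model
#'
#' @return Character vector (14 names).
#' @export
significant_param_names <- function() .significant_params

#' Literature-based parameter bounds
#'
#' Lower/upper bounds for every kinetic parameter, with a provenance tag:
#' `"literature"` for ranges taken from prior yeast-culture studies,
#' `"this-work"` for ranges derived from the experimental design, `"NA"`
#' where no prior information existed.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`, `source`.
#' @export
param_bounds <- function() {
  tibble::tribble(
    ~parameter,     ~lower, ~upper, ~source,
    "mu_max_Et",    0.1,    0.3,    "literature",
    "mu_max_G",     0.1,    0.5,    "literature",
    "mu_max_R",     0.05,   0.5,    "literature",
    "mu_max_postG", 0.04,   1.5,    "NA",
    "m_G",          0.01,   0.09,   "literature",
    "m_R",          0.01,   0.09,   "literature",
    "alpha_S",      4,      30,     "this-work",
    "K_G",          0.001,  0.5,    "literature",
    "K_R",          0.001,  0.5,    "literature",
    "K_R_postG",    0,      0.5,    "NA",
    "K_S",          0.1,    20,     "NA",
    "K_Et",         0.01,   0.15,   "literature",
    "K_i_Et",       15,     30,     "literature",
    "K_inh_AF",     0.01,   0.2,    "this-work",
    "Y_AF_S",       0.4,    0.6,    "literature",
    "Y_Et_G",       0.3,    0.8,    "literature",
    "Y_Et_R",       0.3,    0.8,    "literature",
    "Y_Et_X",       10,     20,     "literature",
    "Y_cEt_X",      5,      50,     "this-work",
    "Y_G_X",        10,     50,     "literature",
    "Y_R_X",        10,     50,     "literature",
    "Y_X_Ur",       3,      5,      "literature"
  )
}

#' Smooth gating configuration
#'
#' The depletion/appearance switches in the rate laws use a leaky-ReLU
#' style gate normalized by its own argument,
#' `max(gamma * z, z) / sqrt(z^2 + epsilon)`, which runs continuously
#' between ~0 and 1. `threshold` (g/L) is the concentration at which a
#' pool is considered depleted; `gamma` is the small leak slope below the
#' threshold; `epsilon` ((g/L)^2) smooths the normalization. `epsilon`
#' must be well below `threshold^2` for the gate to be ~1 one threshold
#' width above the switch point.
#'
#' @param gamma leak slope, 0 < gamma < 1.
#' @param epsilon smoothing constant, (g/L)^2, > 0.
#' @param threshold depletion threshold, g/L.
#' @return Named list with class `gating_config`.
#' @export
gating_config <- function(gamma = 0.01, epsilon = 1e-6, threshold = 0.001) {
  stopifnot(gamma > 0, gamma < 1, epsilon > 0, threshold >= 0)
  structure(list(gamma = gamma, epsilon = epsilon, threshold = threshold),
            class = "gating_config")
}

#' Feed inputs (batch by default)
#'
#' Volumetric feed and feed concentrations for the mass balances. All the
#' experiments modeled here are batch, so every field defaults to zero;
#' the fields are retained so the balances stay general.
#'
#' @param F_i feed flow, L/h. @param G_i,R_i,S_i,U_i feed concentrations, g/L.
#' @param dVdt volume change, L/h.
#' @return Named list with class `feed_inputs`.
#' @export
feed_inputs <- function(F_i = 0, G_i = 0, R_i = 0, S_i = 0, U_i = 0,
                        dVdt = 0) {
  structure(list(F_i = F_i, G_i = G_i, R_i = R_i, S_i = S_i, U_i = U_i,
                 dVdt = dVdt),
            class = "feed_inputs")
}

#' Model structure options
#'
#' Two rate-law details admit alternate readings; both are exposed here.
#' `fructose_ethanol_yield_denominator`: the ethanol-linked term of the
#' fructose consumption rate divides by the glucose ethanol yield
#' (`"G"`, the default) or the fructose one (`"R"`).
#' `ethanol_production_gate`: ethanol production switches off when
#' fructose is depleted (`"R"`, the default) or when both monosaccharides
#' are (`"G+R"`).
#'
#' @param fructose_ethanol_yield_denominator `"G"` or `"R"`.
#' @param ethanol_production_gate `"R"` or `"G+R"`.
#' @return Named list with class `model_options`.
#' @export
model_options <- function(fructose_ethanol_yield_denominator = c("G", "R"),
                          ethanol_production_gate = c("R", "G+R")) {
  structure(list(
    fructose_ethanol_yield_denominator =
      match.arg(fructose_ethanol_yield_denominator),
    ethanol_production_gate = match.arg(ethanol_production_gate)
  ), class = "model_options")
}

# Full 33-element parameter vector handed to the compiled RHS.
.ferm_parms_vector <- function(p, cfg = gating_config(),
                               feed = feed_inputs(),
                               opts = model_options()) {
  p <- kinetic_params(.values = p)
  c(unclass(p),
    gamma = cfg$gamma, epsilon = cfg$epsilon, threshold = cfg$threshold,
    F_i = feed$F_i, G_i = feed$G_i, R_i = feed$R_i, S_i = feed$S_i,
    U_i = feed$U_i, dVdt = feed$dVdt,
    flag_eth_den =
      as.numeric(opts$fructose_ethanol_yield_denominator == "R"),
    flag_eth_gate = as.numeric(opts$ethanol_production_gate == "G+R"))
}

#' State vector constructor
#'
#' @param X,G,R,S,U,Et concentrations in g/L (biomass, glucose, fructose,
#'   sucrose, urea, ethanol).
#' @param V culture volume, L.
#' @return Named numeric vector of length 7.
#' @export
state_vector <- function(X, G, R, S, U, Et = 0, V = 0.4) {
  st <- c(X = X, G = G, R = R, S = S, U = U, Et = Et, V = V)
  if (any(!is.finite(st))) stop("non-finite state")
  if (any(st[state_names()[1:6]] < -1e-9)) {
    stop("negative concentrations in state vector")
  }
  if (V <= 0) stop("culture volume must be positive")
  pmax(st, c(rep(0, 6), -Inf))
}

#' State variable names in canonical order
#' @return Character vector `c("X","G","R","S","U","Et","V")`.
#' @export
state_names <- function() c("X", "G", "R", "S", "U", "Et", "V")

# Concentration channels reported in datasets (volume excluded).
.channel_names <- c("biomass", "glucose", "fructose", "sucrose",
                    "urea", "ethanol")
.state_to_channel <- c(X = "biomass", G = "glucose", R = "fructose",
                       S = "sucrose", U = "urea", Et = "ethanol")

#' Read / write a model configuration file
#'
#' YAML round-trip of the full model configuration: kinetic parameters,
#' gating constants, solver settings and structure options.
#'
#' @param path file path.
#' @param params `ferm_params`. @param gating `gating_config`.
#' @param options `model_options`.
#' @param solver list of solver settings (method, atol, rtol).
#' @return `write_ferm_config()` returns `path` invisibly;
#'   `read_ferm_config()` returns a list with elements `params`,
#'   `gating`, `options`, `solver`.
#' @export
write_ferm_config <- function(path, params = default_params(),
                              gating = gating_config(),
                              options = model_options(),
                              solver = list(method = "rk78dp",
                                            atol = 1e-6, rtol = 1e-6)) {
  yaml::write_yaml(list(
    params = as.list(unclass(params)),
    gating = unclass(gating),
    options = unclass(options),
    solver = solver
  ), path)
  invisible(path)
}

#' @rdname write_ferm_config
#' @export
read_ferm_config <- function(path) {
  raw <- yaml::read_yaml(path)
  list(
    params = kinetic_params(.values = raw$params),
    gating = do.call(gating_config, raw$gating),
    options = do.call(model_options, raw$options),
    solver = raw$solver
  )
}
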