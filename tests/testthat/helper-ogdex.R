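# Shared fixtures, built in code and cached for the session.

MODEL_COV_NAMES <- c("snow_depth", "warmth_index", "slope_angle",
                     "positive_openness", "log10_catchment_area",
                     "solar_radiation")

# model_parameters-shaped list with chosen coefficients
toy_params <- function(beta0 = -3, beta1 = 0.02,
                       beta_lin = rep(0, 6), beta_quad = rep(0, 6),
                       period_eff = c(`1` = 0, `2` = 0)) {
  list(beta0 = beta0, beta1 = beta1,
       beta_lin = stats::setNames(beta_lin, MODEL_COV_NAMES),
       beta_quad = stats::setNames(beta_quad, MODEL_COV_NAMES),
       period_eff = period_eff, sigma_plot = 0.3, sigma_resid = 0.5)
}

zero_covs <- function() stats::setNames(rep(0, 6), MODEL_COV_NAMES)

.cache <- new.env(parent = emptyenv())

# Small but converged fit reused by prediction/mapping tests.
get_test_fit <- function() {
  if (is.null(.cache$fit)) {
    g <- generator_config(n_plots = 120, seed = 42)
    dat <- gen_plot_samples(g)
    cfg <- fit_config(n_chains = 2, burn_in = 300, iterations = 800,
                      max_extension_rounds = 2, seed = 42)
    .cache$samples <- dat
    .cache$fit <- fit_development_model(dat, "I_og", cfg)
  }
  .cache$fit
}

get_test_samples <- function() {
  get_test_fit()
  .cache$samples
}

# Uniform covariate raster stack (every cell = the given named values).
uniform_stack <- function(values, nr = 5, nc = 5, cell = 20) {
  lapply(as.list(values), function(v)
    raster_grid(matrix(v, nr, nc), cell))
}

# Raster stack whose cells are draws from the generator, reshaped.
covariate_stack <- function(n_side, seed, cell = 20) {
  g <- generator_config(seed = seed)
  covs <- prepare_covariates(gen_covariates(g, n = n_side^2, seed = seed))
  lapply(covs[MODEL_COV_NAMES], function(v)
    raster_grid(matrix(v, n_side, n_side), cell))
}
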