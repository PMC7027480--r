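#' Configuration of the synthetic inventory generator
#'
#' Describes the statistical structure of generated plot-sample data: number
#' of plots, measurement periods, covariate marginals and their correlation
#' (on the Gaussian-copula scale), the true development-model parameters,
#' and the stand-age distribution. Defaults reflect the study conditions the
#' analysis assumes: stand ages concentrated near 50 years, snow depth and
#' warmth index correlated at -0.57, positive openness and log10 catchment
#' area at -0.62 with all other pairs near zero, negative measurement bias
#' in periods 1 and 2, and logistic index trajectories that pass 0.5 near
#' age 100 and reach about 0.8 by age 150 at average covariates.
#'
#' @param n_plots number of plots (default 500; with 3 periods each, 1500
#'   plot samples).
#' @param periods measurement periods each plot is observed in (default
#'   `1:3`).
#' @param period_spacing years between consecutive periods (default 5).
#' @param age_meanlog,age_sdlog lognormal stand-age parameters at the first
#'   measured period (defaults `log(50)` and 0.5).
#' @param marginals named list per raw covariate: `list(dist, mean, sd)`
#'   with `dist` `"normal"` or `"log10normal"` (mean/sd then apply to
#'   log10 of the value, used for catchment area in m^2).
#' @param correlation 6 x 6 positive-definite latent correlation matrix in
#'   the order of `marginals`.
#' @param true_params list with `beta0`, `beta1`, named `beta_lin` and
#'   `beta_quad` (per model covariate, standardized scale), `period_eff`
#'   (periods 1 and 2), `sigma_plot`, `sigma_resid`.
#' @param seed RNG seed.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_plots = 500, periods = 1:3,
                             period_spacing = 5,
                             age_meanlog = log(50), age_sdlog = 0.5,
                             marginals = default_marginals(),
                             correlation = default_correlation(),
                             true_params = default_true_params(),
                             seed = 1) {
  stopifnot(n_plots >= 2, all(periods %in% 1:3),
            nrow(correlation) == length(marginals))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("correlation matrix is not positive-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3),
         "); project to the nearest PD matrix, e.g. with Matrix::nearPD")
  structure(list(n_plots = n_plots, periods = sort(unique(periods)),
                 period_spacing = period_spacing,
                 age_meanlog = age_meanlog, age_sdlog = age_sdlog,
                 marginals = marginals, correlation = correlation,
                 true_params = true_params, seed = seed),
            class = "generator_config")
}

#' Default covariate marginals of the generator
#'
#' Loose stand-ins for temperate mountain-forest conditions: snow depth in
#' cm, warmth index in degree-months (mostly inside the 45-180 screening
#' band), slope angle and positive openness in degrees, catchment area in
#' m^2 with log10 values around 3, and relative solar radiation around 1.
#'
#' @return named list of marginal specifications.
#' @export
default_marginals <- function() {
  list(snow_depth = list(dist = "normal", mean = 150, sd = 60),
       warmth_index = list(dist = "normal", mean = 100, sd = 22),
       slope_angle = list(dist = "normal", mean = 25, sd = 8),
       positive_openness = list(dist = "normal", mean = 90, sd = 8),
       catchment_area = list(dist = "log10normal", mean = 3, sd = 0.6),
       solar_radiation = list(dist = "normal", mean = 1, sd = 0.08))
}

#' Default latent correlation matrix of the generator
#'
#' Identity except corr(snow depth, warmth index) = -0.57 and
#' corr(positive openness, log10 catchment area) = -0.62.
#'
#' @return 6 x 6 correlation matrix.
#' @export
default_correlation <- function() {
  R <- diag(6)
  dimnames(R) <- list(RAW_COVS, RAW_COVS)
  R["snow_depth", "warmth_index"] <- R["warmth_index", "snow_depth"] <- -0.57
  R["positive_openness", "catchment_area"] <-
    R["catchment_area", "positive_openness"] <- -0.62
  R
}

#' Default true parameters of the generator
#'
#' On the standardized covariate scale. The signs follow the fitted
#' directions for the old-growth index (snow and catchment positive, warmth,
#' slope and radiation negative), the intercept and rate give a trajectory
#' reaching index 0.5 near age 103 and about 0.79 at age 150 at average
#' covariates, and periods 1-2 carry negative measurement bias.
#'
#' @return list of true model parameters.
#' @export
default_true_params <- function() {
  list(beta0 = -3, beta1 = 0.029,
       beta_lin = stats::setNames(
         c(0.006, -0.005, -0.004, 0.000, 0.006, -0.004), MODEL_COVS),
       beta_quad = stats::setNames(
         c(-0.002, -0.002, 0.000, -0.001, 0.001, 0.000), MODEL_COVS),
       period_eff = c(`1` = -0.6, `2` = -0.3),
       sigma_plot = 0.6, sigma_resid = 1.6)
}

#' Generate correlated environmental covariates
#'
#' Gaussian-copula draws: latent multivariate normal deviates with the
#' configured correlation matrix are pushed through each covariate's
#' marginal. Normal marginals preserve the latent Pearson correlation;
#' the catchment-area marginal is lognormal so its log10 transform (the
#' modeling scale) is normal and likewise preserves correlation.
#'
#' @param config a [generator_config()].
#' @param n number of rows (default `config$n_plots`).
#' @param seed seed; `NULL` continues the current RNG stream.
#' @return data frame of the 6 raw covariates, with a `pop_scaler`
#'   attribute holding the population mean/SD on the modeling scale.
#' @export
gen_covariates <- function(config, n = config$n_plots, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) set.seed(seed)
  R <- config$correlation
  Z <- matrix(stats::rnorm(n * nrow(R)), n) %*% chol(R)
  out <- data.frame(row.names = seq_len(n))
  center <- scale <- stats::setNames(numeric(length(MODEL_COVS)), MODEL_COVS)
  for (i in seq_along(config$marginals)) {
    nm <- names(config$marginals)[i]
    m <- config$marginals[[i]]
    v <- m$mean + m$sd * Z[, i]
    model_nm <- if (identical(m$dist, "log10normal")) {
      out[[nm]] <- 10^v
      paste0("log10_", nm)
    } else {
      out[[nm]] <- v
      nm
    }
    center[model_nm] <- m$mean
    scale[model_nm] <- m$sd
  }
  # physical floors; affect well under 1% of draws under the defaults
  out$snow_depth <- pmax(out$snow_depth, 0)
  out$slope_angle <- pmin(pmax(out$slope_angle, 0), 89)
  out$warmth_index <- pmax(out$warmth_index, 0)
  attr(out, "pop_scaler") <- standard_scaler(center, scale)
  out
}

#' Transform raw covariates to the modeling scale
#'
#' Replaces `catchment_area` (m^2) by `log10_catchment_area`; the other
#' five covariates are passed through.
#'
#' @param covariates data frame with the 6 raw covariate columns.
#' @return data frame with the 6 model covariate columns.
#' @export
prepare_covariates <- function(covariates) {
  stopifnot("catchment_area" %in% names(covariates))
  out <- covariates
  out$log10_catchment_area <- log10(out$catchment_area)
  out$catchment_area <- NULL
  out
}

#' Generate plot samples from the forward development model
#'
#' For each plot: correlated covariates, a normal random plot intercept, a
#' lognormal first-period stand age, and one sample per configured period
#' with ages advancing by the period spacing. Each sample's index is the
#' inverse-logit of the true linear predictor (intercept + development rate
#' times age + plot effect + period effect + residual), so responses lie
#' strictly inside (0, 1) and periods 1-2 are biased low as in older
#' surveys.
#'
#' @param config a [generator_config()].
#' @return data frame of plot samples (`plot_id`, `period`, `age`, the 6
#'   model covariates, `I_og`), with attributes `pop_scaler` (population
#'   covariate scaler) and `true_params`.
#' @export
gen_plot_samples <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_plots
  tp <- config$true_params
  cov_raw <- gen_covariates(config, n, seed = NULL)
  scaler <- attr(cov_raw, "pop_scaler")
  mc <- prepare_covariates(cov_raw)[MODEL_COVS]
  x <- as.matrix(standardize(mc, scaler)$data)
  coeff <- drop(tp$beta1 + x %*% tp$beta_lin[MODEL_COVS] +
                  x^2 %*% tp$beta_quad[MODEL_COVS])
  if (all(coeff <= 0))
    warning("all development rates are non-positive under this config; ",
            "t_0.5 is undefined everywhere")
  plot_eff <- stats::rnorm(n, 0, tp$sigma_plot)
  age1 <- pmax(1, round(stats::rlnorm(n, config$age_meanlog,
                                      config$age_sdlog)))
  periods <- config$periods
  parts <- vector("list", length(periods))
  for (k in seq_along(periods)) {
    p <- periods[k]
    age <- age1 + config$period_spacing * (k - 1)
    pe <- if (p %in% c(1, 2)) tp$period_eff[[as.character(p)]] else 0
    e <- stats::rnorm(n, 0, tp$sigma_resid)
    lin <- tp$beta0 + coeff * age + plot_eff + pe + e
    parts[[k]] <- data.frame(plot_id = sprintf("P%05d", seq_len(n)),
                             period = p, age = age, mc,
                             I_og = inv_logit(lin), row.names = NULL)
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$plot_id, out$period), ]
  rownames(out) <- NULL
  attr(out, "pop_scaler") <- scaler
  attr(out, "true_params") <- tp
  out
}

#' Generate a tree list matching a target stand structure
#'
#' Draws dbh values from a gamma distribution moment-matched to the target
#' mean and SD, truncated above the qualifying threshold, then adjusts the
#' upper tail so the large-tree count is hit exactly. Densities are exact
#' by construction; mean and SD match the target to within a few percent
#' for realistic targets.
#'
#' @param target named list or one-row data frame with `mean_dbh`, `sd_dbh`,
#'   `tree_density`, `large_tree_density`.
#' @param plot_area plot area in ha (default 0.1).
#' @param seed RNG seed.
#' @param plot_id,period identifiers written into the records.
#' @param min_dbh,large_dbh thresholds in cm (defaults 5 strict, 40
#'   inclusive).
#' @return data frame of tree records (`plot_id`, `period`, `dbh`,
#'   `status`), all live.
#' @export
gen_tree_list <- function(target, plot_area = 0.1, seed = 1,
                          plot_id = "P00001", period = 3,
                          min_dbh = 5, large_dbh = 40) {
  if (is.data.frame(target)) target <- as.list(target[1, ])
  m <- target$mean_dbh; s <- target$sd_dbh
  n <- round(target$tree_density * plot_area)
  nl <- round(target$large_tree_density * plot_area)
  if (is.na(m) || is.na(s) || s < 0 || nl > n || (n > 0 && m <= min_dbh))
    stop("infeasible target stand structure")
  set.seed(seed)
  if (n == 0)
    return(data.frame(plot_id = character(0), period = integer(0),
                      dbh = numeric(0), status = character(0)))
  if (s == 0) {
    d <- rep(m, n)
    if (nl != sum(d >= large_dbh))
      stop("infeasible target: SD 0 cannot hit the large-tree count")
  } else {
    shape <- (m / s)^2
    rate <- m / s^2
    d <- numeric(0)
    while (length(d) < n) {
      cand <- stats::rgamma(2 * n + 20, shape, rate)
      d <- c(d, cand[cand > min_dbh])
    }
    d <- d[seq_len(n)]
    d <- sort(d, decreasing = TRUE)
    if (nl > 0)
      d[seq_len(nl)] <- pmax(d[seq_len(nl)],
                             large_dbh + stats::runif(nl, 0, 2))
    if (n > nl) {
      rest <- (nl + 1):n
      over <- rest[d[rest] >= large_dbh]
      d[over] <- large_dbh - stats::runif(length(over), 0.1, 2)
    }
  }
  data.frame(plot_id = plot_id, period = period, dbh = d, status = "live")
}

#' Generate a synthetic DEM
#'
#' Three fixture families with known terrain properties: an inclined
#' `plane` (exact analytic slope), a `valley` (a V with a north-south axis
#' whose axis cells have reduced openness), and `random_smooth`
#' (band-limited noise from repeated 3 x 3 smoothing of white noise).
#'
#' @param kind `"plane"`, `"valley"` or `"random_smooth"`.
#' @param shape integer length 2, rows x cols (at least 5 x 5).
#' @param cell_size cell size in metres (default 20).
#' @param seed RNG seed (used by `random_smooth`).
#' @param gradient length-2 plane gradient (dz/dx east, dz/dy north).
#' @param valley_slope side slope of the V (dz per metre).
#' @param amplitude SD in metres of the smoothed noise field.
#' @param smooth_passes number of 3 x 3 smoothing passes.
#' @return a `raster_grid`.
#' @export
gen_dem <- function(kind = c("plane", "valley", "random_smooth"),
                    shape = c(20, 20), cell_size = 20, seed = 1,
                    gradient = c(0.1, 0), valley_slope = 0.2,
                    amplitude = 10, smooth_passes = 4) {
  kind <- match.arg(kind)
  if (length(shape) != 2 || any(shape < 5))
    stop("shape must be at least 5 x 5")
  nr <- shape[1]; nc <- shape[2]
  xs <- (seq_len(nc) - 0.5) * cell_size
  ys <- (nr - seq_len(nr) + 0.5) * cell_size   # row 1 = north
  z <- switch(kind,
    plane = outer(ys, xs, function(y, x) gradient[1] * x + gradient[2] * y),
    valley = {
      xc <- mean(range(xs))
      outer(ys, xs, function(y, x) valley_slope * abs(x - xc))
    },
    random_smooth = {
      set.seed(seed)
      m <- matrix(stats::rnorm(nr * nc), nr, nc)
      for (i in seq_len(smooth_passes)) {
        acc <- matrix(0, nr, nc)
        for (dr in -1:1) for (dc in -1:1)
          acc <- acc + shift_rep(m, dr, dc)
        m <- acc / 9
      }
      m * amplitude / stats::sd(m)
    })
  raster_grid(z, cell_size)
}
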