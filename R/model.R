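#' Standardize covariates
#'
#' Centers and scales each covariate column to mean 0, SD 1, either fitting
#' a new scaler from the data or applying a stored one (for prediction, new
#' data standardized with a stored scaler need not have mean 0).
#'
#' @param x data frame of numeric covariate columns.
#' @param scaler optional `standard_scaler` fitted earlier.
#' @return list with `data` (standardized data frame) and `scaler`.
#' @export
standardize <- function(x, scaler = NULL) {
  stopifnot(is.data.frame(x))
  if (is.null(scaler)) {
    center <- vapply(x, mean, numeric(1))
    scale <- vapply(x, stats::sd, numeric(1))
    if (any(!is.finite(scale) | scale == 0))
      stop("zero-variance covariate(s): ",
           paste(names(x)[!is.finite(scale) | scale == 0], collapse = ", "))
    scaler <- standard_scaler(center, scale)
  }
  stopifnot(inherits(scaler, "standard_scaler"))
  miss <- setdiff(names(scaler$center), names(x))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  vars <- names(scaler$center)
  out <- x
  for (v in vars) out[[v]] <- (x[[v]] - scaler$center[[v]]) / scaler$scale[[v]]
  list(data = out, scaler = scaler)
}

#' Construct a covariate scaler
#'
#' @param center,scale named numeric vectors of per-covariate means and SDs.
#' @return a `standard_scaler` object.
#' @export
standard_scaler <- function(center, scale) {
  stopifnot(length(center) == length(scale), !is.null(names(center)),
            all(scale > 0))
  names(scale) <- names(center)
  structure(list(center = center, scale = scale), class = "standard_scaler")
}

#' Fixed-effect design matrix of the varying-slope model
#'
#' The varying-slope model is linear in its fixed effects once the age slope
#' is expanded: columns are the intercept, stand age, age times each
#' standardized covariate, age times each squared standardized covariate,
#' and indicators for measurement periods 1 and 2 (period 3 is the
#' reference), 16 columns in all for 6 covariates.
#'
#' @param samples data frame with `age`, `period` and standardized covariate
#'   columns.
#' @param covs covariate column names (default the 6 model covariates).
#' @return numeric matrix with `nrow(samples)` rows.
#' @export
build_design <- function(samples, covs = MODEL_COVS) {
  stopifnot(is.data.frame(samples), all(c("age", "period") %in% names(samples)))
  miss <- setdiff(covs, names(samples))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  if (!all(samples$period %in% 1:3))
    stop("unknown period code(s): ",
         paste(unique(samples$period[!samples$period %in% 1:3]), collapse = ", "))
  age <- samples$age
  Xc <- as.matrix(samples[covs])
  X <- cbind(beta0 = 1, beta1 = age, age * Xc, age * Xc^2,
             period_eff.1 = as.numeric(samples$period == 1),
             period_eff.2 = as.numeric(samples$period == 2))
  colnames(X) <- c("beta0", "beta1", paste0("beta_lin.", covs),
                   paste0("beta_quad.", covs), "period_eff.1", "period_eff.2")
  X
}

#' Gibbs sampler for a Gaussian linear mixed model
#'
#' Conjugate block updates for `y = X b + u[group] + e`: the fixed-effect
#' vector is drawn jointly from its multivariate normal full conditional
#' under a N(0, `prior_var_beta`) prior, group random intercepts from their
#' normal conditionals, and the two variances from inverse-gamma
#' conditionals with shape/rate `prior_shape`/`prior_rate` on the
#' precisions. Either variance can be fixed (known-variance sub-models), and
#' `group = NULL` drops the random effects; with both, the fixed-effect
#' draws are i.i.d. from the exact posterior.
#'
#' @param X design matrix (n x p).
#' @param y numeric response (logit scale).
#' @param group integer group index 1..J per row, or `NULL`.
#' @param n_iter post-burn-in iterations.
#' @param burn_in discarded initial iterations.
#' @param seed RNG seed; runs are fully reproducible given the seed.
#' @param prior_var_beta prior variance of fixed effects (default 1e6).
#' @param prior_shape,prior_rate inverse-gamma hyperparameters (default
#'   0.001, 0.001, the conventional vague choice).
#' @param fix_sigma_resid,fix_sigma_group if non-`NULL`, the residual or
#'   group SD is held at this value instead of being sampled.
#' @param init_sd SD of the overdispersed N(0, `init_sd`^2) initial values
#'   for fixed effects (default 2).
#' @return list with `draws` (matrix, `n_iter` rows, columns the fixed
#'   effects plus `sigma_plot` and `sigma_resid`), `u_mean` (posterior-mean
#'   random intercepts), `burn_in` and `seed`.
#' @export
gibbs_linear_mixed <- function(X, y, group = NULL, n_iter = 10000,
                               burn_in = 1000, seed = 1,
                               prior_var_beta = 1e6,
                               prior_shape = 0.001, prior_rate = 0.001,
                               fix_sigma_resid = NULL,
                               fix_sigma_group = NULL, init_sd = 2) {
  set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(p) - 1)
  stopifnot(length(y) == n)
  has_group <- !is.null(group)
  if (has_group) {
    group <- as.integer(group)
    J <- max(group)
    ngroup <- tabulate(group, nbins = J)
    if (any(ngroup == 0)) stop("group indices must be contiguous 1..J")
    Xg <- rowsum(X, group)            # J x p group-summed design
  } else {
    J <- 0L
  }
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  beta <- stats::rnorm(p, 0, init_sd)
  u <- if (has_group) numeric(J) else NULL
  vy <- stats::var(y)
  s2e <- if (is.null(fix_sigma_resid)) vy * stats::runif(1, 0.5, 2)
         else fix_sigma_resid^2
  s2u <- if (!has_group) 0
         else if (is.null(fix_sigma_group)) vy * stats::runif(1, 0.1, 1)
         else fix_sigma_group^2
  total <- burn_in + n_iter
  draws <- matrix(NA_real_, n_iter, p + 2,
                  dimnames = list(NULL, c(colnames(X), "sigma_plot",
                                          "sigma_resid")))
  u_sum <- if (has_group) numeric(J) else NULL
  for (it in seq_len(total)) {
    # fixed-effect block
    A <- XtX / s2e
    diag(A) <- diag(A) + 1 / prior_var_beta
    rhs <- if (has_group) (Xty - drop(crossprod(Xg, u))) / s2e else Xty / s2e
    R <- chol(A)
    mu <- backsolve(R, forwardsolve(t(R), rhs))
    beta <- drop(mu + backsolve(R, stats::rnorm(p)))
    xb <- drop(X %*% beta)
    if (has_group) {
      r <- y - xb
      sums <- drop(rowsum(r, group))
      v <- 1 / (ngroup / s2e + 1 / s2u)
      u <- stats::rnorm(J, v * sums / s2e, sqrt(v))
      if (is.null(fix_sigma_group))
        s2u <- 1 / stats::rgamma(1, prior_shape + J / 2,
                                 prior_rate + sum(u^2) / 2)
      resid <- r - u[group]
    } else {
      resid <- y - xb
    }
    if (is.null(fix_sigma_resid))
      s2e <- 1 / stats::rgamma(1, prior_shape + n / 2,
                               prior_rate + sum(resid^2) / 2)
    if (it > burn_in) {
      draws[it - burn_in, ] <- c(beta, sqrt(s2u), sqrt(s2e))
      if (has_group) u_sum <- u_sum + u
    }
  }
  list(draws = draws,
       u_mean = if (has_group) u_sum / n_iter else NULL,
       burn_in = burn_in, seed = seed)
}

#' Fit configuration for the varying-slope model
#'
#' @param n_chains number of MCMC chains (default 3).
#' @param burn_in discarded initial iterations per chain. The default is
#'   1000; a shorter burn-in of 100 can be requested to mirror minimal
#'   settings, at some risk for a bespoke sampler.
#' @param iterations post-burn-in iterations per chain per round (default
#'   10000).
#' @param max_extension_rounds additional rounds of `iterations` run while
#'   any R-hat is at or above `rhat_threshold` (default 3).
#' @param seed base seed; chain c uses `seed + c`.
#' @param rhat_threshold convergence cutoff (default 1.1).
#' @param prior_var_beta,prior_shape,prior_rate vague-prior hyperparameters
#'   passed to [gibbs_linear_mixed()].
#' @param scaler optional pre-fitted [standard_scaler()]; by default a
#'   scaler is fitted from the training covariates.
#' @param epsilon optional `epsilon_rule`; by default derived per response
#'   from the training data.
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_chains = 3, burn_in = 1000, iterations = 10000,
                       max_extension_rounds = 3, seed = 1,
                       rhat_threshold = 1.1, prior_var_beta = 1e6,
                       prior_shape = 0.001, prior_rate = 0.001,
                       scaler = NULL, epsilon = NULL) {
  stopifnot(n_chains >= 2, iterations >= 10, burn_in >= 0)
  structure(list(n_chains = n_chains, burn_in = burn_in,
                 iterations = iterations,
                 max_extension_rounds = max_extension_rounds, seed = seed,
                 rhat_threshold = rhat_threshold,
                 prior_var_beta = prior_var_beta, prior_shape = prior_shape,
                 prior_rate = prior_rate, scaler = scaler, epsilon = epsilon),
            class = "fit_config")
}

#' Fit the hierarchical varying-slope model of structural development
#'
#' Fits, by Gibbs sampling, the model in which the epsilon-adjusted logit of
#' an old-growth index (or one subindex) is a linear function of stand age
#' whose slope — the structural development rate — is itself a quadratic
#' function of six standardized environmental covariates, with a random
#' plot intercept and fixed measurement-period effects (period 3 reference).
#' Chains are auto-extended until all R-hat values fall below the threshold
#' or the extension budget is exhausted.
#'
#' @param samples data frame with columns `plot_id`, `period` (1-3), `age`
#'   (years), the 6 model covariates (`snow_depth`, `warmth_index`,
#'   `slope_angle`, `positive_openness`, `log10_catchment_area`,
#'   `solar_radiation`) on their raw scale, and the response column.
#' @param response name of the response column, a proportion in \[0, 1\]
#'   (default `"I_og"`).
#' @param config a [fit_config()].
#' @return an `og_fit` object: posterior chains, summary table, epsilon
#'   rule, covariate scaler, 2.5/97.5% training quantiles for clamping,
#'   convergence report and posterior-mean plot effects.
#' @export
fit_development_model <- function(samples, response = "I_og",
                                  config = fit_config()) {
  stopifnot(is.data.frame(samples), inherits(config, "fit_config"))
  if (!response %in% names(samples)) stop("no response column ", response)
  resp <- samples[[response]]
  if (any(!is.finite(resp)) || any(resp < 0 | resp > 1))
    stop("response must lie in [0, 1]")
  if (length(unique(samples$plot_id)) < 2) stop("need at least 2 plots")
  if (stats::var(resp) == 0) stop("all responses are identical")
  eps <- if (is.null(config$epsilon)) epsilon_from_data(resp)
         else config$epsilon
  y <- logit_eps(resp, eps)
  std <- standardize(samples[MODEL_COVS], config$scaler)
  sdf <- samples
  sdf[MODEL_COVS] <- std$data
  X <- build_design(sdf)
  if (qr(X)$rank < ncol(X))
    stop("singular design: collinear fixed-effect columns")
  plot_f <- factor(samples$plot_id)
  group <- as.integer(plot_f)
  run_chains <- function(n_iter) {
    lapply(seq_len(config$n_chains), function(ch)
      gibbs_linear_mixed(X, y, group, n_iter = n_iter,
                         burn_in = config$burn_in,
                         seed = config$seed + ch,
                         prior_var_beta = config$prior_var_beta,
                         prior_shape = config$prior_shape,
                         prior_rate = config$prior_rate))
  }
  n_iter <- config$iterations
  rounds <- 0
  repeat {
    chains <- run_chains(n_iter)
    rh <- chain_rhat(lapply(chains, `[[`, "draws"))
    converged <- all(rh < config$rhat_threshold, na.rm = TRUE)
    if (converged || rounds >= config$max_extension_rounds) break
    rounds <- rounds + 1
    n_iter <- n_iter + config$iterations
  }
  if (!converged)
    warning("not converged: max R-hat ", round(max(rh, na.rm = TRUE), 3),
            " after ", rounds, " extension round(s)")
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  u_mean <- rowMeans(do.call(cbind, lapply(chains, `[[`, "u_mean")))
  names(u_mean) <- levels(plot_f)
  clamp <- clamp_rule(samples[MODEL_COVS])
  structure(list(
    chains = lapply(chains, `[[`, "draws"),
    draws = draws,
    summary = posterior_summary(draws),
    epsilon = eps,
    scaler = std$scaler,
    clamp = clamp,
    plot_eff = u_mean,
    convergence = list(rhat = rh, converged = converged,
                       extension_rounds = rounds,
                       threshold = config$rhat_threshold),
    config = config,
    response = response,
    n = nrow(samples),
    n_plots = nlevels(plot_f)
  ), class = "og_fit")
}

#' @export
print.og_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical varying-slope fit: %d samples, %d plots, response '%s'\n",
    x$n, x$n_plots, x$response))
  cat(sprintf("  %d chains x %d draws; %s (max R-hat %.3f, %d extension%s)\n",
              length(x$chains), nrow(x$chains[[1]]),
              if (x$convergence$converged) "converged" else "NOT converged",
              max(x$convergence$rhat, na.rm = TRUE),
              x$convergence$extension_rounds,
              if (x$convergence$extension_rounds == 1) "" else "s"))
  print(x$summary, digits = 3)
  invisible(x)
}

# R-hat per column across a list of per-chain draw matrices; columns with
# zero variance everywhere (e.g. a fixed variance) are NA.
chain_rhat <- function(chain_list) {
  cols <- colnames(chain_list[[1]])
  vapply(cols, function(cl) {
    m <- vapply(chain_list, function(d) d[, cl], numeric(nrow(chain_list[[1]])))
    if (all(apply(m, 2, stats::var) == 0)) return(NA_real_)
    rhat(m)
  }, numeric(1))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic multi-chain R-hat: with m chains of n draws each, the pooled
#' posterior variance estimate `((n-1)/n) W + B/n` (W the mean within-chain
#' variance, B the between-chain variance of chain means times n) is
#' compared with W, and R-hat is the square root of their ratio. Values
#' below 1.1 are conventionally taken as converged.
#'
#' @param chains matrix with one column per chain (n draws x m chains), or a
#'   list of equal-length numeric vectors.
#' @return R-hat (scalar).
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  stopifnot(is.matrix(chains))
  m <- ncol(chains); n <- nrow(chains)
  if (m < 2) stop("need at least 2 chains")
  if (n < 10) stop("need at least 10 draws per chain")
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) stop("zero within-chain variance in all chains")
  B <- n * stats::var(colMeans(chains))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior summaries of MCMC draws
#'
#' @param x an `og_fit` or a matrix of draws (columns = parameters).
#' @return data frame with per-parameter mean, median, SD, 2.5% and 97.5%
#'   quantiles, and a significance flag (the 95% credible interval excludes
#'   zero).
#' @export
posterior_summary <- function(x) {
  if (inherits(x, "og_fit")) x <- x$draws
  stopifnot(is.matrix(x))
  if (nrow(x) == 0) stop("empty chains")
  q <- t(apply(x, 2, stats::quantile, probs = c(0.025, 0.5, 0.975)))
  data.frame(parameter = colnames(x),
             mean = colMeans(x),
             median = q[, 2],
             sd = apply(x, 2, stats::sd),
             q2.5 = q[, 1],
             q97.5 = q[, 3],
             significant = q[, 1] > 0 | q[, 3] < 0,
             row.names = NULL)
}

#' Extract point-estimate model parameters from a fit
#'
#' @param fit an `og_fit`.
#' @param estimate `"mean"` (default; spatial predictions use posterior
#'   means) or `"median"`.
#' @return a `model_parameters` list: `beta0`, `beta1`, named `beta_lin` and
#'   `beta_quad` vectors, `period_eff` (periods 1 and 2), `sigma_plot`,
#'   `sigma_resid`, and posterior-mean `plot_eff`.
#' @export
model_parameters <- function(fit, estimate = c("mean", "median")) {
  stopifnot(inherits(fit, "og_fit"))
  estimate <- match.arg(estimate)
  s <- fit$summary
  est <- stats::setNames(s[[estimate]], s$parameter)
  covs <- names(fit$scaler$center)
  structure(list(
    beta0 = est[["beta0"]],
    beta1 = est[["beta1"]],
    beta_lin = stats::setNames(est[paste0("beta_lin.", covs)], covs),
    beta_quad = stats::setNames(est[paste0("beta_quad.", covs)], covs),
    period_eff = c(`1` = est[["period_eff.1"]], `2` = est[["period_eff.2"]]),
    sigma_plot = est[["sigma_plot"]],
    sigma_resid = est[["sigma_resid"]],
    plot_eff = fit$plot_eff
  ), class = "model_parameters")
}
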