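#' Fixed-effect linear predictor of a fit on new samples
#'
#' Standardizes the samples' covariates with the fit's scaler, rebuilds the
#' design and applies the posterior point estimates. Plot random effects are
#' never included; measurement-period effects are included by default
#' (matching how goodness of fit is assessed) and can be dropped for
#' reference-period predictions.
#'
#' @param fit an `og_fit`.
#' @param samples data frame of plot samples (raw covariates).
#' @param include_period include period fixed effects (default `TRUE`).
#' @param estimate `"mean"` or `"median"`.
#' @return numeric vector on the logit scale.
#' @export
linear_predictor <- function(fit, samples, include_period = TRUE,
                             estimate = "mean") {
  stopifnot(inherits(fit, "og_fit"))
  sdf <- samples
  sdf[names(fit$scaler$center)] <-
    standardize(samples[names(fit$scaler$center)], fit$scaler)$data
  X <- build_design(sdf, names(fit$scaler$center))
  s <- fit$summary
  beta <- stats::setNames(s[[estimate]], s$parameter)[colnames(X)]
  if (!include_period)
    beta[c("period_eff.1", "period_eff.2")] <- 0
  drop(X %*% beta)
}

#' Logit-scale coefficient of determination
#'
#' R-squared computed as the squared Pearson correlation between the
#' epsilon-adjusted logit of the observed index and the fixed-effect linear
#' predictor, which includes measurement-period effects but excludes plot
#' random effects.
#'
#' @param fit an `og_fit`.
#' @param samples data frame with the response and covariates (defaults to
#'   evaluating the training fit if these are the training samples).
#' @param response response column name (default the fit's response).
#' @return scalar R-squared.
#' @export
r_squared <- function(fit, samples, response = fit$response) {
  obs <- logit_eps(samples[[response]], fit$epsilon)
  pred <- linear_predictor(fit, samples, include_period = TRUE)
  if (stats::var(obs) == 0 || stats::var(pred) == 0)
    stop("zero variance in observed or predicted values")
  stats::cor(obs, pred)^2
}

#' Holdout cross-validation of the varying-slope model
#'
#' Repeatedly splits the samples at random into a training fraction and a
#' held-out test set, refits the full model on the training part (the
#' epsilon rule is recomputed per training split), and scores the held-out
#' logit-scale R-squared. Splits are simple random draws over sample rows.
#'
#' @param samples data frame of plot samples.
#' @param response response column name (default `"I_og"`).
#' @param train_fraction fraction used for training (default 0.9).
#' @param n_reps number of repetitions (default 100).
#' @param seed base seed; repetition r uses `seed + r` for both the split
#'   and the refit, making the whole procedure reproducible.
#' @param config [fit_config()] used for each refit.
#' @return a `cv_result` list: per-repetition `r2`, their `mean` and `sd`,
#'   and the settings. Degenerate repetitions (zero-variance test response)
#'   are skipped with a warning and recorded as `NA`.
#' @export
holdout_cv <- function(samples, response = "I_og", train_fraction = 0.9,
                       n_reps = 100, seed = 1, config = fit_config()) {
  stopifnot(is.data.frame(samples))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly inside (0, 1)")
  n <- nrow(samples)
  n_train <- floor(train_fraction * n)
  if (n_train < 4 || n_train >= n)
    stop("split leaves too few training or test samples")
  r2 <- rep(NA_real_, n_reps)
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    idx <- sample.int(n, n_train)
    train <- samples[idx, , drop = FALSE]
    test <- samples[-idx, , drop = FALSE]
    if (length(unique(train$plot_id)) < 2) {
      warning("repetition ", rep, " skipped: fewer than 2 training plots")
      next
    }
    cfg <- config
    cfg$seed <- seed + rep
    f <- tryCatch(fit_development_model(train, response, cfg),
                  error = function(e) NULL)
    if (is.null(f)) {
      warning("repetition ", rep, " skipped: refit failed")
      next
    }
    obs <- logit_eps(test[[response]], f$epsilon)
    pred <- linear_predictor(f, test, include_period = TRUE)
    if (stats::var(obs) == 0 || stats::var(pred) == 0) {
      warning("repetition ", rep, " skipped: zero-variance test split")
      next
    }
    r2[rep] <- stats::cor(obs, pred)^2
  }
  structure(list(r2 = r2, mean = mean(r2, na.rm = TRUE),
                 sd = stats::sd(r2[!is.na(r2)]),
                 train_fraction = train_fraction, n_reps = n_reps,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "holdout CV: %d reps at %.0f%% training; held-out R^2 = %.3f (SD %.3f)\n",
    x$n_reps, 100 * x$train_fraction, x$mean, x$sd))
  invisible(x)
}

# Map a model_parameters-style truth list onto the 16 fixed-effect
# parameter names used in fit summaries.
flatten_fixed_effects <- function(true_params, covs = MODEL_COVS) {
  c(beta0 = true_params$beta0, beta1 = true_params$beta1,
    stats::setNames(true_params$beta_lin[covs], paste0("beta_lin.", covs)),
    stats::setNames(true_params$beta_quad[covs], paste0("beta_quad.", covs)),
    period_eff.1 = unname(true_params$period_eff[1]),
    period_eff.2 = unname(true_params$period_eff[2]))
}

#' Parameter-recovery experiment for the Gibbs sampler
#'
#' Simulates datasets from known parameters with the synthetic generator,
#' refits each with the full machinery (using the generator's population
#' covariate scaler so estimates are on the truth's scale), and reports
#' per-parameter posterior-mean bias and 95% credible-interval coverage of
#' the 16 fixed effects plus recovery of the variance components.
#'
#' @param gen_config a [generator_config()] carrying the true parameters.
#' @param fit_cfg a [fit_config()] for the refits.
#' @param n_reps number of replicates (default 10).
#' @param seed base seed; replicate r simulates with `seed + r`.
#' @return list with `per_parameter` (data frame: truth, mean estimate,
#'   bias, coverage), `coverage_overall` (pooled over fixed effects of
#'   converged replicates), `sigma_resid` and `sigma_plot` recovery, and
#'   the convergence count. Non-converged replicates are excluded from
#'   coverage with a warning.
#' @export
recovery_experiment <- function(gen_config, fit_cfg = fit_config(),
                                n_reps = 10, seed = 1) {
  stopifnot(inherits(gen_config, "generator_config"))
  truth <- flatten_fixed_effects(gen_config$true_params)
  p <- length(truth)
  est <- matrix(NA_real_, n_reps, p, dimnames = list(NULL, names(truth)))
  cover <- matrix(NA, n_reps, p, dimnames = list(NULL, names(truth)))
  sig_e <- sig_u <- rep(NA_real_, n_reps)
  converged <- logical(n_reps)
  for (rep in seq_len(n_reps)) {
    g <- gen_config
    g$seed <- seed + rep
    dat <- gen_plot_samples(g)
    cfg <- fit_cfg
    cfg$seed <- seed + 1000L * rep
    cfg$scaler <- attr(dat, "pop_scaler")
    f <- fit_development_model(dat, "I_og", cfg)
    converged[rep] <- f$convergence$converged
    s <- f$summary
    rownames(s) <- s$parameter
    est[rep, ] <- s[names(truth), "mean"]
    cover[rep, ] <- s[names(truth), "q2.5"] <= truth &
      truth <= s[names(truth), "q97.5"]
    sig_e[rep] <- s["sigma_resid", "mean"]
    sig_u[rep] <- s["sigma_plot", "mean"]
  }
  if (any(!converged))
    warning(sum(!converged),
            " replicate(s) did not converge; excluded from coverage")
  ok <- converged
  per_param <- data.frame(
    parameter = names(truth),
    true = unname(truth),
    mean_estimate = colMeans(est[ok, , drop = FALSE]),
    bias = colMeans(est[ok, , drop = FALSE]) - unname(truth),
    coverage = colMeans(cover[ok, , drop = FALSE]),
    row.names = NULL)
  list(per_parameter = per_param,
       coverage_overall = mean(cover[ok, , drop = FALSE]),
       sigma_resid = list(true = gen_config$true_params$sigma_resid,
                          mean_estimate = mean(sig_e[ok]),
                          rel_error = mean(sig_e[ok]) /
                            gen_config$true_params$sigma_resid - 1),
       sigma_plot = list(true = gen_config$true_params$sigma_plot,
                         mean_estimate = mean(sig_u[ok]),
                         rel_error = mean(sig_u[ok]) /
                           gen_config$true_params$sigma_plot - 1),
       n_converged = sum(converged), n_reps = n_reps, seed = seed)
}
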