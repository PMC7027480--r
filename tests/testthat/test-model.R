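test_that("standardization centers and scales, and stored scalers transfer", {
  x <- data.frame(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- standardize(x)
  expect_equal(s$data$a, c(-1, 0, 1))
  expect_equal(mean(s$data$b), 0, tolerance = 1e-12)
  expect_equal(sd(s$data$b), 1, tolerance = 1e-12)
  # re-applying the stored scaler to its training data reproduces mean 0
  again <- standardize(x, s$scaler)
  expect_equal(colMeans(again$data), c(a = 0, b = 0), tolerance = 1e-12)
  # new data under a stored scaler need not be centered
  shifted <- standardize(data.frame(a = c(5, 6), b = c(1, 2)), s$scaler)
  expect_gt(abs(mean(shifted$data$a)), 1)
  expect_error(standardize(data.frame(a = c(2, 2, 2))), "zero-variance")
})

test_that("the design matrix expands the varying slope into 16 fixed columns", {
  g <- generator_config(n_plots = 10, seed = 1)
  dat <- gen_plot_samples(g)
  sdf <- dat
  sdf[MODEL_COV_NAMES] <- standardize(dat[MODEL_COV_NAMES])$data
  X <- build_design(sdf)
  expect_equal(dim(X), c(nrow(dat), 16))
  # age * covariate column: direct product
  expect_equal(X[, "beta_lin.snow_depth"],
               sdf$age * sdf$snow_depth)
  expect_equal(X[, "beta_quad.snow_depth"],
               sdf$age * sdf$snow_depth^2)
  # period 3 rows are the reference: both indicators zero
  p3 <- sdf$period == 3
  expect_true(all(X[p3, "period_eff.1"] == 0 & X[p3, "period_eff.2"] == 0))
  expect_true(all(X[sdf$period == 1, "period_eff.1"] == 1))
  sdf$period[1] <- 9
  expect_error(build_design(sdf), "unknown period")
})

test_that("the Gibbs sampler is deterministic given its seed", {
  set.seed(1)
  X <- cbind(1, rnorm(40))
  y <- drop(X %*% c(1, 2)) + rnorm(40)
  g <- rep(1:8, each = 5)
  a <- gibbs_linear_mixed(X, y, g, n_iter = 200, burn_in = 50, seed = 99)
  b <- gibbs_linear_mixed(X, y, g, n_iter = 200, burn_in = 50, seed = 99)
  expect_identical(a$draws, b$draws)
  c2 <- gibbs_linear_mixed(X, y, g, n_iter = 200, burn_in = 50, seed = 100)
  expect_false(identical(a$draws, c2$draws))
})

test_that("known-variance sub-model matches the analytic Gaussian posterior", {
  # 3 samples, intercept + slope, sigma known: the posterior is exactly
  # N(V X'y / s2, V), V = (X'X/s2 + I/tau)^-1, and the block update draws
  # i.i.d. from it
  X <- cbind(1, c(10, 50, 120))
  y <- c(-2.5, -1.2, 0.9)
  s2 <- 1; tau <- 100
  V <- solve(crossprod(X) / s2 + diag(2) / tau)
  m <- drop(V %*% crossprod(X, y)) / s2
  r <- gibbs_linear_mixed(X, y, group = NULL, n_iter = 8000, burn_in = 200,
                          seed = 4, prior_var_beta = tau,
                          fix_sigma_resid = 1)
  for (j in 1:2) {
    mcse <- sd(r$draws[, j]) / sqrt(nrow(r$draws))
    expect_lt(abs(mean(r$draws[, j]) - m[j]), 3 * mcse + 1e-12)
    expect_equal(sd(r$draws[, j]), sqrt(V[j, j]), tolerance = 0.05)
  }
})

test_that("chain histograms match a brute-force grid posterior (KS)", {
  X <- cbind(1, c(10, 50, 120))
  y <- c(-2.5, -1.2, 0.9)
  tau <- 100
  # dense 2-D grid posterior, marginalized to the intercept
  b0 <- seq(-6, 3, length.out = 400)
  b1 <- seq(-0.1, 0.15, length.out = 400)
  logpost <- outer(b0, b1, function(a, b) {
    ll <- 0
    for (i in 1:3) ll <- ll - 0.5 * (y[i] - a - b * X[i, 2])^2
    ll - 0.5 * (a^2 + b^2) / tau
  })
  w <- exp(logpost - max(logpost))
  marg <- rowSums(w); marg <- marg / sum(marg)
  grid_cdf <- cumsum(marg)
  r <- gibbs_linear_mixed(X, y, group = NULL, n_iter = 6000, burn_in = 200,
                          seed = 11, prior_var_beta = tau,
                          fix_sigma_resid = 1)
  draws <- sort(r$draws[, 1])
  emp_at_grid <- findInterval(b0, draws) / length(draws)
  ks <- max(abs(emp_at_grid - grid_cdf))
  expect_lt(ks, 0.05)
})

test_that("R-hat behaves on converged, separated and degenerate chains", {
  set.seed(21)
  same <- cbind(rnorm(10000), rnorm(10000))
  expect_gt(rhat(same), 0.99)
  expect_lt(rhat(same), 1.01)
  apart <- cbind(rnorm(500, 0), rnorm(500, 10))
  expect_gt(rhat(apart), 5)
  expect_error(rhat(cbind(rep(1, 50), rep(1, 50))), "zero within-chain")
  expect_error(rhat(matrix(rnorm(50), ncol = 1)), "2 chains")
  expect_error(rhat(cbind(rnorm(5), rnorm(5))), "10 draws")
  # list input is accepted
  expect_lt(rhat(list(rnorm(5000), rnorm(5000))), 1.02)
})

test_that("posterior summaries report moments, quantiles and significance", {
  d <- cbind(a = c(1, 2, 3), b = c(-1, 0, 1), c = c(2, 3, 4))
  s <- posterior_summary(d)
  expect_equal(s$mean, c(2, 0, 3))
  expect_equal(s$median, c(2, 0, 3))
  expect_equal(s$significant, c(TRUE, FALSE, TRUE))
  expect_error(posterior_summary(matrix(numeric(0), 0, 2)), "empty")
})

test_that("design-matrix likelihood equals the direct model evaluation", {
  fit <- get_test_fit()
  dat <- get_test_samples()
  pred <- linear_predictor(fit, dat, include_period = TRUE)
  p <- model_parameters(fit)
  x <- as.matrix(standardize(dat[MODEL_COV_NAMES], fit$scaler)$data)
  direct <- vapply(seq_len(nrow(dat)), function(j) {
    coeff <- p$beta1 + sum(p$beta_lin * x[j, ]) + sum(p$beta_quad * x[j, ]^2)
    pe <- if (dat$period[j] == 1) p$period_eff[["1"]]
          else if (dat$period[j] == 2) p$period_eff[["2"]] else 0
    p$beta0 + coeff * dat$age[j] + pe
  }, numeric(1))
  expect_equal(pred, direct, tolerance = 1e-10)
})

test_that("fitting rejects degenerate inputs", {
  g <- generator_config(n_plots = 30, seed = 2)
  dat <- gen_plot_samples(g)
  cfg <- fit_config(n_chains = 2, burn_in = 50, iterations = 100, seed = 1)
  one <- dat
  one$plot_id <- "P00001"
  expect_error(fit_development_model(one, "I_og", cfg), "2 plots")
  flatr <- dat
  flatr$I_og <- 0.4
  expect_error(fit_development_model(flatr, "I_og", cfg), "identical")
  coll <- dat
  coll$warmth_index <- coll$snow_depth       # duplicate covariate
  expect_error(fit_development_model(coll, "I_og", cfg), "[Ss]ingular")
})

test_that("swapping period labels 1 and 2 swaps the period-effect posteriors", {
  g <- generator_config(n_plots = 150, seed = 8)
  dat <- gen_plot_samples(g)
  cfg <- fit_config(n_chains = 2, burn_in = 300, iterations = 1200, seed = 5)
  f1 <- fit_development_model(dat, "I_og", cfg)
  swapped <- dat
  swapped$period <- ifelse(dat$period == 1, 2,
                           ifelse(dat$period == 2, 1, 3))
  f2 <- fit_development_model(swapped, "I_og", cfg)
  s1 <- setNames(f1$summary$mean, f1$summary$parameter)
  s2 <- setNames(f2$summary$mean, f2$summary$parameter)
  expect_equal(s1[["period_eff.1"]], s2[["period_eff.2"]], tolerance = 0.02)
  expect_equal(s1[["period_eff.2"]], s2[["period_eff.1"]], tolerance = 0.02)
})

test_that("true fixed effects are recovered within 95% CIs on synthetic data", {
  g <- generator_config(n_plots = 500, seed = 31)
  dat <- gen_plot_samples(g)
  cfg <- fit_config(n_chains = 3, burn_in = 400, iterations = 1500,
                    seed = 17, scaler = attr(dat, "pop_scaler"))
  f <- fit_development_model(dat, "I_og", cfg)
  expect_true(f$convergence$converged)
  truth <- ogdex:::flatten_fixed_effects(attr(dat, "true_params"))
  s <- f$summary; rownames(s) <- s$parameter
  inside <- s[names(truth), "q2.5"] <= truth &
    truth <= s[names(truth), "q97.5"]
  expect_gte(sum(inside), 13)
})
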