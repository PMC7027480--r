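test_that("development rate reduces to the rate intercept at centered covariates", {
  p <- toy_params(beta1 = 0.025)
  expect_equal(development_rate(p, zero_covs()), 0.025)
  p2 <- toy_params(beta1 = 0.02, beta_lin = seq(0.001, 0.006, by = 0.001),
                   beta_quad = rep(c(0.001, -0.001), 3))
  x <- setNames(rnorm(6), MODEL_COV_NAMES)
  brute <- p2$beta1
  for (v in MODEL_COV_NAMES)
    brute <- brute + p2$beta_lin[[v]] * x[[v]] + p2$beta_quad[[v]] * x[[v]]^2
  expect_equal(development_rate(p2, x), brute, tolerance = 1e-12)
  expect_error(development_rate(p2, x[-3]), "missing covariate")
})

test_that("predicted index follows the logistic curve in age", {
  p <- toy_params(beta0 = -3, beta1 = 0.02)
  x <- zero_covs()
  expect_equal(predict_index(p, x, 150), 0.5)
  expect_equal(predict_index(p, x, 0), 0.04742587, tolerance = 1e-7)
  p0 <- toy_params(beta0 = -1, beta1 = 0)
  expect_equal(predict_index(p0, x, 10), predict_index(p0, x, 500))
  expect_error(predict_index(p, x, -5), "non-negative")
})

test_that("numeric age inversion agrees with the closed form", {
  x <- zero_covs()
  p <- toy_params(beta0 = -3, beta1 = 0.02)
  expect_equal(age_at_index(p, x, 0.5)$t, 150, tolerance = 1e-6)
  neg <- toy_params(beta0 = -3, beta1 = -0.01)
  r <- age_at_index(neg, x, 0.5)
  expect_false(r$reachable)
  expect_true(is.na(r$t))
  # slow development: root beyond the bracketing limit is unreachable
  slow <- toy_params(beta0 = -3, beta1 = 0.001)
  expect_false(age_at_index(slow, x, 0.5, age_max = 1000)$reachable)
  set.seed(12)
  for (i in 1:200) {
    b0 <- runif(1, -6, -0.5); cf <- runif(1, 0.005, 0.1)
    q <- runif(1, 0.05, 0.95)
    pp <- toy_params(beta0 = b0, beta1 = cf)
    closed <- (log(q / (1 - q)) - b0) / cf
    if (closed <= 0 || closed > 1000) next
    expect_equal(age_at_index(pp, x, q)$t, closed, tolerance = 1e-6)
  }
  expect_error(age_at_index(p, x, 1.2), "inside")
})

test_that("inverse consistency: predicting at the solved age returns the target", {
  set.seed(7)
  for (q in c(0.2, 0.5, 0.8)) {
    p <- toy_params(beta0 = runif(1, -5, -1), beta1 = runif(1, 0.01, 0.05),
                    beta_lin = rnorm(6, 0, 0.003))
    x <- setNames(rnorm(6), MODEL_COV_NAMES)
    r <- age_at_index(p, x, q)
    if (!r$reachable || r$t == 0) next   # 0: already past the target at age 0
    expect_equal(predict_index(p, x, r$t), q, tolerance = 1e-6)
  }
})

test_that("t_target does not increase with the development rate", {
  x <- zero_covs()
  ts <- vapply(c(0.01, 0.02, 0.05, 0.1), function(cf)
    age_at_index(toy_params(beta0 = -3, beta1 = cf), x, 0.5)$t, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("covariate clamping is a componentwise idempotent band clamp", {
  set.seed(2)
  train <- as.data.frame(matrix(rnorm(600), 100, 6))
  names(train) <- MODEL_COV_NAMES
  rule <- clamp_rule(train)
  hi <- setNames(rep(10, 6), MODEL_COV_NAMES)
  cl <- clamp_covariates(hi, rule)
  expect_equal(unname(unlist(cl)), rule$q97.5, tolerance = 1e-12)
  inside <- setNames(rep(0, 6), MODEL_COV_NAMES)
  expect_equal(clamp_covariates(inside, rule), inside)
  expect_equal(clamp_covariates(cl, rule), cl)   # idempotent
  # cells already in the training band never change
  mid <- train[5, ]
  midc <- clamp_covariates(mid, rule)
  keep <- mid >= rule$q2.5[match(names(mid), rule$variable)] &
    mid <= rule$q97.5[match(names(mid), rule$variable)]
  expect_equal(unlist(midc)[unlist(keep)], unlist(mid)[unlist(keep)])
})

test_that("t-target maps are cellwise consistent with the scalar solver", {
  fit <- get_test_fit()
  vals <- fit$scaler$center                 # raw-scale covariate means
  stack <- uniform_stack(vals, nr = 4, nc = 4)
  t05 <- map_t_target(stack, fit, target = 0.5)
  scalar <- age_at_index(model_parameters(fit),
                         setNames(rep(0, 6), names(vals)), 0.5)
  if (scalar$reachable) {
    expect_equal(max(abs(t05$values - scalar$t)), 0, tolerance = 1e-6)
  } else {
    expect_true(all(t05$values == -1))
  }
  # nodata propagates cell for cell
  stack2 <- stack
  stack2$snow_depth$values[2, 3] <- NA
  tn <- map_t_target(stack2, fit)
  expect_equal(sum(is.na(tn$values)), 1)
  expect_true(is.na(tn$values[2, 3]))
  # geometry mismatch is refused
  stack3 <- stack
  stack3$snow_depth <- raster_grid(matrix(0, 3, 3), 20)
  expect_error(map_t_target(stack3, fit), "geometry mismatch")
})

test_that("index maps honor stand age, masks and the inverse relation", {
  fit <- get_test_fit()
  stack <- covariate_stack(6, seed = 77)
  t05 <- map_t_target(stack, fit, target = 0.5)
  age <- t05
  reachable <- t05$values > 0
  idx <- map_index(stack, age, mask = NULL, fit)
  expect_true(all(abs(idx$values[reachable] - 0.5) < 1e-6))
  # masking removes cells
  mask0 <- raster_grid(matrix(0, 6, 6), 20)
  allna <- map_index(stack, age, mask0, fit)
  expect_true(all(is.na(allna$values)))
  # older stands on developing cells have higher indices
  p <- model_parameters(fit)
  age2 <- raster_grid(age$values * 2, 20)
  idx2 <- map_index(stack, age2, mask = NULL, fit)
  expect_true(all(idx2$values[reachable] >= idx$values[reachable]))
})
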