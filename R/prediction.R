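#' Structural development rate for given covariates
#'
#' The age slope of the logit-index line: the rate intercept plus the
#' linear and quadratic covariate terms, evaluated at standardized
#' covariate values. May be negative (structure not developing).
#'
#' @param params a [model_parameters()] list (or any list with `beta1`,
#'   `beta_lin`, `beta_quad`).
#' @param covariates named numeric vector (or one-row data frame) of the
#'   model covariates, standardized with the fit's scaler.
#' @return scalar development rate on the logit-per-year scale.
#' @export
development_rate <- function(params, covariates) {
  if (is.data.frame(covariates)) covariates <- unlist(covariates[1, ])
  covs <- names(params$beta_lin)
  miss <- setdiff(covs, names(covariates))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  x <- covariates[covs]
  unname(params$beta1 + sum(params$beta_lin * x) + sum(params$beta_quad * x^2))
}

#' Predicted old-growth index at a stand age
#'
#' Inverse-logit of the fixed-effect linear predictor without plot or
#' period effects (i.e. as measured in the reference third period).
#'
#' @param params a [model_parameters()] list.
#' @param covariates standardized covariates (named vector).
#' @param age stand age in years (>= 0), may be a vector.
#' @return predicted index in (0, 1).
#' @export
predict_index <- function(params, covariates, age) {
  if (any(age < 0)) stop("age must be non-negative")
  coeff <- development_rate(params, covariates)
  inv_logit(params$beta0 + coeff * age)
}

#' Stand age at which the index reaches a target value
#'
#' Numerically solves `beta0 + coeff * age = logit(target)` for age by
#' bracketed root finding over (0, `age_max`\]. When the development rate is
#' non-positive or the root exceeds `age_max` the target is unreachable.
#'
#' @param params a [model_parameters()] list.
#' @param covariates standardized covariates (named vector).
#' @param target index value in (0, 1) (0.5 gives the conventional t_0.5).
#' @param age_max bracketing limit in years (default 1000).
#' @return list with `t` (years, or `NA`) and `reachable` (logical).
#' @export
age_at_index <- function(params, covariates, target = 0.5, age_max = 1000) {
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("target must lie strictly inside (0, 1)")
  coeff <- development_rate(params, covariates)
  lt <- logit(target)
  f <- function(a) params$beta0 + coeff * a - lt
  if (f(0) >= 0)                      # already at or above target at age 0
    return(list(t = 0, reachable = TRUE))
  if (coeff <= 0 || f(age_max) < 0)
    return(list(t = NA_real_, reachable = FALSE))
  root <- stats::uniroot(f, c(0, age_max), tol = 1e-9)$root
  list(t = root, reachable = TRUE)
}

#' Clamping rule from training covariates
#'
#' Stores the 2.5% and 97.5% quantiles of each training covariate; applied
#' before prediction so mapped covariates never leave the central 95% band
#' of the data the model was fitted to.
#'
#' @param covariates data frame of raw (unstandardized) training covariates.
#' @return a `clamp_rule` data frame with columns `variable`, `q2.5`, `q97.5`.
#' @export
clamp_rule <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  q <- vapply(covariates, stats::quantile, numeric(2),
              probs = c(0.025, 0.975), names = FALSE)
  structure(data.frame(variable = names(covariates),
                       q2.5 = q[1, ], q97.5 = q[2, ], row.names = NULL),
            class = c("clamp_rule", "data.frame"))
}

#' Clamp covariates into the training 95% band
#'
#' Componentwise clamp into \[q2.5, q97.5\]; idempotent, and values already
#' inside the band are unchanged.
#'
#' @param covariates named numeric vector or data frame (raw scale).
#' @param rule a [clamp_rule()] from the training data.
#' @return clamped covariates, same shape as the input.
#' @export
clamp_covariates <- function(covariates, rule) {
  stopifnot(inherits(rule, "clamp_rule"))
  clamp1 <- function(v, name) {
    r <- rule[rule$variable == name, ]
    if (!nrow(r)) return(v)
    pmin(pmax(v, r$q2.5), r$q97.5)
  }
  if (is.data.frame(covariates)) {
    for (v in intersect(names(covariates), rule$variable))
      covariates[[v]] <- clamp1(covariates[[v]], v)
    covariates
  } else {
    out <- covariates
    for (v in intersect(names(covariates), rule$variable))
      out[[v]] <- clamp1(covariates[[v]], v)
    out
  }
}

# Collect a covariate raster stack into a per-cell data frame, checking
# aligned geometry against a template grid.
stack_to_frame <- function(stack, covs) {
  stopifnot(is.list(stack))
  miss <- setdiff(covs, names(stack))
  if (length(miss))
    stop("covariate stack is missing raster(s): ", paste(miss, collapse = ", "))
  tmpl <- stack[[covs[1]]]
  for (v in covs) {
    stopifnot(inherits(stack[[v]], "raster_grid"))
    if (!same_geometry(stack[[v]], tmpl))
      stop("raster geometry mismatch for covariate ", v)
  }
  as.data.frame(lapply(stack[covs], function(g) as.vector(g$values)))
}

# Clamp then standardize per-cell covariates with the fit's rules; returns
# a matrix with one row per cell (NA rows where any covariate is nodata).
prepare_cells <- function(stack, fit) {
  covs <- names(fit$scaler$center)
  cells <- stack_to_frame(stack, covs)
  cells <- clamp_covariates(cells, fit$clamp)
  as.matrix(standardize(cells, fit$scaler)$data)
}

#' Map the stand age needed to reach a target index
#'
#' For every cell of an aligned covariate raster stack: clamp the
#' covariates to the training 95% band, standardize with the fit's scaler,
#' and solve for the age at which the predicted index reaches `target`.
#' Nodata cells propagate; cells where the target is unreachable (negative
#' development rate, or older than `age_max`) receive the `unreachable`
#' sentinel value.
#'
#' @param stack named list of `raster_grid`s, one per model covariate (raw
#'   scale; catchment area already log10-transformed).
#' @param fit an `og_fit`.
#' @param target index value in (0, 1) (default 0.5).
#' @param age_max bracketing limit in years (default 1000).
#' @param unreachable sentinel value written to unreachable cells
#'   (default -1, distinct from the nodata sentinel).
#' @param estimate passed to [model_parameters()].
#' @return a `raster_grid` of ages in years.
#' @export
map_t_target <- function(stack, fit, target = 0.5, age_max = 1000,
                         unreachable = -1, estimate = "mean") {
  stopifnot(inherits(fit, "og_fit"))
  params <- model_parameters(fit, estimate)
  Xs <- prepare_cells(stack, fit)
  covs <- colnames(Xs)
  tmpl <- stack[[covs[1]]]
  out <- rep(NA_real_, nrow(Xs))
  ok <- stats::complete.cases(Xs)
  for (i in which(ok)) {
    res <- age_at_index(params,
                        stats::setNames(Xs[i, ], covs), target, age_max)
    out[i] <- if (res$reachable) res$t else unreachable
  }
  raster_grid(matrix(out, nrow(tmpl$values), ncol(tmpl$values)),
              tmpl$cell_size, tmpl$origin, tmpl$nodata)
}

#' Map the predicted index at current stand ages
#'
#' Per-cell predicted index at the cell's stand age, restricted to the
#' masked (natural-forest) cells; everything else is nodata.
#'
#' @param stack named list of covariate `raster_grid`s (aligned).
#' @param stand_age `raster_grid` of stand ages in years.
#' @param mask `raster_grid`; cells with value > 0 are predicted, others
#'   (or nodata) are masked out. `NULL` predicts everywhere.
#' @param fit an `og_fit`.
#' @param estimate passed to [model_parameters()].
#' @return a `raster_grid` of predicted index values in (0, 1).
#' @export
map_index <- function(stack, stand_age, mask = NULL, fit,
                      estimate = "mean") {
  stopifnot(inherits(fit, "og_fit"), inherits(stand_age, "raster_grid"))
  params <- model_parameters(fit, estimate)
  Xs <- prepare_cells(stack, fit)
  tmpl <- stack[[colnames(Xs)[1]]]
  if (!same_geometry(stand_age, tmpl))
    stop("raster geometry mismatch for stand_age")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "raster_grid"))
    if (!same_geometry(mask, tmpl))
      stop("raster geometry mismatch for mask")
  }
  age <- as.vector(stand_age$values)
  coeff <- drop(params$beta1 + Xs %*% params$beta_lin +
                  Xs^2 %*% params$beta_quad)
  idx <- inv_logit(params$beta0 + coeff * age)
  idx[!stats::complete.cases(Xs) | is.na(age)] <- NA
  if (!is.null(mask)) {
    m <- as.vector(mask$values)
    idx[is.na(m) | m <= 0] <- NA
  }
  raster_grid(matrix(idx, nrow(tmpl$values), ncol(tmpl$values)),
              tmpl$cell_size, tmpl$origin, tmpl$nodata)
}
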