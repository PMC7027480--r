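# Canonical structural variable and covariate names used across the package.
STRUCT_VARS <- c("mean_dbh", "sd_dbh", "tree_density", "large_tree_density")
RAW_COVS <- c("snow_depth", "warmth_index", "slope_angle",
              "positive_openness", "catchment_area", "solar_radiation")
MODEL_COVS <- c("snow_depth", "warmth_index", "slope_angle",
                "positive_openness", "log10_catchment_area", "solar_radiation")

#' Rescale one structural variable to a [0, 1] subindex
#'
#' Linearly rescales a structural variable between a young-forest reference
#' value and an old-growth reference value, then clips to \[0, 1\]. The same
#' formula serves variables that decrease with stand age (tree density):
#' there `x_old < x_young` and the linear map reverses sign, so no separate
#' absolute-value branch is needed.
#'
#' @param x numeric vector, the structural variable.
#' @param x_young young-forest reference value (same units as `x`).
#' @param x_old old-growth reference value (same units as `x`).
#' @return numeric vector in \[0, 1\].
#' @examples
#' subindex(30, 20, 40)          # 0.5
#' subindex(600, 800, 400)       # 0.5 for a decreasing variable
#' @export
subindex <- function(x, x_young, x_old) {
  if (!is.finite(x_young) || !is.finite(x_old) || x_young == x_old)
    stop("reference bounds must be finite and distinct (x_young != x_old)")
  s <- (x - x_young) / (x_old - x_young)
  pmin(pmax(s, 0), 1)
}

#' Composite old-growth index of a stand
#'
#' The old-growth index is the arithmetic mean of four subindices computed
#' from mean dbh, SD of dbh, live tree density and large-tree density, each
#' rescaled between young-forest and old-growth reference medians.
#'
#' @param structure named numeric vector or one-row data frame with elements
#'   `mean_dbh`, `sd_dbh`, `tree_density`, `large_tree_density`.
#' @param bounds a `reference_bounds` object (see [reference_bounds()]).
#' @return list with `subindices` (named, length 4) and `value` (their mean).
#' @seealso [og_index_table()] for whole tables of stands.
#' @export
og_index <- function(structure, bounds) {
  stopifnot(inherits(bounds, "reference_bounds"))
  if (is.data.frame(structure)) structure <- unlist(structure[1, , drop = TRUE])
  miss <- setdiff(STRUCT_VARS, names(structure))
  if (length(miss))
    stop("structure is missing variable(s): ", paste(miss, collapse = ", "))
  x <- structure[STRUCT_VARS]
  if (any(!is.finite(x)))
    stop("structure has missing value(s) for: ",
         paste(STRUCT_VARS[!is.finite(x)], collapse = ", "))
  sub <- vapply(STRUCT_VARS, function(v) {
    b <- bounds[bounds$variable == v, ]
    subindex(x[[v]], b$x_young, b$x_old)
  }, numeric(1))
  list(subindices = sub, value = mean(sub))
}

#' Old-growth index for a table of stands
#'
#' @param structures data frame with columns `mean_dbh`, `sd_dbh`,
#'   `tree_density`, `large_tree_density` (other columns are carried through).
#' @param bounds a `reference_bounds` object.
#' @return the input with appended columns `I_1` .. `I_4` (subindices in the
#'   order mean dbh, SD dbh, tree density, large-tree density) and `I_og`.
#' @export
og_index_table <- function(structures, bounds) {
  stopifnot(is.data.frame(structures), inherits(bounds, "reference_bounds"))
  for (i in seq_along(STRUCT_VARS)) {
    v <- STRUCT_VARS[i]
    b <- bounds[bounds$variable == v, ]
    structures[[paste0("I_", i)]] <- subindex(structures[[v]], b$x_young, b$x_old)
  }
  structures$I_og <- rowMeans(structures[paste0("I_", 1:4)])
  structures
}

#' Epsilon rule for boundary proportions
#'
#' Logit regression on proportion data cannot accept exact 0 or 1. Following
#' the minimum-nonzero convention, values of 0 are replaced by the smallest
#' nonzero proportion observed (`eps_low`) and values of 1 by one minus the
#' smallest nonzero complement (`eps_high`), both capped at 0.5.
#'
#' @param values numeric vector of proportions in \[0, 1\].
#' @param symmetric if `TRUE`, a single epsilon — the smaller of the two
#'   boundary values — is used at both ends (the simpler reading of the
#'   minimum-nonzero convention). Default `FALSE` (per-boundary epsilons).
#' @return an `epsilon_rule` list with `eps_low` and `eps_high`.
#' @export
epsilon_from_data <- function(values, symmetric = FALSE) {
  if (any(!is.finite(values)) || any(values < 0 | values > 1))
    stop("values must be proportions in [0, 1]")
  inner <- values[values > 0 & values < 1]
  if (!length(inner))
    stop("all values are exactly 0 or 1; epsilon-adjusted logit is undefined")
  rule <- list(eps_low = min(0.5, min(values[values > 0])),
               eps_high = min(0.5, min(1 - values[values < 1])))
  if (symmetric)
    rule$eps_low <- rule$eps_high <- min(rule$eps_low, rule$eps_high)
  class(rule) <- "epsilon_rule"
  rule
}

#' @export
print.epsilon_rule <- function(x, ...) {
  cat(sprintf("epsilon rule: eps_low = %g (at 0), eps_high = %g (at 1)\n",
              x$eps_low, x$eps_high))
  invisible(x)
}

#' Epsilon-adjusted logit transform
#'
#' Maps a proportion to the logit scale after replacing exact boundary values
#' per the epsilon rule: `p = 0` becomes `eps_low`, `p = 1` becomes
#' `1 - eps_high`; interior values are untouched.
#'
#' @param p numeric vector of proportions in \[0, 1\].
#' @param rule an `epsilon_rule` (see [epsilon_from_data()]).
#' @return numeric vector `log(p'/(1 - p'))`.
#' @export
logit_eps <- function(p, rule) {
  stopifnot(inherits(rule, "epsilon_rule"))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p must lie in [0, 1]")
  p2 <- p
  p2[p == 0] <- rule$eps_low
  p2[p == 1] <- 1 - rule$eps_high
  log(p2 / (1 - p2))
}

#' Inverse logit
#'
#' @param x numeric vector on the logit scale.
#' @return proportions in (0, 1).
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

# plain logit for interior proportions (internal)
logit <- function(p) log(p / (1 - p))
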