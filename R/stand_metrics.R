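#' Structural variables of a stand from its tree list
#'
#' Computes the four structural variables of one plot-by-period tree list:
#' mean dbh and sample SD of dbh of qualifying live trees, live-tree density
#' and large-tree density (stems/ha). Only live trees with dbh strictly
#' above `min_dbh` qualify; large trees are qualifying trees with dbh at or
#' above `large_dbh`.
#'
#' @param trees data frame with columns `plot_id`, `period`, `dbh` (cm) and
#'   `status` (`"live"` or `"dead"`); all rows must share one plot and period.
#' @param plot_area plot area in hectares (default 0.1 ha).
#' @param min_dbh lower dbh cut in cm, strict (default 5: a 5.0 cm stem is
#'   excluded).
#' @param large_dbh large-tree threshold in cm, inclusive (default 40).
#' @return one-row data frame with `mean_dbh`, `sd_dbh`, `tree_density`,
#'   `large_tree_density`. With no qualifying tree the densities are 0 and
#'   mean/SD are `NA`; with a single qualifying tree the SD is 0.
#' @export
compute_stand_structure <- function(trees, plot_area = 0.1,
                                    min_dbh = 5, large_dbh = 40) {
  if (!is.finite(plot_area) || plot_area <= 0)
    stop("plot_area must be positive (hectares)")
  stopifnot(is.data.frame(trees),
            all(c("plot_id", "period", "dbh", "status") %in% names(trees)))
  if (nrow(trees)) {
    if (length(unique(trees$plot_id)) > 1L || length(unique(trees$period)) > 1L)
      stop("all tree records must share one plot_id and period")
    if (any(!is.finite(trees$dbh)) || any(trees$dbh <= 0))
      stop("dbh must be finite and positive")
    if (!all(trees$status %in% c("live", "dead")))
      stop("status must be 'live' or 'dead'")
  }
  d <- trees$dbh[trees$status == "live" & trees$dbh > min_dbh]
  n <- length(d)
  data.frame(
    mean_dbh = if (n) mean(d) else NA_real_,
    sd_dbh = if (n >= 2) stats::sd(d) else if (n == 1) 0 else NA_real_,
    tree_density = n / plot_area,
    large_tree_density = sum(d >= large_dbh) / plot_area
  )
}

#' Screen plot samples by warmth index
#'
#' Retains samples whose warmth index lies inside the screening window
#' (inclusive bounds), preserving input order. Samples with a missing warmth
#' index are dropped with a warning.
#'
#' @param samples data frame with a `warmth_index` column.
#' @param lower,upper window in degree-months (defaults 45 and 180, the
#'   cool- to warm-temperate broad-leaved forest band).
#' @return the retained rows of `samples`.
#' @export
screen_by_warmth <- function(samples, lower = 45, upper = 180) {
  stopifnot(is.data.frame(samples), "warmth_index" %in% names(samples))
  wi <- samples$warmth_index
  if (anyNA(wi))
    warning(sum(is.na(wi)), " sample(s) dropped: missing warmth index")
  keep <- !is.na(wi) & wi >= lower & wi <= upper
  samples[keep, , drop = FALSE]
}

#' Young and old-growth reference bounds for the subindices
#'
#' Per-variable medians of the young reference set (stands up to the young
#' age cutoff) and of the old-growth reference set. Medians of even-sized
#' sets are the midpoint of the two central order statistics.
#'
#' @param young_samples,old_samples data frames with columns `mean_dbh`,
#'   `sd_dbh`, `tree_density`, `large_tree_density`; both non-empty.
#' @return a `reference_bounds` data frame with columns `variable`,
#'   `x_young`, `x_old`.
#' @export
reference_bounds <- function(young_samples, old_samples) {
  stopifnot(is.data.frame(young_samples), is.data.frame(old_samples),
            nrow(young_samples) > 0, nrow(old_samples) > 0)
  for (v in STRUCT_VARS) {
    if (!v %in% names(young_samples) || !v %in% names(old_samples))
      stop("both sets must carry column ", v)
  }
  b <- data.frame(
    variable = STRUCT_VARS,
    x_young = vapply(STRUCT_VARS, function(v)
      stats::median(young_samples[[v]], na.rm = TRUE), numeric(1)),
    x_old = vapply(STRUCT_VARS, function(v)
      stats::median(old_samples[[v]], na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
  eq <- b$x_young == b$x_old
  if (any(eq))
    stop("young and old medians coincide for: ",
         paste(b$variable[eq], collapse = ", "))
  class(b) <- c("reference_bounds", "data.frame")
  b
}

#' @export
print.reference_bounds <- function(x, ...) {
  cat("reference bounds (young / old medians):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Select the young-forest reference set by stand age
#'
#' Young reference stands are those up to `max_age` years old (default 30);
#' whether very young stands (below ~10 y) belong in the reference set is a
#' judgment call, so an optional lower cutoff is exposed too.
#'
#' @param structures data frame with an `age` column.
#' @param max_age inclusive upper age cutoff in years (default 30).
#' @param min_age optional inclusive lower cutoff (default none).
#' @return the young-reference rows of `structures`.
#' @export
select_young_reference <- function(structures, max_age = 30,
                                   min_age = NULL) {
  stopifnot(is.data.frame(structures), "age" %in% names(structures))
  keep <- structures$age <= max_age
  if (!is.null(min_age)) keep <- keep & structures$age >= min_age
  structures[keep & !is.na(structures$age), , drop = FALSE]
}

#' Structural variables for every plot-by-period group of a tree table
#'
#' @param trees data frame of tree records across plots and periods.
#' @param plot_area plot area in hectares applied to every plot.
#' @param ... passed to [compute_stand_structure()].
#' @return data frame with one row per plot-by-period combination.
#' @export
stand_structure_table <- function(trees, plot_area = 0.1, ...) {
  stopifnot(is.data.frame(trees))
  key <- interaction(trees$plot_id, trees$period, drop = TRUE)
  parts <- lapply(split(trees, key), function(g) {
    cbind(plot_id = g$plot_id[1], period = g$period[1],
          compute_stand_structure(g, plot_area = plot_area, ...))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
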