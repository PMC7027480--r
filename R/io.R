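# Delimited-table dialect: tab-separated, one header line, no quoting.
# Stand ages are integer years since disturbance (>= 1); tree dbh is in cm.

#' Read a delimited table with strict validation
#'
#' Tab-separated with a header line. Every row must carry exactly the
#' header's field count; a malformed row aborts with its line number.
#'
#' @param path file path.
#' @param required optional character vector of columns that must exist.
#' @return data frame with types inferred per column.
#' @export
read_ogdex_table <- function(path, required = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop(path, ": empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ncol <- length(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf != ncol)) {
    bad <- which(nf != ncol)[1]
    stop(path, " line ", bad + 1, ": expected ", ncol, " fields, found ",
         nf[bad])
  }
  out <- as.data.frame(lapply(seq_len(ncol), function(j)
    utils::type.convert(vapply(cells, `[[`, character(1), j), as.is = TRUE)),
    col.names = header, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(out))
    if (length(miss))
      stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  out
}

#' Write a delimited table
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ogdex_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tree table
#'
#' Expected columns: `plot_id`, `period`, `dbh_cm`, `status`; `dbh_cm` is
#' renamed `dbh` internally.
#'
#' @param path file path.
#' @return data frame of tree records.
#' @export
read_tree_table <- function(path) {
  df <- read_ogdex_table(path, required = c("plot_id", "period", "dbh_cm",
                                            "status"))
  names(df)[names(df) == "dbh_cm"] <- "dbh"
  df
}

#' Write a tree table
#'
#' @param trees data frame with `plot_id`, `period`, `dbh`, `status`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_table <- function(trees, path) {
  out <- trees
  names(out)[names(out) == "dbh"] <- "dbh_cm"
  write_ogdex_table(out, path)
}

#' Persist posterior chains and fit metadata
#'
#' Chains go to one tab-separated file per chain (one row per draw, one
#' column per parameter); seeds, priors, the epsilon rule, the covariate
#' scaler, clamping quantiles, burn-in and the convergence report go to a
#' JSON sidecar.
#'
#' @param fit an `og_fit`.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "og_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chain_paths <- vapply(seq_along(fit$chains), function(i) {
    p <- file.path(dir, sprintf("chain_%d.tsv", i))
    write_ogdex_table(as.data.frame(fit$chains[[i]]), p)
    p
  }, character(1))
  summary_path <- file.path(dir, "posterior_summary.tsv")
  write_ogdex_table(fit$summary, summary_path)
  meta <- list(
    response = fit$response,
    n_samples = fit$n, n_plots = fit$n_plots,
    n_chains = length(fit$chains),
    iterations = nrow(fit$chains[[1]]),
    burn_in = fit$config$burn_in,
    seed = fit$config$seed,
    priors = list(var_beta = fit$config$prior_var_beta,
                  shape = fit$config$prior_shape,
                  rate = fit$config$prior_rate),
    epsilon = unclass(fit$epsilon),
    scaler = list(center = as.list(fit$scaler$center),
                  scale = as.list(fit$scaler$scale)),
    clamp = as.data.frame(unclass(fit$clamp)),
    convergence = list(rhat = as.list(fit$convergence$rhat),
                       converged = fit$convergence$converged,
                       extension_rounds = fit$convergence$extension_rounds))
  meta_path <- file.path(dir, "fit_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(chains = chain_paths, summary = summary_path,
                 metadata = meta_path))
}
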