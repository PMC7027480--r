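#' Construct a raster grid
#'
#' Minimal georeferenced 2-D field used for DEMs, covariate stacks and
#' prediction maps. Values are stored as a matrix in north-up row-major
#' order: row 1 is the northernmost row. Missing cells are `NA` internally
#' and written as the nodata sentinel on disk.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell edge length in metres.
#' @param origin numeric length 2, (x, y) of the lower-left corner of the
#'   lower-left cell.
#' @param nodata sentinel written to disk for `NA` cells (default -9999).
#' @return a `raster_grid` object.
#' @export
raster_grid <- function(values, cell_size, origin = c(0, 0), nodata = -9999) {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0,
            length(origin) == 2)
  g <- list(values = values, cell_size = as.numeric(cell_size),
            origin = as.numeric(origin), nodata = as.numeric(nodata))
  class(g) <- "raster_grid"
  g
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  cat(sprintf("  values: [%g, %g], %d nodata cell(s)\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Read an ESRI ASCII grid
#'
#' @param path file path to a `.asc` grid.
#' @return a `raster_grid`; nodata cells become `NA`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path, ": needs ",
         paste(need, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop(path, ": expected ", hdr$nrows, " data rows, found ", length(body))
  rows <- lapply(seq_along(body), function(r) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(vals) != hdr$ncols || anyNA(vals))
      stop(path, " line ", i - 1 + r, ": expected ", hdr$ncols,
           " numeric fields")
    vals
  })
  m <- do.call(rbind, rows)
  m[m == nodata] <- NA
  raster_grid(m, hdr$cellsize, origin = c(xll, yll), nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a `raster_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$origin[1]),
    sprintf("yllcorner %.10g", grid$origin[2]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(v, 1, function(r) paste(format(r, scientific = FALSE,
                                               trim = TRUE, digits = 15),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
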