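# Matrix shift helpers. Row 1 is the northern edge; x grows east (columns),
# y grows north (decreasing row index).

shift_rep <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

shift_na <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  sr1 <- max(1, 1 + dr); sr2 <- min(nr, nr + dr)
  sc1 <- max(1, 1 + dc); sc2 <- min(nc, nc + dc)
  if (sr1 <= sr2 && sc1 <= sc2)
    out[(sr1:sr2) - dr, (sc1:sc2) - dc] <- m[sr1:sr2, sc1:sc2, drop = FALSE]
  out
}

#' Warmth index from monthly mean temperatures
#'
#' Kira's thermal sum: over the months whose mean temperature exceeds 5 deg C,
#' the sum of (temperature - 5). Units are degree-months.
#'
#' @param monthly_means numeric vector of exactly 12 monthly mean
#'   temperatures in deg C.
#' @return warmth index (>= 0).
#' @export
warmth_index <- function(monthly_means) {
  if (length(monthly_means) != 12 || any(!is.finite(monthly_means)))
    stop("monthly_means must be 12 finite temperatures")
  sum(pmax(monthly_means - 5, 0))
}

# Horn 3x3 gradient; edge cells fall back to one-sided differences via
# index clamping with the denominator scaled to the actual span.
horn_gradient <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3) stop("DEM must be at least 3 x 3")
  cs <- dem$cell_size
  spanx <- matrix(rep(pmin(seq_len(ncol(z)) + 1, ncol(z)) -
                        pmax(seq_len(ncol(z)) - 1, 1),
                      each = nrow(z)), nrow(z)) * cs
  spany <- matrix(rep(pmin(seq_len(nrow(z)) + 1, nrow(z)) -
                        pmax(seq_len(nrow(z)) - 1, 1),
                      times = ncol(z)), nrow(z)) * cs
  sh <- function(dr, dc) shift_rep(z, dr, dc)
  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (4 * spanx)
  gy <- ((sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1)) -
           (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1))) / (4 * spany)
  bad <- is.na(z)
  for (dr in -1:1) for (dc in -1:1)
    bad <- bad | is.na(shift_rep(z, dr, dc))
  gx[bad] <- NA; gy[bad] <- NA
  list(gx = gx, gy = gy)
}

#' Slope angle from a DEM
#'
#' Horn 3x3 finite-difference gradient; edge cells use one-sided
#' differences. Any nodata cell in the 3x3 window yields nodata.
#'
#' @param dem a `raster_grid` DEM (elevations in metres).
#' @return a `raster_grid` of slope angles in degrees, in \[0, 90).
#' @export
slope_angle <- function(dem) {
  g <- horn_gradient(dem)
  s <- atan(sqrt(g$gx^2 + g$gy^2)) * 180 / pi
  raster_grid(s, dem$cell_size, dem$origin, dem$nodata)
}

#' Positive terrain openness
#'
#' For each cell the terrain horizon is scanned along `n_azimuths` evenly
#' spaced azimuths out to `radius`: along each azimuth the maximum elevation
#' angle to any sampled cell is found, and openness is the mean over azimuths
#' of (90 degrees - that angle). A flat plane gives exactly 90; convex
#' terrain (ridges) more, concave terrain (valleys) less. Azimuths leaving
#' the grid immediately contribute 90 (no terrain obstructs them).
#'
#' @param dem a `raster_grid` DEM.
#' @param radius scan radius in metres (default 200; must be >= one cell).
#' @param n_azimuths number of azimuths (default 8; minimum 4).
#' @return a `raster_grid` of openness in degrees.
#' @export
positive_openness <- function(dem, radius = 200, n_azimuths = 8) {
  stopifnot(inherits(dem, "raster_grid"))
  cs <- dem$cell_size
  if (radius < cs) stop("radius must be at least one cell size")
  if (n_azimuths < 4) stop("need at least 4 azimuths")
  z <- dem$values
  az <- 2 * pi * (seq_len(n_azimuths) - 1) / n_azimuths
  nsteps <- floor(radius / cs)
  acc <- matrix(0, nrow(z), ncol(z))
  for (a in az) {
    tanmax <- matrix(-Inf, nrow(z), ncol(z))
    prev <- c(0L, 0L)
    for (s in seq_len(nsteps)) {
      dc <- as.integer(round(s * sin(a)))
      dr <- as.integer(round(-s * cos(a)))    # north = decreasing row
      if ((dc == 0L && dr == 0L) || (dc == prev[1] && dr == prev[2])) next
      prev <- c(dc, dr)
      dist <- cs * sqrt(dc^2 + dr^2)
      if (dist > radius) break
      tanmax <- pmax(tanmax, (shift_na(z, dr, dc) - z) / dist, na.rm = TRUE)
    }
    tanmax[is.infinite(tanmax)] <- 0
    acc <- acc + (90 - atan(tanmax) * 180 / pi)
  }
  out <- acc / n_azimuths
  out[is.na(z)] <- NA
  raster_grid(out, cs, dem$origin, dem$nodata)
}

# D8 neighbor offsets in the fixed tie-break order E, SE, S, SW, W, NW, N, NE
D8_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DR <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)

# Iterative depression filling (Planchon-Darboux): water level W starts at
# the surface on open-boundary cells and +Inf elsewhere, then relaxes to the
# lowest drainable level with an eps gradient so no flats remain.
fill_depressions <- function(z, eps = 1e-6) {
  nr <- nrow(z); nc <- ncol(z)
  open <- matrix(FALSE, nr, nc)
  open[1, ] <- open[nr, ] <- TRUE
  open[, 1] <- open[, nc] <- TRUE
  if (anyNA(z))
    for (k in 1:8) open <- open | is.na(shift_na(z, D8_DR[k], D8_DC[k]))
  open <- open & !is.na(z)
  w <- matrix(Inf, nr, nc)
  w[open] <- z[open]
  zi <- z
  zi[is.na(z)] <- Inf
  repeat {
    nmin <- matrix(Inf, nr, nc)
    for (k in 1:8) {
      s <- shift_na(w, D8_DR[k], D8_DC[k])
      s[is.na(s)] <- Inf
      nmin <- pmin(nmin, s)
    }
    cand <- pmax(zi, nmin + eps)
    upd <- cand < w & !is.na(z)
    if (!any(upd)) break
    w[upd] <- cand[upd]
  }
  w[is.na(z)] <- NA
  w
}

#' D8 catchment area from a DEM
#'
#' Depressions are filled internally (iterative Planchon-Darboux with a
#' small epsilon gradient), flow is routed to the steepest of the eight
#' neighbors with ties broken in the fixed order E, SE, S, SW, W, NW, N, NE,
#' and the contributing area of a cell is (number of upslope cells + 1)
#' times the cell area, so every cell carries at least its own area. Cells
#' with no lower in-grid neighbor drain off the grid.
#'
#' @param dem a `raster_grid` DEM.
#' @return a `raster_grid` of catchment areas in square metres.
#' @export
catchment_area <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  if (all(is.na(z))) stop("DEM is entirely nodata")
  cs <- dem$cell_size
  nr <- nrow(z); nc <- ncol(z)
  w <- fill_depressions(z)
  # receiver of each cell (matrix index), 0 = drains off grid, NA = nodata
  recv <- matrix(0L, nr, nc)
  best <- matrix(0, nr, nc)          # best positive slope so far
  wi <- w
  wi[is.na(w)] <- -Inf               # nodata never receives flow
  for (k in 1:8) {
    dist <- cs * sqrt(D8_DC[k]^2 + D8_DR[k]^2)
    nb <- shift_na(wi, D8_DR[k], D8_DC[k])
    sl <- (w - nb) / dist
    sl[is.na(sl) | is.infinite(sl)] <- -Inf
    take <- sl > best                # strict: earlier order wins ties
    if (any(take, na.rm = TRUE)) {
      idx <- which(take)
      rr <- (idx - 1L) %% nr + 1L + D8_DR[k]
      cc <- (idx - 1L) %/% nr + 1L + D8_DC[k]
      recv[idx] <- (cc - 1L) * nr + rr
      best[idx] <- sl[idx]
    }
  }
  acc <- rep(1, nr * nc)
  acc[is.na(as.vector(w))] <- 0
  ord <- order(as.vector(w), decreasing = TRUE, na.last = TRUE)
  for (i in ord) {
    r <- recv[i]
    if (!is.na(r) && r > 0L) acc[r] <- acc[r] + acc[i]
  }
  out <- matrix(acc * cs^2, nr, nc)
  out[is.na(z)] <- NA
  raster_grid(out, cs, dem$origin, dem$nodata)
}

# Annual clear-sky direct insolation sums for surface normal components
# (ne, nn, nu): returns list(surface, flat) of time-integrated cosine sums.
solar_sums <- function(latitude, ne, nn, nu, day_step = 1, hour_step = 1) {
  phi <- latitude * pi / 180
  surf <- 0 * nu
  flat <- 0
  for (day in seq(1, 365, by = day_step)) {
    delta <- (23.45 * pi / 180) * sin(2 * pi * (284 + day) / 365)
    for (h in seq(hour_step / 2, 24 - hour_step / 2, by = hour_step)) {
      H <- (15 * (h - 12)) * pi / 180
      up <- sin(delta) * sin(phi) + cos(delta) * cos(H) * cos(phi)
      if (up <= 0) next
      east <- -cos(delta) * sin(H)
      north <- sin(delta) * cos(phi) - cos(delta) * cos(H) * sin(phi)
      surf <- surf + pmax(0, ne * east + nn * north + nu * up)
      flat <- flat + up
    }
  }
  list(surface = surf, flat = flat)
}

#' Relative annual potential solar radiation of a DEM
#'
#' Clear-sky annual potential direct insolation on each cell's slope/aspect,
#' integrated with a daily loop and hourly steps and normalized by the
#' flat-surface value at the same latitude, so flat cells are exactly 1.
#' No horizon shading or atmospheric transmission is modeled.
#'
#' @param dem a `raster_grid` DEM.
#' @param latitude site latitude in degrees (|latitude| <= 66.5).
#' @param day_step,hour_step integration steps in days and hours.
#' @return a `raster_grid` of dimensionless relative insolation.
#' @export
potential_solar_radiation <- function(dem, latitude, day_step = 1,
                                      hour_step = 1) {
  if (abs(latitude) > 66.5)
    stop("polar latitudes (|latitude| > 66.5) are not supported")
  g <- horn_gradient(dem)
  slope <- atan(sqrt(g$gx^2 + g$gy^2))
  aspect <- atan2(-g$gx, -g$gy)        # azimuth of downslope, from north
  ne <- sin(slope) * sin(aspect)
  nn <- sin(slope) * cos(aspect)
  nu <- cos(slope)
  ss <- solar_sums(latitude, ne, nn, nu, day_step, hour_step)
  out <- ss$surface / ss$flat
  out[is.na(g$gx)] <- NA
  raster_grid(out, dem$cell_size, dem$origin, dem$nodata)
}

#' Relative annual potential solar radiation for one slope/aspect
#'
#' @param latitude degrees (|latitude| <= 66.5).
#' @param slope slope angle in degrees.
#' @param aspect downslope azimuth in degrees from north (180 = south-facing).
#' @param day_step,hour_step integration steps.
#' @return dimensionless relative insolation (1 for a flat surface).
#' @export
potential_solar_point <- function(latitude, slope, aspect,
                                  day_step = 1, hour_step = 1) {
  if (abs(latitude) > 66.5)
    stop("polar latitudes (|latitude| > 66.5) are not supported")
  s <- slope * pi / 180; a <- aspect * pi / 180
  ss <- solar_sums(latitude, sin(s) * sin(a), sin(s) * cos(a), cos(s),
                   day_step, hour_step)
  ss$surface / ss$flat
}
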