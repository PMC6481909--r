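EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (haversine) distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return Distance in kilometres (Earth radius 6371.0088 km).
#' @export
geodesic_distance <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90]")
  }
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

population_coordinates <- function(info) {
  ing <- info[info$role == "ingroup", , drop = FALSE]
  ing <- ing[!duplicated(ing$population_id), , drop = FALSE]
  data.frame(population_id = ing$population_id,
             lat = ing$latitude, lon = ing$longitude,
             stringsAsFactors = FALSE)
}

#' Build a regular lat/lon search grid
#'
#' Covers the ingroup populations' bounding box expanded by
#' `padding_fraction` of its span on each side (the broadened search area
#' used when the origin may lie near or beyond the sampled region), clipped
#' to valid coordinates.
#'
#' @param info a `sample_info` data.frame.
#' @param spacing_deg grid spacing in degrees (default 0.25).
#' @param padding_fraction fraction of each bbox span added on each side
#'   (default 0.5).
#' @return An `origin_grid`: data.frame `grid` (lat, lon; lat varies
#'   slowest), axis vectors, the population bbox and settings.
#' @export
make_grid <- function(info, spacing_deg = 0.25, padding_fraction = 0.5) {
  stopifnot(spacing_deg > 0, padding_fraction >= 0)
  pc <- population_coordinates(info)
  if (nrow(unique(pc[, c("lat", "lon")])) < 2L) {
    stop("degenerate extent: all populations at one coordinate")
  }
  bbox <- c(lat_min = min(pc$lat), lat_max = max(pc$lat),
            lon_min = min(pc$lon), lon_max = max(pc$lon))
  lat_span <- bbox["lat_max"] - bbox["lat_min"]
  lon_span <- bbox["lon_max"] - bbox["lon_min"]
  lat_lo <- max(-90, bbox["lat_min"] - padding_fraction * lat_span)
  lat_hi <- min(90, bbox["lat_max"] + padding_fraction * lat_span)
  lon_lo <- max(-180, bbox["lon_min"] - padding_fraction * lon_span)
  lon_hi <- min(180, bbox["lon_max"] + padding_fraction * lon_span)
  lats <- seq(lat_lo, lat_hi, by = spacing_deg)
  lons <- seq(lon_lo, lon_hi, by = spacing_deg)
  grid <- expand.grid(lon = lons, lat = lats,
                      KEEP.OUT.ATTRS = FALSE)[, c("lat", "lon")]
  structure(list(grid = grid, lats = lats, lons = lons, bbox = bbox,
                 spacing_deg = spacing_deg,
                 padding_fraction = padding_fraction),
            class = "origin_grid")
}

# defined unordered pairs of a psi matrix, as index vectors + psi values
psi_pairs <- function(psi) {
  P <- length(psi$populations)
  ij <- which(upper.tri(psi$psi), arr.ind = TRUE)
  ok <- psi$n_informative[ij] > 0L & !is.na(psi$psi[ij])
  list(i = ij[ok, 1L], j = ij[ok, 2L], psi = psi$psi[ij][ok])
}

#' Time-difference-of-arrival fit at a candidate origin
#'
#' For each defined unordered population pair (i, j) forms the distance
#' difference from the candidate origin, Delta d = d(origin, j) -
#' d(origin, i), and fits psi = q * Delta d by least squares through the
#' origin (psi of a population with itself is 0 at Delta d = 0 by
#' construction, so no intercept).
#'
#' @param origin_lat,origin_lon candidate origin in decimal degrees.
#' @param psi a `psi_matrix`.
#' @param info a `sample_info` data.frame.
#' @return List with `slope` (psi per km), `rss`, `r2` and `n_pairs`. When
#'   the origin is equidistant from all populations the fit is undefined:
#'   `slope = NA`, `rss = Inf`.
#' @export
tdoa_fit_at <- function(origin_lat, origin_lon, psi, info) {
  pairs <- psi_pairs(psi)
  if (length(pairs$psi) < 3L) stop("need >=3 defined psi pairs")
  pc <- population_coordinates(info)
  pc <- pc[match(psi$populations, pc$population_id), ]
  d <- geodesic_distance(origin_lat, origin_lon, pc$lat, pc$lon)
  dd <- d[pairs$j] - d[pairs$i]
  fit_through_origin(pairs$psi, dd)
}

fit_through_origin <- function(y, x) {
  tss <- sum(y^2)
  sxx <- sum(x^2)
  if (tss == 0) {
    return(list(slope = 0, rss = 0, r2 = 0, n_pairs = length(y)))
  }
  if (sxx == 0) {
    return(list(slope = NA_real_, rss = Inf, r2 = NA_real_,
                n_pairs = length(y)))
  }
  sxy <- sum(x * y)
  slope <- sxy / sxx
  rss <- max(0, tss - sxy^2 / sxx)  # guard cancellation at a perfect fit
  list(slope = slope, rss = rss, r2 = 1 - rss / tss, n_pairs = length(y))
}

# cells x populations distance matrix
grid_pop_distances <- function(grid, pc) {
  ncell <- nrow(grid$grid)
  D <- matrix(0, ncell, nrow(pc))
  for (p in seq_len(nrow(pc))) {
    D[, p] <- geodesic_distance(grid$grid$lat, grid$grid$lon,
                                pc$lat[p], pc$lon[p])
  }
  D
}

# vectorized through-origin fit over all cells; returns slope/rss/r2 vectors
scan_cells <- function(D, pairs) {
  dd <- D[, pairs$j, drop = FALSE] - D[, pairs$i, drop = FALSE]
  tss <- sum(pairs$psi^2)
  sxx <- rowSums(dd^2)
  sxy <- as.vector(dd %*% pairs$psi)
  if (tss == 0) {
    n <- nrow(D)
    return(list(slope = rep(0, n), rss = rep(0, n), r2 = rep(0, n)))
  }
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- ifelse(sxx > 0, pmax(0, tss - sxy^2 / sxx), Inf)
  r2 <- ifelse(sxx > 0, 1 - rss / tss, NA_real_)
  list(slope = slope, rss = rss, r2 = r2)
}

#' Grid search for the expansion origin
#'
#' Evaluates the TDOA fit at every grid cell and returns the full fit
#' surface (for heat-mapping) plus the best cell, the one minimizing the
#' residual sum of squares (equivalently maximizing r2). Ties are broken by
#' the first cell in row-major order and logged; a flag is raised when the
#' best cell lies on the grid boundary, where origin detection is less
#' reliable.
#'
#' @param psi a `psi_matrix`.
#' @param info a `sample_info` data.frame.
#' @param grid an `origin_grid` from [make_grid()].
#' @return An `origin_surface`: `grid` (lat, lon, rss, r2, slope),
#'   `best` (lat, lon, rss, r2, slope), `boundary`, `tie`, `bbox`,
#'   settings, and `pvalue` (NA until [test_expansion_vs_ibd()] is run).
#' @export
origin_scan <- function(psi, info, grid) {
  pairs <- psi_pairs(psi)
  if (!length(pairs$psi)) stop("no defined psi pairs")
  pc <- population_coordinates(info)
  pc <- pc[match(psi$populations, pc$population_id), ]
  D <- grid_pop_distances(grid, pc)
  fits <- scan_cells(D, pairs)
  g <- grid$grid
  g$rss <- fits$rss; g$r2 <- fits$r2; g$slope <- fits$slope
  best_idx <- which.min(g$rss)  # first minimum in row-major order
  tie <- sum(g$rss == g$rss[best_idx]) > 1L
  if (tie) message("origin_scan: tied best cells; first in row-major order kept")
  best <- as.list(g[best_idx, c("lat", "lon", "rss", "r2", "slope")])
  boundary <- best$lat %in% range(grid$lats) | best$lon %in% range(grid$lons)
  if (boundary) {
    message("origin_scan: best cell on the grid boundary; ",
            "origin accuracy is reduced near edges")
  }
  structure(list(grid = g, best = best, boundary = boundary, tie = tie,
                 bbox = grid$bbox, spacing_deg = grid$spacing_deg,
                 padding_fraction = grid$padding_fraction,
                 pvalue = NA_real_),
            class = "origin_surface")
}

#' @export
print.origin_surface <- function(x, ...) {
  cat(sprintf(paste0("origin_surface: best origin (%.3f, %.3f), ",
                     "slope %.3g psi/km, r2 %.3f%s\n"),
              x$best$lat, x$best$lon, x$best$slope, x$best$r2,
              if (is.na(x$pvalue)) "" else sprintf(", p = %.4g", x$pvalue)))
  invisible(x)
}

#' Permutation test of expansion against isolation by distance
#'
#' The observed statistic is the r2 of the best TDOA fit over the grid. The
#' null distribution is built by permuting the population-to-coordinate
#' assignment (psi held fixed), which destroys geographic signal while
#' preserving the psi distribution, as under pure isolation by distance no
#' origin should explain psi much better than a relabelled geography.
#' p = (1 + #\{T_perm >= T_obs\}) / (1 + n_perm).
#'
#' @param psi a `psi_matrix`.
#' @param info a `sample_info` data.frame.
#' @param grid an `origin_grid`.
#' @param n_perm number of permutations (>= 99; default 199).
#' @param seed integer seed.
#' @return List with `pvalue`, `T_obs`, `T_perm`, `n_perm`, `seed`, and
#'   `underpowered` (TRUE with fewer than 4 populations).
#' @export
test_expansion_vs_ibd <- function(psi, info, grid, n_perm = 199L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  pairs <- psi_pairs(psi)
  if (!length(pairs$psi)) stop("no defined psi pairs")
  P <- length(psi$populations)
  underpowered <- P < 4L
  if (underpowered) warning("fewer than 4 populations: test is underpowered")
  pc <- population_coordinates(info)
  pc <- pc[match(psi$populations, pc$population_id), ]
  D <- grid_pop_distances(grid, pc)

  best_r2 <- function(Dm) {
    f <- scan_cells(Dm, pairs)
    m <- suppressWarnings(max(f$r2, na.rm = TRUE))
    if (!is.finite(m)) 0 else m
  }
  T_obs <- best_r2(D)
  # draw permutations in sorted-label order so the p-value does not depend
  # on the order populations were supplied in
  s <- order(psi$populations)
  set.seed(as.integer(seed))
  T_perm <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(P)
    idx <- integer(P)
    idx[s] <- s[perm]
    best_r2(D[, idx, drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(T_perm >= T_obs)) / (1 + n_perm)
  list(pvalue = p, T_obs = T_obs, T_perm = T_perm,
       n_perm = as.integer(n_perm), seed = as.integer(seed),
       underpowered = underpowered)
}
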