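# Landscape quantification around study sites: categorical land-cover grids,
# circular buffer extraction (pixel-centre inclusion rule), urban index,
# effective number of land covers (Hill number, q = 1), and great-circle
# pair distances.

EARTH_RADIUS_KM <- 6371.0088

#' Read an ESRI ASCII categorical grid
#'
#' Parses the plain-text ASCII grid format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/optional `NODATA_value` header, then rows from
#' the top of the grid down).
#'
#' @param path File path.
#' @param crs `"lonlat"` if the georeference is in decimal degrees (buffer
#'   radii are then geodesic metres) or `"planar"` (grid units are metres).
#' @return A `landcover_grid` list: integer matrix `values`
#'   (rows = grid rows, top row first), `xll`, `yll`, `cellsize`, `crs`.
#' @export
read_ascii_grid <- function(path, crs = c("planar", "lonlat")) {
  crs <- match.arg(crs)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  landcover_grid(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize, crs = crs)
}

#' Construct a land-cover grid object
#'
#' @param values Integer category matrix, top grid row first.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Pixel width in georeference units.
#' @param crs `"planar"` (units are metres) or `"lonlat"` (decimal
#'   degrees).
#' @return A `landcover_grid` list.
#' @export
landcover_grid <- function(values, xll = 0, yll = 0, cellsize = 1,
                           crs = c("planar", "lonlat")) {
  crs <- match.arg(crs)
  structure(list(values = values, xll = xll, yll = yll, cellsize = cellsize,
                 crs = crs),
            class = "landcover_grid")
}

#' Write a land-cover grid as an ESRI ASCII file
#'
#' @param grid A `landcover_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
               paste("xllcorner", format(grid$xll, digits = 12)),
               paste("yllcorner", format(grid$yll, digits = 12)),
               paste("cellsize", format(grid$cellsize, digits = 12)),
               "NODATA_value -9999"), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Pixel-centre coordinates of a grid. Row 1 of `values` is the TOP row.
pixel_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  x <- grid$xll + (seq_len(nc) - 0.5) * grid$cellsize
  y <- grid$yll + (nr - seq_len(nr) + 0.5) * grid$cellsize
  list(x = x, y = y)
}

#' Count land-cover categories within a circular buffer
#'
#' Counts pixels whose centres fall within the circle of the given radius
#' around a point. On `"lonlat"` grids the inclusion test uses per-pixel
#' great-circle distance (geodesic circle, no projection needed); on
#' `"planar"` grids Euclidean distance in grid units (metres).
#'
#' @param grid A `landcover_grid`.
#' @param point `c(x, y)` (`c(lon, lat)` for `"lonlat"` grids); must lie
#'   within the grid extent.
#' @param radius Buffer radius in metres; at least half a pixel width.
#' @return Named integer vector of counts per category present in the
#'   buffer.
#' @export
buffer_extract <- function(grid, point, radius) {
  cs <- grid$cellsize
  unit <- if (grid$crs == "lonlat") 111320 * cs else cs  # rough metres/pixel
  if (radius < unit / 2) stop("radius smaller than half a pixel")
  pc <- pixel_centres(grid)
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  xmin <- grid$xll; xmax <- grid$xll + nc * cs
  ymin <- grid$yll; ymax <- grid$yll + nr * cs
  if (point[1] < xmin || point[1] > xmax || point[2] < ymin || point[2] > ymax)
    stop("point outside raster extent")
  if (grid$crs == "lonlat") {
    d <- outer(pc$y, pc$x, function(y, x) {
      1000 * great_circle_km(point[1], point[2], x, y)
    })
    inside <- d <= radius
  } else {
    dx2 <- (pc$x - point[1])^2
    dy2 <- (pc$y - point[2])^2
    inside <- outer(dy2, dx2, "+") <= radius^2
  }
  vals <- grid$values[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("empty buffer")
  counts <- table(vals)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Effective number of land covers (Hill number, q = 1)
#'
#' The exponential of the Shannon-Wiener diversity of the category
#' proportions: equals the number of categories when they are equally
#' common, and 1 for a single category.
#'
#' @param counts Non-negative category counts, not all zero.
#' @return Effective number of categories (>= 1).
#' @export
effective_landcovers <- function(counts) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("all-zero counts")
  p <- counts[counts > 0] / total
  exp(-sum(p * log(p)))
}

#' Urban index of a buffer
#'
#' The proportion of buffer pixels classified as an urban land-cover
#' category.
#'
#' @param counts Named category counts (see [buffer_extract()]).
#' @param urban_categories Category labels counted as urban.
#' @return Proportion in `[0, 1]`.
#' @export
urban_index <- function(counts, urban_categories) {
  total <- sum(counts)
  if (total == 0) stop("all-zero counts")
  sum(counts[names(counts) %in% as.character(urban_categories)]) / total
}

#' Multi-scale landscape profiles for study sites
#'
#' Runs [buffer_extract()] for each site over a ladder of radii (default
#' 250 m to 5000 m in 250 m steps) and derives the urban index and
#' effective number of land covers at each scale. Per-site errors (outside
#' extent, empty buffer) are collected, not fatal.
#'
#' @param grid A `landcover_grid`.
#' @param sites `data.frame` with columns `site_id`, `x`, `y`.
#' @param radii Buffer radii in metres.
#' @param urban_categories Category labels counted as urban.
#' @return `data.frame` keyed by (`site_id`, `radius`) with `n_pixels`,
#'   `urban_index`, `effective_landcovers`, and the per-category counts as
#'   an attribute `"counts"`; failed extractions recorded in attribute
#'   `"errors"`.
#' @export
multiscale_profile <- function(grid, sites, radii = seq(250, 5000, by = 250),
                               urban_categories = "1") {
  rows <- list()
  counts_list <- list()
  errors <- list()
  for (i in seq_len(nrow(sites))) {
    for (r in radii) {
      key <- paste0(sites$site_id[i], "@", r)
      res <- tryCatch(buffer_extract(grid, c(sites$x[i], sites$y[i]), r),
                      error = function(e) e)
      if (inherits(res, "error")) {
        errors[[key]] <- conditionMessage(res)
        next
      }
      counts_list[[key]] <- res
      rows[[key]] <- data.frame(
        site_id = sites$site_id[i], radius = r, n_pixels = sum(res),
        urban_index = urban_index(res, urban_categories),
        effective_landcovers = effective_landcovers(res),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- counts_list
  attr(out, "errors") <- errors
  out
}

# Haversine great-circle distance in km on a sphere of radius
# EARTH_RADIUS_KM.
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Great-circle distance between two sites
#'
#' Haversine distance on a spherical Earth of radius 6371.0088 km.
#'
#' @param p1,p2 `c(lon, lat)` in decimal degrees.
#' @return Distance in km.
#' @export
pair_distance <- function(p1, p2) {
  if (abs(p1[2]) > 90 || abs(p2[2]) > 90) stop("latitude outside [-90, 90]")
  if (abs(p1[1]) > 180 || abs(p2[1]) > 180) stop("longitude outside [-180, 180]")
  great_circle_km(p1[1], p1[2], p2[1], p2[2])
}

#' Build pair-level spatial moderators
#'
#' Joins the urban and non-urban site profiles of each population pair at
#' each radius into the urban-index and heterogeneity differences
#' (urban minus non-urban) used as meta-regression moderators, plus the
#' pair distance where coordinates are available.
#'
#' @param profiles Output of [multiscale_profile()].
#' @param pairs `data.frame` with columns `population_pair_id`,
#'   `site_urban`, `site_nonurban` (site ids), optional `lon_urban`,
#'   `lat_urban`, `lon_nonurban`, `lat_nonurban`.
#' @return `data.frame` keyed by (`population_pair_id`, `radius`) with
#'   `d_urban_index`, `d_heterogeneity`, `pair_distance_km`; rows only
#'   where both sites have a profile at that radius.
#' @export
pair_moderators <- function(profiles, pairs) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pu <- profiles[profiles$site_id == pairs$site_urban[i], , drop = FALSE]
    pn <- profiles[profiles$site_id == pairs$site_nonurban[i], , drop = FALSE]
    shared <- intersect(pu$radius, pn$radius)
    if (length(shared) == 0) next
    dist_km <- if (all(c("lon_urban", "lat_urban", "lon_nonurban", "lat_nonurban")
                       %in% names(pairs))) {
      pair_distance(c(pairs$lon_urban[i], pairs$lat_urban[i]),
                    c(pairs$lon_nonurban[i], pairs$lat_nonurban[i]))
    } else NA_real_
    for (r in shared) {
      rows[[paste0(i, "@", r)]] <- data.frame(
        population_pair_id = pairs$population_pair_id[i], radius = r,
        d_urban_index = pu$urban_index[pu$radius == r] -
          pn$urban_index[pn$radius == r],
        d_heterogeneity = pu$effective_landcovers[pu$radius == r] -
          pn$effective_landcovers[pn$radius == r],
        pair_distance_km = dist_km, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test whether paired urban sites are more urban than non-urban sites
#'
#' Intercept-only linear model of the per-pair urban-index difference at
#' one radius (equivalently a one-sample mean with `SE = sd/sqrt(n)`).
#'
#' @param d_urban_index Per-pair urban-index differences (urban minus
#'   non-urban) at a single radius; at least 2 values.
#' @return List with `estimate`, `se`, `ci_lower`, `ci_upper`, `n`.
#' @export
urban_index_difference_test <- function(d_urban_index) {
  n <- length(d_urban_index)
  if (n < 2) stop("need at least 2 pairs")
  est <- mean(d_urban_index)
  se <- stats::sd(d_urban_index) / sqrt(n)
  ci <- wald_ci(est, se)
  list(estimate = est, se = se, ci_lower = ci$lower, ci_upper = ci$upper, n = n)
}
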