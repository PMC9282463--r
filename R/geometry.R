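#' Configuration for the synthetic study geometry
#'
#' Parameters describing a Pomo/Jabuka-like survey domain: a convex bounding
#' polygon in decimal degrees, an analytic bathymetry made of a flat shelf
#' plus Gaussian-bump depressions ("pits"), a west/east split meridian, and
#' three nested management zones (A = innermost ban zone, B and C = buffers)
#' centred on the deepest pit.
#'
#' @param lon_range,lat_range numeric(2), extent of the bounding polygon
#'   (decimal degrees).
#' @param base_depth shelf depth in metres outside the pits (positive down).
#' @param pits data frame with columns `lon`, `lat`, `depth` (maximum depth of
#'   the depression, m), `sx`, `sy` (Gaussian half-widths in nautical miles).
#'   Use `NULL` or a zero-row frame for a flat shelf.
#' @param max_depth maximum admissible depth (m); pits deeper than this are
#'   rejected.
#' @param split_lon meridian separating the western and eastern sides of the
#'   domain (decimal degrees).
#' @param zone_radii_nm named numeric, outer radii (nautical miles) of the
#'   nested zones `A`, `B`, `C` around the deepest pit; must be increasing.
#' @param n_vertices number of vertices of the elliptical bounding polygon.
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(lon_range = c(14.9, 16.1),
                            lat_range = c(42.75, 43.55),
                            base_depth = 150,
                            pits = data.frame(
                              lon = c(15.10, 15.42, 15.85),
                              lat = c(43.32, 43.10, 43.00),
                              depth = c(225, 268, 235),
                              sx = c(9, 10, 6),
                              sy = c(5, 7, 5)),
                            max_depth = 270,
                            split_lon = 15.5,
                            zone_radii_nm = c(A = 10, B = 14, C = 17),
                            n_vertices = 48) {
  stopifnot(length(lon_range) == 2, length(lat_range) == 2,
            diff(lon_range) > 0, diff(lat_range) > 0,
            base_depth > 0, max_depth > 0)
  if (is.null(pits)) {
    pits <- data.frame(lon = numeric(0), lat = numeric(0), depth = numeric(0),
                       sx = numeric(0), sy = numeric(0))
  }
  if (nrow(pits) > 0 && any(pits$depth > max_depth)) {
    stop("pit depth exceeds configured maximum depth (", max_depth, " m)")
  }
  if (nrow(pits) > 0 && any(pits$depth <= base_depth)) {
    stop("pit depths must exceed the base shelf depth")
  }
  if (is.unsorted(zone_radii_nm, strictly = TRUE)) {
    stop("zone_radii_nm must be strictly increasing (A < B < C)")
  }
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 base_depth = base_depth, pits = pits, max_depth = max_depth,
                 split_lon = split_lon, zone_radii_nm = zone_radii_nm,
                 n_vertices = n_vertices),
            class = "geometry_config")
}

#' Build the synthetic study geometry
#'
#' Constructs the survey domain: an elliptical bounding polygon inscribed in
#' the configured lon/lat box, an analytic depth surface
#' \eqn{D(lon,lat) = base + \sum_i (depth_i - base)\,
#'   \exp\{-\tfrac12[(dx_i/sx_i)^2 + (dy_i/sy_i)^2]\}}
#' with offsets measured in nautical miles from each pit centre, and three
#' nested circular management zones around the deepest pit.
#'
#' @param config a [geometry_config()].
#' @return an object of class `study_geometry` with elements `polygon`
#'   (data frame lon/lat, open ring), `config`, `origin` (projection centre),
#'   `zones` (list of rings) and `split_lon`.
#' @examples
#' geom <- make_study_geometry(geometry_config())
#' range(depth_at(geom, geom$polygon$lon, geom$polygon$lat))
#' @export
make_study_geometry <- function(config = geometry_config()) {
  stopifnot(inherits(config, "geometry_config"))
  th <- seq(0, 2 * pi, length.out = config$n_vertices + 1)[-(config$n_vertices + 1)]
  cx <- mean(config$lon_range); cy <- mean(config$lat_range)
  ax <- diff(config$lon_range) / 2; ay <- diff(config$lat_range) / 2
  poly <- data.frame(lon = cx + ax * cos(th), lat = cy + ay * sin(th))
  if (nrow(poly) < 3) stop("bounding polygon is empty")
  origin <- c(lon = cx, lat = cy)
  geom <- structure(list(polygon = poly, config = config, origin = origin,
                         split_lon = config$split_lon),
                    class = "study_geometry")
  # zones around the deepest pit; with a flat shelf, around the domain centre
  if (nrow(config$pits) > 0) {
    i <- which.max(config$pits$depth)
    zc <- c(lon = config$pits$lon[i], lat = config$pits$lat[i])
  } else {
    zc <- origin
  }
  geom$zone_center <- zc
  geom$zones <- lapply(config$zone_radii_nm, function(r) {
    ring_nm <- cbind(x = r * cos(th), y = r * sin(th))
    ll <- nm_to_lonlat(geom, ring_nm[, 1], ring_nm[, 2], center = zc)
    data.frame(lon = ll$lon, lat = ll$lat)
  })
  names(geom$zones) <- names(config$zone_radii_nm)
  geom
}

# Local planar frame: nautical miles east/north of `center` (equirectangular
# about the domain centre latitude; adequate at the ~60 nm scale used here).
lonlat_to_nm <- function(geom, lon, lat, center = geom$origin) {
  k <- cos(geom$origin[["lat"]] * pi / 180)
  list(x = (lon - center[["lon"]]) * 60 * k, y = (lat - center[["lat"]]) * 60)
}

nm_to_lonlat <- function(geom, x, y, center = geom$origin) {
  k <- cos(geom$origin[["lat"]] * pi / 180)
  list(lon = center[["lon"]] + x / (60 * k), lat = center[["lat"]] + y / 60)
}

#' Point-in-polygon test
#'
#' @param poly data frame with `lon`, `lat` vertices (open ring).
#' @param lon,lat point coordinates (vectorised).
#' @return logical vector.
#' @export
in_polygon <- function(poly, lon, lat) {
  if (length(lon) == 0) return(logical(0))
  bnd <- as.matrix(rbind(poly[, c("lon", "lat")],
                         poly[1, c("lon", "lat")]))
  mgcv::in.out(bnd, cbind(lon, lat))
}

#' Evaluate the analytic depth surface
#'
#' @param geom a `study_geometry`.
#' @param lon,lat coordinates (vectorised).
#' @return depth in metres (positive down).
#' @export
depth_at <- function(geom, lon, lat) {
  cfg <- geom$config
  d <- rep(cfg$base_depth, length(lon))
  if (nrow(cfg$pits) > 0) {
    for (i in seq_len(nrow(cfg$pits))) {
      p <- cfg$pits[i, ]
      xy <- lonlat_to_nm(geom, lon, lat, center = c(lon = p$lon, lat = p$lat))
      d <- d + (p$depth - cfg$base_depth) *
        exp(-0.5 * ((xy$x / p$sx)^2 + (xy$y / p$sy)^2))
    }
  }
  d
}

#' Management zone at a point
#'
#' Zones are nested discs around the deepest pit; the innermost disc
#' containing the point wins, so the regions effectively assigned to A, B and
#' C are pairwise disjoint (disc A, then the B and C annuli).
#'
#' @param geom a `study_geometry`.
#' @param lon,lat coordinates (vectorised).
#' @return character vector with values `"A"`, `"B"`, `"C"` or `NA` (outside
#'   all zones).
#' @export
zone_at <- function(geom, lon, lat) {
  xy <- lonlat_to_nm(geom, lon, lat, center = geom$zone_center)
  r <- sqrt(xy$x^2 + xy$y^2)
  radii <- geom$config$zone_radii_nm
  out <- rep(NA_character_, length(r))
  for (z in rev(names(radii))) out[r <= radii[[z]]] <- z
  out
}

#' @export
print.study_geometry <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic study geometry\n")
  cat("  polygon:", nrow(x$polygon), "vertices, lon",
      sprintf("%.2f-%.2f", min(x$polygon$lon), max(x$polygon$lon)),
      "lat", sprintf("%.2f-%.2f", min(x$polygon$lat), max(x$polygon$lat)), "\n")
  cat("  bathymetry: shelf", cfg$base_depth, "m,", nrow(cfg$pits),
      "pit(s), max", if (nrow(cfg$pits)) max(cfg$pits$depth) else cfg$base_depth, "m\n")
  cat("  zones:", paste(names(x$zones), collapse = ", "),
      "around", sprintf("(%.2f, %.2f)", x$zone_center[["lon"]],
                        x$zone_center[["lat"]]), "\n")
  invisible(x)
}

# Uniform rejection sampling of points inside the polygon, optionally
# restricted to a depth band. Uses the current RNG stream.
sample_in_polygon <- function(geom, n, depth_range = NULL, max_tries = 10000) {
  out <- data.frame(lon = numeric(0), lat = numeric(0))
  lr <- range(geom$polygon$lon); br <- range(geom$polygon$lat)
  tries <- 0
  while (nrow(out) < n && tries < max_tries) {
    m <- max(4 * (n - nrow(out)), 32)
    lon <- stats::runif(m, lr[1], lr[2])
    lat <- stats::runif(m, br[1], br[2])
    ok <- in_polygon(geom$polygon, lon, lat)
    if (!is.null(depth_range)) {
      d <- depth_at(geom, lon, lat)
      ok <- ok & d >= depth_range[1] & d <= depth_range[2]
    }
    out <- rbind(out, data.frame(lon = lon[ok], lat = lat[ok]))
    tries <- tries + 1
  }
  if (nrow(out) < n) {
    stop("could not sample ", n, " points; eligible region ",
         "(depth band ", paste(depth_range, collapse = "-"), " m) may be empty")
  }
  out[seq_len(n), , drop = FALSE]
}
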