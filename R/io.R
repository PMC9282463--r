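# GeoJSON + CSV export helpers. Polygons are written as GeoJSON rings
# (closed, lon/lat order) with jsonlite; no spatial package is required for
# these simple feature collections.

geojson_polygon <- function(df, properties = list()) {
  ring <- rbind(as.matrix(df[, c("lon", "lat")]),
                as.matrix(df[1, c("lon", "lat")]))
  list(type = "Feature", properties = properties,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)),
                                                 function(i) ring[i, ]))))
}

#' Export the study geometry as GeoJSON
#'
#' Writes the bounding polygon and the three management-zone rings as a
#' GeoJSON FeatureCollection.
#'
#' @param geom a `study_geometry`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
geometry_to_geojson <- function(geom, path) {
  feats <- c(list(geojson_polygon(geom$polygon, list(name = "study_area"))),
             lapply(names(geom$zones), function(z) {
               geojson_polygon(geom$zones[[z]], list(name = paste0("zone_", z)))
             }))
  fc <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

#' Export an informed grid as GeoJSON
#'
#' One square feature per cell carrying the cell's attribute columns as
#' properties.
#'
#' @param grid an (informed) grid.
#' @param geom the `study_geometry` defining the local frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
grid_to_geojson <- function(grid, geom, path) {
  cs <- attr(grid, "cell_size_nm")
  h <- cs / 2
  cols <- setdiff(names(grid), c("ix", "iy", "x_nm", "y_nm"))
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    corners <- data.frame(
      x = grid$x_nm[i] + c(-h, h, h, -h),
      y = grid$y_nm[i] + c(-h, -h, h, h))
    ll <- nm_to_lonlat(geom, corners$x, corners$y)
    geojson_polygon(data.frame(lon = ll$lon, lat = ll$lat),
                    as.list(grid[i, cols, drop = FALSE]))
  })
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection",
                                   features = feats),
                              auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Export a fitted-model summary in the layout of the result tables:
# parametric coefficient rows then smooth rows.
summary_to_csv <- function(summ, path) {
  pt <- summ$parametric
  pt <- data.frame(term = rownames(pt), type = "parametric",
                   estimate = pt$estimate, se = pt$se, stat = pt$t, p = pt$p)
  st <- summ$smooths
  st <- if (nrow(st)) {
    data.frame(term = rownames(st), type = "smooth",
               estimate = st$edf, se = st$ref_df, stat = st$F, p = st$p)
  } else NULL
  out <- rbind(pt, st)
  names(out) <- c("term", "type", "estimate_or_edf", "se_or_refdf",
                  "t_or_F", "p")
  write_csv_file(out, path)
}
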