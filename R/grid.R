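#' Build a constant-area prediction grid
#'
#' Tessellates the study domain with axis-aligned square cells of side
#' `cell_size_nm` nautical miles in the local planar frame (anchored at the
#' lower-left corner of the polygon's bounding box), keeping every cell that
#' intersects the polygon. Cell ids encode the integer column/row indices of
#' the tessellation, so the same geometry and cell size always yield the
#' same cells.
#'
#' @param geom a `study_geometry`.
#' @param cell_size_nm cell side in nautical miles (> 0); the nominal cell
#'   area is `cell_size_nm^2` square nautical miles.
#' @return data frame of class `neph_grid`: `cell_id`, `ix`, `iy` (integer
#'   tessellation indices), `lon`, `lat` (cell centre), `x_nm`, `y_nm`
#'   (centre in the local frame), `area_nm2`, `western` (centre west of the
#'   split meridian). Attributes `cell_size_nm` and `anchor` record the
#'   tessellation.
#' @export
build_grid <- function(geom, cell_size_nm = 2) {
  if (!(cell_size_nm > 0)) stop("cell size must be positive")
  if (nrow(geom$polygon) < 3) stop("empty study polygon")
  p <- lonlat_to_nm(geom, geom$polygon$lon, geom$polygon$lat)
  anchor <- c(x = min(p$x), y = min(p$y))
  nx <- ceiling((max(p$x) - anchor["x"]) / cell_size_nm)
  ny <- ceiling((max(p$y) - anchor["y"]) / cell_size_nm)
  cells <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  cx <- anchor[["x"]] + (cells$ix + 0.5) * cell_size_nm
  cy <- anchor[["y"]] + (cells$iy + 0.5) * cell_size_nm
  # keep cells that intersect the polygon: probe centre, corners and edge
  # midpoints, and catch polygon vertices falling inside a cell
  h <- cell_size_nm / 2 * (1 - 1e-6)  # probes strictly inside the cell, so a
  probes <- rbind(c(0, 0), c(-h, -h), c(h, -h), c(-h, h), c(h, h),
                  c(0, -h), c(0, h), c(-h, 0), c(h, 0))
  keep <- rep(FALSE, nrow(cells))    # zero-area edge touch does not count
  for (j in seq_len(nrow(probes))) {
    ll <- nm_to_lonlat(geom, cx + probes[j, 1], cy + probes[j, 2])
    keep <- keep | in_polygon(geom$polygon, ll$lon, ll$lat)
  }
  eps <- 1e-9 * cell_size_nm
  vx <- floor((p$x - anchor[["x"]] - eps) / cell_size_nm)
  vy <- floor((p$y - anchor[["y"]] - eps) / cell_size_nm)
  keep <- keep | (paste(cells$ix, cells$iy) %in% paste(vx, vy))
  cells <- cells[keep, , drop = FALSE]
  ll <- nm_to_lonlat(geom, cx[keep], cy[keep])
  out <- data.frame(cell_id = sprintf("c%03d_%03d", cells$ix, cells$iy),
                    ix = cells$ix, iy = cells$iy,
                    lon = ll$lon, lat = ll$lat,
                    x_nm = cx[keep], y_nm = cy[keep],
                    area_nm2 = cell_size_nm^2,
                    western = ll$lon < geom$split_lon)
  rownames(out) <- NULL
  attr(out, "cell_size_nm") <- cell_size_nm
  attr(out, "anchor") <- anchor
  class(out) <- c("neph_grid", class(out))
  out
}

#' Locate points in grid cells
#'
#' @param grid a grid from [build_grid()].
#' @param geom the `study_geometry` used to build it.
#' @param lon,lat point coordinates.
#' @return character vector of cell ids (`NA` for points outside all kept
#'   cells); the tessellation is disjoint, so each point maps to at most one
#'   cell.
#' @export
cell_of <- function(grid, geom, lon, lat) {
  anchor <- attr(grid, "anchor")
  cs <- attr(grid, "cell_size_nm")
  q <- lonlat_to_nm(geom, lon, lat)
  id <- sprintf("c%03d_%03d",
                floor((q$x - anchor[["x"]]) / cs),
                floor((q$y - anchor[["y"]]) / cs))
  id[!id %in% grid$cell_id] <- NA_character_
  id
}

#' Attach depth, management and environmental attributes to the grid
#'
#' Informs the grid for one survey/year: mean depth per cell by midpoint
#' quadrature of the analytic depth surface over the cell, fishery level
#' resolved at the cell centre for the survey's reference date (May 1 for
#' spring, October 1 for autumn), the survey's reference week, and - when an
#' environmental field is supplied - per-cell `BT`, `Sal` and `Oxy` values
#' kriged from the CTD stations ([krige_environment()]). Autumn surveys
#' cover only the western side, recorded in `in_domain`.
#'
#' @param grid a grid from [build_grid()].
#' @param geom a `study_geometry`.
#' @param timeline a `management_timeline`.
#' @param survey `"spring"` or `"autumn"`.
#' @param year integer year.
#' @param env optional `env_field` (or a plain list with a `stations` data
#'   frame) for the same survey/year.
#' @param n_quad quadrature points per cell side for the mean depth.
#' @param vgm optional `variogram_model` forwarded to the kriging step.
#' @return the grid with columns `D` (mean depth, m), `Fishery`, `week`,
#'   `Yr`, `survey`, `in_domain` and, with `env`, `BT`, `Sal`, `Oxy`;
#'   attribute `env_provenance` records `"observed"` layers.
#' @export
assign_cell_attributes <- function(grid, geom, timeline, survey, year,
                                   env = NULL, n_quad = 4, vgm = NULL) {
  stopifnot(inherits(grid, "neph_grid"), survey %in% c("spring", "autumn"))
  cs <- attr(grid, "cell_size_nm")
  u <- (seq_len(n_quad) - 0.5) / n_quad - 0.5  # midpoint rule offsets
  qd <- matrix(0, nrow(grid), n_quad^2)
  k <- 0
  for (a in u) for (b in u) {
    k <- k + 1
    ll <- nm_to_lonlat(geom, grid$x_nm + a * cs, grid$y_nm + b * cs)
    qd[, k] <- depth_at(geom, ll$lon, ll$lat)
  }
  grid$D <- rowMeans(qd)
  ref_date <- survey_reference_date(survey, year)
  grid$Fishery <- fishery_level_at(geom, timeline, ref_date, grid$lon, grid$lat)
  grid$week <- round(stats::median(season_windows()[[survey]]))
  grid$Yr <- year
  grid$survey <- survey
  grid$Y <- grid$lat
  grid$X <- grid$lon
  grid$in_domain <- if (survey == "autumn") grid$western else TRUE
  if (!is.null(env)) {
    for (p in env_params) {
      grid[[p]] <- krige_environment(env$stations, grid, p, geom, vgm = vgm)
    }
    attr(grid, "env_provenance") <- "observed"
  }
  grid
}

#' Fill missing environmental layers from donor survey/years
#'
#' Applies the proxy rules used to complete the prediction layers:
#' the spring-2012 oxygen layer is taken from spring 2013, and the whole
#' spring-2018 environment (BT, Sal, Oxy) is taken from spring 2019. All
#' other layers are untouched; filled layers get provenance flags and never
#' overwrite observed values for other parameters.
#'
#' @param layers named list of informed grids keyed `"<survey>_<year>"`
#'   (from [assign_cell_attributes()]); donors must be present.
#' @param rules data frame with columns `target`, `donor`, `params`
#'   (comma-separated parameter names); the default encodes the two rules
#'   above.
#' @return the completed list; each touched grid gains an attribute
#'   `env_provenance_detail`, a named vector mapping parameters to
#'   `"observed"` or `"proxy:<donor>"`.
#' @export
proxy_fill <- function(layers,
                       rules = data.frame(
                         target = c("spring_2012", "spring_2018"),
                         donor = c("spring_2013", "spring_2019"),
                         params = c("Oxy", "BT,Sal,Oxy"))) {
  for (i in seq_len(nrow(rules))) {
    tg <- rules$target[i]; dn <- rules$donor[i]
    if (!tg %in% names(layers)) next
    if (!dn %in% names(layers)) {
      stop("proxy donor layer missing: ", dn, " (needed for ", tg, ")")
    }
    pars <- trimws(strsplit(rules$params[i], ",")[[1]])
    need <- pars[vapply(pars, function(p) {
      !p %in% names(layers[[tg]]) || anyNA(layers[[tg]][[p]])
    }, TRUE)]
    if (!length(need)) next
    if (!all(need %in% names(layers[[dn]]))) {
      stop("donor ", dn, " lacks parameter(s): ",
           paste(setdiff(need, names(layers[[dn]])), collapse = ", "))
    }
    prov <- attr(layers[[tg]], "env_provenance_detail") %||%
      stats::setNames(rep("observed", length(env_params)), env_params)
    m <- match(layers[[tg]]$cell_id, layers[[dn]]$cell_id)
    for (p in need) {
      layers[[tg]][[p]] <- layers[[dn]][[p]][m]
      prov[p] <- paste0("proxy:", dn)
    }
    attr(layers[[tg]], "env_provenance_detail") <- prov
  }
  layers
}

#' Standardized abundance index for one survey/year
#'
#' Predicts the fitted model over the informed grid at a fixed time of day
#' (sunrise by default, standardizing the daytime domain), restricted to the
#' survey's spatial domain, and averages the per-cell response-scale
#' predictions into a standardized index. The index standard error
#' aggregates the per-cell delta-method SEs under an independence
#' approximation, `SE = sqrt(sum(se_i^2)) / n`.
#'
#' @param fitted a `neph_gam`.
#' @param grid an informed grid (see [assign_cell_attributes()]; after
#'   [proxy_fill()] if layers were missing).
#' @param tod time-of-day level used for standardization.
#' @param denominator unused here; see [compare_observed_predicted()].
#' @return one-row data frame of class `standardized_index`: `survey`,
#'   `Yr`, `response`, `index`, `se`, `n_cells`.
#' @export
standardized_index <- function(fitted, grid, tod = "sunrise") {
  stopifnot(inherits(fitted, "neph_gam"), inherits(grid, "neph_grid"))
  g <- grid[grid$in_domain, , drop = FALSE]
  if (nrow(g) == 0) stop("no grid cells in the survey domain")
  used <- unique(c(vapply(fitted$spec$smooths, `[[`, "", "var"),
                   unlist(lapply(fitted$spec$smooths, `[[`, "by")),
                   fitted$spec$factors))
  used <- setdiff(used, "ToD")
  for (v in used) {
    if (!v %in% names(g)) stop("grid lacks attribute '", v, "'")
    if (anyNA(g[[v]])) {
      stop("grid attribute '", v, "' missing for cell(s): ",
           paste(utils::head(g$cell_id[is.na(g[[v]])], 5), collapse = ", "))
    }
  }
  g$ToD <- tod
  p <- predict(fitted, g, se.fit = TRUE)
  out <- data.frame(survey = g$survey[1], Yr = g$Yr[1],
                    response = fitted$spec$response,
                    index = mean(p$fit),
                    se = sqrt(sum(p$se.fit^2)) / nrow(g),
                    n_cells = nrow(g))
  class(out) <- c("standardized_index", class(out))
  out
}

#' Relative difference between observed and standardized-predicted CPUE
#'
#' Signed percent difference `100 (index - observed) / denominator`, with
#' the predicted index as the default denominator.
#'
#' @param observed observed mean CPUE (same units as the index).
#' @param index predicted standardized index (scalar, or a
#'   `standardized_index` row).
#' @param denominator `"predicted"` (default) or `"observed"`.
#' @return signed percent difference.
#' @examples
#' compare_observed_predicted(24.9, 37.33)  # ~ +33
#' @export
compare_observed_predicted <- function(observed, index,
                                       denominator = c("predicted", "observed")) {
  denominator <- match.arg(denominator)
  if (inherits(index, "standardized_index")) index <- index$index
  if (denominator == "predicted" && any(index <= 0)) {
    stop("predicted index must be positive")
  }
  den <- if (denominator == "predicted") index else observed
  100 * (index - observed) / den
}
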