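#' Configuration of the synthetic environmental climatology
#'
#' Deterministic trend surfaces for bottom temperature (BT, deg C), bottom
#' salinity (Sal, PSU) and bottom dissolved-oxygen saturation (Oxy, %),
#' with seasonal (survey) and interannual offsets, plus the parameters of the
#' spatially correlated noise added on top by [sample_environment()].
#'
#' The defaults place the domain in realistic deep-Adriatic ranges: BT near
#' 12 deg C (slightly warmer in autumn), Sal near 38.4 PSU, Oxy near 85%
#' saturation with a west-east gradient. `oxy_range` bounds the admissible
#' oxygen values; scenarios on either side of the 85% inflection (including
#' documented hypoxic conditions approaching 40%) are obtained by shifting
#' `oxy_mean`.
#'
#' @param bt_mean,sal_mean,oxy_mean spatial means of the three parameters.
#' @param bt_autumn_offset,oxy_autumn_offset additive seasonal offsets
#'   applied to autumn surveys.
#' @param year_amp named numeric, amplitude of a sinusoidal interannual
#'   cycle per parameter.
#' @param year_period,year_phase named numeric, period (years) and phase
#'   (radians) of the interannual cycle per parameter; distinct periods keep
#'   the parameters' annual means from tracking one another.
#' @param grad_per_nm named list of `c(gx, gy)` spatial gradients (units per
#'   nautical mile east/north).
#' @param sill named numeric, variance of the spatially correlated noise.
#' @param range_nm variogram (exponential) range of the noise, nautical miles.
#' @param oxy_range admissible oxygen-saturation interval, a subset of
#'   (0, 130].
#' @return list of class `env_config`.
#' @export
env_config <- function(bt_mean = 11.8, sal_mean = 38.45, oxy_mean = 88,
                       bt_autumn_offset = 0.3, oxy_autumn_offset = -2,
                       year_amp = c(BT = 0.25, Sal = 0.05, Oxy = 4),
                       year_period = c(BT = 3.5, Sal = 6, Oxy = 5),
                       year_phase = c(BT = 0, Sal = 1, Oxy = 2),
                       grad_per_nm = list(BT = c(0.002, -0.002),
                                          Sal = c(0.001, 0.0005),
                                          Oxy = c(-0.05, 0.03)),
                       sill = c(BT = 0.09, Sal = 0.01, Oxy = 25),
                       range_nm = 12,
                       oxy_range = c(40, 130)) {
  stopifnot(oxy_range[1] > 0, oxy_range[2] <= 130, oxy_range[1] < oxy_range[2])
  structure(list(bt_mean = bt_mean, sal_mean = sal_mean, oxy_mean = oxy_mean,
                 bt_autumn_offset = bt_autumn_offset,
                 oxy_autumn_offset = oxy_autumn_offset,
                 year_amp = year_amp, year_period = year_period,
                 year_phase = year_phase, grad_per_nm = grad_per_nm,
                 sill = sill, range_nm = range_nm, oxy_range = oxy_range),
            class = "env_config")
}

env_params <- c("BT", "Sal", "Oxy")

# Deterministic trend of one parameter at given locations.
env_trend <- function(geom, cfg, param, lon, lat, survey, year) {
  xy <- lonlat_to_nm(geom, lon, lat)
  base <- switch(param, BT = cfg$bt_mean, Sal = cfg$sal_mean, Oxy = cfg$oxy_mean)
  seas <- if (survey == "autumn") {
    switch(param, BT = cfg$bt_autumn_offset, Sal = 0, Oxy = cfg$oxy_autumn_offset)
  } else 0
  ann <- cfg$year_amp[[param]] *
    sin(2 * pi * (year - 2012) / cfg$year_period[[param]] +
          cfg$year_phase[[param]])
  g <- cfg$grad_per_nm[[param]]
  v <- base + seas + ann + g[1] * xy$x + g[2] * xy$y
  if (param == "Oxy") v <- pmin(pmax(v, cfg$oxy_range[1]), cfg$oxy_range[2])
  v
}

exp_cov <- function(d, sill, range_nm) sill * exp(-d / range_nm)

#' Sample a synthetic environmental field for one survey/year
#'
#' Emulates a CTD-station campaign: `n_stations` stations are placed uniformly
#' at random inside the study polygon and each environmental parameter is
#' realised as its deterministic trend plus a Gaussian random field with an
#' exponential variogram (partial sill `noise^2 x` the configured relative
#' sill, range `cfg$range_nm`, zero nugget), simulated exactly at the
#' stations by Cholesky factorisation. The returned object also evaluates a
#' continuous surface anywhere in the domain: the trend plus the simple-
#' kriging interpolant of the station residuals under the generating
#' variogram, so the surface reproduces the stations exactly and decays to
#' the trend away from them.
#'
#' @param geom a `study_geometry`.
#' @param survey `"spring"` or `"autumn"`.
#' @param year integer year.
#' @param n_stations number of CTD stations (>= 4).
#' @param noise noise multiplier (>= 0): scales the configured sill
#'   variances; `0` gives a purely deterministic field.
#' @param cfg an [env_config()].
#' @param seed integer seed; identical inputs give identical fields.
#' @return object of class `env_field` with elements `stations` (data frame
#'   `lon`, `lat`, `BT`, `Sal`, `Oxy`), `survey`, `year`, and `surface(param,
#'   lon, lat)`.
#' @export
sample_environment <- function(geom, survey, year, n_stations = 30,
                               noise = 1, cfg = env_config(), seed = 1) {
  stopifnot(n_stations >= 4, noise >= 0, survey %in% c("spring", "autumn"))
  with_seed(derive_seed(seed, paste("env", survey, year)), {
    st <- sample_in_polygon(geom, n_stations)
    xy <- lonlat_to_nm(geom, st$lon, st$lat)
    D <- as.matrix(stats::dist(cbind(xy$x, xy$y)))
    resid <- list()
    for (p in env_params) {
      mu <- env_trend(geom, cfg, p, st$lon, st$lat, survey, year)
      s2 <- noise^2 * cfg$sill[[p]]
      if (s2 > 0) {
        C <- exp_cov(D, s2, cfg$range_nm)
        diag(C) <- s2 + 1e-10 * s2
        z <- drop(t(chol(C)) %*% stats::rnorm(n_stations))
      } else {
        z <- rep(0, n_stations)
      }
      resid[[p]] <- z
      st[[p]] <- mu + z
    }
    st$Oxy <- pmin(pmax(st$Oxy, cfg$oxy_range[1]), cfg$oxy_range[2])
    # precompute C^{-1} residuals for the interpolating surface
    interp <- lapply(env_params, function(p) {
      s2 <- noise^2 * cfg$sill[[p]]
      if (s2 == 0) return(rep(0, n_stations))
      C <- exp_cov(D, s2, cfg$range_nm)
      diag(C) <- s2 + 1e-10 * s2
      solve(C, resid[[p]])
    })
    names(interp) <- env_params
    field <- structure(
      list(stations = st, survey = survey, year = year, cfg = cfg,
           noise = noise, geom_origin = geom$origin),
      class = "env_field")
    st_xy <- cbind(xy$x, xy$y)
    field$surface <- function(param, lon, lat) {
      stopifnot(param %in% env_params)
      mu <- env_trend(geom, cfg, param, lon, lat, survey, year)
      s2 <- noise^2 * cfg$sill[[param]]
      if (s2 == 0) return(mu)
      q <- lonlat_to_nm(geom, lon, lat)
      d <- sqrt(outer(q$x, st_xy[, 1], "-")^2 + outer(q$y, st_xy[, 2], "-")^2)
      v <- mu + drop(exp_cov(d, s2, cfg$range_nm) %*% interp[[param]])
      if (param == "Oxy") v <- pmin(pmax(v, cfg$oxy_range[1]), cfg$oxy_range[2])
      v
    }
    field
  })
}

#' @export
print.env_field <- function(x, ...) {
  cat("Environmental field:", x$survey, x$year, "-", nrow(x$stations),
      "stations\n")
  print(summary(x$stations[, env_params]))
  invisible(x)
}
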