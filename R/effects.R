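#' True generating effects for the synthetic survey
#'
#' Defines the additive model on the log scale from which synthetic CPUE is
#' drawn: an intercept, smooth shape functions of latitude, depth, bottom
#' temperature, oxygen saturation, salinity and week, per-fishery-level
#' linear year trends (the year-by-fishery interaction), and factor offsets
#' for fishery level and time of day. Biomass and density responses share
#' the smooth shapes and year trends but carry their own intercepts, factor
#' offsets and Gamma shape parameters, mirroring two indices measured on the
#' same hauls.
#'
#' Default magnitudes follow the fitted study values: biomass intercept 3.29
#' (log kg/km^2), density intercept 7.61 (log N/km^2), sunset offsets -0.39 /
#' -0.35, limited-fishery offsets 0.65 / 0.46 and ban offsets 0.66 / 0.72;
#' the depth shape peaks near 175 m and flattens beyond ~225 m, the oxygen
#' shape is mildly negative below 85% saturation and strongly positive
#' above, salinity acts negatively, and the temperature and week effects are
#' zero by default (both were retained nowhere in the reference analysis).
#'
#' @param b0 named numeric, intercepts `c(biomass=, density=)` (log scale).
#' @param tod_sunset named numeric, sunset offsets per response.
#' @param fishery list with `biomass` and `density` named vectors of offsets
#'   for levels `Y`, `L`, `N`.
#' @param yr_slope named numeric, per-level linear year slopes (per year,
#'   centred on `yr_center`), shared by the two responses.
#' @param yr_center centring year of the year trends.
#' @param shape named numeric, Gamma shape parameters per response (> 0).
#' @param depth_amp,oxy_amp,sal_slope,lat_slope,bt_slope,week_amp scalar
#'   magnitudes of the smooth shapes (see Details); set any to 0 to remove
#'   that effect.
#' @return list of class `true_effects`.
#' @export
true_effects <- function(b0 = c(biomass = 3.29, density = 7.61),
                         tod_sunset = c(biomass = -0.39, density = -0.35),
                         fishery = list(
                           biomass = c(Y = 0, L = 0.65, N = 0.66),
                           density = c(Y = 0, L = 0.46, N = 0.72)),
                         yr_slope = c(Y = -0.10, L = 0, N = 0.12),
                         yr_center = 2015.5,
                         shape = c(biomass = 4, density = 4),
                         depth_amp = 0.9, oxy_amp = 0.09, sal_slope = -2.5,
                         lat_slope = -0.5, bt_slope = 0, week_amp = 0) {
  stopifnot(all(shape > 0), all(c("Y", "L", "N") %in% names(fishery$biomass)),
            all(c("Y", "L", "N") %in% names(yr_slope)))
  structure(list(b0 = b0, tod_sunset = tod_sunset, fishery = fishery,
                 yr_slope = yr_slope, yr_center = yr_center, shape = shape,
                 depth_amp = depth_amp, oxy_amp = oxy_amp,
                 sal_slope = sal_slope, lat_slope = lat_slope,
                 bt_slope = bt_slope, week_amp = week_amp),
            class = "true_effects")
}

# Smooth shape functions (log scale), all finite on their natural ranges.
effect_depth <- function(eff, d) {
  # rises to a peak near 175 m, declines to ~225 m, then flat
  peak <- eff$depth_amp * exp(-0.5 * ((d - 175) / 35)^2)
  floorv <- eff$depth_amp * exp(-0.5 * ((225 - 175) / 35)^2)
  ifelse(d > 225, floorv, peak) - 0.5 * eff$depth_amp
}

effect_oxy <- function(eff, o) {
  # slightly negative below 85% saturation, strongly positive above
  eff$oxy_amp * (-0.15 * (o - 85) + 1.15 * log1p(exp((o - 85) / 2)) * 2) -
    eff$oxy_amp * 1.15 * 2 * log(2)
}

effect_sal <- function(eff, s) eff$sal_slope * (s - 38.45)
effect_lat <- function(eff, y) eff$lat_slope * (y - 43.15)
effect_bt <- function(eff, t) eff$bt_slope * (t - 12)
effect_week <- function(eff, w) eff$week_amp * sin(2 * pi * w / 52)

#' Linear predictor of the generating model
#'
#' Assembles the log-scale mean for each row of a haul-covariate table.
#'
#' @param effects a [true_effects()].
#' @param data data frame with columns `Y` (latitude), `D` (depth m), `BT`,
#'   `Oxy`, `Sal`, `week`, `Yr`, `Fishery` (`"Y"/"L"/"N"`), `ToD`
#'   (`"sunrise"/"sunset"`).
#' @param response `"biomass"` or `"density"`.
#' @return numeric vector, the linear predictor eta (log scale).
#' @export
linear_predictor <- function(effects, data, response = c("biomass", "density")) {
  response <- match.arg(response)
  stopifnot(inherits(effects, "true_effects"))
  lev <- as.character(data$Fishery)
  effects$b0[[response]] +
    effect_lat(effects, data$Y) +
    effect_depth(effects, data$D) +
    effect_bt(effects, data$BT) +
    effect_oxy(effects, data$Oxy) +
    effect_sal(effects, data$Sal) +
    effect_week(effects, data$week) +
    effects$yr_slope[lev] * (data$Yr - effects$yr_center) +
    effects$fishery[[response]][lev] +
    ifelse(as.character(data$ToD) == "sunset",
           effects$tod_sunset[[response]], 0)
}
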