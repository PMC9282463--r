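# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_geom <- function() cached("geom", make_study_geometry())
test_timeline <- function() cached("timeline", make_management_timeline())

# default-condition synthetic dataset, filtered, keyed by seed
test_dataset <- function(seed = 7) {
  cached(paste0("data", seed), {
    sim <- simulate_survey_series(test_geom(), test_timeline(), seed = seed)
    filter_records(compute_indices(sim$hauls))$table
  })
}

# a square study_geometry (side_nm x side_nm) for grid arithmetic
square_geom <- function(side_nm = 4, base_depth = 150) {
  lat0 <- 43.15; lon0 <- 15.5
  k <- cos(lat0 * pi / 180)
  dlat <- side_nm / 2 / 60; dlon <- side_nm / 2 / (60 * k)
  cfg <- geometry_config(lon_range = c(lon0 - dlon, lon0 + dlon),
                         lat_range = c(lat0 - dlat, lat0 + dlat),
                         base_depth = base_depth, pits = NULL)
  geom <- make_study_geometry(cfg)
  geom$polygon <- data.frame(lon = lon0 + dlon * c(-1, 1, 1, -1),
                             lat = lat0 + dlat * c(-1, -1, 1, 1))
  geom
}

# an axis-aligned rectangular geometry (wx_nm x wy_nm)
rect_geom <- function(wx_nm, wy_nm, base_depth = 150) {
  lat0 <- 43.15; lon0 <- 15.5
  k <- cos(lat0 * pi / 180)
  dlat <- wy_nm / 2 / 60; dlon <- wx_nm / 2 / (60 * k)
  cfg <- geometry_config(lon_range = c(lon0 - dlon, lon0 + dlon),
                         lat_range = c(lat0 - dlat, lat0 + dlat),
                         base_depth = base_depth, pits = NULL)
  geom <- make_study_geometry(cfg)
  geom$polygon <- data.frame(lon = lon0 + dlon * c(-1, 1, 1, -1),
                             lat = lat0 + dlat * c(-1, -1, 1, 1))
  geom
}

# clearly detectable planted effects used by recovery properties: same
# structure as the default generator, larger factor/trend magnitudes and a
# higher Gamma shape so each replicate dataset carries its planted signal
strong_effects <- function() {
  true_effects(tod_sunset = c(biomass = -0.8, density = -0.8),
               fishery = list(biomass = c(Y = 0, L = 0.9, N = 1.0),
                              density = c(Y = 0, L = 0.9, N = 1.0)),
               yr_slope = c(Y = -0.2, L = 0, N = 0.3),
               shape = c(biomass = 6, density = 6),
               lat_slope = -1.5, oxy_amp = 0.12, sal_slope = -3.5)
}

strong_survey_config <- function() survey_config(n_spring = 14, n_autumn = 10)

# uniform in-polygon points under a fixed, restored seed
with_seed_pts <- function(geom, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(42)
  nephcpue:::sample_in_polygon(geom, n)
}

# Gamma(log) data with a single linear covariate effect
gamma_lin_data <- function(n, b0, b1, shape, seed) {
  set.seed(seed)
  x <- runif(n, -1, 1)
  mu <- exp(b0 + b1 * x)
  data.frame(x = x, y = rgamma(n, shape = shape, rate = shape / mu))
}

# textbook cardinal cubic regression spline in value/second-derivative form
# (independent of the basis construction under test)
cr_reference <- function(x, knots) {
  k <- length(knots); h <- diff(knots)
  D <- matrix(0, k - 2, k); B <- matrix(0, k - 2, k - 2)
  for (i in seq_len(k - 2)) {
    D[i, i] <- 1 / h[i]; D[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    D[i, i + 2] <- 1 / h[i + 1]
    B[i, i] <- (h[i] + h[i + 1]) / 3
    if (i < k - 2) { B[i, i + 1] <- h[i + 1] / 6; B[i + 1, i] <- h[i + 1] / 6 }
  }
  Fm <- rbind(0, solve(B, D), 0)
  X <- matrix(0, length(x), k)
  for (m in seq_along(x)) {
    j <- max(1, min(k - 1, findInterval(x[m], knots)))
    hj <- h[j]; xm <- x[m]
    am <- (knots[j + 1] - xm) / hj; ap <- (xm - knots[j]) / hj
    cm <- ((knots[j + 1] - xm)^3 / hj - hj * (knots[j + 1] - xm)) / 6
    cp <- ((xm - knots[j])^3 / hj - hj * (xm - knots[j])) / 6
    e <- numeric(k); e[j] <- am; e[j + 1] <- e[j + 1] + ap
    X[m, ] <- e + cm * Fm[j, ] + cp * Fm[j + 1, ]
  }
  list(X = X, S = t(D) %*% solve(B, D))
}

# spring haul-table fixture reproducing the per-year removal pattern:
# 89 rows; 2012 entirely lacking oxygen; scattered missing readings in
# later years; exactly two zero-CPUE rows -> 56 retained
filter_fixture <- function() {
  plan <- data.frame(
    Yr = c(2012, 2013, 2014, 2015, 2016, 2017, 2019),
    n = c(17, 10, 15, 8, 14, 14, 11),
    n_missing = c(17, 4, 2, 1, 2, 3, 2),
    n_zero = c(0, 1, 0, 0, 1, 0, 0))
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    n <- plan$n[i]
    d <- data.frame(
      haul_id = sprintf("sp%d_%02d", plan$Yr[i], seq_len(n)),
      survey = "spring", Yr = plan$Yr[i], week = 17,
      ToD = rep(c("sunrise", "sunset"), length.out = n),
      Y = 43 + seq_len(n) / 100, X = 15.3, D = 180,
      BT = 11.9, Sal = 38.4, Oxy = 88, Fishery = "Y",
      swept_area = 0.06, catch_weight = 2 + seq_len(n) / 10,
      catch_count = 100 + seq_len(n))
    if (plan$n_missing[i] > 0) d$Oxy[seq_len(plan$n_missing[i])] <- NA
    if (plan$n_zero[i] > 0) {
      j <- plan$n_missing[i] + seq_len(plan$n_zero[i])
      d$catch_weight[j] <- 0
      d$catch_count[j] <- 0
    }
    rows[[i]] <- d
  }
  do.call(rbind, rows)
}

# the printed significance tallies of the initial biomass model
# (counts of p < 0.05 out of 100 cross-validation fits)
table1_counts <- function() {
  c(Y = 99, D = 100, BT = 18, Oxy = 96, Sal = 98, week = 0, ToD = 100,
    FisheryL = 95, FisheryN = 89,
    "Yr:FisheryY" = 100, "Yr:FisheryL" = 0, "Yr:FisheryN" = 100)
}
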