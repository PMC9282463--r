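test_that("a 4x4 nm square region tessellates into exactly four cells", {
  geom <- square_geom(4)
  grid <- build_grid(geom, cell_size_nm = 2)
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$area_nm2 == 4))
  expect_error(build_grid(geom, cell_size_nm = 0), "positive")
})

test_that("cell areas conserve the region area for an aligned rectangle", {
  geom <- rect_geom(12, 8)
  grid <- build_grid(geom, cell_size_nm = 2)
  expect_lt(abs(sum(grid$area_nm2) - 96) / 96, 0.01)
  # all cells share the nominal area
  expect_equal(length(unique(grid$area_nm2)), 1)
})

test_that("grid construction is deterministic and centres lie in their cells", {
  geom <- test_geom()
  g1 <- build_grid(geom, 2)
  g2 <- build_grid(geom, 2)
  expect_identical(g1, g2)
  expect_gt(nrow(g1), 100)
  ids <- cell_of(g1, geom, g1$lon, g1$lat)
  expect_identical(ids, g1$cell_id)
})

test_that("every simulated haul falls inside exactly one grid cell", {
  geom <- test_geom()
  grid <- build_grid(geom, 2)
  sim <- simulate_survey_series(geom, test_timeline(), seed = 12)
  ids <- cell_of(grid, geom, sim$hauls$X, sim$hauls$Y)
  expect_false(anyNA(ids))
  expect_true(all(ids %in% grid$cell_id))
})

test_that("cell mean depth matches independent fine quadrature of the surface", {
  geom <- test_geom()
  grid <- build_grid(geom, 2)
  informed <- assign_cell_attributes(grid, geom, test_timeline(),
                                     "spring", 2016)
  cfg <- geom$config
  k <- cos(geom$origin[["lat"]] * pi / 180)
  cs <- attr(grid, "cell_size_nm")
  pick <- c(1, nrow(grid) %/% 2, nrow(grid))
  for (i in pick) {
    # 20x20 midpoint quadrature straight off the analytic formula
    u <- (seq_len(20) - 0.5) / 20 - 0.5
    gx <- grid$x_nm[i] + u * cs
    gy <- grid$y_nm[i] + u * cs
    qq <- expand.grid(x = gx, y = gy)
    d_ref <- rep(cfg$base_depth, nrow(qq))
    for (j in seq_len(nrow(cfg$pits))) {
      p <- cfg$pits[j, ]
      pll <- nephcpue:::lonlat_to_nm(geom, p$lon, p$lat)
      d_ref <- d_ref + (p$depth - cfg$base_depth) *
        exp(-0.5 * (((qq$x - pll$x) / p$sx)^2 + ((qq$y - pll$y) / p$sy)^2))
    }
    expect_lt(abs(informed$D[i] - mean(d_ref)) / mean(d_ref), 0.005)
  }
})

test_that("constant depth surfaces give every cell that constant", {
  geom <- square_geom(8, base_depth = 180)
  grid <- build_grid(geom, 2)
  informed <- assign_cell_attributes(grid, geom, test_timeline(),
                                     "spring", 2016)
  expect_equal(informed$D, rep(180, nrow(grid)))
})

test_that("the autumn domain is the western subset of the spring domain", {
  geom <- test_geom()
  grid <- build_grid(geom, 2)
  sp <- assign_cell_attributes(grid, geom, test_timeline(), "spring", 2017)
  au <- assign_cell_attributes(grid, geom, test_timeline(), "autumn", 2017)
  expect_true(all(au$cell_id[au$in_domain] %in% sp$cell_id[sp$in_domain]))
  expect_lt(sum(au$in_domain), sum(sp$in_domain))
  expect_true(all(au$lon[au$in_domain] < geom$split_lon))
  # management levels follow the zones at the survey reference date
  expect_setequal(unique(sp$Fishery), c("Y", "L", "N"))
})

test_that("proxy filling copies donor layers and flags provenance", {
  geom <- test_geom()
  grid <- build_grid(geom, 4)
  tl <- test_timeline()
  mk <- function(survey, year, seed) {
    env <- sample_environment(geom, survey, year, n_stations = 15, seed = seed)
    assign_cell_attributes(grid, geom, tl, survey, year, env = env)
  }
  layers <- list(spring_2012 = mk("spring", 2012, 1),
                 spring_2013 = mk("spring", 2013, 2),
                 spring_2018 = mk("spring", 2018, 3),
                 spring_2019 = mk("spring", 2019, 4))
  layers$spring_2012$Oxy <- NA
  layers$spring_2018$BT <- NA
  layers$spring_2018$Sal <- NA
  layers$spring_2018$Oxy <- NA
  bt_2012 <- layers$spring_2012$BT
  filled <- proxy_fill(layers)
  expect_equal(filled$spring_2012$Oxy, filled$spring_2013$Oxy)
  for (p in c("BT", "Sal", "Oxy")) {
    expect_equal(filled$spring_2018[[p]], filled$spring_2019[[p]])
  }
  # observed layers are untouched
  expect_identical(filled$spring_2012$BT, bt_2012)
  expect_identical(filled$spring_2013, layers$spring_2013)
  prov12 <- attr(filled$spring_2012, "env_provenance_detail")
  expect_equal(unname(prov12["Oxy"]), "proxy:spring_2013")
  expect_equal(unname(prov12["BT"]), "observed")
  # complete inputs pass through unchanged
  again <- proxy_fill(filled)
  expect_equal(again$spring_2012$Oxy, filled$spring_2012$Oxy)
  # a missing donor is fatal and named
  expect_error(proxy_fill(layers["spring_2012"]), "spring_2013")
})

test_that("a constant-mean model yields the constant as standardized index", {
  d <- data.frame(biomass_index = rep(25, 30))
  fit <- fit_gam(gam_spec("biomass_index"), d)
  geom <- square_geom(8)
  grid <- assign_cell_attributes(build_grid(geom, 2), geom, test_timeline(),
                                 "spring", 2016)
  idx <- standardized_index(fit, grid)
  expect_equal(idx$index, 25, tolerance = 1e-8)
  expect_equal(idx$n_cells, sum(grid$in_domain))
  expect_gte(idx$se, 0)
})

test_that("the index is the arithmetic mean of per-cell predictions", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("D", 6)),
                          factors = c("Fishery", "ToD")), d)
  geom <- test_geom()
  grid <- assign_cell_attributes(build_grid(geom, 2), geom, test_timeline(),
                                 "spring", 2016)
  toy <- grid[1:3, ]
  toy$ToD <- "sunrise"
  by_hand <- mean(predict(fit, toy))
  idx <- standardized_index(fit, grid[1:3, ])
  expect_equal(idx$index, by_hand, tolerance = 1e-12)
  p <- predict(fit, toy, se.fit = TRUE)
  expect_equal(idx$se, sqrt(sum(p$se.fit^2)) / 3, tolerance = 1e-12)
})

test_that("a positive ban offset raises the index of a fully closed grid", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("D", 6)),
                          factors = c("Fishery", "ToD")), d)
  stopifnot(coef(fit$fit)[["FisheryN"]] > 0)
  geom <- test_geom()
  grid <- assign_cell_attributes(build_grid(geom, 2), geom, test_timeline(),
                                 "spring", 2016)
  g_open <- grid; g_open$Fishery <- "Y"
  g_ban <- grid; g_ban$Fishery <- "N"
  expect_gt(standardized_index(fit, g_ban)$index,
            standardized_index(fit, g_open)$index)
})

test_that("missing grid attributes are reported with the cell and attribute", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("D", 6)),
                          factors = "ToD"), d)
  geom <- square_geom(8)
  grid <- assign_cell_attributes(build_grid(geom, 2), geom, test_timeline(),
                                 "spring", 2016)
  grid$D[2] <- NA
  expect_error(standardized_index(fit, grid), "'D'")
})

test_that("observed-vs-predicted differences reproduce the reported increments", {
  expect_equal(round(compare_observed_predicted(24.9, 37.33)), 33)
  expect_equal(compare_observed_predicted(10, 10), 0)
  expect_equal(compare_observed_predicted(24.6, 71.3), 65.5, tolerance = 0.05)
  # the observed-denominator variant is available by flag
  expect_equal(compare_observed_predicted(20, 30, denominator = "observed"),
               50)
  expect_error(compare_observed_predicted(10, -5), "positive")
})
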