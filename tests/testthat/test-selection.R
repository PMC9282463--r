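test_that("VIF backward selection removes a longitude built from other covariates", {
  set.seed(21)
  n <- 150
  d <- data.frame(Y = runif(n, 42.8, 43.5), D = runif(n, 100, 270),
                  Oxy = rnorm(n, 88, 5), Sal = rnorm(n, 38.45, 0.1),
                  week = sample(15:47, n, TRUE))
  # longitude depends on latitude and depth, so it carries the highest VIF
  d$X <- 15.5 + 0.8 * (d$Y - 43.15) + 0.001 * (d$D - 180) + rnorm(n, 0, 0.01)
  v <- vif_backward(d, c("Y", "X", "D", "Oxy", "Sal", "week"), threshold = 3)
  expect_false("X" %in% v$retained)
  expect_true(all(c("Y", "D", "Oxy", "Sal", "week") %in% v$retained))
  final <- v$trace[[length(v$trace)]]$vif
  expect_true(all(final < 3))
  expect_equal(v$trace[[1]]$dropped, "X")
})

test_that("orthogonal covariates all survive with VIF near one", {
  set.seed(22)
  d <- as.data.frame(matrix(rnorm(300), ncol = 3))
  names(d) <- c("a", "b", "c")
  v <- vif_backward(d, c("a", "b", "c"))
  expect_setequal(v$retained, c("a", "b", "c"))
  expect_true(all(abs(v$trace[[1]]$vif - 1) < 0.2))
})

test_that("reported VIFs equal an independent implementation", {
  set.seed(23)
  n <- 100
  d <- data.frame(a = rnorm(n))
  d$b <- 0.7 * d$a + rnorm(n, 0, 0.5)
  d$c <- rnorm(n)
  d$resp <- rnorm(n)
  v <- vif_backward(d, c("a", "b", "c"), threshold = 1e9)
  vifs <- v$trace[[1]]$vif
  oracle <- car::vif(lm(resp ~ a + b + c, data = d))
  expect_equal(unname(vifs[c("a", "b", "c")]), unname(oracle[c("a", "b", "c")]),
               tolerance = 1e-8)
})

test_that("perfect collinearity is broken deterministically", {
  set.seed(24)
  d <- data.frame(a = rnorm(50))
  d$b <- 2 * d$a   # exact copy: both VIFs infinite
  d$c <- rnorm(50)
  v <- vif_backward(d, c("a", "b", "c"))
  expect_equal(v$trace[[1]]$dropped, "a")  # alphabetical tie-break
  expect_setequal(v$retained, c("b", "c"))
})

test_that("the four candidate specifications match their printed term sets", {
  cands <- candidate_models("biomass_index")
  expect_named(cands, c("modINITIAL", "modNOEM", "modNOE", "modNOM"))
  sm_vars <- function(s) vapply(s$smooths, `[[`, "", "var")
  expect_setequal(sm_vars(cands$modNOEM), c("Y", "D", "week", "Yr"))
  expect_equal(cands$modNOEM$factors, "ToD")
  # the initial model carries the year-by-fishery smooth and both factors
  by_of <- function(s) unlist(lapply(s$smooths, `[[`, "by"))
  expect_equal(by_of(cands$modINITIAL), "Fishery")
  expect_setequal(cands$modINITIAL$factors, c("Fishery", "ToD"))
  expect_setequal(sm_vars(cands$modINITIAL),
                  c("Y", "D", "BT", "Oxy", "Sal", "week", "Yr"))
  expect_equal(by_of(cands$modNOE), "Fishery")
  expect_false("Fishery" %in% cands$modNOM$factors)
  for (s in cands) {
    expect_equal(s$response, "biomass_index")
    expect_true(all(vapply(s$smooths, `[[`, 0, "k") <= 6))
  }
  expect_lt(n_covariates(cands$modNOEM), n_covariates(cands$modNOE))
  expect_lt(n_covariates(cands$modNOE), n_covariates(cands$modNOM))
  expect_lt(n_covariates(cands$modNOM), n_covariates(cands$modINITIAL))
})

test_that("fold partitions are disjoint, exhaustive and level-complete", {
  d <- test_dataset(7)
  set.seed(5)
  fd <- nephcpue:::draw_folds(d, k = 10, fac_cols = c("Fishery", "ToD"))
  expect_equal(length(fd$fold), nrow(d))
  expect_setequal(unique(fd$fold), 1:10)
  for (i in 1:10) {
    train <- d[fd$fold != i, ]
    expect_setequal(unique(train$Fishery), unique(d$Fishery))
    expect_setequal(unique(train$ToD), unique(d$ToD))
  }
})

test_that("repeated k-fold CV yields k x repeats records and is seed-stable", {
  d <- test_dataset(7)
  spec <- candidate_models("biomass_index")$modNOEM
  cv <- repeated_kfold_cv(spec, d, k = 10, repeats = 2, seed = 42)
  expect_s3_class(cv, "cv_result")
  expect_equal(length(cv$aic), 20)
  expect_equal(nrow(cv$pvals), 20)
  expect_equal(cv$n_fits, 20)
  expect_true(all(cv$sig_counts >= 0 & cv$sig_counts <= 20))
  cv2 <- repeated_kfold_cv(spec, d, k = 10, repeats = 2, seed = 42)
  expect_identical(cv$aic, cv2$aic)
  expect_identical(cv$rmse, cv2$rmse)
  cv3 <- repeated_kfold_cv(spec, d, k = 10, repeats = 2, seed = 43)
  expect_false(identical(cv$aic, cv3$aic))
})

fake_cv <- function(id, aic) {
  structure(list(id = id, aic = aic, pvals = NULL,
                 sig_counts = integer(0), n_fits = length(aic),
                 rmse = rep(1, length(aic)), alpha = 0.05, redraws = 0L),
            class = "cv_result")
}

test_that("identical AIC distributions fall back to the simplest candidate", {
  aic <- rep(500, 40)
  cvs <- list(fake_cv("modINITIAL", aic), fake_cv("modNOEM", aic),
              fake_cv("modNOE", aic), fake_cv("modNOM", aic))
  cmp <- compare_models_aic(cvs)
  expect_equal(cmp$selected, "modNOEM")
  expect_equal(cmp$rationale, "no_clear_separation_simplest_model")
})

test_that("well-separated AIC distributions pick the lowest mean with all pairs significant", {
  set.seed(31)
  base <- rnorm(100, sd = 1)
  cvs <- list(fake_cv("modINITIAL", 500 + base),
              fake_cv("modNOEM", 510 + rnorm(100)),
              fake_cv("modNOE", 520 + rnorm(100)),
              fake_cv("modNOM", 530 + rnorm(100)))
  cmp <- compare_models_aic(cvs)
  expect_equal(cmp$selected, "modINITIAL")
  expect_equal(cmp$rationale, "lowest_mean_aic_all_pairs_significant")
  expect_true(all(cmp$tukey$p < 0.05))
  expect_equal(cmp$anova$type, "anova")
})

test_that("heteroscedastic AIC distributions route through Welch and Games-Howell", {
  set.seed(32)
  cvs <- list(fake_cv("modINITIAL", 500 + rnorm(100, sd = 0.5)),
              fake_cv("modNOEM", 515 + rnorm(100, sd = 8)),
              fake_cv("modNOE", 525 + rnorm(100, sd = 0.5)),
              fake_cv("modNOM", 535 + rnorm(100, sd = 8)))
  cmp <- compare_models_aic(cvs)
  expect_equal(cmp$anova$type, "welch")
  expect_equal(cmp$selected, "modINITIAL")
})

test_that("replaying the printed significance tallies reproduces the final term set", {
  ret <- retention_rule(table1_counts(), threshold = 0.80, total = 100)
  expect_setequal(ret$retained,
                  c("Y", "D", "Oxy", "Sal", "ToD", "Fishery", "Yr:Fishery"))
  expect_setequal(ret$dropped, c("BT", "week"))
})

test_that("retention respects the threshold boundary and saturation", {
  counts <- c(A = 100, B = 100, C = 100)
  ret <- retention_rule(counts, total = 100)
  expect_setequal(ret$retained, c("A", "B", "C"))
  ret2 <- retention_rule(c(A = 80, B = 79), total = 100)
  expect_equal(ret2$retained, "A")
  expect_equal(ret2$dropped, "B")
})

test_that("retention is monotone in the significance counts", {
  set.seed(33)
  nm <- names(table1_counts())
  for (i in 1:20) {
    counts <- stats::setNames(sample(0:100, length(nm), TRUE), nm)
    before <- retention_rule(counts, total = 100)$retained
    j <- sample(seq_along(nm), 1)
    counts[j] <- min(100, counts[j] + sample(1:20, 1))
    after <- retention_rule(counts, total = 100)$retained
    expect_true(all(before %in% after))
  }
})

test_that("pruning a spec keeps exactly the retained terms", {
  spec <- candidate_models("biomass_index")$modINITIAL
  final <- prune_spec(spec, c("Y", "D", "Oxy", "Sal", "ToD", "Fishery",
                              "Yr:Fishery"))
  vars <- vapply(final$smooths, `[[`, "", "var")
  expect_setequal(vars, c("Y", "D", "Oxy", "Sal", "Yr"))
  expect_setequal(final$factors, c("Fishery", "ToD"))
  expect_false("BT" %in% vars)
  expect_false("week" %in% vars)
})

test_that("held-out RMSE is reproducible and follows its arithmetic", {
  d <- test_dataset(7)
  spec <- candidate_models("biomass_index")$modNOEM
  r1 <- rmse_compare(spec, spec, d, k = 5, repeats = 1, seed = 9)
  expect_identical(r1$rmse[[1]], r1$rmse[[2]])
  expect_equal(unname(r1$mean_rmse[1]), unname(r1$mean_rmse[2]))
  # arithmetic on a constant-response fit: residuals 1, 2, 2 -> sqrt(3)
  dtrain <- data.frame(biomass_index = rep(4, 12))
  fit <- fit_gam(gam_spec("biomass_index"), dtrain)
  pred <- predict(fit, data.frame(z = 1:3))
  y_test <- c(5, 6, 6)
  expect_equal(sqrt(mean((y_test - pred)^2)), sqrt(3), tolerance = 1e-8)
})

test_that("stratified partitions balance folds within each survey", {
  d <- test_dataset(7)
  set.seed(6)
  fd <- nephcpue:::draw_folds(d, k = 5, fac_cols = "ToD",
                              stratify = "survey")
  for (s in unique(d$survey)) {
    tab <- table(fd$fold[d$survey == s])
    expect_lte(max(tab) - min(tab), 1)  # near-equal within stratum
  }
})

test_that("the joint retention rule drops a term only when both responses drop it", {
  a <- list(retained = c("D", "Oxy", "Fishery"), dropped = c("BT", "week"))
  b <- list(retained = c("D", "Sal", "Fishery", "BT"), dropped = c("week"))
  expect_identical(combine_retention(list(a, b)), list(a, b))
  joint <- combine_retention(list(a, b), rule = "drop_if_both")
  expect_setequal(joint$retained, c("D", "Oxy", "Sal", "Fishery", "BT"))
  expect_equal(joint$dropped, "week")
})

test_that("the cascade recovers the planted term set under detectable effects", {
  geom <- test_geom(); tl <- test_timeline()
  target <- sort(c("Y", "D", "Oxy", "Sal", "Yr:Fishery", "Fishery", "ToD"))
  hits <- 0
  n_rep <- 10
  for (s in seq_len(n_rep)) {
    sim <- simulate_survey_series(geom, tl, strong_effects(),
                                  strong_survey_config(), seed = 100 + s)
    fr <- filter_records(compute_indices(sim$hauls))
    cv <- repeated_kfold_cv(candidate_models("biomass_index")$modINITIAL,
                            fr$table, k = 10, repeats = 2, seed = s)
    ret <- retention_rule(cv)
    hits <- hits + identical(sort(ret$retained), target)
  }
  expect_gte(hits / n_rep, 0.8)
})
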