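test_that("the spline basis matches a textbook cubic regression spline", {
  set.seed(1)
  x <- sort(runif(40, 0, 10))
  bb <- build_basis(x, k = 6)
  # evaluate both constructions at 11 interior points
  xe <- seq(min(x) + 0.1, max(x) - 0.1, length.out = 11)
  sm <- mgcv::smoothCon(mgcv::s(x, k = 6, bs = "cr"),
                        data = data.frame(x = x), absorb.cons = FALSE)[[1]]
  Xe <- mgcv::PredictMat(sm, data.frame(x = xe))
  ref <- cr_reference(xe, bb$knots)
  expect_lt(max(abs(Xe - ref$X)), 1e-8)
  expect_lt(max(abs(bb$S / max(bb$S) - ref$S / max(ref$S))), 1e-8)
})

test_that("the wiggliness penalty has a two-dimensional null space", {
  set.seed(2)
  x <- runif(60, 0, 1)
  bb <- build_basis(x, k = 6)
  expect_equal(qr(bb$S)$rank, 4)
  # linear functions are penalty-free: represent a + b*x and check both the
  # residual and the penalty of the representation
  y <- 2 + 3 * x
  beta <- qr.solve(bb$X, y)
  expect_lt(max(abs(bb$X %*% beta - y)), 1e-8)
  expect_lt(drop(t(beta) %*% bb$S %*% beta), 1e-12)
})

test_that("basis construction rejects covariates with too few distinct values", {
  expect_error(build_basis(rep(c(1, 2, 3), 10), k = 6), "distinct")
})

test_that("an intercept-only Gamma fit recovers log of a constant response", {
  d <- data.frame(biomass_index = rep(7.5, 20))
  spec <- gam_spec("biomass_index")
  fit <- fit_gam(spec, d)
  expect_equal(unname(coef(fit$fit)[1]), log(7.5), tolerance = 1e-8)
  # and the response-scale prediction equals the training mean
  expect_equal(predict(fit, data.frame(x = 1:3)), rep(7.5, 3),
               tolerance = 1e-8)
})

test_that("a single linear log-link effect is recovered against a GLM oracle", {
  hits_glm <- 0; agree <- 0
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    d <- gamma_lin_data(n = 100, b0 = 1, b1 = 0.8, shape = 4, seed = 5000 + s)
    d$biomass_index <- d$y
    # oracle: unpenalized Gamma GLM
    g <- glm(y ~ x, family = Gamma(link = "log"), data = d)
    ci_ok <- abs(coef(g)[["x"]] - 0.8) <= 3 * summary(g)$coefficients["x", 2]
    hits_glm <- hits_glm + ci_ok
    # package route: penalized smooth of x; implied slope from predictions
    fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("x", 5))), d)
    eta <- log(predict(fit, data.frame(x = c(-0.5, 0.5))))
    agree <- agree + (abs((eta[2] - eta[1]) - coef(g)[["x"]]) < 0.25)
  }
  expect_gte(hits_glm / n_rep, 0.95)
  expect_gte(agree / n_rep, 0.95)
})

test_that("infinite smoothing reduces the fit to an unpenalized linear GLM", {
  d <- gamma_lin_data(n = 120, b0 = 1, b1 = 0.6, shape = 5, seed = 77)
  d$biomass_index <- d$y
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("x", 6))), d,
                 sp = 1e10)
  g <- glm(y ~ x, family = Gamma(link = "log"), data = d)
  xe <- data.frame(x = seq(-0.9, 0.9, length.out = 7))
  eta_gam <- log(predict(fit, xe))
  eta_glm <- as.numeric(predict(g, xe, type = "link"))
  expect_equal(eta_gam, eta_glm, tolerance = 1e-4)
  # AIC agrees with the textbook GLM AIC computed with an independently
  # estimated maximum-likelihood shape
  shape_or <- MASS::gamma.shape(g)$alpha
  mu <- fitted(g)
  ll_or <- sum(dgamma(d$y, shape = shape_or, rate = shape_or / mu, log = TRUE))
  aic_or <- -2 * ll_or + 2 * (2 + 1)
  expect_equal(gam_aic(fit), aic_or, tolerance = 1e-3)
})

test_that("AIC follows its definition and penalizes useless complexity", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("D", 6)),
                          factors = "ToD"), d)
  expect_equal(gam_aic(fit),
               -2 * fit$loglik + 2 * (sum(fit$fit$edf) + 1))
  expect_true(is.finite(gam_aic(fit)))
  # a planted strong effect must be preferred by AIC nearly always
  wins <- 0
  for (s in seq_len(100)) {
    dd <- gamma_lin_data(n = 80, b0 = 1, b1 = 1, shape = 4, seed = 6000 + s)
    dd$biomass_index <- dd$y
    with_x <- fit_gam(gam_spec("biomass_index", list(smooth_term("x", 5))), dd)
    without <- fit_gam(gam_spec("biomass_index"), dd)
    wins <- wins + (gam_aic(with_x) < gam_aic(without))
  }
  expect_gte(wins, 95)
})

test_that("response-scale standard errors follow the delta method", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index",
                          list(smooth_term("D", 6), smooth_term("Oxy", 6)),
                          factors = "ToD"), d)
  nd <- d[1:15, ]
  p <- predict(fit, nd, se.fit = TRUE)
  expect_true(all(p$se.fit >= 0))
  # numeric differentiation of the inverse link at eta
  pl <- mgcv::predict.gam(fit$fit, nd, type = "link", se.fit = TRUE)
  h <- 1e-6
  dinv <- (exp(pl$fit + h) - exp(pl$fit - h)) / (2 * h)
  expect_equal(p$se.fit, as.numeric(dinv * pl$se.fit), tolerance = 1e-6)
  expect_equal(p$fit, as.numeric(exp(pl$fit)))
})

test_that("prediction rejects factor levels never seen in training", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index", list(smooth_term("D", 6)),
                          factors = "ToD"), d)
  nd <- d[1:3, ]
  nd$ToD <- "midnight"
  expect_error(predict(fit, nd), "midnight")
})

test_that("summaries expose deviance explained, adjusted R2 and by-level smooth rows", {
  d <- test_dataset(7)
  null_fit <- fit_gam(gam_spec("biomass_index"), d)
  expect_equal(summarize_fit(null_fit)$deviance_explained, 0, tolerance = 1e-12)
  fit <- fit_gam(candidate_models("biomass_index")$modINITIAL, d)
  s <- summarize_fit(fit)
  # recomputation from the two deviances
  expect_equal(s$deviance_explained,
               1 - fit$fit$deviance / fit$fit$null.deviance)
  expect_gte(s$deviance_explained, 0)
  expect_lte(s$deviance_explained, 1)
  # one smooth row per level of the year-by-fishery interaction
  yr_rows <- grep("^s\\(Yr\\):", rownames(s$smooths))
  expect_equal(length(yr_rows), 3)
  # per-smooth edf bounded by basis size
  expect_true(all(s$smooths$edf >= 0 & s$smooths$edf <= 6 - 1))
  # residual deviance never exceeds the null deviance
  expect_lte(fit$fit$deviance, fit$fit$null.deviance)
})

test_that("term significance is a calibrated test of a null factor", {
  d <- test_dataset(7)
  fit <- fit_gam(candidate_models("biomass_index")$modINITIAL, d)
  p <- term_pvalues(fit)
  expect_true(all(p >= 0 & p <= 1))
  expect_setequal(names(p),
                  c("FisheryL", "FisheryN", "ToD", "Y", "D", "BT", "Oxy",
                    "Sal", "week", "Yr:FisheryY", "Yr:FisheryL",
                    "Yr:FisheryN"))
  expect_equal(term_significance(fit, "D"), unname(p[["D"]]))
  expect_error(term_significance(fit, "nope"), "unknown term")
  # type-I behaviour: a covariate with no effect rejects at ~alpha
  rej <- 0
  n_sim <- 500
  for (s in seq_len(n_sim)) {
    set.seed(7000 + s)
    dd <- data.frame(ToD = rep(c("sunrise", "sunset"), each = 30))
    dd$biomass_index <- rgamma(60, shape = 4, rate = 4 / exp(3))
    f0 <- fit_gam(gam_spec("biomass_index", factors = "ToD"), dd)
    rej <- rej + (term_significance(f0, "ToD") < 0.05)
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.08)
})

test_that("a planted four-sigma effect is detected nearly always", {
  hits <- 0
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    set.seed(8000 + s)
    n <- 100
    tod <- rep(c("sunrise", "sunset"), each = n / 2)
    # effect sized ~4 standard errors: SE ~ sd_log * 2 / sqrt(n)
    eff <- 4 * (1 / sqrt(4)) * 2 / sqrt(n)
    mu <- exp(3 + ifelse(tod == "sunset", eff, 0))
    dd <- data.frame(ToD = tod,
                     biomass_index = rgamma(n, shape = 4, rate = 4 / mu))
    f0 <- fit_gam(gam_spec("biomass_index", factors = "ToD"), dd)
    hits <- hits + (term_significance(f0, "ToD") < 0.05)
  }
  expect_gte(hits / n_sim, 0.95)
})

test_that("factor flips act multiplicatively through the log link", {
  d <- test_dataset(7)
  fit <- fit_gam(gam_spec("biomass_index",
                          list(smooth_term("D", 6), smooth_term("Oxy", 6)),
                          factors = c("Fishery", "ToD")), d)
  nd <- d[5, ]
  nd_y <- nd; nd_y$Fishery <- "Y"
  nd_l <- nd; nd_l$Fishery <- "L"
  ratio <- predict(fit, nd_l) / predict(fit, nd_y)
  expect_equal(log(ratio), unname(coef(fit$fit)[["FisheryL"]]),
               tolerance = 1e-10)
})

test_that("log-link coefficients translate to the reported percent effects", {
  expect_equal(effect_percent(0), 0)
  # limited fishery and ban offsets, biomass then density
  expect_equal(round(effect_percent(0.65)), 92)
  expect_equal(round(effect_percent(0.66)), 93)
  expect_equal(round(effect_percent(0.46)), 58)
  expect_equal(round(effect_percent(0.72)), 105)
  # sunset offsets
  expect_equal(round(effect_percent(-0.39)), -32)
  expect_equal(round(effect_percent(-0.35)), -30)
})

test_that("model specs round-trip through their compact text form", {
  spec <- candidate_models("biomass_index")$modINITIAL
  txt <- format(spec)
  back <- parse_gam_spec(txt, "biomass_index", id = "modINITIAL")
  expect_equal(format(back), txt)
  expect_equal(n_covariates(back), n_covariates(spec))
  expect_error(gam_spec("biomass_index",
                        list(smooth_term("D"), smooth_term("D"))),
               "duplicate")
})
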