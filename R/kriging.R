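#' Empirical semivariogram
#'
#' Method-of-moments (Matheron) estimator on distance bins:
#' \eqn{\hat\gamma(h) = \frac{1}{2|N(h)|}\sum_{N(h)} (z_i - z_j)^2}.
#'
#' @param x,y planar coordinates (e.g. nautical miles).
#' @param values observed values.
#' @param n_bins number of distance bins.
#' @param cutoff maximum pair distance considered; default half the maximum
#'   distance.
#' @return data frame with `dist` (bin mean distance), `gamma`, `n` (pairs).
#' @export
empirical_semivariogram <- function(x, y, values, n_bins = 12, cutoff = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(values))
  d <- as.matrix(stats::dist(cbind(x, y)))
  g <- 0.5 * outer(values, values, "-")^2
  iu <- upper.tri(d)
  dd <- d[iu]; gg <- g[iu]
  cutoff <- cutoff %||% (max(dd) / 2)
  keep <- dd <= cutoff & dd > 0
  dd <- dd[keep]; gg <- gg[keep]
  br <- seq(0, cutoff, length.out = n_bins + 1)
  bin <- cut(dd, br, include.lowest = TRUE)
  out <- data.frame(
    dist = as.numeric(tapply(dd, bin, mean)),
    gamma = as.numeric(tapply(gg, bin, mean)),
    n = as.integer(tapply(gg, bin, length)))
  out[!is.na(out$gamma), , drop = FALSE]
}

vgm_gamma <- function(h, model, nugget, psill, range) {
  s <- switch(model,
              exponential = psill * (1 - exp(-h / range)),
              spherical = psill * ifelse(h < range,
                                         1.5 * h / range - 0.5 * (h / range)^3, 1),
              gaussian = psill * (1 - exp(-(h / range)^2)),
              stop("unknown variogram model: ", model))
  ifelse(h > 0, nugget + s, 0)
}

vgm_cov <- function(h, model, nugget, psill, range) {
  nugget + psill - vgm_gamma(h, model, nugget, psill, range)
}

#' Fit a variogram model by weighted least squares
#'
#' Fits partial sill and range (nugget fixed, default 0) to an empirical
#' semivariogram, minimising \eqn{\sum_j n_j (\hat\gamma_j -
#' \gamma(h_j))^2 / \gamma(h_j)^2} (Cressie weights).
#'
#' @param emp output of [empirical_semivariogram()].
#' @param model `"exponential"` (default), `"spherical"` or `"gaussian"`.
#' @param nugget fixed nugget value.
#' @param max_range upper bound on the fitted range; defaults to three times
#'   the largest lag. An unbounded (trend-dominated) semivariogram drives
#'   sill and range jointly to infinity, so the bound keeps the model
#'   identified and the downstream kriging system well conditioned.
#' @return list of class `variogram_model` with `model`, `nugget`, `psill`,
#'   `range`.
#' @export
fit_variogram_wls <- function(emp, model = "exponential", nugget = 0,
                              max_range = NULL) {
  stopifnot(nrow(emp) >= 3)
  max_range <- max_range %||% (3 * max(emp$dist))
  obj <- function(par) {
    g <- vgm_gamma(emp$dist, model, nugget, exp(par[1]), exp(par[2]))
    sum(emp$n * (emp$gamma - g)^2 / pmax(g, 1e-12)^2)
  }
  start <- c(log(max(max(emp$gamma), 1e-8)), log(max(emp$dist) / 3))
  fit <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = c(log(1e-10), log(max(emp$dist) / 100)),
                      upper = c(log(100 * max(emp$gamma) + 1e-8),
                                log(max_range)),
                      control = list(maxit = 2000, factr = 1e4))
  structure(list(model = model, nugget = nugget,
                 psill = exp(fit$par[1]), range = exp(fit$par[2])),
            class = "variogram_model")
}

#' Ordinary kriging
#'
#' Exact interpolation with the unbiasedness constraint (weights sum to 1):
#' solves the standard ordinary-kriging system built from the variogram
#' covariances. Stations at (numerically) duplicate locations are jittered
#' slightly, with a message.
#'
#' @param x,y station coordinates (planar).
#' @param values station values.
#' @param x0,y0 target coordinates (vectorised).
#' @param vgm a `variogram_model` (see [fit_variogram_wls()]); when `NULL`,
#'   one is fitted to the stations' empirical semivariogram.
#' @param return_weights also return the weight matrix (targets x stations).
#' @return list with `pred`, `var` (kriging variance) and optionally
#'   `weights`.
#' @export
krige_ordinary <- function(x, y, values, x0, y0, vgm = NULL,
                           return_weights = FALSE) {
  n <- length(x)
  stopifnot(n >= 4, length(y) == n, length(values) == n)
  if (stats::sd(values) == 0) {
    # constant field: kriging returns the constant everywhere
    k <- length(x0)
    return(list(pred = rep(values[1], k), var = rep(0, k),
                weights = if (return_weights)
                  matrix(1 / n, k, n) else NULL))
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  dup <- which(d < 1e-9 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    message("jittering ", nrow(dup), " duplicate station location(s)")
    jit <- 1e-6 * max(d)
    x[dup[, 2]] <- x[dup[, 2]] + jit
    y[dup[, 2]] <- y[dup[, 2]] + jit
    d <- as.matrix(stats::dist(cbind(x, y)))
  }
  if (is.null(vgm)) {
    emp <- empirical_semivariogram(x, y, values)
    vgm <- fit_variogram_wls(emp)
  }
  c0 <- vgm$nugget + vgm$psill
  # solve on correlation scale: the weights are invariant to a constant
  # rescaling of the covariance, and conditioning improves markedly
  C <- vgm_cov(d, vgm$model, vgm$nugget, vgm$psill, vgm$range) / c0
  diag(C) <- 1
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(x0, x, "-")^2 + outer(y0, y, "-")^2)
  C0 <- vgm_cov(d0, vgm$model, vgm$nugget, vgm$psill, vgm$range) / c0
  # at zero distance the target coincides with a station: full covariance
  C0[d0 < 1e-12] <- 1
  B <- rbind(t(C0), 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    solve(A + diag(1e-10, n + 1), B)
  })
  W <- t(sol[seq_len(n), , drop = FALSE])
  mlag <- sol[n + 1, ]
  pred <- as.numeric(W %*% values)
  varz <- pmax(c0 * (1 - rowSums(W * C0) - mlag), 0)
  list(pred = pred, var = as.numeric(varz),
       weights = if (return_weights) W else NULL)
}

#' Krige one environmental parameter onto grid-cell centres
#'
#' Projects stations and cell centres into the local nautical-mile frame,
#' fits an exponential variogram (nugget 0) to the stations by weighted
#' least squares unless one is supplied, and predicts by ordinary kriging at
#' each cell centre.
#'
#' @param stations data frame with `lon`, `lat` and the parameter column.
#' @param grid a grid built by [build_grid()].
#' @param param parameter column name (`"BT"`, `"Sal"` or `"Oxy"`).
#' @param geom the `study_geometry` defining the local frame.
#' @param vgm optional `variogram_model` overriding the fitted one.
#' @return numeric vector of per-cell values (one per grid row).
#' @export
krige_environment <- function(stations, grid, param, geom, vgm = NULL) {
  stopifnot(param %in% names(stations), nrow(stations) >= 4)
  st <- lonlat_to_nm(geom, stations$lon, stations$lat)
  tg <- lonlat_to_nm(geom, grid$lon, grid$lat)
  krige_ordinary(st$x, st$y, stations[[param]], tg$x, tg$y, vgm = vgm)$pred
}
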