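#' Specify a Gamma additive model
#'
#' A model specification holds the response, the list of penalized cubic
#' regression spline terms (each with its basis dimension `k` and optional
#' by-factor), and the parametric factor terms. All models use the Gamma
#' family with log link and REML smoothness selection; the basis dimension
#' is capped at 6 by default to suit small survey samples.
#'
#' @param response `"biomass_index"` or `"density_index"`.
#' @param smooths list of smooth terms created by [smooth_term()].
#' @param factors character vector of factor covariates (e.g. `"Fishery"`,
#'   `"ToD"`).
#' @param id optional label for reports.
#' @return object of class `gam_spec`.
#' @export
gam_spec <- function(response, smooths = list(), factors = character(0),
                     id = NULL) {
  stopifnot(response %in% c("biomass_index", "density_index"))
  vars <- c(vapply(smooths, `[[`, "", "var"), factors)
  if (anyDuplicated(vars)) stop("duplicate model terms: ",
                                paste(vars[duplicated(vars)], collapse = ", "))
  structure(list(response = response, smooths = smooths, factors = factors,
                 id = id %||% "model"),
            class = "gam_spec")
}

#' @rdname gam_spec
#' @param var covariate name of a smooth term.
#' @param k basis dimension (>= 3).
#' @param by optional by-factor name: the smooth is estimated separately per
#'   factor level.
#' @export
smooth_term <- function(var, k = 6, by = NULL) {
  stopifnot(k >= 3)
  list(var = var, k = k, by = by)
}

#' Distinct covariates used by a specification
#'
#' Counts each covariate once (a by-factor smooth counts its covariate and
#' its factor), the complexity measure used for the "fewest covariates"
#' tie-break in model comparison.
#'
#' @param spec a `gam_spec`.
#' @return integer.
#' @export
n_covariates <- function(spec) {
  v <- c(vapply(spec$smooths, `[[`, "", "var"),
         unlist(lapply(spec$smooths, `[[`, "by")),
         spec$factors)
  length(unique(v))
}

#' @export
format.gam_spec <- function(x, ...) {
  sm <- vapply(x$smooths, function(s) {
    if (is.null(s$by)) sprintf("s(%s,k=%d)", s$var, s$k)
    else sprintf("s(%s,k=%d,by=%s)", s$var, s$k, s$by)
  }, "")
  paste0("gamma_log: ", paste(c(sm, x$factors), collapse = "+"))
}

#' @export
print.gam_spec <- function(x, ...) {
  cat(x$id, "->", x$response, "\n  ", format(x), "\n")
  invisible(x)
}

#' Parse a compact model-formula string
#'
#' Inverse of `format.gam_spec`: reads strings like
#' `"gamma_log: s(Y,k=6)+s(Yr,k=6,by=Fishery)+Fishery+ToD"`.
#'
#' @param text the compact formula.
#' @param response response column name.
#' @param id optional label.
#' @return a [gam_spec()].
#' @export
parse_gam_spec <- function(text, response, id = NULL) {
  body <- sub("^\\s*gamma_log\\s*:\\s*", "", text)
  parts <- strsplit(body, "\\+")[[1]]
  parts <- trimws(parts)
  smooths <- list(); factors <- character(0)
  for (p in parts) {
    if (grepl("^s\\(", p)) {
      inner <- sub("^s\\((.*)\\)$", "\\1", p)
      kv <- strsplit(inner, ",")[[1]]
      var <- trimws(kv[1]); k <- 6; by <- NULL
      for (a in kv[-1]) {
        a <- trimws(a)
        if (grepl("^k=", a)) k <- as.integer(sub("^k=", "", a))
        if (grepl("^by=", a)) by <- sub("^by=", "", a)
      }
      smooths <- c(smooths, list(smooth_term(var, k, by)))
    } else if (nzchar(p)) {
      factors <- c(factors, p)
    }
  }
  gam_spec(response, smooths, factors, id = id)
}

mgcv_formula <- function(spec) {
  sm <- vapply(spec$smooths, function(s) {
    if (is.null(s$by)) sprintf('s(%s, k = %d, bs = "cr")', s$var, s$k)
    else sprintf('s(%s, k = %d, bs = "cr", by = %s)', s$var, s$k, s$by)
  }, "")
  rhs <- paste(c(sm, spec$factors), collapse = " + ")
  if (!nzchar(rhs)) rhs <- "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Cubic regression spline basis and penalty
#'
#' Builds the design matrix and wiggliness penalty of a penalized cubic
#' regression spline with knots at evenly spaced quantiles of `x`: the
#' penalty is the integrated squared second derivative, so its null space
#' (constant + linear functions) has dimension 2 and the penalty matrix has
#' rank `k - 2`. With `center = TRUE` the sum-to-zero constraint used when
#' the term coexists with an intercept is absorbed, leaving `k - 1` columns.
#'
#' @param x numeric covariate vector with at least `k` distinct values.
#' @param k basis dimension (>= 3).
#' @param center absorb the centering (sum-to-zero) constraint.
#' @return list with `X` (basis matrix), `S` (penalty matrix) and `knots`.
#' @export
build_basis <- function(x, k, center = FALSE) {
  stopifnot(k >= 3)
  if (length(unique(x)) < k) {
    stop("covariate has fewer than k = ", k, " distinct values")
  }
  sm <- mgcv::smoothCon(mgcv::s(x, k = k, bs = "cr"),
                        data = data.frame(x = x),
                        absorb.cons = center)[[1]]
  list(X = sm$X, S = sm$S[[1]], knots = sm$xp)
}

# Maximum-likelihood Gamma shape given observations and fitted means.
# A perfect fit drives the shape to infinity; it is capped so downstream
# likelihood arithmetic stays finite.
gamma_shape_ml <- function(y, mu, cap = 1e8) {
  r <- mean(log(y / mu) - y / mu)  # <= -1, equality iff y == mu
  if (r >= -1 - 1e-12) return(cap)
  f <- function(a) log(a) - digamma(a) + 1 + r
  min(stats::uniroot(f, c(1e-6, 1e8), tol = 1e-10)$root, cap)
}

gamma_loglik <- function(y, mu, shape) {
  sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
}

#' Fit a Gamma additive model
#'
#' Fits the specification with `mgcv::gam` (Gamma family, log link, REML
#' smoothness selection, penalized cubic regression splines), then estimates
#' the Gamma shape by maximum likelihood given the fitted means. Factor
#' covariates are coerced with reference levels `Fishery = "Y"` and
#' `ToD = "sunrise"`, matching the open-fishery / sunrise baseline used for
#' interpretation.
#'
#' @param spec a [gam_spec()].
#' @param data a filtered `cpue_table`: positive response, no missing values
#'   in modelled covariates, and at least 2 observations per factor level.
#' @param sp optional fixed smoothing parameters (passed to `mgcv::gam`);
#'   `NULL` (default) selects them by REML. Very large values drive every
#'   smooth into its penalty null space (a linear fit).
#' @return object of class `neph_gam` wrapping the mgcv fit, with elements
#'   `fit`, `spec`, `shape` (ML Gamma shape), `loglik` and `aic`.
#' @export
fit_gam <- function(spec, data, sp = NULL) {
  stopifnot(inherits(spec, "gam_spec"), is.data.frame(data))
  used <- unique(c(vapply(spec$smooths, `[[`, "", "var"),
                   unlist(lapply(spec$smooths, `[[`, "by")),
                   spec$factors, spec$response))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) stop("data lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (anyNA(data[, used])) stop("missing values in modelled covariates; ",
                                "apply filter_records() first")
  y <- data[[spec$response]]
  if (any(y <= 0)) stop("response must be strictly positive for the Gamma family")
  if ("Fishery" %in% names(data)) {
    data$Fishery <- factor(data$Fishery,
                           levels = intersect(c("Y", "L", "N"),
                                              unique(as.character(data$Fishery))))
  }
  if ("ToD" %in% names(data)) {
    data$ToD <- factor(data$ToD,
                       levels = intersect(c("sunrise", "sunset"),
                                          unique(as.character(data$ToD))))
  }
  fac_used <- intersect(c(spec$factors, unlist(lapply(spec$smooths, `[[`, "by"))),
                        names(data))
  for (f in fac_used) {
    tab <- table(data[[f]])
    if (any(tab < 2)) stop("factor ", f, " has level(s) with < 2 observations: ",
                           paste(names(tab)[tab < 2], collapse = ", "))
  }
  # a zero-variance response makes the REML scale profile degenerate; fixing
  # the scale leaves the (exact) coefficient estimates untouched
  scale_arg <- if (stats::var(y) == 0) 1 else -1
  fit <- mgcv::gam(mgcv_formula(spec), family = stats::Gamma(link = "log"),
                   data = data, method = "REML", sp = sp, scale = scale_arg,
                   control = mgcv::gam.control(epsilon = 1e-8, maxit = 200))
  if (!fit$converged) stop("GAM fit did not converge (outer iterations: ",
                           fit$outer.info$iter %||% NA, ")")
  mu <- as.numeric(stats::fitted(fit))
  shape <- gamma_shape_ml(y, mu)
  ll <- gamma_loglik(y, mu, shape)
  structure(list(fit = fit, spec = spec, shape = shape, loglik = ll,
                 aic = -2 * ll + 2 * (sum(fit$edf) + 1),
                 n = nrow(data)),
            class = "neph_gam")
}

#' AIC of a fitted Gamma additive model
#'
#' `AIC = -2 loglik + 2 (total edf + 1)`, where the log-likelihood is the
#' Gamma likelihood at the maximum-likelihood shape given the fitted means,
#' total edf sums the effective degrees of freedom of all coefficients, and
#' the `+ 1` counts the estimated shape parameter.
#'
#' @param fitted a `neph_gam`.
#' @return numeric scalar.
#' @export
gam_aic <- function(fitted) {
  stopifnot(inherits(fitted, "neph_gam"))
  fitted$aic
}

#' @export
AIC.neph_gam <- function(object, ..., k = 2) object$aic

#' @export
logLik.neph_gam <- function(object, ...) {
  structure(object$loglik, df = sum(object$fit$edf) + 1, class = "logLik")
}

#' Predict from a fitted Gamma additive model
#'
#' Predictions on the response scale: `mean = exp(eta)`; standard errors by
#' the delta method, `SE = exp(eta) * SE(eta)`.
#'
#' @param object a `neph_gam`.
#' @param newdata data frame containing every modelled covariate; factor
#'   levels must have been seen in training.
#' @param se.fit also return delta-method standard errors.
#' @param ... unused.
#' @return numeric vector of means, or a list with `fit` and `se.fit`.
#' @export
predict.neph_gam <- function(object, newdata, se.fit = FALSE, ...) {
  for (f in intersect(c("Fishery", "ToD"), names(object$fit$xlevels))) {
    seen <- object$fit$xlevels[[f]]
    new_lev <- setdiff(unique(as.character(newdata[[f]])), seen)
    if (length(new_lev)) stop("factor ", f, " has unseen level(s): ",
                              paste(new_lev, collapse = ", "))
    newdata[[f]] <- factor(as.character(newdata[[f]]), levels = seen)
  }
  p <- mgcv::predict.gam(object$fit, newdata = newdata, type = "link",
                         se.fit = se.fit)
  if (!se.fit) return(as.numeric(exp(p)))
  mu <- as.numeric(exp(p$fit))
  list(fit = mu, se.fit = mu * as.numeric(p$se.fit))
}

# Canonical term names: parametric coefficient rows keep their coefficient
# names ("FisheryL", "ToDsunset" -> "ToD"); smooth rows drop the s() wrapper
# ("s(Yr):FisheryY" -> "Yr:FisheryY").
canonical_term_names <- function(rn, parametric) {
  if (parametric) sub("^ToD.*$", "ToD", rn)
  else gsub("^s\\(([^)]+)\\)", "\\1", rn)
}

#' Per-term p-values of a fitted model
#'
#' Wald-type tests from the model summary: t-tests for parametric
#' coefficients (each non-reference factor level separately, e.g.
#' `FisheryL`, `FisheryN`; time of day reported as `ToD`), and the F-type
#' smooth test for each spline (by-factor smooths one row per level, e.g.
#' `Yr:FisheryY`).
#'
#' @param fitted a `neph_gam`.
#' @return named numeric vector of p-values in `[0, 1]`.
#' @export
term_pvalues <- function(fitted) {
  s <- summary(fitted$fit)
  pt <- s$p.table; st <- s$s.table
  p <- c()
  if (nrow(pt) > 1) {
    rows <- rownames(pt) != "(Intercept)"
    p <- stats::setNames(pt[rows, "Pr(>|t|)"],
                         canonical_term_names(rownames(pt)[rows], TRUE))
  }
  if (!is.null(st) && nrow(st) > 0) {
    p <- c(p, stats::setNames(st[, "p-value"],
                              canonical_term_names(rownames(st), FALSE)))
  }
  pmin(pmax(p, 0), 1)
}

#' @rdname term_pvalues
#' @param term one of the names returned by [term_pvalues()].
#' @export
term_significance <- function(fitted, term) {
  p <- term_pvalues(fitted)
  if (!term %in% names(p)) stop("unknown term '", term, "'; available: ",
                                paste(names(p), collapse = ", "))
  unname(p[term])
}

#' Summary tables of a fitted Gamma additive model
#'
#' @param fitted a `neph_gam`.
#' @return list of class `neph_gam_summary`: `parametric` (estimate, SE, t,
#'   p per coefficient), `smooths` (edf, reference df, F, p per smooth row),
#'   `deviance_explained` (in \[0, 1\]), `adj_r2`, `aic`, `edf_total`,
#'   `shape` and `n`.
#' @export
summarize_fit <- function(fitted) {
  stopifnot(inherits(fitted, "neph_gam"))
  s <- summary(fitted$fit)
  pt <- as.data.frame(s$p.table)
  names(pt) <- c("estimate", "se", "t", "p")
  st <- if (!is.null(s$s.table) && nrow(s$s.table) > 0) {
    x <- as.data.frame(s$s.table)
    names(x) <- c("edf", "ref_df", "F", "p")
    x
  } else data.frame(edf = numeric(0), ref_df = numeric(0), F = numeric(0),
                    p = numeric(0))
  structure(list(parametric = pt, smooths = st,
                 deviance_explained = as.numeric(s$dev.expl),
                 adj_r2 = as.numeric(s$r.sq),
                 aic = fitted$aic, edf_total = sum(fitted$fit$edf),
                 shape = fitted$shape, n = fitted$n),
            class = "neph_gam_summary")
}

#' @export
print.neph_gam_summary <- function(x, ...) {
  cat("Gamma(log) additive model -", x$n, "obs, total edf",
      sprintf("%.2f", x$edf_total), "\n\nParametric coefficients:\n")
  print(round(x$parametric, 4))
  if (nrow(x$smooths)) {
    cat("\nSmooth terms:\n")
    print(round(x$smooths, 4))
  }
  cat(sprintf("\nDeviance explained: %.1f%%   adj. R2: %.3f   AIC: %.2f\n",
              100 * x$deviance_explained, x$adj_r2, x$aic))
  invisible(x)
}

#' @export
print.neph_gam <- function(x, ...) {
  cat("Fitted", x$spec$id, "->", x$spec$response, "\n  ",
      format(x$spec), "\n  n =", x$n,
      " AIC =", sprintf("%.2f", x$aic),
      " shape =", sprintf("%.2f", x$shape), "\n")
  invisible(x)
}

#' Percent change of the response mean implied by a log-link coefficient
#'
#' On the log link a parametric coefficient `b` multiplies the response mean
#' by `exp(b)`, i.e. changes it by `100 (exp(b) - 1)` percent. Negative
#' results read as "percent lower".
#'
#' @param coefficient numeric (vectorised).
#' @return percent change of the response mean.
#' @examples
#' effect_percent(0.65)   # ~ +92%
#' effect_percent(-0.39)  # ~ -32%
#' @export
effect_percent <- function(coefficient) {
  100 * (exp(coefficient) - 1)
}
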