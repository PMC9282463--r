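#' Backward covariate selection by variance inflation factor
#'
#' Computes, for each continuous covariate, `VIF = 1 / (1 - R^2)` from the
#' linear regression of that covariate on the remaining ones, and
#' iteratively removes the single highest-VIF covariate while any VIF is at
#' or above the threshold (default 3). Perfectly collinear covariates give
#' infinite VIF; ties on the maximum are broken alphabetically so the
#' procedure is deterministic.
#'
#' @param data data frame holding the covariates.
#' @param covariates character vector of continuous covariate columns.
#' @param threshold retention threshold; covariates survive when all
#'   remaining VIFs are `< threshold`.
#' @return list with `retained` (character vector) and `trace` (list of
#'   per-round named VIF vectors, plus the variable dropped).
#' @export
vif_backward <- function(data, covariates, threshold = 3) {
  stopifnot(length(covariates) >= 2, all(covariates %in% names(data)),
            nrow(data) > length(covariates))
  vif_of <- function(v, others) {
    if (length(others) == 0) return(1)
    f <- stats::as.formula(paste(v, "~", paste(others, collapse = "+")))
    # perfect fits are expected under exact collinearity; their R^2 is all
    # that is needed here
    r2 <- suppressWarnings(summary(stats::lm(f, data = data))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  keep <- sort(covariates)
  trace <- list()
  repeat {
    vifs <- vapply(keep, function(v) vif_of(v, setdiff(keep, v)), 0)
    if (all(vifs < threshold) || length(keep) <= 1) {
      trace[[length(trace) + 1]] <- list(vif = vifs, dropped = NA_character_)
      break
    }
    worst <- keep[which.max(vifs)]  # which.max: first on ties; keep is sorted
    trace[[length(trace) + 1]] <- list(vif = vifs, dropped = worst)
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, trace = trace)
}

#' The four candidate model specifications
#'
#' Builds the candidate set compared in the selection cascade, all Gamma/log
#' with penalized cubic regression splines capped at `k` basis functions:
#' * `modINITIAL` - smooths of latitude `Y`, depth `D`, `BT`, `Oxy`, `Sal`
#'   and `week`, a year smooth per fishery level (`Yr` by `Fishery`), plus
#'   `Fishery` and `ToD` intercepts;
#' * `modNOEM` - no environmental nor management terms: smooths of `Y`,
#'   `D`, `week`, `Yr`, plus `ToD`;
#' * `modNOE` - no environmental terms: as `modNOEM` but with the
#'   `Yr`-by-`Fishery` smooth and the `Fishery` intercept;
#' * `modNOM` - no management terms: all environmental smooths, a plain
#'   `Yr` smooth, plus `ToD`.
#'
#' @param response `"biomass_index"` or `"density_index"`.
#' @param k maximum basis dimension.
#' @return named list of four [gam_spec()] objects.
#' @export
candidate_models <- function(response, k = 6) {
  list(
    modINITIAL = gam_spec(response, list(
      smooth_term("Y", k), smooth_term("D", k), smooth_term("BT", k),
      smooth_term("Oxy", k), smooth_term("Sal", k), smooth_term("week", k),
      smooth_term("Yr", k, by = "Fishery")),
      factors = c("Fishery", "ToD"), id = "modINITIAL"),
    modNOEM = gam_spec(response, list(
      smooth_term("Y", k), smooth_term("D", k), smooth_term("week", k),
      smooth_term("Yr", k)),
      factors = "ToD", id = "modNOEM"),
    modNOE = gam_spec(response, list(
      smooth_term("Y", k), smooth_term("D", k), smooth_term("week", k),
      smooth_term("Yr", k, by = "Fishery")),
      factors = c("Fishery", "ToD"), id = "modNOE"),
    modNOM = gam_spec(response, list(
      smooth_term("Y", k), smooth_term("D", k), smooth_term("BT", k),
      smooth_term("Oxy", k), smooth_term("Sal", k), smooth_term("week", k),
      smooth_term("Yr", k)),
      factors = "ToD", id = "modNOM"))
}

# Draw a k-fold partition; re-draw (bounded) until every training fold
# contains every level of every factor used by the spec. With `stratify`,
# fold labels are balanced within each stratum.
draw_folds <- function(data, k, fac_cols, max_retries = 100, stratify = NULL) {
  n <- nrow(data)
  for (try in seq_len(max_retries)) {
    if (is.null(stratify)) {
      fold <- sample(rep(seq_len(k), length.out = n))
    } else {
      fold <- integer(n)
      for (s in unique(data[[stratify]])) {
        idx <- which(data[[stratify]] == s)
        fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
      }
    }
    ok <- TRUE
    for (f in fac_cols) {
      lev <- unique(as.character(data[[f]]))
      for (i in seq_len(k)) {
        tab <- table(factor(as.character(data[[f]][fold != i]), levels = lev))
        if (any(tab < 2)) {  # fit_gam needs >= 2 rows per level in training
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) return(list(fold = fold, retries = try - 1L))
  }
  stop("could not draw a k-fold partition with all factor levels in every ",
       "training fold after ", max_retries, " attempts")
}

#' Repeated k-fold cross-validation of one candidate
#'
#' For each of `repeats` random partitions into `k` folds, the model is
#' refitted on each set of `k - 1` training folds. Each refit contributes
#' its training AIC (see [gam_aic()]), its per-term p-values, and the
#' root-mean-squared error of response-scale predictions on the held-out
#' fold - `k x repeats` values of each in total. Partitions that would
#' leave a factor level out of some training fold are re-drawn (bounded
#' retries, counted in the result).
#'
#' @param spec a [gam_spec()].
#' @param data filtered `cpue_table`.
#' @param k folds per repeat.
#' @param repeats number of repeated partitions.
#' @param alpha significance level used for the significance tallies.
#' @param seed integer seed; identical inputs give identical results.
#' @param stratify optional column name (e.g. `"survey"`): fold labels are
#'   then balanced within each stratum instead of simple random. Default
#'   off, matching an unstratified random partition.
#' @return object of class `cv_result`: `id`, `aic` (length `k * repeats`),
#'   `pvals` (matrix, fits x terms), `sig_counts` (per-term count of
#'   `p < alpha`), `n_fits`, `rmse` (held-out, per fit), `alpha`, `redraws`.
#' @export
repeated_kfold_cv <- function(spec, data, k = 10, repeats = 10, alpha = 0.05,
                              seed = 1, stratify = NULL) {
  stopifnot(inherits(spec, "gam_spec"), nrow(data) >= 2 * k)
  fac_cols <- intersect(unique(c(spec$factors,
                                 unlist(lapply(spec$smooths, `[[`, "by")))),
                        names(data))
  y <- data[[spec$response]]
  with_seed(derive_seed(seed, paste("cv", spec$id, spec$response)), {
    aics <- numeric(0); rmses <- numeric(0); plist <- list()
    redraws <- 0L
    for (r in seq_len(repeats)) {
      fd <- draw_folds(data, k, fac_cols, stratify = stratify)
      redraws <- redraws + fd$retries
      for (i in seq_len(k)) {
        train <- data[fd$fold != i, , drop = FALSE]
        test <- data[fd$fold == i, , drop = FALSE]
        fit <- fit_gam(spec, train)
        aics <- c(aics, fit$aic)
        plist[[length(plist) + 1]] <- term_pvalues(fit)
        pred <- predict(fit, test)
        rmses <- c(rmses, sqrt(mean((test[[spec$response]] - pred)^2)))
      }
    }
    terms <- names(plist[[1]])
    P <- do.call(rbind, lapply(plist, function(p) p[terms]))
    colnames(P) <- terms
    structure(list(id = spec$id, aic = aics, pvals = P,
                   sig_counts = colSums(P < alpha), n_fits = length(aics),
                   rmse = rmses, alpha = alpha, redraws = redraws),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CV result for", x$id, "-", x$n_fits, "fits\n",
      " mean AIC", sprintf("%.2f", mean(x$aic)),
      " mean held-out RMSE", sprintf("%.3f", mean(x$rmse)), "\n")
  cat("  significant p-values (<", x$alpha, ") out of", x$n_fits, ":\n")
  print(x$sig_counts)
  invisible(x)
}

# Games-Howell all-pairs comparison (unequal variances), used when Levene
# rejects homoscedasticity: Welch-type t statistics referred to the
# studentized range distribution.
games_howell <- function(values, groups) {
  groups <- factor(groups)
  g <- levels(groups)
  stats_g <- lapply(g, function(l) {
    v <- values[groups == l]
    c(m = mean(v), v = stats::var(v), n = length(v))
  })
  names(stats_g) <- g
  pairs <- utils::combn(g, 2)
  out <- data.frame(a = pairs[1, ], b = pairs[2, ], diff = NA_real_,
                    p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    s1 <- stats_g[[pairs[1, i]]]; s2 <- stats_g[[pairs[2, i]]]
    se2 <- s1["v"] / s1["n"] + s2["v"] / s2["n"]
    t <- (s1["m"] - s2["m"]) / sqrt(se2)
    df <- se2^2 / ((s1["v"] / s1["n"])^2 / (s1["n"] - 1) +
                     (s2["v"] / s2["n"])^2 / (s2["n"] - 1))
    out$diff[i] <- unname(s1["m"] - s2["m"])
    out$p[i] <- stats::ptukey(abs(t) * sqrt(2), length(g), df,
                              lower.tail = FALSE)
  }
  out
}

#' Compare candidate models on their cross-validated AIC distributions
#'
#' Stacks the per-fit AIC values of all candidates, tests homogeneity of
#' variance with Levene's test, then - when homoscedastic - runs a one-way
#' ANOVA with Tukey HSD post hoc. The winner is the lowest-mean-AIC
#' candidate provided its pairwise comparison with every other candidate is
#' significant; otherwise the candidate with the fewest distinct covariates
#' wins (candidate-order tie-break `modNOEM < modNOE < modNOM <
#' modINITIAL`). If Levene rejects homoscedasticity the comparison falls
#' back to Welch's ANOVA with Games-Howell pairwise tests, so the cascade
#' never proceeds through an invalid classical ANOVA.
#'
#' @param cv_results named list of `cv_result` objects (equal `n_fits`).
#' @param specs optional named list of the matching [gam_spec()]s, used for
#'   the fewest-covariates tie-break; defaults to the candidate set
#'   structure by id.
#' @param alpha significance level.
#' @return object of class `model_comparison`: `mean_aic`, `levene`
#'   (statistic, df, p), `anova` (F, p, type), `tukey` (pairwise table),
#'   `selected`, `rationale`.
#' @export
compare_models_aic <- function(cv_results, specs = NULL, alpha = 0.05) {
  stopifnot(length(cv_results) >= 2)
  ids <- vapply(cv_results, `[[`, "", "id")
  names(cv_results) <- ids
  lens <- vapply(cv_results, function(z) length(z$aic), 0L)
  stopifnot(length(unique(lens)) == 1)
  df <- do.call(rbind, lapply(cv_results, function(z)
    data.frame(aic = z$aic, model = z$id)))
  df$model <- factor(df$model, levels = ids)
  lev <- suppressWarnings(car::leveneTest(aic ~ model, data = df))
  lev_p <- lev[["Pr(>F)"]][1]
  mean_aic <- vapply(cv_results, function(z) mean(z$aic), 0)
  # degenerate all-equal AIC vectors: Levene/ANOVA are undefined; treat as
  # homoscedastic with no separation
  if (is.na(lev_p) || lev_p > alpha) {
    fit <- stats::aov(aic ~ model, data = df)
    an <- summary(fit)[[1]]
    anova_res <- list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                      type = "anova")
    pw <- if (is.na(anova_res$p)) {
      data.frame(pair = character(0), diff = numeric(0), p = numeric(0))
    } else {
      tk <- as.data.frame(stats::TukeyHSD(fit)$model)
      data.frame(pair = rownames(tk), diff = tk$diff, p = tk$`p adj`)
    }
  } else {
    wt <- stats::oneway.test(aic ~ model, data = df, var.equal = FALSE)
    anova_res <- list(F = unname(wt$statistic), p = wt$p.value,
                      type = "welch")
    gh <- games_howell(df$aic, df$model)
    pw <- data.frame(pair = paste(gh$a, gh$b, sep = "-"), diff = gh$diff,
                     p = gh$p)
  }
  best <- ids[which.min(mean_aic)]
  involves <- grepl(paste0("(^|-)", best, "(-|$)"), pw$pair)
  all_sig <- !is.na(anova_res$p) && anova_res$p < alpha &&
    all(pw$p[involves] < alpha)
  if (all_sig) {
    selected <- best
    rationale <- "lowest_mean_aic_all_pairs_significant"
  } else {
    # simplest candidate: fewest distinct covariates, deterministic order
    pref <- c("modNOEM", "modNOE", "modNOM", "modINITIAL")
    ord <- c(intersect(pref, ids), setdiff(ids, pref))
    ncov <- if (!is.null(specs)) {
      vapply(ord, function(i) n_covariates(specs[[i]]), 0L)
    } else {
      defaults <- c(modINITIAL = 9L, modNOEM = 5L, modNOE = 6L, modNOM = 8L)
      ifelse(ord %in% names(defaults), defaults[ord], .Machine$integer.max)
    }
    selected <- ord[which.min(ncov)]
    rationale <- "no_clear_separation_simplest_model"
  }
  structure(list(mean_aic = mean_aic,
                 levene = list(F = lev[["F value"]][1],
                               df = paste(lev$Df, collapse = ","), p = lev_p),
                 anova = anova_res, tukey = pw, selected = selected,
                 rationale = rationale, alpha = alpha),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison on CV AIC distributions\n  mean AIC:\n")
  print(round(x$mean_aic, 2))
  cat(sprintf("  Levene p = %.4g; %s p = %.4g\n", x$levene$p,
              toupper(x$anova$type), x$anova$p))
  cat("  selected:", x$selected, "(", x$rationale, ")\n")
  invisible(x)
}

#' Significance-frequency retention rule
#'
#' Retains a term iff it was significant (p below the CV alpha) in at least
#' `threshold` of the cross-validation fits. A by-factor interaction (terms
#' named like `Yr:FisheryY`) is retained as a whole iff any of its
#' level-wise smooths meets the threshold, and the parent factor intercept
#' is then retained as well. A plain factor with per-level coefficients
#' (e.g. `FisheryL`, `FisheryN`) is retained iff any level meets the
#' threshold.
#'
#' @param cv_result a `cv_result`, or a named integer vector of
#'   significance counts (then `total` must be given).
#' @param threshold retention fraction (default 0.80).
#' @param total number of fits behind the counts (taken from the
#'   `cv_result` when available).
#' @return list with `retained` (canonical term names, interactions
#'   collapsed to e.g. `"Yr:Fishery"`), `dropped`, and `table` (per-term
#'   counts, fractions and decisions).
#' @export
retention_rule <- function(cv_result, threshold = 0.80, total = NULL) {
  if (inherits(cv_result, "cv_result")) {
    counts <- cv_result$sig_counts
    total <- cv_result$n_fits
  } else {
    counts <- cv_result
    stopifnot(!is.null(total))
  }
  stopifnot(all(counts >= 0), all(counts <= total))
  frac <- counts / total
  keep_term <- frac >= threshold
  nm <- names(counts)
  is_inter <- grepl(":", nm)
  inter_parent <- sub("^([^:]+):([A-Za-z]+?)[A-Z]$", "\\1:\\2", nm)
  # group level rows: interactions by "smooth:Factor", factor levels by factor
  fac_lev <- grepl("^(Fishery)[A-Z]$", nm) & !is_inter
  group <- ifelse(is_inter, inter_parent,
                  ifelse(fac_lev, sub("^(Fishery).*$", "\\1", nm), nm))
  retained <- character(0)
  for (g in unique(group)) {
    rows <- group == g
    if (any(keep_term[rows])) retained <- c(retained, g)
  }
  # parent factor intercept retained whenever its interaction is
  for (g in retained[grepl(":", retained)]) {
    retained <- c(retained, sub("^[^:]+:", "", g))
  }
  retained <- unique(retained)
  dropped <- setdiff(unique(group), retained)
  tab <- data.frame(term = nm, count = as.integer(counts), total = total,
                    fraction = frac, group = group,
                    meets_threshold = keep_term, row.names = NULL)
  list(retained = retained, dropped = dropped, table = tab,
       threshold = threshold)
}

#' Combine per-response retention decisions
#'
#' The biomass and density analyses run as a pair and each produces its own
#' retained term set. Under the default `"per_response"` rule the sets are
#' kept separate (returned unchanged); under `"drop_if_both"` a term is
#' dropped only when every response dropped it, i.e. the combined retained
#' set is the union.
#'
#' @param retentions list of [retention_rule()] results (one per response).
#' @param rule `"per_response"` or `"drop_if_both"`.
#' @return for `"per_response"`, the input list; for `"drop_if_both"`, one
#'   list with the union `retained` and the intersection `dropped`.
#' @export
combine_retention <- function(retentions,
                              rule = c("per_response", "drop_if_both")) {
  rule <- match.arg(rule)
  if (rule == "per_response") return(retentions)
  retained <- sort(unique(unlist(lapply(retentions, `[[`, "retained"))))
  dropped <- sort(Reduce(intersect, lapply(retentions, `[[`, "dropped")))
  list(retained = retained, dropped = dropped, rule = rule)
}

#' Prune a specification to a retained term set
#'
#' @param spec a [gam_spec()] (typically `modINITIAL`).
#' @param retained character vector from [retention_rule()].
#' @param id label for the pruned spec.
#' @return a new [gam_spec()] keeping only retained smooths and factors.
#' @export
prune_spec <- function(spec, retained, id = "modFINAL") {
  keep_smooth <- vapply(spec$smooths, function(s) {
    key <- if (is.null(s$by)) s$var else paste0(s$var, ":", s$by)
    key %in% retained
  }, TRUE)
  keep_fac <- spec$factors %in% retained
  gam_spec(spec$response, spec$smooths[keep_smooth], spec$factors[keep_fac],
           id = id)
}

#' Head-to-head held-out RMSE comparison of two specifications
#'
#' Runs repeated k-fold cross-validation with identical partitions for both
#' specifications (same seed, folds drawn once per repeat) and compares the
#' mean held-out root-mean-squared errors.
#'
#' @param specA,specB [gam_spec()]s sharing the response.
#' @param data filtered `cpue_table`.
#' @param k,repeats,seed as in [repeated_kfold_cv()].
#' @return list with `rmse` (named list of per-fold vectors), `mean_rmse`,
#'   `winner` (id of the lower-mean spec).
#' @export
rmse_compare <- function(specA, specB, data, k = 10, repeats = 10, seed = 1) {
  stopifnot(specA$response == specB$response)
  fac_cols <- intersect(unique(c(specA$factors, specB$factors,
                                 unlist(lapply(c(specA$smooths, specB$smooths),
                                               `[[`, "by")))),
                        names(data))
  with_seed(derive_seed(seed, "rmse_compare"), {
    r_a <- numeric(0); r_b <- numeric(0)
    for (r in seq_len(repeats)) {
      fd <- draw_folds(data, k, fac_cols)
      for (i in seq_len(k)) {
        train <- data[fd$fold != i, , drop = FALSE]
        test <- data[fd$fold == i, , drop = FALSE]
        fa <- fit_gam(specA, train); fb <- fit_gam(specB, train)
        ya <- test[[specA$response]]
        r_a <- c(r_a, sqrt(mean((ya - predict(fa, test))^2)))
        r_b <- c(r_b, sqrt(mean((ya - predict(fb, test))^2)))
      }
    }
    mr <- c(mean(r_a), mean(r_b))
    names(mr) <- c(specA$id, specB$id)
    list(rmse = stats::setNames(list(r_a, r_b), c(specA$id, specB$id)),
         mean_rmse = mr, winner = names(mr)[which.min(mr)])
  })
}
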