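#' Configuration of the end-to-end standardization pipeline
#'
#' One flat configuration object drives the whole cascade: simulate (or
#' load) hauls, compute and filter CPUE, screen covariates by VIF, compare
#' the four candidates by repeated k-fold CV, apply the retention rule, fit
#' the final models, build and inform the prediction grid, and produce the
#' standardized index series for both responses.
#'
#' @param geometry a [geometry_config()].
#' @param episodes management episodes (see [make_management_timeline()]).
#' @param effects a [true_effects()].
#' @param survey a [survey_config()].
#' @param env an [env_config()].
#' @param cv_k,cv_repeats,cv_alpha cross-validation settings.
#' @param retention_threshold significance-frequency retention threshold.
#' @param cell_size_nm prediction-grid cell side (nautical miles).
#' @param vif_threshold VIF retention threshold.
#' @param seed base seed; every stochastic stage derives its own stream
#'   from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = geometry_config(),
                            episodes = default_episodes(),
                            effects = true_effects(),
                            survey = survey_config(),
                            env = env_config(),
                            cv_k = 10, cv_repeats = 10, cv_alpha = 0.05,
                            retention_threshold = 0.80,
                            cell_size_nm = 2, vif_threshold = 3,
                            seed = 1) {
  stopifnot(cv_k >= 2, cv_repeats >= 1, cv_k * cv_repeats > 0,
            cv_alpha > 0, cv_alpha < 1,
            retention_threshold > 0, retention_threshold <= 1)
  structure(list(geometry = geometry, episodes = episodes, effects = effects,
                 survey = survey, env = env, cv_k = cv_k,
                 cv_repeats = cv_repeats, cv_alpha = cv_alpha,
                 retention_threshold = retention_threshold,
                 cell_size_nm = cell_size_nm, vif_threshold = vif_threshold,
                 seed = seed),
            class = "pipeline_config")
}

pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = paste0("[", name, "] ", conditionMessage(e)),
                        call = sys.call(-1), stage = name,
                        code = paste0("E_", toupper(name)))))
  })
}

log_stage <- function(con, stage, ...) {
  msg <- list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage, ...)
  writeLines(jsonlite::toJSON(msg, auto_unbox = TRUE), con)
}

#' Run the full standardization pipeline
#'
#' Executes every stage in order for both responses (biomass and density are
#' always analysed as a pair) and writes all artifacts (CSV/JSON/GeoJSON)
#' plus a manifest with content hashes to `out_dir`. Any stage failure
#' aborts with a `pipeline_error` carrying the stage name and a
#' machine-readable code (`E_SIMULATE`, `E_FILTER`, `E_VIF`, `E_CV`,
#' `E_FIT`, `E_KRIGE`, `E_PREDICT`, `E_IO`).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param hauls optional pre-existing haul table; when supplied the
#'   simulation stage is skipped and `env` must also be given.
#' @param env_fields optional named list of `env_field`s keyed
#'   `"<survey>_<year>"`.
#' @param quiet suppress progress logging to the console.
#' @return invisible list with the main in-memory artifacts: `hauls`,
#'   `filtered`, `vif`, `cv`, `comparison`, `retention`, `final_fits`,
#'   `grids`, `indices`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("nephcpue_"),
                         hauls = NULL, env_fields = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline_log.jsonl")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  note <- function(stage, ...) {
    log_stage(con, stage, ...)
    if (!quiet) message("[", stage, "] ", paste(c(...), collapse = " "))
  }
  seed <- config$seed

  geom <- pipeline_stage("validate", make_study_geometry(config$geometry))
  timeline <- pipeline_stage("validate",
                             make_management_timeline(config$episodes))

  sim <- pipeline_stage("simulate", {
    if (is.null(hauls)) {
      s <- simulate_survey_series(geom, timeline, config$effects,
                                  config$survey, config$env, seed = seed)
      note("simulate", n_hauls = nrow(s$hauls), n_withheld = nrow(s$withheld))
      s
    } else {
      if (is.null(env_fields)) stop("env_fields must accompany user hauls")
      note("simulate", skipped = TRUE, n_hauls = nrow(hauls))
      list(hauls = hauls, withheld = NULL, env = env_fields)
    }
  })
  pipeline_stage("io", {
    write_csv_file(sim$hauls, file.path(out_dir, "hauls.csv"))
    for (key in names(sim$env)) {
      write_csv_file(sim$env[[key]]$stations,
                     file.path(out_dir, paste0("stations_", key, ".csv")))
    }
    geometry_to_geojson(geom, file.path(out_dir, "geometry.geojson"))
  })

  filtered <- pipeline_stage("filter", {
    tab <- compute_indices(sim$hauls)
    fr <- filter_records(tab)
    note("filter", n_input = attr(fr$report, "n_input"),
         n_retained = attr(fr$report, "n_retained"))
    filter_report_json(fr$report, file.path(out_dir, "filter_report.json"))
    fr
  })
  dat <- filtered$table

  vif <- pipeline_stage("vif", {
    v <- vif_backward(dat, c("Y", "X", "D", "BT", "Oxy", "Sal", "week"),
                      threshold = config$vif_threshold)
    note("vif", retained = paste(v$retained, collapse = ","))
    final_vifs <- v$trace[[length(v$trace)]]$vif
    write_csv_file(data.frame(covariate = names(final_vifs),
                              vif = as.numeric(final_vifs)),
                   file.path(out_dir, "vif_final.csv"))
    v
  })

  responses <- c("biomass_index", "density_index")
  cv <- list(); comparison <- list(); retention <- list()
  final_fits <- list(); final_specs <- list()
  for (resp in responses) {
    cands <- candidate_models(resp)
    cvr <- pipeline_stage("cv", {
      out <- lapply(cands, repeated_kfold_cv, data = dat, k = config$cv_k,
                    repeats = config$cv_repeats, alpha = config$cv_alpha,
                    seed = seed)
      note("cv", response = resp,
           mean_aic = paste(sprintf("%s=%.1f", names(out),
                                    vapply(out, function(z) mean(z$aic), 0)),
                            collapse = " "))
      out
    })
    cv[[resp]] <- cvr
    comparison[[resp]] <- pipeline_stage("cv", {
      cmp <- compare_models_aic(cvr, specs = cands, alpha = config$cv_alpha)
      note("cv", response = resp, selected = cmp$selected)
      cmp
    })
    retention[[resp]] <- pipeline_stage("cv", {
      ret <- retention_rule(cvr[[comparison[[resp]]$selected]],
                            threshold = config$retention_threshold)
      note("cv", response = resp,
           retained = paste(ret$retained, collapse = ","))
      ret
    })
    final_specs[[resp]] <- prune_spec(cands[[comparison[[resp]]$selected]],
                                      retention[[resp]]$retained,
                                      id = "modFINAL")
    final_fits[[resp]] <- pipeline_stage("fit", {
      fit <- fit_gam(final_specs[[resp]], dat)
      summ <- summarize_fit(fit)
      note("fit", response = resp,
           deviance_explained = round(100 * summ$deviance_explained, 1),
           adj_r2 = round(summ$adj_r2, 3))
      summary_to_csv(summ, file.path(
        out_dir, paste0("final_model_", sub("_index", "", resp), ".csv")))
      fit
    })
    pipeline_stage("io", {
      tab <- retention[[resp]]$table
      write_csv_file(tab, file.path(
        out_dir, paste0("retention_", sub("_index", "", resp), ".csv")))
      cmp <- comparison[[resp]]
      jsonlite::write_json(
        list(mean_aic = as.list(cmp$mean_aic),
             levene_p = cmp$levene$p, anova = cmp$anova,
             selected = cmp$selected, rationale = cmp$rationale),
        file.path(out_dir, paste0("comparison_", sub("_index", "", resp),
                                  ".json")),
        auto_unbox = TRUE, digits = NA)
    })
  }

  grids <- pipeline_stage("krige", {
    base <- build_grid(geom, config$cell_size_nm)
    needed <- unique(paste(sim$hauls$survey, sim$hauls$Yr, sep = "_"))
    missing_env <- setdiff(needed, names(sim$env))
    if (length(missing_env)) {
      stop("missing station/environment data for: ",
           paste(missing_env, collapse = ", "))
    }
    layers <- list()
    for (key in names(sim$env)) {
      sv <- sub("_.*$", "", key); yr <- as.integer(sub("^.*_", "", key))
      layers[[key]] <- assign_cell_attributes(base, geom, timeline, sv, yr,
                                              env = sim$env[[key]])
    }
    # blank the structurally unobserved layers, then proxy-fill them
    if ("spring_2012" %in% names(layers)) layers$spring_2012$Oxy <- NA
    if (length(config$survey$withheld_spring)) {
      for (yy in config$survey$withheld_spring) {
        k2 <- paste0("spring_", yy)
        if (k2 %in% names(layers)) {
          layers[[k2]]$BT <- NA; layers[[k2]]$Sal <- NA; layers[[k2]]$Oxy <- NA
        }
      }
    }
    layers <- proxy_fill(layers)
    note("krige", n_layers = length(layers), n_cells = nrow(base))
    layers
  })

  indices <- pipeline_stage("predict", {
    rows <- list()
    for (key in names(grids)) {
      for (resp in responses) {
        rows[[paste(key, resp)]] <- standardized_index(final_fits[[resp]],
                                                       grids[[key]])
      }
    }
    idx <- do.call(rbind, rows)
    rownames(idx) <- NULL
    obs <- stats::aggregate(cbind(biomass_index, density_index) ~ survey + Yr,
                            data = dat, FUN = mean)
    idx$observed <- NA_real_
    for (i in seq_len(nrow(idx))) {
      m <- obs$survey == idx$survey[i] & obs$Yr == idx$Yr[i]
      if (any(m)) idx$observed[i] <- obs[[idx$response[i]]][m]
    }
    idx$rel_diff_pct <- ifelse(is.na(idx$observed), NA_real_,
                               compare_observed_predicted(idx$observed,
                                                          idx$index))
    write_csv_file(idx, file.path(out_dir, "standardized_indices.csv"))
    note("predict", n_rows = nrow(idx))
    idx
  })
  pipeline_stage("io", {
    grid_to_geojson(grids[[1]], geom, file.path(out_dir, "grid_example.geojson"))
  })

  manifest <- pipeline_stage("io", {
    files <- setdiff(list.files(out_dir), "manifest.json")
    mf <- data.frame(file = files,
                     md5 = as.character(tools::md5sum(file.path(out_dir, files))),
                     row.names = NULL)
    jsonlite::write_json(list(seed = seed,
                              package_version =
                                as.character(utils::packageVersion("nephcpue")),
                              files = mf),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    mf
  })
  note("done", out_dir = out_dir)
  invisible(list(hauls = sim$hauls, filtered = filtered, vif = vif, cv = cv,
                 comparison = comparison, retention = retention,
                 final_specs = final_specs, final_fits = final_fits,
                 grids = grids, indices = indices, manifest = manifest,
                 out_dir = out_dir, geom = geom, timeline = timeline,
                 env = sim$env))
}
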