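#' Season windows of the two survey series
#'
#' Week-of-year windows within which haul dates are drawn: late spring
#' (April-May) for the spring series and September-November for the autumn
#' series.
#'
#' @return named list of integer week ranges.
#' @export
season_windows <- function() {
  list(spring = 15:21, autumn = 37:47)
}

# Mid-window reference date used to resolve management levels for a survey.
survey_reference_date <- function(survey, year) {
  as.Date(paste0(year, if (survey == "spring") "-05-01" else "-10-01"))
}

#' Simulate haul records for one survey/year
#'
#' Draws haul locations uniformly over the part of the study polygon whose
#' depth lies in the 100-270 m towable band, assigns weeks within the
#' season window, alternates sunrise/sunset hauls, reads the environmental
#' surfaces at the haul positions, resolves the fishery level from the
#' management timeline, assembles the log-scale linear predictor from the
#' generating effects, and draws biomass and density CPUE from Gamma
#' distributions with mean `exp(eta)` and the configured shape. Catch weight
#' and count are back-computed from a drawn swept area, so recomputing the
#' indices from the raw fields reproduces the generated CPUE (up to integer
#' rounding of the count).
#'
#' @param geom a `study_geometry`.
#' @param env an `env_field` for the same survey/year.
#' @param timeline a `management_timeline`.
#' @param effects a [true_effects()].
#' @param n_hauls number of hauls (>= 1).
#' @param survey `"spring"` or `"autumn"`; autumn hauls are restricted to the
#'   western side of the split meridian.
#' @param year integer year.
#' @param seed integer seed.
#' @param depth_range towable depth band in metres.
#' @return data frame of haul records (one row per haul).
#' @export
simulate_hauls <- function(geom, env, timeline, effects, n_hauls, survey,
                           year, seed = 1, depth_range = c(100, 270)) {
  stopifnot(n_hauls >= 1, inherits(effects, "true_effects"),
            survey %in% c("spring", "autumn"))
  with_seed(derive_seed(seed, paste("hauls", survey, year)), {
    pts <- sample_in_polygon(geom, 4 * n_hauls, depth_range = depth_range)
    if (survey == "autumn") {
      pts <- pts[pts$lon < geom$split_lon, , drop = FALSE]
    }
    if (nrow(pts) < n_hauls) {
      pts2 <- sample_in_polygon(geom, 20 * n_hauls, depth_range = depth_range)
      if (survey == "autumn") pts2 <- pts2[pts2$lon < geom$split_lon, , drop = FALSE]
      pts <- rbind(pts, pts2)
    }
    if (nrow(pts) < n_hauls) {
      stop("eligible depth band ", depth_range[1], "-", depth_range[2],
           " m is (nearly) empty for survey ", survey)
    }
    pts <- pts[seq_len(n_hauls), , drop = FALSE]
    wk <- season_windows()[[survey]]
    d <- data.frame(
      survey = survey,
      Yr = year,
      week = sample(wk, n_hauls, replace = TRUE),
      ToD = sample(rep(c("sunrise", "sunset"), length.out = n_hauls)),
      Y = pts$lat, X = pts$lon,
      D = depth_at(geom, pts$lon, pts$lat),
      stringsAsFactors = FALSE)
    d$date <- as.Date(paste0(year, "-01-01")) + (d$week - 1) * 7 + 3
    d$BT <- env$surface("BT", d$X, d$Y)
    d$Sal <- env$surface("Sal", d$X, d$Y)
    d$Oxy <- env$surface("Oxy", d$X, d$Y)
    ref_date <- survey_reference_date(survey, year)
    d$Fishery <- fishery_level_at(geom, timeline, ref_date, d$X, d$Y)
    eta_b <- linear_predictor(effects, d, "biomass")
    eta_d <- linear_predictor(effects, d, "density")
    sh_b <- effects$shape[["biomass"]]; sh_d <- effects$shape[["density"]]
    cpue_b <- stats::rgamma(n_hauls, shape = sh_b, rate = sh_b / exp(eta_b))
    cpue_d <- stats::rgamma(n_hauls, shape = sh_d, rate = sh_d / exp(eta_d))
    d$swept_area <- stats::runif(n_hauls, 0.055, 0.075)  # km^2, 1-h haul
    d$catch_weight <- cpue_b * d$swept_area
    d$catch_count <- round(cpue_d * d$swept_area)
    d$haul_id <- sprintf("%s%d_%02d", substr(survey, 1, 2), year,
                         seq_len(n_hauls))
    d[, c("haul_id", "survey", "Yr", "week", "date", "ToD", "Y", "X", "D",
          "BT", "Sal", "Oxy", "Fishery", "swept_area", "catch_weight",
          "catch_count")]
  })
}

#' Survey plan and generator settings for the full synthetic study
#'
#' The default plan reproduces the study design: a spring series 2012-2019
#' with the 2018 campaign generated and then withheld (emulating the
#' cancelled survey), and an autumn series 2015-2019 restricted to the
#' western side. Oxygen was not measured in spring 2012, so that survey's
#' `Oxy` values are blanked; a small fraction of other hauls lose one
#' environmental reading at random, emulating failed CTD casts.
#'
#' @param n_spring,n_autumn hauls per spring / autumn survey.
#' @param spring_years,autumn_years integer year vectors.
#' @param withheld_spring years whose spring survey is generated then
#'   withheld from the returned haul table.
#' @param missing_env_rate per-haul probability of losing one environmental
#'   reading (besides the structural spring-2012 oxygen gap).
#' @param n_stations CTD stations per survey/year.
#' @param env_noise noise multiplier passed to [sample_environment()].
#' @return list of class `survey_config`.
#' @export
survey_config <- function(n_spring = 12, n_autumn = 8,
                          spring_years = 2012:2019, autumn_years = 2015:2019,
                          withheld_spring = 2018, missing_env_rate = 0.12,
                          n_stations = 30, env_noise = 1) {
  structure(list(n_spring = n_spring, n_autumn = n_autumn,
                 spring_years = spring_years, autumn_years = autumn_years,
                 withheld_spring = withheld_spring,
                 missing_env_rate = missing_env_rate,
                 n_stations = n_stations, env_noise = env_noise),
            class = "survey_config")
}

#' Simulate the full two-series synthetic survey
#'
#' Runs [sample_environment()] and [simulate_hauls()] over the whole survey
#' plan and applies the design gaps (withheld spring survey, spring-2012
#' oxygen blank, sporadic missing CTD readings).
#'
#' @param geom a `study_geometry`.
#' @param timeline a `management_timeline`.
#' @param effects a [true_effects()].
#' @param config a [survey_config()].
#' @param env_cfg an [env_config()].
#' @param seed integer seed.
#' @return list with `hauls` (combined haul table), `withheld` (haul table of
#'   withheld surveys), and `env` (named list of `env_field`s keyed
#'   `"<survey>_<year>"`, including withheld years).
#' @export
simulate_survey_series <- function(geom, timeline, effects = true_effects(),
                                   config = survey_config(),
                                   env_cfg = env_config(), seed = 1) {
  plan <- rbind(
    data.frame(survey = "spring", year = config$spring_years,
               n = config$n_spring),
    data.frame(survey = "autumn", year = config$autumn_years,
               n = config$n_autumn))
  env <- list()
  hauls <- list()
  for (i in seq_len(nrow(plan))) {
    sv <- plan$survey[i]; yr <- plan$year[i]
    key <- paste(sv, yr, sep = "_")
    env[[key]] <- sample_environment(geom, sv, yr,
                                     n_stations = config$n_stations,
                                     noise = config$env_noise,
                                     cfg = env_cfg, seed = seed)
    hauls[[key]] <- simulate_hauls(geom, env[[key]], timeline, effects,
                                   plan$n[i], sv, yr, seed = seed)
  }
  all_hauls <- do.call(rbind, hauls)
  rownames(all_hauls) <- NULL
  # structural gap: oxygen not measured in spring 2012
  all_hauls$Oxy[all_hauls$survey == "spring" & all_hauls$Yr == 2012] <- NA
  # sporadic missing CTD readings elsewhere
  if (config$missing_env_rate > 0) {
    with_seed(derive_seed(seed, "missing"), {
      cand <- which(!(all_hauls$survey == "spring" & all_hauls$Yr == 2012))
      hit <- cand[stats::runif(length(cand)) < config$missing_env_rate]
      if (length(hit)) {
        which_par <- sample(env_params, length(hit), replace = TRUE)
        for (j in seq_along(hit)) all_hauls[hit[j], which_par[j]] <- NA
      }
    })
  }
  withheld_mask <- all_hauls$survey == "spring" &
    all_hauls$Yr %in% config$withheld_spring
  list(hauls = all_hauls[!withheld_mask, , drop = FALSE],
       withheld = all_hauls[withheld_mask, , drop = FALSE],
       env = env)
}
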