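#' Compute biomass and density CPUE indices
#'
#' Adds the two catch-per-unit-effort indices to a haul table: the biomass
#' index `catch_weight / swept_area` (kg/km^2) and the density index
#' `catch_count / swept_area` (N/km^2). Row order is preserved.
#'
#' @param hauls data frame of haul records with at least `catch_weight`
#'   (kg), `catch_count` (individuals) and `swept_area` (km^2); a `haul_id`
#'   column, if present, is used in error messages.
#' @return the input with `biomass_index` and `density_index` columns
#'   appended, classed `cpue_table`.
#' @examples
#' h <- data.frame(haul_id = "h1", catch_weight = 30, catch_count = 900,
#'                 swept_area = 0.06)
#' compute_indices(h)[, c("biomass_index", "density_index")]  # 500, 15000
#' @export
compute_indices <- function(hauls) {
  stopifnot(is.data.frame(hauls),
            all(c("catch_weight", "catch_count", "swept_area") %in%
                  names(hauls)))
  bad <- which(!(hauls$swept_area > 0) | is.na(hauls$swept_area))
  if (length(bad)) {
    id <- if ("haul_id" %in% names(hauls)) hauls$haul_id[bad] else bad
    stop("non-positive swept area for haul(s): ",
         paste(utils::head(id, 5), collapse = ", "))
  }
  if (any(hauls$catch_weight < 0, na.rm = TRUE) ||
      any(hauls$catch_count < 0, na.rm = TRUE)) {
    stop("negative catch weight or count")
  }
  hauls$biomass_index <- hauls$catch_weight / hauls$swept_area
  hauls$density_index <- hauls$catch_count / hauls$swept_area
  class(hauls) <- unique(c("cpue_table", class(hauls)))
  hauls
}

#' Covariates of the full candidate model
#'
#' Column names over which record filtering evaluates missingness: every
#' covariate that can enter a candidate model (latitude `Y`, depth `D`,
#' bottom temperature `BT`, oxygen `Oxy`, salinity `Sal`, `week`, year `Yr`,
#' time of day `ToD`, `Fishery`). Filtering is done once against this full
#' set, so later dropping a term from a model never resurrects rows.
#'
#' @return character vector of column names.
#' @export
model_covariates <- function() {
  c("Y", "D", "BT", "Oxy", "Sal", "week", "Yr", "ToD", "Fishery")
}

#' Filter haul records for modelling
#'
#' Applies the two record-level exclusion rules used before model fitting:
#' a row is dropped iff (i) any modelled covariate is missing, or (ii)
#' either CPUE index equals zero (the Gamma density is undefined at zero).
#' The report counts removals by reason, survey and year. Filtering is
#' idempotent.
#'
#' @param table a `cpue_table` (see [compute_indices()]).
#' @param covariates covariate columns checked for missingness; defaults to
#'   the full candidate-model set [model_covariates()].
#' @return list with `table` (retained rows) and `report` (data frame with
#'   columns `survey`, `Yr`, `reason`, `n`, plus attributes `n_input`,
#'   `n_retained`).
#' @export
filter_records <- function(table, covariates = model_covariates()) {
  stopifnot(is.data.frame(table),
            all(c("biomass_index", "density_index") %in% names(table)))
  covariates <- intersect(covariates, names(table))
  miss <- rowSums(is.na(table[, covariates, drop = FALSE])) > 0
  zero <- !miss & (table$biomass_index == 0 | table$density_index == 0)
  drop <- miss | zero
  sv <- if ("survey" %in% names(table)) table$survey else "all"
  yr <- if ("Yr" %in% names(table)) table$Yr else NA
  reason <- ifelse(miss, "missing_covariate", "zero_cpue")
  rep_df <- if (any(drop)) {
    agg <- stats::aggregate(list(n = rep(1L, sum(drop))),
                            by = list(survey = sv[drop], Yr = yr[drop],
                                      reason = reason[drop]),
                            FUN = sum)
    agg[order(agg$survey, agg$Yr, agg$reason), , drop = FALSE]
  } else {
    data.frame(survey = character(0), Yr = numeric(0),
               reason = character(0), n = integer(0))
  }
  attr(rep_df, "n_input") <- nrow(table)
  attr(rep_df, "n_retained") <- sum(!drop)
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, report = rep_df)
}

#' Serialize a filter report to JSON
#'
#' @param report the `report` element of [filter_records()].
#' @param path optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
filter_report_json <- function(report, path = NULL) {
  obj <- list(n_input = attr(report, "n_input"),
              n_retained = attr(report, "n_retained"),
              removals = report)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
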