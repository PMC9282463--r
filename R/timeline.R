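#' Default fishery-management episodes for the synthetic study area
#'
#' Emulates the staged regulation of the area: a first partial closure from
#' July 2015 (ban in the core zone A, limited fishery in buffer B), then a
#' permanent Fishery Restricted Area from 2018 (ban in A, limited fishery in
#' both buffers B and C). Dates before the first episode resolve to open
#' fishery (level `"Y"`) everywhere.
#'
#' @return data frame with columns `start`, `end` (Date), `zone`, `level`.
#' @export
default_episodes <- function() {
  data.frame(
    start = as.Date(c("2015-07-01", "2015-07-01",
                      "2018-01-01", "2018-01-01", "2018-01-01")),
    end   = as.Date(c("2017-12-31", "2017-12-31",
                      "2099-12-31", "2099-12-31", "2099-12-31")),
    zone  = c("A", "B", "A", "B", "C"),
    level = c("N", "L", "N", "L", "L"),
    stringsAsFactors = FALSE)
}

#' Build a management timeline
#'
#' @param episodes data frame with columns `start`, `end` (coercible to
#'   Date), `zone` and `level` (one of `"Y"`, `"L"`, `"N"`). Episodes for the
#'   same zone must not overlap in time.
#' @return object of class `management_timeline`.
#' @examples
#' tl <- make_management_timeline()
#' resolve_level(tl, as.Date("2015-05-01"), "A")  # before first closure: "Y"
#' resolve_level(tl, as.Date("2018-05-01"), "A")  # ban: "N"
#' @export
make_management_timeline <- function(episodes = default_episodes()) {
  if (nrow(episodes) == 0) {
    return(structure(list(episodes = episodes), class = "management_timeline"))
  }
  episodes$start <- as.Date(episodes$start)
  episodes$end <- as.Date(episodes$end)
  stopifnot(all(episodes$level %in% c("Y", "L", "N")),
            all(episodes$end >= episodes$start))
  for (z in unique(episodes$zone)) {
    e <- episodes[episodes$zone == z, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)])) {
      stop("overlapping management episodes for zone ", z)
    }
  }
  structure(list(episodes = episodes[order(episodes$start), ]),
            class = "management_timeline")
}

#' Resolve the fishery level for a date and zone
#'
#' @param timeline a `management_timeline`.
#' @param date a Date (scalar).
#' @param zone zone identifier(s) (`"A"`, `"B"`, `"C"`) or `NA` for points
#'   outside all zones.
#' @return character vector of levels; `"Y"` where no episode applies.
#' @export
resolve_level <- function(timeline, date, zone) {
  stopifnot(inherits(timeline, "management_timeline"), length(date) == 1)
  date <- as.Date(date)
  out <- rep("Y", length(zone))
  e <- timeline$episodes
  if (nrow(e) == 0) return(out)
  active <- e[e$start <= date & e$end >= date, ]
  if (nrow(active) > 0) {
    m <- match(zone, active$zone)
    out[!is.na(m)] <- active$level[m[!is.na(m)]]
  }
  out
}

#' Fishery level at geographic points
#'
#' Convenience wrapper: maps points to management zones through the geometry,
#' then resolves levels on the timeline.
#'
#' @param geom a `study_geometry`.
#' @param timeline a `management_timeline`.
#' @param date survey date (scalar Date).
#' @param lon,lat coordinates (vectorised).
#' @return character vector of fishery levels (`"Y"`, `"L"`, `"N"`).
#' @export
fishery_level_at <- function(geom, timeline, date, lon, lat) {
  resolve_level(timeline, date, zone_at(geom, lon, lat))
}

#' @export
print.management_timeline <- function(x, ...) {
  cat("Management timeline:", nrow(x$episodes), "episode(s)\n")
  if (nrow(x$episodes)) print(x$episodes, row.names = FALSE)
  invisible(x)
}
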