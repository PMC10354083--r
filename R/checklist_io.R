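# Mapping from the tab-separated observation-table column names (the eBird
# Basic Dataset layout) to internal names.
.EBD_COLUMNS <- c(
  checklist_id = "SAMPLING EVENT IDENTIFIER",
  species_code = "SPECIES CODE",
  count_raw    = "OBSERVATION COUNT",
  lat          = "LATITUDE",
  lon          = "LONGITUDE",
  date         = "OBSERVATION DATE",
  time_started = "TIME OBSERVATIONS STARTED",
  duration_min = "DURATION MINUTES",
  distance_km  = "EFFORT DISTANCE KM",
  n_observers  = "NUMBER OBSERVERS",
  protocol     = "PROTOCOL TYPE",
  complete     = "ALL SPECIES REPORTED"
)

# "HH:MM" or "HH:MM:SS" -> minutes since midnight (NA on anything else)
.parse_time_min <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) {
      as.numeric(p[1]) * 60 + as.numeric(p[2]) +
        if (length(p) == 3) as.numeric(p[3]) / 60 else 0
    }, numeric(1))
  }
  out[out < 0 | out >= 1440] <- NA_real_
  out
}

.parse_num <- function(x) suppressWarnings(as.numeric(x))

#' Read an EBD-like observation table
#'
#' Reads a tab-separated, UTF-8 observation table in the eBird Basic Dataset
#' layout (one row per species per checklist) and splits it into a
#' checklist-level table and an observation table linked by checklist id.
#' Effort fields are parsed to numbers; malformed numeric fields become
#' missing and are counted in the attached parse log rather than aborting
#' the read. Count fields may be a positive integer or a presence marker
#' (`"X"`), which is preserved in `count_raw` and left `NA` in the numeric
#' `count` column for downstream policy to resolve.
#'
#' @param path path to the tab-separated file (header row required).
#' @param crs coordinate system of the `LATITUDE`/`LONGITUDE` columns:
#'   `"wgs84"` (degrees, the native EBD convention) or `"planar_km"`
#'   (synthetic worlds, where the columns carry planar kilometres).
#' @return A list with components `checklists` (one row per unique
#'   checklist id: lon, lat, date, time_started in minutes, duration_min,
#'   distance_km, n_observers, protocol, complete), `observations`
#'   (checklist_id, species_code, count_raw, count), and `log` (named
#'   counts of malformed fields coerced to missing).
#' @export
read_checklists <- function(path, crs = c("wgs84", "planar_km")) {
  crs <- match.arg(crs)
  raw <- utils::read.delim(path,
    check.names = FALSE, colClasses = "character",
    na.strings = c("", "NA"), fileEncoding = "UTF-8"
  )
  missing_cols <- setdiff(unname(.EBD_COLUMNS), names(raw))
  if (length(missing_cols)) {
    stop("input is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  names(raw)[match(.EBD_COLUMNS, names(raw))] <- names(.EBD_COLUMNS)

  log <- c()
  parse_log <- function(label, raw_vals, parsed) {
    bad <- sum(!is.na(raw_vals) & is.na(parsed))
    if (bad > 0) log[label] <<- bad
    parsed
  }

  obs <- data.frame(
    checklist_id = raw$checklist_id,
    species_code = raw$species_code,
    count_raw = raw$count_raw,
    stringsAsFactors = FALSE
  )
  count_num <- .parse_num(raw$count_raw)
  count_num[!is.na(count_num) & (count_num < 1 | count_num != floor(count_num))] <- NA
  obs$count <- count_num

  first <- !duplicated(raw$checklist_id)
  cl <- raw[first, , drop = FALSE]
  checklists <- data.frame(
    checklist_id = cl$checklist_id,
    lon = parse_log("lon", cl$lon, .parse_num(cl$lon)),
    lat = parse_log("lat", cl$lat, .parse_num(cl$lat)),
    date = parse_log(
      "date", cl$date,
      as.Date(cl$date, format = "%Y-%m-%d", optional = TRUE)
    ),
    time_started = parse_log(
      "time_started", cl$time_started, .parse_time_min(cl$time_started)
    ),
    duration_min = parse_log(
      "duration_min", cl$duration_min, .parse_num(cl$duration_min)
    ),
    distance_km = parse_log(
      "distance_km", cl$distance_km, .parse_num(cl$distance_km)
    ),
    n_observers = parse_log(
      "n_observers", cl$n_observers, .parse_num(cl$n_observers)
    ),
    protocol = cl$protocol,
    complete = cl$complete %in% c("1", "TRUE", "true", "T"),
    stringsAsFactors = FALSE
  )
  rownames(checklists) <- NULL
  attr(checklists, "crs") <- crs
  list(checklists = checklists, observations = obs, log = log)
}

#' Write checklist and observation tables back to the EBD-like layout
#'
#' Inverse of [read_checklists()]: joins the checklist-level fields onto
#' each observation row and writes one tab-separated file. Round-tripping
#' through write and read preserves every field.
#'
#' @param checklists,observations tables as returned by [read_checklists()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_checklists <- function(checklists, observations, path) {
  m <- match(observations$checklist_id, checklists$checklist_id)
  if (anyNA(m)) {
    stop("observation rows reference unknown checklist ids", call. = FALSE)
  }
  cl <- checklists[m, , drop = FALSE]
  fmt_time <- function(t) {
    ifelse(is.na(t), NA_character_, sprintf("%02d:%02d:%02.0f",
      floor(t / 60), floor(t %% 60), round((t %% 1) * 60)
    ))
  }
  out <- data.frame(
    check.names = FALSE, stringsAsFactors = FALSE,
    `SAMPLING EVENT IDENTIFIER` = observations$checklist_id,
    `SPECIES CODE` = observations$species_code,
    `OBSERVATION COUNT` = observations$count_raw,
    `LATITUDE` = cl$lat,
    `LONGITUDE` = cl$lon,
    `OBSERVATION DATE` = format(cl$date, "%Y-%m-%d"),
    `TIME OBSERVATIONS STARTED` = fmt_time(cl$time_started),
    `DURATION MINUTES` = cl$duration_min,
    `EFFORT DISTANCE KM` = cl$distance_km,
    `NUMBER OBSERVERS` = cl$n_observers,
    `PROTOCOL TYPE` = cl$protocol,
    `ALL SPECIES REPORTED` = as.integer(cl$complete)
  )
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "", fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Checklist inclusion rules
#'
#' Defaults reproduce the standard effort filter for checklist-based
#' abundance modelling: complete checklists only; stationary, travelling or
#' area-search protocols; at most 5 h duration and 5 km travelled
#' (inclusive boundaries: a 300-min or 5.0-km checklist survives, 301 min
#' or 5.1 km does not); and an observation-date window. Checklists with
#' missing duration or distance are removed under their own reason code.
#'
#' @param max_duration_min maximum duration, minutes (inclusive).
#' @param max_distance_km maximum distance travelled, km (inclusive).
#' @param date_start,date_end inclusive observation-date window.
#' @param protocols allowed protocol names.
#' @param require_complete drop incomplete checklists.
#' @return A list of rules for [filter_checklists()].
#' @export
filter_rules <- function(max_duration_min = 300,
                         max_distance_km = 5,
                         date_start = "2010-01-01",
                         date_end = "2021-06-30",
                         protocols = c(
                           "Stationary", "Traveling", "Travelling",
                           "Birdlife Australia 20min-2ha survey",
                           "Birdlife Australia 500m radius search",
                           "Birdlife Australia 5km radius search"
                         ),
                         require_complete = TRUE) {
  stopifnot(max_duration_min > 0, max_distance_km > 0)
  list(
    max_duration_min = max_duration_min,
    max_distance_km = max_distance_km,
    date_start = as.Date(date_start),
    date_end = as.Date(date_end),
    protocols = protocols,
    require_complete = require_complete
  )
}

#' Filter checklists by effort and completeness
#'
#' Applies the conjunctive inclusion rules of [filter_rules()] in a fixed
#' documented order (incomplete, protocol, missing/over duration,
#' missing/over distance, date window) and reports how many checklists each
#' rule removed. Because the rules are conjunctive the surviving set does
#' not depend on the order; only the attribution of removals does.
#' Filtering is idempotent.
#'
#' @param checklists checklist table from [read_checklists()].
#' @param rules a [filter_rules()] list.
#' @return A list with `checklists` (survivors) and `report`, a data frame
#'   of per-rule removal counts whose `removed` column plus the retained
#'   count sums to the input size.
#' @export
filter_checklists <- function(checklists, rules = filter_rules()) {
  n0 <- nrow(checklists)
  alive <- rep(TRUE, n0)
  report <- list()
  drop_rule <- function(name, bad) {
    kill <- alive & bad
    report[[name]] <<- sum(kill)
    alive <<- alive & !kill
  }
  if (rules$require_complete) {
    drop_rule("incomplete", !checklists$complete)
  } else {
    report[["incomplete"]] <- 0L
  }
  drop_rule("protocol", !(checklists$protocol %in% rules$protocols))
  drop_rule("missing_duration", is.na(checklists$duration_min))
  drop_rule("duration", checklists$duration_min > rules$max_duration_min)
  # stationary protocols legitimately have distance 0; missing distance on a
  # travelling checklist is unusable effort information
  dist <- checklists$distance_km
  stationary <- checklists$protocol == "Stationary"
  dist[is.na(dist) & stationary] <- 0
  drop_rule("missing_distance", is.na(dist))
  drop_rule("distance", !is.na(dist) & dist > rules$max_distance_km)
  drop_rule(
    "date_window",
    is.na(checklists$date) |
      checklists$date < rules$date_start | checklists$date > rules$date_end
  )
  out <- checklists[alive, , drop = FALSE]
  attr(out, "crs") <- attr(checklists, "crs")
  report_df <- data.frame(
    rule = names(report),
    removed = unlist(report, use.names = FALSE)
  )
  stopifnot(sum(report_df$removed) + nrow(out) == n0)
  list(
    checklists = out,
    report = structure(report_df,
      retained = nrow(out), input = n0, class = c("filter_report", "data.frame")
    )
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Checklist filter: %d in, %d retained\n",
    attr(x, "input"), attr(x, "retained")
  ))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  removed by %-16s %d\n", x$rule[i], x$removed[i]))
  }
  invisible(x)
}
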