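# From raw detections to visits, survey days, sighting frequencies,
# residency and eligibility filters.

#' Read camera-trap detection records from CSV
#'
#' Strict parser for delimited detections with header columns
#' `timestamp, territory, patch, fox, season`.  Timestamps must be ISO-8601
#' (`2014-03-01T21:00:00Z` or `2014-03-01 21:00:00`, UTC).  Malformed rows
#' are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of detection records with POSIXct timestamps.
#' @export
read_detections <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "territory", "patch", "fox", "season")
  if (!all(need %in% names(df))) {
    stop("detections file must have columns: ", paste(need, collapse = ", "))
  }
  ts <- parse_iso8601(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("unparseable timestamps at data line(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  df$timestamp <- ts
  df[need]
}

#' Read a fox attribute table from CSV
#'
#' Expects columns `fox, sex, status, age_class` (additional columns such as
#' `territory` are kept).  `sex` must be M/F/unknown, `status`
#' dominant/subordinate, `age_class` cub/independent.
#'
#' @param path CSV file path.
#' @return data.frame of attributes.
#' @export
read_attributes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fox", "sex", "status", "age_class")
  if (!all(need %in% names(df))) {
    stop("attribute file must have columns: ", paste(need, collapse = ", "))
  }
  chk <- function(col, allowed) {
    bad <- which(!df[[col]] %in% allowed & !is.na(df[[col]]))
    if (length(bad)) stop("invalid ", col, " at data line(s): ",
                          paste(head(bad, 10), collapse = ", "))
  }
  chk("sex", c("M", "F", "unknown"))
  chk("status", c("dominant", "subordinate"))
  chk("age_class", c("cub", "independent"))
  df
}

#' Assign noon-to-noon survey day indices
#'
#' Survey days run from noon to noon so that a single nocturnal activity
#' bout is one sampling period: 11:59:59 belongs to the previous day,
#' 12:00:00 opens the next.  Day 1 starts at `survey_start`.
#'
#' @param timestamp POSIXct vector (or numeric seconds since epoch).
#' @param survey_start POSIXct survey start (must be a noon boundary of the
#'   survey calendar; day 1 starts here).
#' @param survey_length_days length of the survey window; timestamps outside
#'   `[survey_start, survey_start + survey_length_days)` are rejected.
#' @param context optional string (e.g. territory/season) used in error
#'   messages.
#' @return integer day indices in `1:survey_length_days`.
#' @export
assign_survey_day <- function(timestamp, survey_start, survey_length_days = 40L,
                              context = NULL) {
  t <- as.numeric(timestamp)
  t0 <- as.numeric(survey_start)
  day <- floor((t - t0) / 86400) + 1
  bad <- which(day < 1 | day > survey_length_days)
  if (length(bad)) {
    stop(sprintf("%d timestamp(s) outside the survey window%s (first: %s)",
                 length(bad),
                 if (is.null(context)) "" else paste0(" [", context, "]"),
                 format(as.POSIXct(t[bad[1]], tz = "UTC",
                                   origin = "1970-01-01"))))
  }
  as.integer(day)
}

#' Collapse photographs into patch visits
#'
#' Photographs of the same fox at the same patch separated by less than the
#' gap threshold belong to one visit; a gap of at least 15 minutes (the
#' boundary included: exactly 15 minutes splits) starts a new visit.  Visit
#' start/end are the first/last photograph; a single photograph yields a
#' zero-length visit.  Input need not be sorted.
#'
#' @param detections data.frame with columns timestamp, territory, patch,
#'   fox, season.
#' @param gap_s gap threshold in seconds (default 900 = 15 min).
#' @param censor_end optional named numeric/POSIXct: recording end per
#'   season (names = seasons); visits whose last photo falls within `gap_s`
#'   of the recording end are flagged `start_only` (end unobserved).
#' @return data.frame of visits: fox, territory, season, patch, start, end,
#'   n_photos, start_only.
#' @export
collapse_to_visits <- function(detections, gap_s = 900, censor_end = NULL) {
  dt <- data.table::as.data.table(detections)
  if (nrow(dt) == 0) {
    return(data.frame(fox = character(0), territory = character(0),
                      season = character(0), patch = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      n_photos = integer(0), start_only = logical(0)))
  }
  dt[, start_num := as.numeric(timestamp)]
  data.table::setorder(dt, fox, patch, start_num)
  dt[, new_visit := {
    gap <- start_num - data.table::shift(start_num, fill = -Inf)
    as.integer(gap >= gap_s)
  }, by = .(fox, patch)]
  dt[, visit_id := cumsum(new_visit), by = .(fox, patch)]
  v <- dt[, .(territory = territory[1], season = season[1],
              start_num = min(start_num), end_num = max(start_num),
              n_photos = .N),
          by = .(fox, patch, visit_id)]
  v[, start_only := FALSE]
  if (!is.null(censor_end)) {
    ce <- as.numeric(censor_end)
    names(ce) <- names(censor_end)
    v[, start_only := end_num >= (ce[season] - gap_s)]
  }
  v[, start := as.POSIXct(start_num, tz = "UTC", origin = "1970-01-01")]
  v[, end := as.POSIXct(end_num, tz = "UTC", origin = "1970-01-01")]
  as.data.frame(v[, .(fox, territory, season, patch, start, end, n_photos,
                      start_only)])
}

#' Attach survey day indices to visits
#'
#' @param visits data.frame from [collapse_to_visits()].
#' @param calendar data.frame with territory, season, start (POSIXct noon
#'   survey starts).
#' @param survey_length_days survey window length.
#' @return visits with a `survey_day` column (indexed by visit start).
#' @export
add_survey_day <- function(visits, calendar, survey_length_days = 40L) {
  key <- paste(calendar$territory, calendar$season)
  starts <- stats::setNames(as.numeric(calendar$start), key)
  k <- paste(visits$territory, visits$season)
  miss <- setdiff(unique(k), names(starts))
  if (length(miss)) stop("no calendar entry for: ", paste(miss, collapse = ", "))
  visits$survey_day <- as.integer(
    floor((as.numeric(visits$start) - starts[k]) / 86400) + 1)
  bad <- which(visits$survey_day < 1 | visits$survey_day > survey_length_days)
  if (length(bad)) {
    stop(sprintf("%d visit(s) outside the survey window (first: %s %s day %d)",
                 length(bad), visits$territory[bad[1]], visits$season[bad[1]],
                 visits$survey_day[bad[1]]))
  }
  visits
}

#' Filter to independent foxes (at least 5 months old)
#'
#' Cubs under 5 months are excluded from all analyses.  Foxes with missing
#' age class are included by default (configurable) and reported.
#'
#' @param attributes data.frame with fox and age_class.
#' @param missing_include include foxes with NA age_class (default TRUE).
#' @return character vector of included fox ids.
#' @export
filter_independent <- function(attributes, missing_include = TRUE) {
  miss <- is.na(attributes$age_class)
  if (any(miss)) {
    message(sum(miss), " fox(es) with missing age class ",
            if (missing_include) "included" else "excluded")
  }
  keep <- attributes$age_class == "independent"
  keep[miss] <- missing_include
  attributes$fox[keep]
}

#' Sighting frequency: days seen per fox
#'
#' Counts distinct survey days on which a fox was seen, per patch and
#' overall (any patch), within each territory-season survey.
#'
#' @param visits data.frame with fox, territory, season, patch, survey_day.
#' @return list with `by_patch` (fox, territory, season, patch, days_seen)
#'   and `by_fox` (fox, territory, season, days_seen over any patch).
#' @export
sighting_frequency <- function(visits) {
  dt <- data.table::as.data.table(visits)
  by_patch <- dt[, .(days_seen = data.table::uniqueN(survey_day)),
                 by = .(fox, territory, season, patch)]
  by_fox <- dt[, .(days_seen = data.table::uniqueN(survey_day)),
               by = .(fox, territory, season)]
  list(by_patch = as.data.frame(by_patch), by_fox = as.data.frame(by_fox))
}

#' Minimum days-seen eligibility filter
#'
#' Foxes qualify for contact-rate analysis (full patch set) or network
#' analysis (standardised patch set) when seen on at least `threshold`
#' distinct days in the survey.
#'
#' @param sf_by_fox `by_fox` table from [sighting_frequency()] computed on
#'   the relevant visit set (full or standardised).
#' @param threshold minimum days seen (default 5).
#' @return data.frame fox, territory, season of eligible fox-surveys.
#' @export
min_days_filter <- function(sf_by_fox, threshold = 5L) {
  out <- sf_by_fox[sf_by_fox$days_seen >= threshold,
                   c("fox", "territory", "season")]
  rownames(out) <- NULL
  out
}

#' Standardise patches across a territory's four seasons
#'
#' Network metrics are compared within territories across seasons, so each
#' territory is reduced to the patches monitored (i.e. with detections) in
#' all four seasons.  Optionally the retained set is further reduced to
#' `n_patches` by dropping the patches with the fewest total detections
#' (ties broken by patch id).
#'
#' @param visits visit table with territory, season, patch.
#' @param n_patches optional target number of patches per territory.
#' @return visits restricted to the standardised patch sets.
#' @export
standardise_patches <- function(visits, n_patches = NULL) {
  dt <- data.table::as.data.table(visits)
  keep_list <- lapply(split(dt, dt$territory), function(d) {
    sets <- lapply(split(d$patch, d$season), unique)
    common <- Reduce(intersect, sets)
    if (length(common) == 0) {
      stop("territory ", d$territory[1], ": no patch was monitored in every ",
           "season; supply an explicit patch list")
    }
    if (!is.null(n_patches) && length(common) > n_patches) {
      counts <- sort(table(d$patch[d$patch %in% common]), decreasing = TRUE)
      # deterministic: by detections desc, then patch id asc
      ord <- order(-as.numeric(counts), names(counts))
      common <- names(counts)[ord][seq_len(n_patches)]
    }
    data.frame(territory = d$territory[1], patch = common,
               stringsAsFactors = FALSE)
  })
  keep <- do.call(rbind, keep_list)
  out <- merge(as.data.frame(visits), keep, by = c("territory", "patch"))
  out[order(out$territory, out$season, out$fox, out$start), ]
}

#' Classify territory residency
#'
#' Residents of a territory-season are foxes photographed on >= `min_days`
#' days that share >= `min_assoc` associations with another resident.  The
#' circular clause (resident via association with a resident) is resolved by
#' a monotone fixed point: seed with all foxes passing the days criterion,
#' then repeatedly remove foxes lacking `min_assoc` associations with a
#' current member until stable.  A fox qualifying in two territories in one
#' season is assigned to the territory where it was seen on more days (ties:
#' alphabetical territory id).
#'
#' @param sf_by_fox days-seen table (`by_fox` from [sighting_frequency()]).
#' @param assoc_counts data.frame of dyadic association counts per
#'   territory-season: fox_a, fox_b, territory, season, n_assoc (unordered
#'   dyads, each listed once).
#' @param min_days days-seen threshold (default 20).
#' @param min_assoc association threshold (default 2).
#' @return data.frame fox, season, territory of resident assignments.
#' @export
classify_residency <- function(sf_by_fox, assoc_counts, min_days = 20L,
                               min_assoc = 2L) {
  sf <- data.table::as.data.table(sf_by_fox)
  ac <- data.table::as.data.table(assoc_counts)
  cand <- sf[days_seen >= min_days]
  if (nrow(cand) == 0) {
    return(data.frame(fox = character(0), season = character(0),
                      territory = character(0)))
  }
  keys <- unique(cand[, .(territory, season)])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    tid <- keys$territory[k]; ssn <- keys$season[k]
    members <- cand[territory == tid & season == ssn, fox]
    a <- ac[territory == tid & season == ssn & n_assoc >= min_assoc]
    repeat {
      ok <- vapply(members, function(f) {
        any((a$fox_a == f & a$fox_b %in% setdiff(members, f)) |
              (a$fox_b == f & a$fox_a %in% setdiff(members, f)))
      }, logical(1))
      if (all(ok) || !any(ok)) { members <- members[ok]; break }
      members <- members[ok]
    }
    if (length(members)) {
      out[[length(out) + 1L]] <- data.frame(fox = members, season = ssn,
                                            territory = tid,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(fox = character(0), season = character(0),
                      territory = character(0)))
  }
  res <- do.call(rbind, out)
  # one territory per fox-season: most days seen, then alphabetical territory
  res <- merge(res, as.data.frame(sf), by = c("fox", "territory", "season"))
  res <- res[order(res$fox, res$season, -res$days_seen, res$territory), ]
  res <- res[!duplicated(res[, c("fox", "season")]), ]
  res <- res[order(res$territory, res$season, res$fox),
             c("fox", "season", "territory")]
  rownames(res) <- NULL
  res
}
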