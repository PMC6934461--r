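# Dyadic encounters, grouping events (gambit of the group) and daily
# contact counts derived from visits.

#' Detect pairwise encounters from overlapping visits
#'
#' Two foxes visiting the same patch concurrently are associating; the
#' encounter duration is the temporal overlap of the two visits, e.g. visits
#' 20:00-20:30 and 20:20-20:30 overlap for 600 seconds.  Visits that merely
#' touch (one ends exactly when the other starts) count as encounters of
#' zero duration.  Encounters involving a `start_only` visit (end
#' unobserved) have their duration set to zero and are flagged so duration
#' models can treat them as zeros.
#'
#' @param visits visit table with fox, territory, season, patch, start, end,
#'   survey_day and optionally start_only.
#' @return data.frame of encounters: fox_a, fox_b (sorted within dyad),
#'   territory, season, patch, survey_day (day of the later visit start,
#'   i.e. of the overlap start), overlap_start, overlap_end, duration_s,
#'   start_only.
#' @export
detect_encounters <- function(visits) {
  v <- data.table::as.data.table(visits)
  if (!"start_only" %in% names(v)) v[, start_only := FALSE]
  if (nrow(v) < 2) {
    return(empty_encounters())
  }
  v[, `:=`(start_num = as.numeric(start), end_num = as.numeric(end))]
  v[, visit_id := seq_len(.N)]
  data.table::setkey(v, territory, season, patch, start_num, end_num)
  ov <- data.table::foverlaps(
    v[, .(territory, season, patch, start_num, end_num, fox, survey_day,
          start_only, visit_id)],
    v[, .(territory, season, patch, start_num, end_num, fox, survey_day,
          start_only, visit_id)],
    by.x = c("territory", "season", "patch", "start_num", "end_num"),
    by.y = c("territory", "season", "patch", "start_num", "end_num"),
    type = "any")
  ov <- ov[i.visit_id < visit_id & i.fox != fox]
  if (nrow(ov) == 0) return(empty_encounters())
  ov[, overlap_start := pmax(start_num, i.start_num)]
  ov[, overlap_end := pmin(end_num, i.end_num)]
  ov[, duration_s := overlap_end - overlap_start]
  ov[, start_only := start_only | i.start_only]
  ov[start_only == TRUE, duration_s := 0]
  # the overlap starts when the later visit starts; use that visit's day
  ov[, day := data.table::fifelse(start_num >= i.start_num, survey_day,
                                  i.survey_day)]
  out <- ov[, .(fox_a = pmin(fox, i.fox), fox_b = pmax(fox, i.fox),
                territory, season, patch, survey_day = day,
                overlap_start = as.POSIXct(overlap_start, tz = "UTC",
                                           origin = "1970-01-01"),
                overlap_end = as.POSIXct(overlap_end, tz = "UTC",
                                         origin = "1970-01-01"),
                duration_s, start_only)]
  data.table::setorder(out, territory, season, patch, survey_day,
                       overlap_start)
  as.data.frame(out)
}

empty_encounters <- function() {
  data.frame(fox_a = character(0), fox_b = character(0),
             territory = character(0), season = character(0),
             patch = character(0), survey_day = integer(0),
             overlap_start = as.POSIXct(character(0), tz = "UTC"),
             overlap_end = as.POSIXct(character(0), tz = "UTC"),
             duration_s = numeric(0), start_only = logical(0))
}

#' Attribute encounters to before/after midnight
#'
#' Households provision in the afternoon/evening and food is generally gone
#' by midnight, so the clock period of an encounter proxies food
#' availability.  An encounter belongs to the period containing its overlap
#' start: clock times in \[12:00, 24:00) are "before midnight" (food),
#' \[00:00, 12:00) "after" (no food).  Midnight-spanning encounters follow
#' their start.
#'
#' @param encounters output of [detect_encounters()].
#' @return encounters with a logical `before_midnight` column.
#' @export
encounter_duration_split <- function(encounters) {
  secs <- as.numeric(encounters$overlap_start) %% 86400
  encounters$before_midnight <- secs >= 12 * 3600
  encounters
}

#' Build gambit-of-the-group grouping events
#'
#' Within each patch and survey day, visits whose intervals form a connected
#' chain of pairwise temporal overlaps constitute one grouping event (all
#' members are taken to be associating).  Touching intervals count as
#' overlapping.  Singleton visits form singleton events.
#'
#' @param visits visit table with fox, territory, season, patch, start, end,
#'   survey_day.
#' @return data.frame of events: event_id, territory, season, patch,
#'   survey_day, span_start, span_end, n_members, members (comma-separated
#'   sorted fox ids).
#' @export
build_grouping_events <- function(visits) {
  v <- data.table::as.data.table(visits)
  if (nrow(v) == 0) {
    return(data.frame(event_id = integer(0), territory = character(0),
                      season = character(0), patch = character(0),
                      survey_day = integer(0),
                      span_start = as.POSIXct(character(0), tz = "UTC"),
                      span_end = as.POSIXct(character(0), tz = "UTC"),
                      n_members = integer(0), members = character(0)))
  }
  v[, `:=`(start_num = as.numeric(start), end_num = as.numeric(end))]
  data.table::setorder(v, territory, season, patch, survey_day, start_num,
                       end_num)
  # on a line, components of the interval-overlap graph are maximal runs in
  # which each interval starts no later than the running max end
  v[, event_id := {
    run_end <- cummax(end_num)
    cumsum(start_num > data.table::shift(run_end, fill = -Inf))
  }, by = .(territory, season, patch, survey_day)]
  ev <- v[, .(span_start = min(start_num), span_end = max(end_num),
              n_members = data.table::uniqueN(fox),
              members = paste(sort(unique(fox)), collapse = ",")),
          by = .(territory, season, patch, survey_day, event_id)]
  ev[, `:=`(span_start = as.POSIXct(span_start, tz = "UTC",
                                    origin = "1970-01-01"),
            span_end = as.POSIXct(span_end, tz = "UTC",
                                  origin = "1970-01-01"))]
  ev[, event_id := seq_len(.N)]
  as.data.frame(ev[, .(event_id, territory, season, patch, survey_day,
                       span_start, span_end, n_members, members)])
}

#' Daily contact counts per fox, patch and survey day
#'
#' The response of the daily contact-rate model: for every eligible fox, on
#' every survey day it was seen at a patch, the number of associations
#' (dyadic encounters) it had with any other eligible fox at that patch that
#' day.  Days with presence but no encounters contribute zeros - the zeros
#' are real observations.
#'
#' @param encounters output of [detect_encounters()] (any dyad filter is
#'   applied here via `eligible`).
#' @param visits visit table (defines presence: fox-patch-days seen).
#' @param eligible character vector of eligible fox ids (independent,
#'   seen >= 5 days); both members of a counted encounter must be eligible.
#' @return data.frame: fox, territory, season, patch, survey_day,
#'   n_contacts.
#' @export
daily_contact_counts <- function(encounters, visits, eligible) {
  v <- data.table::as.data.table(visits)[fox %in% eligible]
  pres <- unique(v[, .(fox, territory, season, patch, survey_day)])
  e <- data.table::as.data.table(encounters)
  e <- e[fox_a %in% eligible & fox_b %in% eligible]
  if (nrow(e)) {
    long <- data.table::rbindlist(list(
      e[, .(fox = fox_a, territory, season, patch, survey_day)],
      e[, .(fox = fox_b, territory, season, patch, survey_day)]))
    cnt <- long[, .(n_contacts = .N),
                by = .(fox, territory, season, patch, survey_day)]
    out <- merge(pres, cnt,
                 by = c("fox", "territory", "season", "patch", "survey_day"),
                 all.x = TRUE)
    out[is.na(n_contacts), n_contacts := 0L]
  } else {
    out <- pres[, .(fox, territory, season, patch, survey_day,
                    n_contacts = 0L)]
  }
  data.table::setorder(out, territory, season, patch, survey_day, fox)
  as.data.frame(out)
}

#' Provisioning covariates per patch and season
#'
#' Provisioning frequency is the mean number of days per week on which food
#' was provided; energy value is the mean nutritional value (MJ) of food
#' supplied per feeding day.
#'
#' @param provisioning log with territory, patch, season, survey_day,
#'   energy_mj.
#' @param survey_length_days survey window length (days).
#' @return data.frame: territory, patch, season, provisioning_freq
#'   (days/week), energy_mj (MJ per feeding day).  Patch-seasons absent from
#'   the log get zeros with a warning.
#' @export
provisioning_covariates <- function(provisioning, survey_length_days = 40L) {
  p <- data.table::as.data.table(provisioning)
  if (nrow(p) == 0) {
    warning("empty provisioning log; covariates set to 0")
    return(data.frame(territory = character(0), patch = character(0),
                      season = character(0), provisioning_freq = numeric(0),
                      energy_mj = numeric(0)))
  }
  out <- p[, .(provisioning_freq =
                 data.table::uniqueN(survey_day) / (survey_length_days / 7),
               energy_mj = mean(energy_mj)),
           by = .(territory, patch, season)]
  data.table::setorder(out, territory, patch, season)
  as.data.frame(out)
}
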