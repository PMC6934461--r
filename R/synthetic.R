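# Synthetic camera-trap detection streams with known social ground truth.
#
# The generator emulates the field design the pipeline expects: several fox
# territories monitored at provisioned food patches, cameras running
# continuously for 40-day surveys in four consecutive seasons, noon-to-noon
# survey days, and nocturnal activity.  Social structure is induced by a
# shared grouping-event process (gambit of the group) whose attendance
# depends on dyadic preference weights and on sex/status/season effects.

#' Scenario configuration for the synthetic detection generator
#'
#' Defaults describe the stated study design: 7 territories, 4-6 monitored
#' food patches per territory, 40-day surveys in four consecutive seasons,
#' groups of roughly 4-8 independent foxes led by a dominant pair, and
#' provisioning on at least 2 days/week.
#'
#' Two log-linear effect sets drive individual behaviour: `effects` scales a
#' fox's solo visit rate (presence at patches), `social_effects` scales its
#' propensity to join grouping events (gregariousness).  Both use the same
#' structure: `sex_male`, `status_dominant`, `season` (named vector, spring
#' reference), and `sex_season` (additional male effect per season).
#'
#' @param n_territories number of territories.
#' @param patches_per_territory integer range (length 2) of monitored patches
#'   per territory.
#' @param group_size_range integer range of independent residents per
#'   territory (lower bound must be >= 2 so a dominant pair exists).
#' @param survey_length_days days per seasonal survey.
#' @param seasons exactly four ordered season labels.
#' @param visit_rate baseline solo visits per fox per patch per day
#'   (reference: subordinate female in spring).
#' @param effects log-linear effects on the solo visit rate.
#' @param social_effects log-linear effects on grouping-event attendance.
#' @param grouping_rate expected grouping events per patch per day.
#' @param join_base baseline attendance probability scale; fox j joins an
#'   event seeded by fox s with probability
#'   `min(1, join_base * preference[s, j] * exp(eta_social_j))`.
#' @param preference_background dyadic preference weight in \[0, 1\] used for
#'   every within-territory dyad unless overridden.
#' @param preference_special optional data.frame with columns `fox_a`,
#'   `fox_b`, `weight` overriding individual dyads (applied symmetrically).
#'   Fox ids follow the generator's naming scheme, e.g. `"T01F01"`.
#' @param nonresident_rate named vector: expected intruder visits per
#'   territory per day, by season.
#' @param nonresident_winter_male_prop probability that a winter intruder is
#'   male (0.5 in other seasons).
#' @param provisioning_spec list with `days_per_week_range` (integer range),
#'   `energy_mean_mj` and `energy_sd_mj` (per feeding day).
#' @param mean_visit_duration_s mean of the exponential visit duration.
#' @param max_visit_duration_s truncation point for visit durations (2 h).
#' @param cubs_per_territory dependent cubs (<5 months) per territory; they
#'   appear in detections at `cub_rate_factor` times the baseline rate and
#'   exercise the age filter downstream.
#' @param cub_rate_factor rate multiplier for cubs.
#' @param survey_starts named character vector of season start dates
#'   (surveys start at noon UTC on these dates).
#' @param seed integer root seed; fixes the full output byte-for-byte.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_territories = 7L,
                            patches_per_territory = c(4L, 6L),
                            group_size_range = c(4L, 8L),
                            survey_length_days = 40L,
                            seasons = c("spring", "summer", "autumn", "winter"),
                            visit_rate = 0.5,
                            effects = list(
                              sex_male = 0, status_dominant = 0.15,
                              season = c(spring = 0, summer = 0, autumn = 0,
                                         winter = -0.4),
                              sex_season = c(spring = 0, summer = 0,
                                             autumn = 0, winter = 0)),
                            social_effects = list(
                              sex_male = 0, status_dominant = 0.2,
                              season = c(spring = 0, summer = 0, autumn = 0,
                                         winter = -0.3),
                              sex_season = c(spring = 0, summer = 0,
                                             autumn = 0, winter = 0)),
                            grouping_rate = 0.5,
                            join_base = 0.5,
                            preference_background = 0.5,
                            preference_special = NULL,
                            nonresident_rate = c(spring = 0.10, summer = 0.10,
                                                 autumn = 0.15, winter = 0.25),
                            nonresident_winter_male_prop = 0.8,
                            provisioning_spec = list(
                              days_per_week_range = c(2L, 7L),
                              energy_mean_mj = 1.5, energy_sd_mj = 0.5),
                            mean_visit_duration_s = 600,
                            max_visit_duration_s = 7200,
                            cubs_per_territory = 1L,
                            cub_rate_factor = 0.3,
                            survey_starts = c(spring = "2014-03-01",
                                              summer = "2014-06-01",
                                              autumn = "2014-09-01",
                                              winter = "2014-12-01"),
                            seed = 1L) {
  cfg <- list(
    n_territories = as.integer(n_territories),
    patches_per_territory = as.integer(rep(patches_per_territory, length.out = 2)),
    group_size_range = as.integer(rep(group_size_range, length.out = 2)),
    survey_length_days = as.integer(survey_length_days),
    seasons = seasons,
    visit_rate = visit_rate,
    effects = effects,
    social_effects = social_effects,
    grouping_rate = grouping_rate,
    join_base = join_base,
    preference_background = preference_background,
    preference_special = preference_special,
    nonresident_rate = nonresident_rate,
    nonresident_winter_male_prop = nonresident_winter_male_prop,
    provisioning_spec = provisioning_spec,
    mean_visit_duration_s = mean_visit_duration_s,
    max_visit_duration_s = max_visit_duration_s,
    cubs_per_territory = as.integer(cubs_per_territory),
    cub_rate_factor = cub_rate_factor,
    survey_starts = survey_starts,
    seed = as.integer(seed)
  )
  validate_scenario_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(
    cfg$n_territories >= 1L,
    length(cfg$patches_per_territory) == 2L,
    all(cfg$patches_per_territory >= 1L),
    length(cfg$group_size_range) == 2L,
    cfg$survey_length_days >= 1L,
    length(cfg$seasons) == 4L,
    cfg$visit_rate >= 0, cfg$grouping_rate >= 0, cfg$join_base >= 0,
    cfg$preference_background >= 0, cfg$preference_background <= 1,
    all(cfg$nonresident_rate >= 0),
    cfg$mean_visit_duration_s > 0,
    all(cfg$seasons %in% names(cfg$survey_starts))
  )
  if (cfg$group_size_range[1] < 2L) {
    stop("group_size_range lower bound must be >= 2 (a dominant pair is required)")
  }
  if (!all(cfg$seasons %in% names(cfg$effects$season)) ||
      !all(cfg$seasons %in% names(cfg$social_effects$season))) {
    stop("effects$season and social_effects$season must name every season")
  }
  if (!is.null(cfg$preference_special)) {
    stopifnot(all(c("fox_a", "fox_b", "weight") %in% names(cfg$preference_special)),
              all(cfg$preference_special$weight >= 0),
              all(cfg$preference_special$weight <= 1))
  }
  invisible(cfg)
}

# sample one integer from an inclusive range (safe for degenerate ranges)
sample_range <- function(lo, hi) {
  if (lo >= hi) lo else sample(seq(lo, hi), 1L)
}

# linear predictor on the log scale for one effect set
eta_effects <- function(eff, sex, status, season) {
  eff$sex_male * (sex == "M") +
    eff$status_dominant * (status == "dominant") +
    unname(eff$season[season]) +
    unname(eff$sex_season[season]) * (sex == "M")
}

# noon-start survey start times (numeric seconds since epoch), named by season
season_starts_num <- function(config) {
  s <- as.POSIXct(paste(config$survey_starts[config$seasons], "12:00:00"),
                  tz = "UTC")
  stats::setNames(as.numeric(s), config$seasons)
}

#' Generate the fox population and ground truth
#'
#' Each territory receives one dominant male, one dominant female, a drawn
#' number of subordinates of random sex, optional dependent cubs, and a small
#' pool of non-resident "strangers" that fuel intrusion events.  The dyadic
#' preference matrix over independent foxes is the background weight with any
#' configured special-dyad overrides.
#'
#' @param config a [scenario_config()].
#' @return list with `attributes` (fox, territory, sex, status, age_class),
#'   `patches` (territory, patch), and `ground_truth` (dyad preference
#'   matrix, true effects, residency truth).
#' @export
generate_population <- function(config) {
  validate_scenario_config(config)
  with_seed(mix_seed(config$seed, 1L), {
    rows <- vector("list", config$n_territories)
    patch_rows <- vector("list", config$n_territories)
    for (t in seq_len(config$n_territories)) {
      tid <- sprintf("T%02d", t)
      n <- sample_range(config$group_size_range[1], config$group_size_range[2])
      sex <- c("M", "F",
               if (n > 2) sample(c("M", "F"), n - 2L, replace = TRUE))
      status <- c("dominant", "dominant", rep("subordinate", n - 2L))
      fox <- sprintf("%sF%02d", tid, seq_len(n))
      df <- data.frame(fox = fox, territory = tid, sex = sex, status = status,
                       age_class = "independent", stringsAsFactors = FALSE)
      if (config$cubs_per_territory > 0) {
        nc <- config$cubs_per_territory
        df <- rbind(df, data.frame(
          fox = sprintf("%sC%02d", tid, seq_len(nc)), territory = tid,
          sex = sample(c("M", "F"), nc, replace = TRUE),
          status = "subordinate", age_class = "cub",
          stringsAsFactors = FALSE))
      }
      # strangers of unknown origin; only ever seen as intruders
      df <- rbind(df, data.frame(
        fox = sprintf("%sX%02d", tid, 1:4), territory = NA_character_,
        sex = c("M", "M", "F", "F"), status = "subordinate",
        age_class = "independent", stringsAsFactors = FALSE))
      rows[[t]] <- df
      n_p <- sample_range(config$patches_per_territory[1],
                          config$patches_per_territory[2])
      patch_rows[[t]] <- data.frame(territory = tid,
                                    patch = sprintf("%sP%d", tid, seq_len(n_p)),
                                    stringsAsFactors = FALSE)
    }
    attributes <- do.call(rbind, rows)
    patches <- do.call(rbind, patch_rows)

    indep <- attributes$fox[attributes$age_class == "independent"]
    pref <- matrix(config$preference_background, length(indep), length(indep),
                   dimnames = list(indep, indep))
    diag(pref) <- 0
    if (!is.null(config$preference_special)) {
      for (k in seq_len(nrow(config$preference_special))) {
        a <- config$preference_special$fox_a[k]
        b <- config$preference_special$fox_b[k]
        if (a %in% indep && b %in% indep) {
          pref[a, b] <- pref[b, a] <- config$preference_special$weight[k]
        }
      }
    }
    res <- attributes[!is.na(attributes$territory) &
                        attributes$age_class == "independent", ]
    residency_truth <- do.call(rbind, lapply(config$seasons, function(s) {
      data.frame(fox = res$fox, territory = res$territory, season = s,
                 stringsAsFactors = FALSE)
    }))
    list(attributes = attributes,
         patches = patches,
         ground_truth = list(dyad_preference = pref,
                             true_effects = list(visit = config$effects,
                                                 social = config$social_effects),
                             residency_truth = residency_truth))
  })
}

# exponential duration, truncated
rdur <- function(n, mean_s, max_s, min_s = 0) {
  pmin(pmax(rexp(n, rate = 1 / mean_s), min_s), max_s)
}

#' Simulate visits and emit camera-trap detections
#'
#' Per fox, patch and survey day, solo visits follow a homogeneous Poisson
#' process with a log-linear rate in the configured sex/status/season
#' effects.  Grouping events occur per patch and day; an event is seeded by
#' one fox (chosen proportionally to its visit rate) and every other
#' independent resident joins with probability proportional to its dyadic
#' preference with the seed and its social effects.  Attendees' visit
#' intervals are guaranteed to overlap, inducing gambit-of-the-group
#' structure.  Non-resident intruders (neighbours or strangers, male-biased
#' in winter) add solo visits.
#'
#' Visits by the same fox at the same patch closer than 16 minutes are merged
#' before photographs are emitted, and photographs within a visit are spaced
#' under 15 minutes with one photograph exactly at the start and the end, so
#' visit reconstruction from the photo stream is exact.
#'
#' @param config a [scenario_config()].
#' @param population output of [generate_population()].
#' @return list with `detections` (timestamp, territory, patch, fox, season),
#'   `visits` (ground-truth visit table with survey_day) and `calendar`
#'   (territory, season, survey start).
#' @export
simulate_visits <- function(config, population) {
  validate_scenario_config(config)
  s0 <- season_starts_num(config)
  terr_ids <- unique(population$patches$territory)
  calendar <- do.call(rbind, lapply(terr_ids, function(tid) {
    data.frame(territory = tid, season = config$seasons,
               start = as.POSIXct(s0[config$seasons], tz = "UTC",
                                  origin = "1970-01-01"),
               stringsAsFactors = FALSE)
  }))

  out <- with_seed(mix_seed(config$seed, 2L), {
    attrs <- population$attributes
    pref <- population$ground_truth$dyad_preference
    act_lo <- 6 * 3600    # 18:00 (offset from the noon day start)
    act_hi <- 20 * 3600   # 08:00 the next morning

    buf <- list(); bi <- 0L
    push <- function(fox, territory, season, patch, s, dur) {
      bi <<- bi + 1L
      buf[[bi]] <<- list(fox = fox, territory = rep(territory, length(fox)),
                         season = rep(season, length(fox)),
                         patch = rep(patch, length.out = length(fox)),
                         start_num = s, end_num = s + dur)
    }

    for (tid in terr_ids) {
      t_patches <- population$patches$patch[population$patches$territory == tid]
      res <- attrs[!is.na(attrs$territory) & attrs$territory == tid, ]
      res_ind <- res[res$age_class == "independent", ]
      neighbours <- attrs[!is.na(attrs$territory) & attrs$territory != tid &
                            attrs$age_class == "independent", ]
      strangers <- attrs[is.na(attrs$territory) & startsWith(attrs$fox, tid), ]
      pref_t <- pref[res_ind$fox, res_ind$fox, drop = FALSE]
      for (season in config$seasons) {
        eta_v <- eta_effects(config$effects, res$sex, res$status, season)
        lambda <- config$visit_rate * exp(eta_v) *
          ifelse(res$age_class == "cub", config$cub_rate_factor, 1)
        eta_s <- eta_effects(config$social_effects, res_ind$sex,
                             res_ind$status, season)
        join_g <- config$join_base * exp(eta_s)
        # the event seed is social behaviour too: seeded proportionally to
        # the same gregariousness that governs joining
        seed_w <- exp(eta_s)
        male_p <- if (season == "winter")
          config$nonresident_winter_male_prop else 0.5
        nr_rate <- unname(config$nonresident_rate[season])
        for (d in seq_len(config$survey_length_days)) {
          dstart <- s0[season] + (d - 1) * 86400
          for (p in t_patches) {
            # solo visits
            n_solo <- rpois(nrow(res), lambda)
            tot <- sum(n_solo)
            if (tot > 0) {
              s <- round(dstart + runif(tot, act_lo, act_hi))
              dur <- round(rdur(tot, config$mean_visit_duration_s,
                                config$max_visit_duration_s))
              push(rep(res$fox, n_solo), tid, season, p, s, dur)
            }
            # grouping events
            n_ev <- rpois(1, config$grouping_rate)
            if (n_ev > 0 && nrow(res_ind) >= 2) {
              for (e in seq_len(n_ev)) {
                ev_t <- round(dstart + runif(1, act_lo, act_hi - 7200))
                seed_i <- sample.int(nrow(res_ind), 1, prob = seed_w)
                # dyadic attendance: preference times the gregariousness of
                # both the joiner and the seed
                p_join <- pmin(1, join_g * pref_t[seed_i, ] * seed_w[seed_i])
                p_join[seed_i] <- 0
                members <- c(seed_i, which(runif(nrow(res_ind)) < p_join))
                s <- round(ev_t + runif(length(members), 0, 60))
                dur <- round(rdur(length(members),
                                  config$mean_visit_duration_s,
                                  config$max_visit_duration_s, min_s = 120))
                push(res_ind$fox[members], tid, season, p, s, dur)
              }
            }
          }
          # non-resident intrusions (one solo visit each, random patch)
          n_int <- rpois(1, nr_rate)
          if (n_int > 0) {
            for (k in seq_len(n_int)) {
              want_sex <- if (runif(1) < male_p) "M" else "F"
              use_neigh <- runif(1) < 0.6 && nrow(neighbours) > 0
              pool <- if (use_neigh) {
                neighbours[neighbours$sex == want_sex, , drop = FALSE]
              } else {
                strangers[strangers$sex == want_sex, , drop = FALSE]
              }
              if (nrow(pool) == 0) pool <- strangers
              intr <- pool[sample.int(nrow(pool), 1), ]
              s <- round(dstart + runif(1, act_lo, act_hi))
              dur <- round(rdur(1, config$mean_visit_duration_s,
                                config$max_visit_duration_s))
              push(intr$fox, tid, season,
                   t_patches[sample.int(length(t_patches), 1)], s, dur)
            }
          }
        }
      }
    }

    if (bi == 0L) {
      list(visits = NULL, detections = NULL)
    } else {
    visits <- data.table::rbindlist(buf)

    # Merge same-fox same-patch visits closer than 16 min so that the 15-min
    # collapse rule reconstructs ground truth exactly (integer-second safe:
    # separated ground-truth visits have photo gaps >= 960 s > 900 s).
    data.table::setorder(visits, fox, patch, start_num)
    visits[, new_visit := {
      gap <- start_num - data.table::shift(cummax(end_num), fill = -Inf)
      as.integer(gap >= 960)
    }, by = .(fox, patch)]
    visits[, visit_id := cumsum(new_visit), by = .(fox, patch)]
    truth <- visits[, .(territory = territory[1], season = season[1],
                        start_num = min(start_num),
                        end_num = max(cummax(end_num))),
                    by = .(fox, patch, visit_id)]
    truth[, survey_day := floor((start_num - s0[season]) / 86400) + 1L]

    # photo emission: a fixed grid every 840 s (including start and end) plus
    # Poisson extras; guarantees in-visit gaps < 15 min
    dur <- truth$end_num - truth$start_num
    n_grid <- floor(dur / 840) + 1L
    grid_t <- rep(truth$start_num, n_grid) +
      840 * (sequence(n_grid) - 1L)
    grid_idx <- rep(seq_len(nrow(truth)), n_grid)
    n_extra <- rpois(nrow(truth), dur / 600)
    extra_idx <- rep(seq_len(nrow(truth)), n_extra)
    extra_t <- round(truth$start_num[extra_idx] +
                       runif(length(extra_idx)) * dur[extra_idx])
    photos <- data.table::data.table(
      idx = c(grid_idx, seq_len(nrow(truth)), extra_idx),
      t = c(grid_t, truth$end_num, extra_t))
    photos <- unique(photos)
    det <- data.table::data.table(
      timestamp = as.POSIXct(photos$t, tz = "UTC", origin = "1970-01-01"),
      territory = truth$territory[photos$idx],
      patch = truth$patch[photos$idx],
      fox = truth$fox[photos$idx],
      season = truth$season[photos$idx])
    data.table::setorder(det, territory, patch, timestamp, fox)
    list(visits = truth, detections = det)
    }
  })

  if (is.null(out$visits)) {
    return(list(detections = data.frame(
      timestamp = as.POSIXct(character(0), tz = "UTC"),
      territory = character(0), patch = character(0),
      fox = character(0), season = character(0)),
      visits = data.frame(), calendar = calendar))
  }
  truth <- out$visits
  truth[, start := as.POSIXct(start_num, tz = "UTC", origin = "1970-01-01")]
  truth[, end := as.POSIXct(end_num, tz = "UTC", origin = "1970-01-01")]
  visits <- as.data.frame(truth[, .(fox, territory, season, patch, start, end,
                                    survey_day)])
  list(detections = as.data.frame(out$detections), visits = visits,
       calendar = calendar)
}

#' Simulate householder provisioning logs
#'
#' Each patch gets a weekly feeding schedule (days/week drawn from the
#' configured range, fixed weekdays) and a per-feeding-day energy value drawn
#' around the configured mean.  Food is placed in the evening (18:00-23:00),
#' consistent with the before-midnight food-availability proxy.
#'
#' @param config a [scenario_config()].
#' @param population output of [generate_population()] (for the patch list).
#' @return data.frame with territory, patch, season, survey_day, timestamp,
#'   energy_mj.
#' @export
simulate_provisioning <- function(config, population) {
  validate_scenario_config(config)
  s0 <- season_starts_num(config)
  spec <- config$provisioning_spec
  with_seed(mix_seed(config$seed, 3L), {
    rows <- list(); ri <- 0L
    for (k in seq_len(nrow(population$patches))) {
      tid <- population$patches$territory[k]
      p <- population$patches$patch[k]
      rng <- spec$days_per_week_range
      dpw <- sample_range(rng[1], rng[2])
      feed_wdays <- sort(sample(0:6, dpw))
      for (season in config$seasons) {
        days <- seq_len(config$survey_length_days)
        dstart <- s0[season] + (days - 1) * 86400
        wday <- as.POSIXlt(as.POSIXct(dstart, tz = "UTC",
                                      origin = "1970-01-01"))$wday
        feed_days <- days[wday %in% feed_wdays]
        if (length(feed_days) == 0) next
        energy <- pmax(0.05, rnorm(length(feed_days), spec$energy_mean_mj,
                                   spec$energy_sd_mj))
        t_feed <- round(s0[season] + (feed_days - 1) * 86400 +
                          runif(length(feed_days), 6 * 3600, 11 * 3600))
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          territory = tid, patch = p, season = season,
          survey_day = feed_days,
          timestamp = as.POSIXct(t_feed, tz = "UTC", origin = "1970-01-01"),
          energy_mj = energy, stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      return(data.frame(territory = character(0), patch = character(0),
                        season = character(0), survey_day = integer(0),
                        timestamp = as.POSIXct(character(0), tz = "UTC"),
                        energy_mj = numeric(0)))
    }
    do.call(rbind, rows)
  })
}

#' Simulate a complete scenario
#'
#' Convenience wrapper running [generate_population()], [simulate_visits()]
#' and [simulate_provisioning()] under one root seed.
#'
#' @param config a [scenario_config()].
#' @return list with config, attributes, patches, detections, visits
#'   (ground truth), provisioning, calendar and ground_truth.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  pop <- generate_population(config)
  vis <- simulate_visits(config, pop)
  prov <- simulate_provisioning(config, pop)
  list(config = config,
       attributes = pop$attributes,
       patches = pop$patches,
       detections = vis$detections,
       visits = vis$visits,
       provisioning = prov,
       calendar = vis$calendar,
       ground_truth = pop$ground_truth)
}

#' Write a simulated scenario to delimited text files
#'
#' Writes detections, attributes, provisioning and the survey calendar as
#' CSV (ISO-8601 timestamps, UTC) plus a JSON manifest recording the
#' configuration and seed.
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  det <- scenario$detections
  det$timestamp <- format_iso8601(det$timestamp)
  write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  write.csv(scenario$attributes, file.path(dir, "attributes.csv"),
            row.names = FALSE)
  prov <- scenario$provisioning
  if (nrow(prov)) prov$timestamp <- format_iso8601(prov$timestamp)
  write.csv(prov, file.path(dir, "provisioning.csv"), row.names = FALSE)
  cal <- scenario$calendar
  cal$start <- format_iso8601(cal$start)
  write.csv(cal, file.path(dir, "calendar.csv"), row.names = FALSE)
  cfg <- scenario$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
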