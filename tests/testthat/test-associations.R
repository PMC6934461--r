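# encounters, grouping events, contact counts, provisioning covariates

ts <- function(x) as.POSIXct(x, tz = "UTC")

mk_visits <- function(fox, start, end, patch = "P1", day = 1) {
  data.frame(fox = fox, territory = "T01", season = "spring", patch = patch,
             start = ts(start), end = ts(end), survey_day = day,
             start_only = FALSE)
}

test_that("worked example: 20:00-20:30 with 20:20-20:30 overlaps 600 s", {
  v <- mk_visits(c("A", "B"),
                 c("2014-03-01 20:00:00", "2014-03-01 20:20:00"),
                 c("2014-03-01 20:30:00", "2014-03-01 20:30:00"))
  e <- detect_encounters(v)
  expect_equal(nrow(e), 1)
  expect_equal(e$duration_s, 600)
  expect_equal(c(e$fox_a, e$fox_b), c("A", "B"))
})

test_that("disjoint visits yield no encounter; touching yields 0 s", {
  v <- mk_visits(c("A", "B"),
                 c("2014-03-01 20:00:00", "2014-03-01 20:20:00"),
                 c("2014-03-01 20:10:00", "2014-03-01 20:30:00"))
  expect_equal(nrow(detect_encounters(v)), 0)
  v2 <- mk_visits(c("A", "B"),
                  c("2014-03-01 20:00:00", "2014-03-01 20:10:00"),
                  c("2014-03-01 20:10:00", "2014-03-01 20:30:00"))
  e2 <- detect_encounters(v2)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$duration_s, 0)
  expect_false(e2$start_only)
})

test_that("start_only encounters get zero duration and the flag", {
  v <- mk_visits(c("A", "B"),
                 c("2014-03-01 20:00:00", "2014-03-01 20:10:00"),
                 c("2014-03-01 20:30:00", "2014-03-01 20:40:00"))
  v$start_only <- c(FALSE, TRUE)
  e <- detect_encounters(v)
  expect_equal(e$duration_s, 0)
  expect_true(e$start_only)
})

test_that("encounters match the per-second co-presence oracle on random
           visit sets", {
  set.seed(11)
  base <- as.numeric(ts("2014-03-01 18:00:00"))
  for (r in 1:20) {
    n <- sample(4:12, 1)
    foxes <- sample(LETTERS[1:5], n, replace = TRUE)
    s <- base + sample(0:7200, n)
    d <- sample(0:1800, n)
    v <- mk_visits(foxes, as.POSIXct(s, tz = "UTC", origin = "1970-01-01"),
                   as.POSIXct(s + d, tz = "UTC", origin = "1970-01-01"))
    # drop same-fox overlapping visits (contract: visits are collapsed)
    e <- detect_encounters(v)
    # oracle: enumerate all visit pairs with different foxes
    exp_rows <- 0L; exp_total <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (foxes[i] == foxes[j]) next
      ov <- oracle_overlap(s[i], s[i] + d[i], s[j], s[j] + d[j])
      if (!is.null(ov)) { exp_rows <- exp_rows + 1L; exp_total <- exp_total + ov }
    }
    expect_equal(nrow(e), exp_rows)
    expect_equal(sum(e$duration_s), exp_total)
  }
})

test_that("midnight split is start-based", {
  v <- mk_visits(c("A", "B", "A", "B"),
                 c("2014-03-01 23:50:00", "2014-03-01 23:55:00",
                   "2014-03-02 00:10:00", "2014-03-02 00:15:00"),
                 c("2014-03-02 00:20:00", "2014-03-02 00:05:00",
                   "2014-03-02 00:30:00", "2014-03-02 00:40:00"))
  e <- encounter_duration_split(detect_encounters(v))
  e <- e[order(as.numeric(e$overlap_start)), ]
  # encounter starting 23:55 (spans midnight): before; starting 00:15: after
  expect_true(e$before_midnight[1])
  expect_false(e$before_midnight[2])
})

test_that("grouping events chain overlapping visits and match the
           union-find oracle", {
  # A-B overlap, B-C overlap, A-C disjoint -> one event {A,B,C}
  v <- mk_visits(c("A", "B", "C"),
                 c("2014-03-01 20:00:00", "2014-03-01 20:25:00",
                   "2014-03-01 20:50:00"),
                 c("2014-03-01 20:30:00", "2014-03-01 21:00:00",
                   "2014-03-01 21:10:00"))
  ev <- build_grouping_events(v)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$members, "A,B,C")
  expect_equal(ev$n_members, 3)
  # no overlaps: three singleton events
  v2 <- mk_visits(c("A", "B", "C"),
                  c("2014-03-01 18:00:00", "2014-03-01 19:00:00",
                    "2014-03-01 20:00:00"),
                  c("2014-03-01 18:10:00", "2014-03-01 19:10:00",
                    "2014-03-01 20:10:00"))
  expect_equal(nrow(build_grouping_events(v2)), 3)
  # random intervals match union-find components
  set.seed(13)
  base <- as.numeric(ts("2014-03-01 18:00:00"))
  for (r in 1:20) {
    n <- sample(3:12, 1)
    s <- base + sample(0:5000, n)
    d <- sample(0:1500, n)
    v <- mk_visits(paste0("F", seq_len(n)),
                   as.POSIXct(s, tz = "UTC", origin = "1970-01-01"),
                   as.POSIXct(s + d, tz = "UTC", origin = "1970-01-01"))
    ev <- build_grouping_events(v)
    comp <- oracle_components(s, s + d)
    expect_equal(nrow(ev), length(unique(comp)))
    expect_equal(sort(table(comp), decreasing = TRUE),
                 sort(ev$n_members, decreasing = TRUE),
                 ignore_attr = TRUE)
    # chaining never merges events with disjoint spans
    spans <- ev[order(ev$span_start), ]
    if (nrow(spans) > 1) {
      expect_true(all(diff(as.numeric(spans$span_start)) >= 0))
    }
  }
})

test_that("daily contact counts include real zeros and balance encounters", {
  v <- mk_visits(c("A", "B", "C"),
                 c("2014-03-01 20:00:00", "2014-03-01 20:10:00",
                   "2014-03-02 20:00:00"),
                 c("2014-03-01 20:30:00", "2014-03-01 20:40:00",
                   "2014-03-02 20:30:00"),
                 day = c(1, 1, 2))
  e <- detect_encounters(v)
  cc <- daily_contact_counts(e, v, c("A", "B", "C"))
  expect_equal(cc$n_contacts[cc$fox == "A"], 1)
  expect_equal(cc$n_contacts[cc$fox == "B"], 1)
  expect_equal(cc$n_contacts[cc$fox == "C"], 0)  # present, alone: a real zero
  # symmetric accounting: sum of counts = 2 x encounters
  expect_equal(sum(cc$n_contacts), 2 * nrow(e))
  # ineligible fox drops from both sides
  cc2 <- daily_contact_counts(e, v, c("A", "C"))
  expect_equal(sum(cc2$n_contacts), 0)
  expect_equal(nrow(cc2), 2)
})

test_that("contact balance holds on simulated data", {
  scn <- simulate_scenario(small_scenario(seed = 31))
  v <- add_survey_day(collapse_to_visits(scn$detections), scn$calendar)
  v <- v[v$fox %in% filter_independent(scn$attributes), ]
  e <- detect_encounters(v)
  foxes <- unique(v$fox)
  cc <- daily_contact_counts(e, v, foxes)
  expect_equal(sum(cc$n_contacts), 2 * nrow(e))
  # duration symmetry: the dyad is unordered
  expect_true(all(e$fox_a <= e$fox_b))
  expect_true(all(e$duration_s >= 0))
})

test_that("provisioning covariates are plain arithmetic", {
  log <- data.frame(territory = "T01", patch = "P1", season = "spring",
                    survey_day = seq(1, 39, by = 2), energy_mj = 1)
  cov <- provisioning_covariates(log, 40)
  expect_equal(cov$provisioning_freq, 20 / (40 / 7))  # 3.5 days/week
  expect_equal(cov$energy_mj, 1)
  expect_warning(provisioning_covariates(log[0, ], 40), "empty")
})
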