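# End-to-end orchestration: detections -> visits -> encounters/groups ->
# networks -> permutation tests -> summary tables.

#' Run the full camera-trap network pipeline
#'
#' Executes, per territory-season survey: visit reconstruction (15-min
#' rule), the independence (age) filter, encounter detection and grouping
#' events, contact-rate eligibility (seen >= `min_days` days, full patch
#' set) and network eligibility (seen >= `min_days` days in the
#' patch-standardised data), SRI association matrices, the Manly/Bejder
#' non-randomness test, global metrics, node metrics, assortativity (for
#' residents in non-random networks) and residency classification.
#'
#' Model fitting (contact-rate GLMMs, hurdle durations, permutation
#' P-values for coefficients) is intentionally left to the dedicated
#' functions; this driver produces the tables those models consume.
#'
#' @param config a [scenario_config()]; used to simulate data when
#'   `scenario` is NULL and for the survey calendar.
#' @param scenario optional pre-simulated scenario (or a list with elements
#'   detections, attributes, calendar, provisioning read from files).
#' @param n_perm permutations for the Manly/Bejder test per network.
#' @param swaps_per_perm swaps per permutation.
#' @param min_days days-seen eligibility threshold.
#' @param residency_days,residency_assoc residency thresholds.
#' @param gap_s visit gap threshold in seconds.
#' @param verbose log applied thresholds with message().
#' @return a result bundle (list); see [summarize_bundle()].
#' @export
run_pipeline <- function(config = scenario_config(), scenario = NULL,
                         n_perm = 2000L, swaps_per_perm = 10L,
                         min_days = 5L, residency_days = 20L,
                         residency_assoc = 2L, gap_s = 900,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(scenario)) scenario <- simulate_scenario(config)
  say("pipeline: gap_s=%g min_days=%d residency_days=%d residency_assoc=%d n_perm=%d swaps=%d seed=%d",
      gap_s, min_days, residency_days, residency_assoc, n_perm,
      swaps_per_perm, config$seed)

  cal <- scenario$calendar
  censor <- stats::setNames(
    as.numeric(unique(cal[, c("season", "start")])$start) +
      config$survey_length_days * 86400,
    unique(cal[, c("season", "start")])$season)
  visits <- collapse_to_visits(scenario$detections, gap_s = gap_s,
                               censor_end = censor)
  visits <- add_survey_day(visits, cal, config$survey_length_days)

  independents <- filter_independent(scenario$attributes)
  visits <- visits[visits$fox %in% independents, ]
  say("pipeline: %d visits by %d independent foxes", nrow(visits),
      length(unique(visits$fox)))

  encounters <- encounter_duration_split(detect_encounters(visits))
  sf <- sighting_frequency(visits)
  eligible_contact <- min_days_filter(sf$by_fox, min_days)

  # contact counts per survey, eligibility applied within territory-season
  cc_list <- list()
  surveys <- unique(visits[, c("territory", "season")])
  for (k in seq_len(nrow(surveys))) {
    tid <- surveys$territory[k]; ssn <- surveys$season[k]
    el <- eligible_contact$fox[eligible_contact$territory == tid &
                                 eligible_contact$season == ssn]
    if (length(el) == 0) next
    vk <- visits[visits$territory == tid & visits$season == ssn, ]
    ek <- encounters[encounters$territory == tid & encounters$season == ssn, ]
    cc_list[[k]] <- daily_contact_counts(ek, vk, el)
  }
  contacts <- do.call(rbind, cc_list)

  # residency from full-patch data
  e_dt <- data.table::as.data.table(encounters)
  assoc_counts <- if (nrow(e_dt)) {
    as.data.frame(e_dt[, .(n_assoc = .N),
                       by = .(fox_a, fox_b, territory, season)])
  } else {
    data.frame(fox_a = character(0), fox_b = character(0),
               territory = character(0), season = character(0),
               n_assoc = integer(0))
  }
  residency <- classify_residency(sf$by_fox, assoc_counts,
                                  min_days = residency_days,
                                  min_assoc = residency_assoc)

  # standardised data for networks
  visits_std <- standardise_patches(visits)
  sf_std <- sighting_frequency(visits_std)
  eligible_net <- min_days_filter(sf_std$by_fox, min_days)
  events <- build_grouping_events(visits_std)

  networks <- list()
  for (k in seq_len(nrow(surveys))) {
    tid <- surveys$territory[k]; ssn <- surveys$season[k]
    el <- eligible_net$fox[eligible_net$territory == tid &
                             eligible_net$season == ssn]
    ev <- events[events$territory == tid & events$season == ssn, ]
    key <- paste(tid, ssn, sep = ".")
    if (length(el) < 2) {
      networks[[key]] <- list(territory = tid, season = ssn, gbi = NULL,
                              sri = NULL, global = NULL, mb = NULL,
                              skipped = TRUE)
      next
    }
    gbi <- gbi_matrix(ev, el)
    sri <- sri_matrix(gbi)
    mb <- tryCatch(
      manly_bejder_test(gbi, n_perm = n_perm,
                        swaps_per_perm = swaps_per_perm,
                        seed = mix_seed(config$seed, 100L + k)),
      error = function(e) list(statistic_obs = NA_real_, p = NA_real_,
                               nonrandom = FALSE, skipped = TRUE))
    node <- data.frame(fox = colnames(sri$sri),
                       territory = tid, season = ssn,
                       strength = unname(strength(sri)),
                       eigenvector = unname(eigenvector_centrality(sri)),
                       clustering = unname(clustering_onnela(sri)),
                       stringsAsFactors = FALSE)
    res_f <- residency$fox[residency$territory == tid &
                             residency$season == ssn]
    node$resident <- node$fox %in% res_f
    attrs <- scenario$attributes
    sx <- stats::setNames(attrs$sex, attrs$fox)[colnames(sri$sri)]
    st <- stats::setNames(attrs$status, attrs$fox)[colnames(sri$sri)]
    assort <- if (isTRUE(mb$nonrandom)) {
      list(sex = assortativity_discrete(sri, sx),
           status = assortativity_discrete(sri, st))
    } else {
      list(sex = NA_real_, status = NA_real_)
    }
    networks[[key]] <- list(territory = tid, season = ssn, gbi = gbi,
                            sri = sri, global = global_metrics(sri),
                            mb = mb, node_metrics = node,
                            assortativity = assort, skipped = FALSE)
  }

  prov_cov <- provisioning_covariates(scenario$provisioning,
                                      config$survey_length_days)

  bundle <- list(config = config, scenario = scenario, visits = visits,
                 encounters = encounters, sighting_frequency = sf,
                 contacts = contacts, residency = residency,
                 networks = networks, provisioning_covariates = prov_cov,
                 thresholds = list(gap_s = gap_s, min_days = min_days,
                                   residency_days = residency_days,
                                   residency_assoc = residency_assoc,
                                   n_perm = n_perm,
                                   swaps_per_perm = swaps_per_perm))
  bundle$summary <- summarize_bundle(bundle)
  bundle
}

#' Summary tables for a pipeline bundle
#'
#' @param bundle output of [run_pipeline()].
#' @return list of data.frames: `global` (per-network connectivity and
#'   Manly/Bejder flags), `nodes` (per-fox centrality with residency), and
#'   `icc` (between-season repeatability of each centrality measure for
#'   residents across all networks).
#' @export
summarize_bundle <- function(bundle) {
  nets <- bundle$networks
  if (length(nets) == 0) {
    return(list(
      global = data.frame(territory = character(0), season = character(0),
                          n_nodes = integer(0),
                          unweighted_density = numeric(0),
                          weighted_density = numeric(0),
                          transitivity = numeric(0),
                          mb_statistic = numeric(0), mb_p = numeric(0),
                          nonrandom = logical(0), assort_sex = numeric(0),
                          assort_status = numeric(0)),
      nodes = data.frame(fox = character(0), territory = character(0),
                         season = character(0), strength = numeric(0),
                         eigenvector = numeric(0), clustering = numeric(0),
                         resident = logical(0)),
      icc = NULL))
  }
  glob_rows <- lapply(nets, function(nw) {
    if (isTRUE(nw$skipped)) {
      return(data.frame(territory = nw$territory, season = nw$season,
                        n_nodes = 0L, unweighted_density = NA_real_,
                        weighted_density = NA_real_, transitivity = NA_real_,
                        mb_statistic = NA_real_, mb_p = NA_real_,
                        nonrandom = FALSE, assort_sex = NA_real_,
                        assort_status = NA_real_, stringsAsFactors = FALSE))
    }
    g <- nw$global
    data.frame(territory = nw$territory, season = nw$season,
               n_nodes = g$n_nodes,
               unweighted_density = g$unweighted_density,
               weighted_density = g$weighted_density,
               transitivity = g$transitivity,
               mb_statistic = nw$mb$statistic_obs, mb_p = nw$mb$p,
               nonrandom = isTRUE(nw$mb$nonrandom),
               assort_sex = nw$assortativity$sex,
               assort_status = nw$assortativity$status,
               stringsAsFactors = FALSE)
  })
  global <- do.call(rbind, c(glob_rows, list(make.row.names = FALSE)))
  node_rows <- lapply(nets, function(nw) {
    if (isTRUE(nw$skipped)) NULL else nw$node_metrics
  })
  nodes <- do.call(rbind, c(node_rows, list(make.row.names = FALSE)))
  icc <- NULL
  if (!is.null(nodes) && nrow(nodes)) {
    res_nodes <- nodes[nodes$resident, ]
    if (nrow(res_nodes) >= 4 && max(table(res_nodes$fox)) >= 2) {
      icc <- do.call(rbind, lapply(
        c("strength", "eigenvector", "clustering"), function(mcol) {
          r <- suppressWarnings(icc_repeatability(res_nodes, mcol))
          data.frame(metric = mcol, icc = r$icc, class = r$class %||% NA,
                     stringsAsFactors = FALSE)
        }))
    }
  }
  list(global = global, nodes = nodes, icc = icc)
}

#' Write a pipeline bundle to an output directory
#'
#' Persists all stage outputs as delimited text: visits, encounters, contact
#' counts, residency, per-network global and node tables, labelled SRI
#' matrices (CSV) and GraphML exports, plus a JSON manifest with the
#' configuration, seed and applied thresholds.
#'
#' @param bundle output of [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    for (cn in names(df)) {
      if (inherits(df[[cn]], "POSIXct")) df[[cn]] <- format_iso8601(df[[cn]])
    }
    write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(bundle$visits, "visits.csv")
  wr(bundle$encounters, "encounters.csv")
  if (!is.null(bundle$contacts)) wr(bundle$contacts, "contacts.csv")
  wr(bundle$residency, "residency.csv")
  wr(bundle$summary$global, "network_global.csv")
  if (!is.null(bundle$summary$nodes)) wr(bundle$summary$nodes, "network_nodes.csv")
  if (!is.null(bundle$summary$icc)) wr(bundle$summary$icc, "icc.csv")
  net_dir <- file.path(dir, "networks")
  if (!dir.exists(net_dir)) dir.create(net_dir)
  attrs <- bundle$scenario$attributes
  for (key in names(bundle$networks)) {
    nw <- bundle$networks[[key]]
    if (isTRUE(nw$skipped)) next
    m <- nw$sri$sri
    write.csv(as.data.frame(m), file.path(net_dir, paste0(key, "_sri.csv")))
    na <- attrs[match(rownames(m), attrs$fox),
                c("fox", "sex", "status", "age_class")]
    write_graphml(m, file.path(net_dir, paste0(key, ".graphml")),
                  node_attrs = na)
  }
  manifest <- list(config = unclass(bundle$config),
                   thresholds = bundle$thresholds,
                   n_networks = length(bundle$networks),
                   created = format_iso8601(Sys.time()))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
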