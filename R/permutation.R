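# Restricted data-stream permutations of the group-by-individual matrix,
# the Manly/Bejder non-randomness test, and permutation P-values.

# strata for restricted swaps: groups may only exchange members within the
# same territory and survey day (seasons are distinct calendar days)
gbi_strata <- function(gbi) {
  key <- paste(gbi$meta$territory, gbi$meta$season, gbi$meta$day)
  rows <- split(seq_len(nrow(gbi$G)), key)
  rows <- rows[lengths(rows) >= 2]
  w <- vapply(rows, function(r) length(r) * (length(r) - 1) / 2, numeric(1))
  list(rows = rows, w = w)
}

# Perform n trial swaps in place on G; returns list(G, n_skipped).
#
# Proposal: a group pair within a random territory-day stratum, then one
# random MEMBER of each group; the move is accepted only if the two form a
# checkerboard (each absent from the other group), otherwise the state is
# kept unchanged and the trial still counts as a chain step.  Group sizes
# are swap-invariant, so the proposal is symmetric and the stationary
# distribution is uniform over the margin-preserving class.  Two designs
# that look natural are biased and deliberately avoided: sampling the
# exchanged pair from the checkerboard candidates (over-weights states with
# few candidates), and resampling until a swap succeeds (the jump chain
# over-weights states by their acceptance rate).
swap_engine <- function(G, strata, n_swaps, max_tries = NULL) {
  n_skipped <- 0L
  if (length(strata$rows) == 0) {
    return(list(G = G, n_skipped = n_swaps))
  }
  ns <- length(strata$rows)
  # pre-draw all randomness; the loop body is pure index arithmetic
  st_idx <- if (ns == 1) rep(1L, n_swaps) else
    sample.int(ns, n_swaps, replace = TRUE, prob = strata$w)
  u <- matrix(runif(4 * n_swaps), n_swaps, 4)
  for (s in seq_len(n_swaps)) {
    rr <- strata$rows[[st_idx[s]]]
    nr <- length(rr)
    a <- 1L + as.integer(u[s, 1] * nr)
    b <- 1L + as.integer(u[s, 2] * (nr - 1L))
    if (b >= a) b <- b + 1L
    r1 <- rr[a]; r2 <- rr[b]
    m1 <- which(G[r1, ] == 1L)
    m2 <- which(G[r2, ] == 1L)
    if (length(m1) && length(m2)) {
      i <- m1[1L + as.integer(u[s, 3] * length(m1))]
      j <- m2[1L + as.integer(u[s, 4] * length(m2))]
      if (i != j && G[r2, i] == 0L && G[r1, j] == 0L) {
        G[r1, i] <- 0L; G[r2, i] <- 1L
        G[r2, j] <- 0L; G[r1, j] <- 1L
        next
      }
    }
    n_skipped <- n_skipped + 1L
  }
  list(G = G, n_skipped = n_skipped)
}

#' Restricted data-stream swap
#'
#' Performs checkerboard trial swaps between groups of the same territory
#' and survey day: a random member of each of two groups is exchanged when
#' the two form a checkerboard (i in group 1 only, j in group 2 only).
#' Every swap preserves all group sizes (row sums) and every individual's
#' daily sighting pattern (column sums within each territory-day),
#' controlling for spatiotemporal variation in sighting histories.  A trial
#' whose sampled pair is not a checkerboard leaves the state unchanged but
#' still counts as a chain step (required for a uniform stationary
#' distribution over the margin-preserving class); rejected trials are
#' counted in the `n_skipped` attribute.
#'
#' @param gbi a `fox_gbi`.
#' @param n_swaps number of trial swaps to perform.
#' @return the permuted `fox_gbi`, with attribute `n_skipped`.
#' @export
restricted_swap <- function(gbi, n_swaps = 1L) {
  strata <- gbi_strata(gbi)
  if (length(strata$rows) == 0 && n_swaps > 0) {
    warning("no valid swap exists anywhere; permutation degenerates to identity")
  }
  res <- swap_engine(gbi$G, strata, n_swaps)
  out <- new_gbi(res$G, gbi$meta)
  attr(out, "n_skipped") <- res$n_skipped
  out
}

#' Data-stream permutation chain
#'
#' Cumulative sequential chain: starting from the observed GBI, perform
#' `swaps_per_perm` restricted swaps, record the metric, and repeat
#' `n_perm` times.  The sampled networks form a Markov chain whose
#' stationary distribution is the restricted-swap null; the observed metric
#' is recorded separately.  Metric failures on a null sample are recorded as
#' NA and counted.
#'
#' @param gbi a `fox_gbi`.
#' @param metric_fn function mapping a `fox_gbi` to a numeric scalar or
#'   fixed-length named vector (e.g. a model coefficient via rebuilt
#'   networks).
#' @param n_perm number of permutations (default 2000).
#' @param swaps_per_perm swaps between recorded samples (default 10).
#' @param seed integer seed for the chain.
#' @param restart if TRUE, each permutation restarts from the observed data
#'   (independent-restart mode for comparison); default FALSE (cumulative).
#' @param burn_in trial swaps performed before the first recorded sample.
#'   The paper-style cumulative chain (burn_in = 0) starts recording right
#'   at the observed data; on large GBIs a burn-in proportional to the
#'   number of groups brings the chain near its stationary distribution
#'   before sampling, which costs swaps (cheap) rather than metric
#'   evaluations (expensive).
#' @return object of class `fox_null`: list with `observed`, `values`
#'   (n_perm x n_stat matrix), `n_failed`, `n_skipped`, and the config.
#' @export
permutation_chain <- function(gbi, metric_fn, n_perm = 2000L,
                              swaps_per_perm = 10L, seed = 1L,
                              restart = FALSE, burn_in = 0L) {
  stopifnot(n_perm >= 1L, swaps_per_perm >= 1L)
  observed <- metric_fn(gbi)
  m <- length(observed)
  values <- matrix(NA_real_, n_perm, m)
  if (!is.null(names(observed))) colnames(values) <- names(observed)
  strata <- gbi_strata(gbi)
  with_seed(seed, {
    G <- gbi$G
    n_skipped <- 0L
    n_failed <- 0L
    work <- gbi
    if (burn_in > 0L) {
      res <- swap_engine(G, strata, burn_in)
      G <- res$G
      n_skipped <- n_skipped + res$n_skipped
    }
    for (k in seq_len(n_perm)) {
      if (restart) G <- gbi$G
      res <- swap_engine(G, strata, swaps_per_perm)
      G <- res$G
      n_skipped <- n_skipped + res$n_skipped
      work$G <- G
      val <- tryCatch(metric_fn(work), error = function(e) NULL)
      if (is.null(val) || length(val) != m || anyNA(val)) {
        n_failed <- n_failed + 1L
        if (!is.null(val) && length(val) == m) values[k, ] <- val
      } else {
        values[k, ] <- val
      }
    }
    structure(list(observed = observed, values = values,
                   n_perm = n_perm, swaps_per_perm = swaps_per_perm,
                   seed = seed, n_failed = n_failed, n_skipped = n_skipped),
              class = "fox_null")
  })
}

#' @export
print.fox_null <- function(x, ...) {
  cat(sprintf("fox_null: %d permutations x %d swaps (%d failed, %d skipped)\n",
              x$n_perm, x$swaps_per_perm, x$n_failed, x$n_skipped))
  invisible(x)
}

#' Permutation P-value for an observed statistic
#'
#' `P_rand` is the proportion of null statistics strictly greater than the
#' observed one (ties count as not greater).  Two-tailed significance at the
#' 0.05 level requires `P_rand` outside \[0.025, 0.975\]; the one-tailed
#' value is `1 - P_rand` for deficits (observed below the null mass).
#'
#' @param null a `fox_null` (scalar statistic), or numeric vector of null
#'   values.
#' @param observed observed statistic (taken from the `fox_null` if absent).
#' @return list: p_rand, significant (logical), n_used (non-missing null
#'   samples), observed.
#' @export
p_rand <- function(null, observed = NULL) {
  if (inherits(null, "fox_null")) {
    if (is.null(observed)) observed <- unname(null$observed[1])
    values <- null$values[, 1]
  } else {
    values <- as.numeric(null)
  }
  stopifnot(!is.null(observed))
  values <- values[!is.na(values)]
  p <- mean(values > observed)
  list(p_rand = p, significant = (p < 0.025 || p > 0.975),
       n_used = length(values), observed = observed)
}

# SD (or CV) of the off-diagonal simple ratio indices of a GBI
sri_dispersion <- function(gbi, statistic = "sd") {
  s <- sri_matrix(gbi)
  v <- s$sri[upper.tri(s$sri)]
  if (statistic == "cv") {
    if (mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  } else {
    sd(v)
  }
}

# Factory: fast SRI-dispersion metric for permutation chains.  Daily
# presence (hence every dyad's SRI denominator) is swap-invariant, so it is
# cached; only the days-together tallies are recomputed per state.
make_sri_dispersion_metric <- function(gbi, statistic = "sd") {
  rows_by_day <- split(seq_len(nrow(gbi$G)), gbi$meta$day)
  n <- ncol(gbi$G)
  seen <- vapply(rows_by_day, function(r)
    colSums(gbi$G[r, , drop = FALSE]) > 0, logical(n))
  seen_days <- rowSums(seen)                     # per fox
  both <- tcrossprod(seen * 1)
  denom <- outer(seen_days, rep(1, n)) + outer(rep(1, n), seen_days) - both
  ut <- upper.tri(denom)
  d_ut <- denom[ut]
  function(g) {
    x <- matrix(0, n, n)
    for (r in rows_by_day) {
      x <- x + (crossprod(g$G[r, , drop = FALSE]) > 0)
    }
    v <- ifelse(d_ut > 0, x[ut] / d_ut, 0)
    if (statistic == "cv") {
      if (mean(v) == 0) return(NA_real_)
      sd(v) / mean(v)
    } else {
      sd(v)
    }
  }
}

#' Manly/Bejder test for non-random association
#'
#' Tests whether foxes have preferred/avoided companions by comparing the
#' dispersion (SD, optionally CV) of the observed simple ratio indices to
#' the restricted-swap null: preferred and avoided companions inflate the
#' SD, so the test is one-tailed with `P = Pr(null >= observed)`.  Networks
#' with an all-zero association matrix are skipped and flagged random.
#'
#' @param gbi `fox_gbi` of one network (a territory-season).
#' @param n_perm permutations (default 2000).
#' @param swaps_per_perm swaps per permutation (default 10).
#' @param statistic `"sd"` (default, SOCPROG-style) or `"cv"`.
#' @param seed chain seed.
#' @return list: statistic_obs, p, nonrandom (P < 0.05), skipped, null (the
#'   `fox_null`, NULL when skipped).
#' @export
manly_bejder_test <- function(gbi, n_perm = 2000L, swaps_per_perm = 10L,
                              statistic = c("sd", "cv"), seed = 1L) {
  statistic <- match.arg(statistic)
  if (ncol(gbi$G) < 2 || length(unique(gbi$meta$day)) < 2) {
    stop("Manly/Bejder test needs >= 2 individuals and >= 2 days")
  }
  s <- sri_matrix(gbi)
  if (all(s$sri == 0)) {
    return(list(statistic_obs = 0, p = NA_real_, nonrandom = FALSE,
                skipped = TRUE, null = NULL))
  }
  null <- permutation_chain(gbi, make_sri_dispersion_metric(gbi, statistic),
                            n_perm = n_perm, swaps_per_perm = swaps_per_perm,
                            seed = seed)
  vals <- null$values[, 1]
  vals <- vals[!is.na(vals)]
  p <- mean(vals >= null$observed)
  list(statistic_obs = unname(null$observed), p = p, nonrandom = p < 0.05,
       skipped = FALSE, null = null)
}

#' Post hoc permutation P-values with Holm adjustment
#'
#' For each contrast, the two-tailed `P_rand` is computed against its null
#' distribution, converted to one-tailed (`min(P, 1 - P)`), and
#' Holm-adjusted across the contrast family.  Null samples where a contrast
#' was inestimable (NA) are dropped for that contrast and counted.
#'
#' @param observed named numeric vector of observed contrast estimates.
#' @param null_values matrix of null contrast estimates (rows =
#'   permutations, columns matching `observed`).
#' @return data.frame: contrast, observed, p_rand (two-tailed), p_one,
#'   p_holm, n_dropped.
#' @export
posthoc_prand <- function(observed, null_values) {
  null_values <- as.matrix(null_values)
  stopifnot(ncol(null_values) == length(observed))
  p2 <- numeric(length(observed))
  dropped <- integer(length(observed))
  for (j in seq_along(observed)) {
    v <- null_values[, j]
    dropped[j] <- sum(is.na(v))
    v <- v[!is.na(v)]
    p2[j] <- mean(v > observed[j])
  }
  p1 <- pmin(p2, 1 - p2)
  data.frame(contrast = names(observed) %||% seq_along(observed),
             observed = unname(observed),
             p_rand = p2, p_one = p1,
             p_holm = p.adjust(p1, method = "holm"),
             n_dropped = dropped,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Persist a null distribution as delimited text
#'
#' One column per statistic, one row per permutation, with the seed and
#' chain configuration embedded as header comments so P-values are exactly
#' reproducible.
#'
#' @param null a `fox_null`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_perm=%d swaps_per_perm=%d seed=%d n_failed=%d",
                     null$n_perm, null$swaps_per_perm, null$seed,
                     null$n_failed), con)
  writeLines(paste0("# observed: ",
                    paste(sprintf("%.10g", null$observed), collapse = ",")),
             con)
  df <- as.data.frame(null$values)
  if (is.null(colnames(null$values))) {
    names(df) <- paste0("stat", seq_len(ncol(df)))
  }
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}
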