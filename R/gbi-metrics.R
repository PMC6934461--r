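# GBI-based contact counting and fast model-coefficient metrics for use
# inside permutation chains.  Contact counts have two countings: the
# encounter-based one in daily_contact_counts() (each overlapping visit pair
# is one association) and the group-based one here (each grouping-event
# co-membership is one association).  Only the group-based counting can be
# recomputed from a permuted GBI, so permutation inference uses it for
# observed and null networks alike.

#' Contact counts recomputed from a GBI
#'
#' For every fox, patch and survey day where the fox appears in at least one
#' group, the number of associations is the summed co-membership
#' `sum(group size - 1)` over its groups at that patch-day.  This is the
#' counting used inside permutation chains (it is a deterministic function
#' of the GBI, so observed and permuted networks are measured identically).
#'
#' @param gbi a `fox_gbi`.
#' @return data.frame: fox, territory, season, patch, survey_day,
#'   n_contacts.
#' @export
gbi_contact_counts <- function(gbi) {
  cc <- contact_frame(gbi)
  data.frame(fox = cc$fox, territory = cc$territory, season = cc$season,
             patch = cc$patch, survey_day = cc$day, n_contacts = cc$y,
             stringsAsFactors = FALSE)
}

# fast internal: vectors for one GBI state (no data.frame overhead beyond
# the final assembly); also returns per-observation days-seen at the patch
contact_frame <- function(gbi) {
  G <- gbi$G
  meta <- gbi$meta
  key <- paste(meta$territory, meta$season, meta$patch, meta$day)
  rs <- rowSums(G)
  contrib <- G * (rs - 1)
  agg <- rowsum(contrib, key)          # patch-day x fox contact totals
  presn <- rowsum(G, key)              # patch-day x fox membership counts
  lev <- rownames(agg)
  first <- match(lev, key)
  pd_terr <- meta$territory[first]
  pd_season <- meta$season[first]
  pd_patch <- meta$patch[first]
  pd_day <- meta$day[first]
  pres <- presn > 0
  # days seen per fox x patch x season (sighting frequency covariate)
  ps <- paste(pd_terr, pd_season, pd_patch)
  sf <- rowsum(pres * 1L, ps)          # patch-season x fox days-seen
  idx <- which(pres)
  nr <- nrow(pres)
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  list(fox = colnames(G)[col],
       territory = pd_terr[row],
       season = pd_season[row],
       patch = pd_patch[row],
       day = pd_day[row],
       y = agg[idx],
       sighting_freq = sf[cbind(match(ps[row], rownames(sf)), col)])
}

#' Metric factory: contact-model coefficient from a GBI
#'
#' Builds a function mapping a `fox_gbi` to one coefficient of the daily
#' contact-rate Poisson regression
#' `n_contacts ~ sighting_freq + sex * season`, for use with
#' [permutation_chain()].  The model is refit on every (observed or
#' permuted) GBI with the group-based contact counting of
#' [gbi_contact_counts()].
#'
#' With `aggregate = "fox_day"` (the default) contacts are totalled per fox
#' and survey day across patches.  Restricted swaps preserve every fox's
#' daily group membership counts, so the observation rows, the
#' sighting-frequency covariate (days seen per survey) and the whole design
#' matrix are swap-invariant and cached in the closure; only the response is
#' recomputed, and refits are warm-started from the observed coefficients.
#' `"fox_season"` totals contacts per fox-survey and adds an offset of
#' log(total group memberships): because the null preserves memberships
#' exactly, this measures social selectivity per membership - the only
#' channel a data-stream permutation can test - and maximises power for
#' rate-type effects.  `"fox_patch_day"` refits the patch-level model from
#' scratch instead.
#'
#' @param attributes attribute table with fox, sex, status.
#' @param coefficient name of the coefficient to extract (a column of the
#'   design, e.g. `"sexM"` or `"sexM:seasonwinter"`).
#' @param seasons season factor levels, first = reference.
#' @param include_status add `status` as a main effect.
#' @param aggregate observation grain (see above).
#' @return function(gbi) -> named numeric scalar.
#' @export
make_contact_metric <- function(attributes, coefficient,
                                seasons = c("spring", "summer", "autumn",
                                            "winter"),
                                include_status = FALSE,
                                aggregate = c("fox_day", "fox_season",
                                              "fox_patch_day")) {
  aggregate <- match.arg(aggregate)
  sex_of <- stats::setNames(attributes$sex, attributes$fox)
  status_of <- stats::setNames(attributes$status, attributes$fox)
  cache <- new.env(parent = emptyenv())

  build_X <- function(fox, season, sighting) {
    sexM <- as.numeric(sex_of[fox] == "M")
    X <- cbind(`(Intercept)` = 1, sighting_freq = sighting, sexM = sexM)
    for (s in seasons[-1]) {
      X <- cbind(X, as.numeric(season == s))
      colnames(X)[ncol(X)] <- paste0("season", s)
    }
    for (s in seasons[-1]) {
      X <- cbind(X, sexM * as.numeric(season == s))
      colnames(X)[ncol(X)] <- paste0("sexM:season", s)
    }
    if (include_status) {
      X <- cbind(X, statusdominant = as.numeric(status_of[fox] == "dominant"))
    }
    keep <- colnames(X) == "(Intercept)" | apply(X != 0, 2, any)
    X <- X[, keep, drop = FALSE]
    if (!coefficient %in% colnames(X)) {
      stop("coefficient ", coefficient, " not estimable in this design")
    }
    X
  }

  fit_coef <- function(X, y, start = NULL) {
    fit <- suppressWarnings(glm.fit(X, y, family = poisson(), start = start))
    list(coef = stats::setNames(fit$coefficients[coefficient], coefficient),
         all = fit$coefficients)
  }

  if (aggregate == "fox_patch_day") {
    return(function(gbi) {
      cc <- contact_frame(gbi)
      X <- build_X(cc$fox, cc$season, cc$sighting_freq)
      fit_coef(X, cc$y)$coef
    })
  }

  if (aggregate == "fox_season") {
    return(function(gbi) {
      G <- gbi$G
      if (is.null(cache$w)) {
        meta <- gbi$meta
        key <- paste(meta$territory, meta$season)
        lev <- sort(unique(key))
        fs_key <- match(key, lev)
        memb <- rowsum(G, fs_key)              # survey x fox memberships
        cache$fs_idx <- which(memb > 0)
        nr <- nrow(memb)
        row <- (cache$fs_idx - 1L) %% nr + 1L  # survey
        col <- (cache$fs_idx - 1L) %/% nr + 1L # fox
        first <- match(lev, key)
        fox <- colnames(G)[col]
        season <- meta$season[first][row]
        X <- build_X(fox, season, sighting = NULL)
        cache$X <- X[, colnames(X) != "sighting_freq", drop = FALSE]
        cache$offset <- log(memb[cache$fs_idx])
        # group sizes are swap-invariant: cache them with the survey index
        cache$w <- rowSums(G) - 1
        cache$fs_key <- fs_key
        cache$n_fs <- length(lev)
        cache$start <- NULL
        y_mat <- matrix(0, cache$n_fs, ncol(G))
        for (r in split(seq_len(nrow(G)), fs_key)) {
          y_mat[fs_key[r[1]], ] <- crossprod(cache$w[r], G[r, , drop = FALSE])
        }
        cache$y_mat <- y_mat
        cache$G_prev <- G
      } else if (!identical(G, cache$G_prev)) {
        # successive chain states differ in a handful of cells: update the
        # fox-survey contact totals incrementally
        d <- which(G != cache$G_prev)
        if (length(d)) {
          r <- (d - 1L) %% nrow(G) + 1L
          f <- (d - 1L) %/% nrow(G) + 1L
          delta <- (G[d] - cache$G_prev[d]) * cache$w[r]
          cell <- (f - 1L) * cache$n_fs + cache$fs_key[r]
          agg <- rowsum(delta, cell)
          cells <- as.integer(rownames(agg))
          cache$y_mat[cells] <- cache$y_mat[cells] + agg[, 1]
          cache$G_prev <- G
        }
      }
      y <- cache$y_mat[cache$fs_idx]
      fit <- suppressWarnings(glm.fit(cache$X, y, family = poisson(),
                                      offset = cache$offset,
                                      start = cache$start))
      if (is.null(cache$start)) cache$start <- unname(fit$coefficients)
      stats::setNames(fit$coefficients[coefficient], coefficient)
    })
  }

  function(gbi) {
    G <- gbi$G
    if (is.null(cache$day_key)) {
      # built once: restricted swaps leave all of this invariant
      meta <- gbi$meta
      key <- paste(meta$territory, meta$season, meta$day)
      lev <- sort(unique(key))
      cache$day_key <- match(key, lev)
      first <- match(lev, key)
      # fox-day presence (daily membership counts are swap-invariant)
      presn <- rowsum(G, cache$day_key)
      pres <- presn > 0
      cache$pres_idx <- which(pres)
      nr <- nrow(pres)
      row <- (cache$pres_idx - 1L) %% nr + 1L
      col <- (cache$pres_idx - 1L) %/% nr + 1L
      fox <- colnames(G)[col]
      season <- meta$season[first][row]
      ts_key <- paste(meta$territory, meta$season)[first]
      sf <- rowsum(pres * 1L, ts_key)   # days seen per fox-survey
      sighting <- sf[cbind(match(ts_key[row], rownames(sf)), col)]
      cache$X <- build_X(fox, season, sighting)
      cache$start <- NULL
    }
    rs <- rowSums(G)
    y <- rowsum(G * (rs - 1), cache$day_key)[cache$pres_idx]
    res <- fit_coef(cache$X, y, start = cache$start)
    if (is.null(cache$start)) cache$start <- unname(res$all)
    res$coef
  }
}

#' Metric factory: strength-model coefficient from a GBI
#'
#' Builds a function mapping a `fox_gbi` to one coefficient of the network
#' strength regression `strength ~ sex * season + territory`, for use with
#' [permutation_chain()].  Per territory-season network, the SRI matrix is
#' recomputed from the (permuted) GBI and each fox's strength is its SRI row
#' sum.  The fox-network observation set, every dyad's SRI denominator and
#' the whole design matrix are swap-invariant and cached (including the QR
#' decomposition of the design), so each chain step costs one set of
#' days-together tallies and a triangular solve.
#'
#' @param attributes attribute table with fox, sex, status.
#' @param coefficient design column to extract (e.g. `"sexM:seasonwinter"`).
#' @param seasons season factor levels, first = reference.
#' @return function(gbi) -> named numeric scalar.
#' @export
make_strength_metric <- function(attributes, coefficient,
                                 seasons = c("spring", "summer", "autumn",
                                             "winter")) {
  sex_of <- stats::setNames(attributes$sex, attributes$fox)
  cache <- new.env(parent = emptyenv())
  function(gbi) {
    G <- gbi$G
    if (is.null(cache$nets)) {
      # built once: restricted swaps leave all of this invariant
      meta <- gbi$meta
      ts_key <- paste(meta$territory, meta$season)
      nets <- list()
      obs_fox <- character(0); obs_season <- character(0)
      obs_terr <- character(0)
      for (k in unique(ts_key)) {
        rows <- which(ts_key == k)
        sub <- G[rows, , drop = FALSE]
        foxes <- which(colSums(sub) > 0)
        if (length(foxes) < 2) next
        day <- meta$day[rows]
        rows_by_day <- split(seq_along(rows), day)
        n <- length(foxes)
        seen <- vapply(rows_by_day, function(r)
          colSums(sub[r, foxes, drop = FALSE]) > 0, logical(n))
        seen_days <- rowSums(seen)
        both <- tcrossprod(seen * 1)
        denom <- outer(seen_days, rep(1, n)) +
          outer(rep(1, n), seen_days) - both
        diag(denom) <- 1
        nets[[k]] <- list(rows = rows, foxes = foxes,
                          rows_by_day = lapply(rows_by_day,
                                               function(r) rows[r]),
                          denom = denom)
        obs_fox <- c(obs_fox, colnames(G)[foxes])
        obs_season <- c(obs_season, rep(meta$season[rows[1]], n))
        obs_terr <- c(obs_terr, rep(meta$territory[rows[1]], n))
      }
      cache$nets <- nets
      sexM <- as.numeric(sex_of[obs_fox] == "M")
      X <- cbind(`(Intercept)` = 1, sexM = sexM)
      for (s in seasons[-1]) {
        X <- cbind(X, as.numeric(obs_season == s))
        colnames(X)[ncol(X)] <- paste0("season", s)
      }
      for (s in seasons[-1]) {
        X <- cbind(X, sexM * as.numeric(obs_season == s))
        colnames(X)[ncol(X)] <- paste0("sexM:season", s)
      }
      for (t in unique(obs_terr)[-1]) {
        X <- cbind(X, as.numeric(obs_terr == t))
        colnames(X)[ncol(X)] <- paste0("territory", t)
      }
      keep <- colnames(X) == "(Intercept)" | apply(X != 0, 2, any)
      X <- X[, keep, drop = FALSE]
      if (!coefficient %in% colnames(X)) {
        stop("coefficient ", coefficient, " not estimable in this design")
      }
      cache$qr <- qr(X)
      cache$coef_names <- colnames(X)
    }
    y <- numeric(0)
    for (net in cache$nets) {
      n <- length(net$foxes)
      x <- matrix(0, n, n)
      for (r in net$rows_by_day) {
        x <- x + (crossprod(G[r, net$foxes, drop = FALSE]) > 0)
      }
      diag(x) <- 0
      y <- c(y, rowSums(x / net$denom))
    }
    beta <- qr.coef(cache$qr, y)
    names(beta) <- cache$coef_names
    stats::setNames(beta[coefficient], coefficient)
  }
}
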