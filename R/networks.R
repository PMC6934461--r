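# Group-by-individual matrices, simple-ratio-index association matrices,
# and global/node-level weighted network metrics.

#' Build a group-by-individual (GBI) matrix from grouping events
#'
#' One row per grouping event (one-day sampling periods: the survey day is
#' the sampling unit), one column per fox.  Row metadata (territory, season,
#' patch, day) is kept for restricted permutations.  Foxes outside `foxes`
#' are dropped from the groups; rows left empty are removed.
#'
#' @param events output of [build_grouping_events()].
#' @param foxes fox ids to include as columns (the network-eligible set).
#' @return object of class `fox_gbi`: list with integer matrix `G`
#'   (groups x foxes) and data.frame `meta` (territory, season, patch, day).
#' @export
gbi_matrix <- function(events, foxes) {
  foxes <- sort(unique(foxes))
  if (nrow(events) == 0 || length(foxes) == 0) {
    G <- matrix(0L, 0, length(foxes), dimnames = list(NULL, foxes))
    meta <- data.frame(territory = character(0), season = character(0),
                       patch = character(0), day = integer(0))
    return(new_gbi(G, meta))
  }
  member_list <- strsplit(events$members, ",", fixed = TRUE)
  member_list <- lapply(member_list, intersect, foxes)
  keep <- lengths(member_list) > 0
  events <- events[keep, , drop = FALSE]
  member_list <- member_list[keep]
  G <- matrix(0L, nrow(events), length(foxes),
              dimnames = list(NULL, foxes))
  for (r in seq_along(member_list)) {
    G[r, member_list[[r]]] <- 1L
  }
  meta <- data.frame(territory = events$territory, season = events$season,
                     patch = events$patch, day = events$survey_day,
                     stringsAsFactors = FALSE)
  new_gbi(G, meta)
}

new_gbi <- function(G, meta) {
  stopifnot(nrow(G) == nrow(meta))
  structure(list(G = G, meta = meta), class = "fox_gbi")
}

#' @export
print.fox_gbi <- function(x, ...) {
  cat(sprintf("fox_gbi: %d groups x %d individuals (%d territory-days)\n",
              nrow(x$G), ncol(x$G),
              length(unique(paste(x$meta$territory, x$meta$season,
                                  x$meta$day)))))
  invisible(x)
}

#' Simple ratio index association matrix
#'
#' With one-day sampling periods, a dyad is "together" on a day if the two
#' foxes shared at least one grouping event that day (at any patch), and
#' "seen" if they appeared in any group that day.  The simple ratio index is
#' `x / (x + yAB + yA + yB)` with x = days together, yAB = days both seen
#' but never together, yA/yB = days only one was seen.  Dyads with an empty
#' denominator get index 0.
#'
#' @param gbi a `fox_gbi` for a single network (one territory-season).
#' @return object of class `fox_sri`: list with `sri` (symmetric matrix,
#'   zero diagonal), count matrices `x`, `yab`, `ya_yb` and `denom`,
#'   per-fox `days_seen`, and `n_days` sampling periods.
#' @export
sri_matrix <- function(gbi) {
  G <- gbi$G
  foxes <- colnames(G)
  n <- length(foxes)
  days <- unique(gbi$meta$day)
  x <- both <- seen_mat <- matrix(0, n, n, dimnames = list(foxes, foxes))
  seen_days <- stats::setNames(numeric(n), foxes)
  for (d in days) {
    Gd <- G[gbi$meta$day == d, , drop = FALSE]
    seen <- as.numeric(colSums(Gd) > 0)
    tog <- (crossprod(Gd) > 0) * 1
    x <- x + tog
    both <- both + outer(seen, seen)
    seen_days <- seen_days + seen
  }
  diag(x) <- 0
  either <- outer(seen_days, rep(1, n)) + outer(rep(1, n), seen_days) - both
  yab <- both - x
  ya_yb <- either - both
  denom <- x + yab + ya_yb
  sri <- ifelse(denom > 0, x / denom, 0)
  diag(sri) <- 0
  dn <- list(foxes, foxes)
  dimnames(sri) <- dimnames(x) <- dimnames(yab) <- dn
  dimnames(ya_yb) <- dimnames(denom) <- dn
  structure(list(sri = sri, x = x, yab = yab, ya_yb = ya_yb, denom = denom,
                 days_seen = seen_days, n_days = length(days)),
            class = "fox_sri")
}

#' @export
print.fox_sri <- function(x, ...) {
  cat(sprintf("fox_sri: %d individuals over %d sampling days; mean SRI %.3f\n",
              ncol(x$sri), x$n_days,
              mean(x$sri[upper.tri(x$sri)])))
  invisible(x)
}

as_weight_matrix <- function(m) {
  if (inherits(m, "fox_sri")) m$sri else as.matrix(m)
}

#' Global network connectivity metrics
#'
#' Unweighted density is the proportion of possible edges present; weighted
#' density is the sum of edge weights over the number of possible edges
#' (equivalently the mean association index); transitivity is the
#' probability that two associates of a node are themselves connected,
#' computed on the binarised (weight > 0) graph.
#'
#' @param m a `fox_sri` or symmetric weight matrix.
#' @return list: n_nodes, unweighted_density, weighted_density, transitivity
#'   (NA when undefined: fewer than 2 nodes, or no connected triples).
#' @export
global_metrics <- function(m) {
  W <- as_weight_matrix(m)
  n <- nrow(W)
  if (n < 2) {
    return(list(n_nodes = n, unweighted_density = NA_real_,
                weighted_density = NA_real_, transitivity = NA_real_))
  }
  up <- upper.tri(W)
  pairs <- n * (n - 1) / 2
  A <- (W > 0) * 1
  diag(A) <- 0
  A2 <- A %*% A
  triples <- sum(A2) - sum(diag(A2))
  closed <- sum(diag(A2 %*% A))
  list(n_nodes = n,
       unweighted_density = sum(W[up] > 0) / pairs,
       weighted_density = sum(W[up]) / pairs,
       transitivity = if (triples > 0) closed / triples else NA_real_)
}

#' Node strength (weighted degree)
#'
#' Sum of edge weights between a focal node and its immediate neighbours.
#' Foxes only ever seen alone have strength zero.
#'
#' @param m a `fox_sri` or symmetric weight matrix.
#' @return named numeric vector of strengths.
#' @export
strength <- function(m) {
  W <- as_weight_matrix(m)
  diag(W) <- 0
  rowSums(W)
}

#' Transform strength for the lognormal model scale
#'
#' Foxes seen only alone have strength 0, so values are shifted by 1 and
#' log10-transformed (used for the before/after-midnight strength model; the
#' whole-day model uses raw strength).
#'
#' @param values nonnegative numeric vector.
#' @return log10(values + 1).
#' @export
strength_transform <- function(values) {
  if (any(values < 0)) stop("strength values must be nonnegative")
  log10(values + 1)
}

#' Eigenvector centrality of a weighted network
#'
#' Leading-eigenvector scores of the SRI matrix (absolute values), scaled so
#' the maximum entry is 1.  In disconnected networks scores concentrate on
#' the dominant component; other components get (numerically) zero.
#'
#' @param m a `fox_sri` or symmetric weight matrix.
#' @param rescale `"max"` (maximum entry 1, default) or `"unit"` (Euclidean
#'   norm 1).
#' @return named numeric vector of centralities (all zero for an empty
#'   network).
#' @export
eigenvector_centrality <- function(m, rescale = c("max", "unit")) {
  rescale <- match.arg(rescale)
  W <- as_weight_matrix(m)
  diag(W) <- 0
  if (all(W == 0)) {
    return(stats::setNames(numeric(nrow(W)), rownames(W)))
  }
  v <- abs(eigen(W, symmetric = TRUE)$vectors[, 1])
  v <- if (rescale == "max") v / max(v) else v / sqrt(sum(v^2))
  stats::setNames(v, rownames(W))
}

#' Onnela weighted clustering coefficient
#'
#' Geometric-mean triangle intensity around each node:
#' `C_i = (k_i (k_i - 1))^-1 * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)` with
#' weights normalised by the network maximum (`w' = w / max(w)`) and k_i the
#' binary degree.  Nodes with degree < 2 are undefined (NA) and excluded
#' from position models.
#'
#' @param m a `fox_sri` or symmetric weight matrix.
#' @return named numeric vector of clustering coefficients.
#' @export
clustering_onnela <- function(m) {
  W <- as_weight_matrix(m)
  diag(W) <- 0
  n <- nrow(W)
  k <- rowSums(W > 0)
  out <- stats::setNames(rep(NA_real_, n), rownames(W))
  if (max(W) == 0) return(out)
  Wh <- (W / max(W))^(1 / 3)
  num <- diag(Wh %*% Wh %*% Wh)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Discrete weighted assortativity
#'
#' Newman's assortativity coefficient for a categorical node attribute on a
#' weighted graph: with the edge-weight mixing matrix `e` (normalised to sum
#' 1 over ordered pairs), `r = (sum_i e_ii - sum_i a_i b_i) /
#' (1 - sum_i a_i b_i)` where a, b are the marginals.  Ranges -1..1;
#' positive values mean nodes associate with their own category.  Undefined
#' (NA) for single-category networks or empty graphs.
#'
#' @param m a `fox_sri` or symmetric weight matrix.
#' @param attribute named character/factor vector of node categories (names
#'   matching the matrix dimnames, or unnamed in matrix order).
#' @param weighted use edge weights (default) or binary edges.
#' @return assortativity coefficient (scalar).
#' @export
assortativity_discrete <- function(m, attribute, weighted = TRUE) {
  W <- as_weight_matrix(m)
  if (!weighted) W <- (W > 0) * 1
  diag(W) <- 0
  ids <- rownames(W)
  a <- if (!is.null(names(attribute)) && !is.null(ids)) {
    attribute[ids]
  } else {
    attribute
  }
  a <- as.character(a)
  stopifnot(length(a) == nrow(W), !anyNA(a))
  cats <- unique(a)
  if (length(cats) < 2 || sum(W) == 0) return(NA_real_)
  M <- outer(a, cats, "==") * 1  # node x category indicator
  E <- t(M) %*% W %*% M
  E <- E / sum(E)
  ab <- rowSums(E) * colSums(E)
  denom <- 1 - sum(ab)
  if (denom == 0) return(NA_real_)
  (sum(diag(E)) - sum(ab)) / denom
}

#' Strength recomputed for a clock period (before/after midnight)
#'
#' Householders provision in the evening and food is gone by midnight, so
#' strength is compared between the before-midnight (food) and
#' after-midnight (no food) halves of the survey day.  Grouping events are
#' assigned to the period containing their span start (clock times in
#' \[12:00, 24:00) are "before"), the SRI matrix is rebuilt from the
#' restricted co-occurrence, and strengths are its row sums.
#'
#' @param events grouping events for one territory-season
#'   ([build_grouping_events()]).
#' @param foxes network-eligible fox ids.
#' @param period `"before"` or `"after"` midnight.
#' @return named numeric vector of strengths.
#' @export
strength_by_period <- function(events, foxes, period = c("before", "after")) {
  period <- match.arg(period)
  secs <- as.numeric(events$span_start) %% 86400
  before <- secs >= 12 * 3600
  sub <- events[if (period == "before") before else !before, , drop = FALSE]
  strength(sri_matrix(gbi_matrix(sub, foxes)))
}
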