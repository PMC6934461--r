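# Independent brute-force oracles used across the suite.  Each is written as
# the most literal possible restatement of the definition, independent of
# the package implementation.

# gap-scan visit collapse: times (numeric), gap splits when >= gap_s
oracle_collapse <- function(times, gap_s = 900) {
  times <- sort(times)
  visits <- list(); cur <- c(times[1], times[1])
  for (t in times[-1]) {
    if (t - cur[2] >= gap_s) {
      visits[[length(visits) + 1]] <- cur
      cur <- c(t, t)
    } else {
      cur[2] <- t
    }
  }
  visits[[length(visits) + 1]] <- cur
  do.call(rbind, visits)
}

# per-second co-presence: overlap of [a1,b1] and [a2,b2] with integer
# endpoints; encounter iff they share an instant, duration = instants - 1
oracle_overlap <- function(a1, b1, a2, b2) {
  shared <- max(0, min(b1, b2) - max(a1, a2) + 1)
  if (shared == 0) return(NULL)
  shared - 1
}

# connected components of the interval overlap graph via union-find
oracle_components <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && starts[i] <= ends[j] && starts[j] <= ends[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive per-day SRI tally from a GBI matrix and day vector
oracle_sri <- function(G, day) {
  n <- ncol(G)
  x <- yab <- ya <- yb <- matrix(0, n, n)
  for (d in unique(day)) {
    Gd <- G[day == d, , drop = FALSE]
    seen <- colSums(Gd) > 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        together <- any(Gd[, i] == 1 & Gd[, j] == 1)
        if (together) {
          x[i, j] <- x[i, j] + 1
        } else if (seen[i] && seen[j]) {
          yab[i, j] <- yab[i, j] + 1
        } else if (seen[i]) {
          ya[i, j] <- ya[i, j] + 1
        } else if (seen[j]) {
          yb[i, j] <- yb[i, j] + 1
        }
      }
    }
  }
  sri <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      den <- x[i, j] + yab[i, j] + ya[i, j] + yb[i, j]
      sri[i, j] <- sri[j, i] <- if (den > 0) x[i, j] / den else 0
    }
  }
  dimnames(sri) <- list(colnames(G), colnames(G))
  sri
}

# global metrics by triple/pair enumeration (innermost index vectorised)
oracle_global <- function(W) {
  n <- nrow(W)
  pairs <- n * (n - 1) / 2
  ne <- 0; sw <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (W[i, j] > 0) ne <- ne + 1
    sw <- sw + W[i, j]
  }
  A <- W > 0
  closed <- 0; triples <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j]) {
      k_ok <- A[j, ] & seq_len(n) != i & seq_len(n) != j
      triples <- triples + sum(k_ok)
      closed <- closed + sum(k_ok & A[i, ])
    }
  }
  list(unweighted_density = ne / pairs, weighted_density = sw / pairs,
       transitivity = if (triples > 0) closed / triples else NA_real_)
}

oracle_strength <- function(W) {
  vapply(seq_len(nrow(W)), function(i) sum(W[i, -i]), numeric(1))
}

# Leading eigenvector by power iteration with matrix squaring (independent
# of eigen()).  The matrix is shifted by c*I (c >= spectral radius) so the
# algebraically largest eigenvalue dominates in modulus even for bipartite
# graphs, where unshifted power iteration oscillates between the +/- lambda
# pair; 60 squarings push the subdominant directions below double precision.
oracle_eigenvector <- function(W) {
  n <- nrow(W)
  if (all(W == 0)) return(numeric(n))
  B <- W + diag(max(rowSums(abs(W))), n)
  B <- B / max(abs(B))
  for (k in 1:60) {
    B <- B %*% B
    B <- B / max(abs(B))
  }
  v <- abs(as.numeric(B %*% rep(1, n)))
  v / max(v)
}

# Onnela clustering by explicit triangle sums (innermost index vectorised)
oracle_onnela <- function(W) {
  n <- nrow(W)
  mw <- max(W)
  out <- rep(NA_real_, n)
  if (mw == 0) return(out)
  Wn <- W / mw
  for (i in seq_len(n)) {
    k <- sum(W[i, -i] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      h_ok <- seq_len(n) != i & seq_len(n) != j
      s <- s + sum((Wn[i, j] * Wn[i, h_ok] * Wn[j, h_ok])^(1 / 3))
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# discrete weighted assortativity via explicit mixing matrix
oracle_assort <- function(W, cats) {
  lev <- unique(cats)
  if (length(lev) < 2) return(NA_real_)
  E <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) E[cats[i], cats[j]] <- E[cats[i], cats[j]] + W[i, j]
  }
  if (sum(E) == 0) return(NA_real_)
  E <- E / sum(E)
  a <- rowSums(E); b <- colSums(E)
  (sum(diag(E)) - sum(a * b)) / (1 - sum(a * b))
}

# exact paired Wilcoxon two-sided p by sign enumeration (no ties assumed)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% rk)
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# random symmetric weight matrix with given edge probability
random_weight_matrix <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1)
  }
  dimnames(W) <- list(paste0("f", seq_len(n)), paste0("f", seq_len(n)))
  W
}

# random GBI with day/territory metadata
random_gbi <- function(n_fox = 8, n_days = 12, n_groups_day = 3,
                       p_member = 0.4) {
  rows <- list(); meta <- list()
  for (d in seq_len(n_days)) {
    for (g in seq_len(n_groups_day)) {
      m <- rbinom(n_fox, 1, p_member)
      if (sum(m) == 0) m[sample.int(n_fox, 1)] <- 1L
      rows[[length(rows) + 1]] <- as.integer(m)
      meta[[length(meta) + 1]] <- data.frame(territory = "T01",
                                             season = "spring",
                                             patch = paste0("P", g),
                                             day = d)
    }
  }
  G <- do.call(rbind, rows)
  colnames(G) <- sprintf("F%02d", seq_len(n_fox))
  foxsna:::new_gbi(G, do.call(rbind, meta))
}

# small deterministic scenario for integration-style tests
small_scenario <- function(seed = 1, territories = 1) {
  scenario_config(n_territories = territories, group_size_range = c(5, 6),
                  patches_per_territory = c(3, 3), cubs_per_territory = 1,
                  seed = seed)
}
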