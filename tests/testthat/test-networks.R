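# SRI matrices and weighted network metrics vs brute-force oracles

mk_gbi <- function(G, day) {
  colnames(G) <- sprintf("F%02d", seq_len(ncol(G)))
  meta <- data.frame(territory = "T01", season = "spring", patch = "P1",
                     day = day)
  foxsna:::new_gbi(G, meta)
}

test_that("SRI arithmetic on hand-built cases", {
  # together 2 days, each alone 1 day: 2/(2+0+1+1) = 0.5
  G <- rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 1))
  s <- sri_matrix(mk_gbi(G, day = 1:4))
  expect_equal(s$sri[1, 2], 0.5)
  expect_equal(unname(s$x[1, 2]), 2)
  expect_equal(unname(s$ya_yb[1, 2]), 2)
  # always together -> 1
  G2 <- rbind(c(1, 1), c(1, 1))
  expect_equal(sri_matrix(mk_gbi(G2, day = 1:2))$sri[1, 2], 1)
  # both seen on a day but apart (different groups) -> yAB
  G3 <- rbind(c(1, 0), c(0, 1))
  s3 <- sri_matrix(mk_gbi(G3, day = c(1, 1)))
  expect_equal(s3$yab[1, 2], 1)
  expect_equal(s3$sri[1, 2], 0)
})

test_that("SRI matches the exhaustive per-day tally oracle on random GBIs", {
  set.seed(5)
  for (r in 1:20) {
    g <- random_gbi(n_fox = sample(4:9, 1), n_days = sample(5:15, 1))
    s <- sri_matrix(g)
    expect_equal(s$sri, oracle_sri(g$G, g$meta$day), tolerance = 1e-12)
    # invariant: SRI unchanged by relabelling days
    perm <- sample(unique(g$meta$day))
    g2 <- g
    g2$meta$day <- perm[match(g$meta$day, unique(g$meta$day))]
    expect_equal(sri_matrix(g2)$sri, s$sri)
  }
})

test_that("global metrics on hand-built graphs", {
  W <- matrix(0.5, 3, 3); diag(W) <- 0
  dimnames(W) <- list(letters[1:3], letters[1:3])
  g <- global_metrics(W)
  expect_equal(g$unweighted_density, 1)
  expect_equal(g$weighted_density, 0.5)
  expect_equal(g$transitivity, 1)
  W0 <- matrix(0, 3, 3)
  g0 <- global_metrics(W0)
  expect_equal(g0$unweighted_density, 0)
  expect_equal(g0$weighted_density, 0)
  expect_true(is.na(g0$transitivity))
  expect_true(is.na(global_metrics(matrix(0, 1, 1))$unweighted_density))
  # weighted density equals the mean association index
  set.seed(2)
  W1 <- random_weight_matrix(6)
  expect_equal(global_metrics(W1)$weighted_density,
               mean(W1[upper.tri(W1)]))
})

test_that("strength, eigenvector and clustering on canonical graphs", {
  # star centre with 3 edges of 0.2
  W <- matrix(0, 4, 4)
  W[1, 2:4] <- W[2:4, 1] <- 0.2
  dimnames(W) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(strength(W)), c(0.6, 0.2, 0.2, 0.2))
  # isolated fox has strength zero
  W5 <- rbind(cbind(W, 0), 0)
  dimnames(W5) <- list(letters[1:5], letters[1:5])
  expect_equal(unname(strength(W5))[5], 0)
  # complete graph equal weights: all eigenvector scores equal (= 1)
  K <- matrix(0.3, 4, 4); diag(K) <- 0
  dimnames(K) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(eigenvector_centrality(K)), rep(1, 4))
  # two-node edge: both equal
  E2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(eigenvector_centrality(E2)), c(1, 1))
  # triangle with equal weights: clustering 1 everywhere
  Tm <- matrix(0.7, 3, 3); diag(Tm) <- 0
  dimnames(Tm) <- list(letters[1:3], letters[1:3])
  expect_equal(unname(clustering_onnela(Tm)), rep(1, 3))
  # path centre with no closing edge: clustering 0; ends undefined
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- 0.5; P[2, 3] <- P[3, 2] <- 0.5
  dimnames(P) <- list(letters[1:3], letters[1:3])
  cl <- clustering_onnela(P)
  expect_equal(unname(cl[2]), 0)
  expect_true(is.na(cl[1]) && is.na(cl[3]))
})

test_that("strength transform is log10(v + 1) and rejects negatives", {
  expect_equal(strength_transform(c(0, 9, 99)), c(0, 1, 2))
  expect_error(strength_transform(-1), "nonnegative")
})

test_that("assortativity on designed structures", {
  # two same-sex cliques, no cross edges -> r = 1
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 0.5; W[4:6, 4:6] <- 0.5; diag(W) <- 0
  dimnames(W) <- list(paste0("f", 1:6), paste0("f", 1:6))
  sex <- c("M", "M", "M", "F", "F", "F")
  expect_equal(assortativity_discrete(W, sex), 1)
  # perfect bipartite mixing -> negative
  B <- matrix(0, 4, 4)
  B[1:2, 3:4] <- 0.5; B[3:4, 1:2] <- 0.5
  dimnames(B) <- list(paste0("f", 1:4), paste0("f", 1:4))
  expect_lt(assortativity_discrete(B, c("M", "M", "F", "F")), 0)
  # single category undefined
  expect_true(is.na(assortativity_discrete(W, rep("M", 6))))
})

test_that("all metrics agree with brute force on random graphs", {
  set.seed(19)
  for (r in 1:40) {
    n <- sample(3:9, 1)
    W <- random_weight_matrix(n, p_edge = runif(1, 0.2, 0.9))
    g <- global_metrics(W)
    o <- oracle_global(W)
    expect_equal(g$unweighted_density, o$unweighted_density, tolerance = 1e-10)
    expect_equal(g$weighted_density, o$weighted_density, tolerance = 1e-10)
    expect_equal(g$transitivity, o$transitivity, tolerance = 1e-10)
    expect_equal(unname(strength(W)), oracle_strength(W), tolerance = 1e-10)
    expect_equal(unname(clustering_onnela(W)), oracle_onnela(W),
                 tolerance = 1e-10)
    if (sum(W) > 0) {
      expect_equal(unname(eigenvector_centrality(W)), oracle_eigenvector(W),
                   tolerance = 1e-6)
    }
    cats <- sample(c("M", "F"), n, replace = TRUE)
    expect_equal(assortativity_discrete(W, cats), oracle_assort(W, cats),
                 tolerance = 1e-10)
  }
})

test_that("GraphML export round-trips nodes and weighted edges", {
  set.seed(3)
  W <- random_weight_matrix(5)
  f <- tempfile(fileext = ".graphml")
  write_graphml(W, f, node_attrs = data.frame(fox = rownames(W),
                                              sex = c("M", "F", "M", "F", "M")))
  x <- readLines(f)
  expect_equal(sum(grepl("<node ", x)), 5)
  expect_equal(sum(grepl("<edge ", x)), sum(W[upper.tri(W)] > 0))
  expect_true(any(grepl("graphml.graphdrawing.org", x)))
})

test_that("period-restricted strength uses only events in that period", {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  v <- data.frame(
    fox = c("A", "B", "A", "C"), territory = "T01", season = "spring",
    patch = "P1",
    start = ts(c("2014-03-01 22:00:00", "2014-03-01 22:05:00",
                 "2014-03-02 03:00:00", "2014-03-02 03:05:00")),
    end = ts(c("2014-03-01 22:30:00", "2014-03-01 22:30:00",
               "2014-03-02 03:30:00", "2014-03-02 03:30:00")),
    survey_day = 1L)
  ev <- build_grouping_events(v)
  foxes <- c("A", "B", "C")
  s_before <- strength_by_period(ev, foxes, "before")
  s_after <- strength_by_period(ev, foxes, "after")
  # before midnight: only the A-B event exists; C has strength 0
  expect_gt(s_before[["A"]], 0)
  expect_equal(s_before[["C"]], 0)
  # after midnight: only the A-C event
  expect_gt(s_after[["C"]], 0)
  expect_equal(s_after[["B"]], 0)
})
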