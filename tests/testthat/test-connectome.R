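make_ts <- function(X, tr = 3) roi_timeseries(X, tr_seconds = tr)

test_that("preprocessing removes means, trends and confines the band", {
  set.seed(8)
  n <- 240; tr <- 3
  t_sec <- (0:(n - 1)) * tr
  const <- rep(5, n)
  ramp <- seq(0, 10, length.out = n)
  keep_f <- 0.05    # inside the band
  drop_f <- 0.002   # below the 0.01 Hz edge
  sig <- sin(2 * pi * keep_f * t_sec) + sin(2 * pi * drop_f * t_sec)
  ts <- make_ts(cbind(c1 = const, c2 = ramp, c3 = sig,
                      c4 = rnorm(n)), tr)
  pre <- preprocess_timeseries(ts, band = c(0.01, 0.25))
  expect_equal(nrow(pre$matrix), n)
  expect_lt(max(abs(pre$matrix[, "c1"])), 1e-10)
  expect_lt(max(abs(pre$matrix[, "c2"])), 1e-8)

  # spectral oracle: power at 0.05 Hz retained, at 0.002 Hz suppressed
  spec_power <- function(x, f) {
    freqs <- (0:(n - 1)) / (n * tr)
    amp <- Mod(fft(x))^2
    sum(amp[abs(freqs - f) < 0.004])
  }
  x_in <- sig - mean(sig)
  x_out <- pre$matrix[, "c3"]
  expect_gt(spec_power(x_out, keep_f) / spec_power(x_in, keep_f), 0.9)
  expect_lt(spec_power(x_out, drop_f) / spec_power(x_in, drop_f), 0.1)
})

test_that("band entirely above Nyquist is rejected", {
  ts <- make_ts(matrix(rnorm(100 * 3), ncol = 3), tr = 3)  # Nyquist 0.167
  expect_error(preprocess_timeseries(ts, band = c(0.2, 0.25)), "Nyquist")
})

test_that("similarity is the elementwise squared correlation", {
  set.seed(13)
  X <- matrix(rnorm(200 * 10), ncol = 10,
              dimnames = list(NULL, paste0("r", 1:10)))
  S <- similarity_matrix(make_ts(X))
  # brute-force pairwise oracle
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(S[i, j], cor(X[, i], X[, j])^2, tolerance = 1e-12)
  expect_equal(S, t(S))
  expect_true(all(diag(S) == 0))

  # duplicated column and a negated column both give similarity 1
  X2 <- cbind(a = X[, 1], b = X[, 1], c = -X[, 1], d = X[, 2])
  S2 <- similarity_matrix(make_ts(X2))
  expect_equal(S2["a", "b"], 1)
  expect_equal(S2["a", "c"], 1)   # sign removed by squaring

  Xz <- X; Xz[, 4] <- 2
  expect_error(similarity_matrix(make_ts(Xz)), "r4")
})

test_that("percolation threshold on a worked 3-node example", {
  S <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  S["A", "B"] <- S["B", "A"] <- 0.9
  S["B", "C"] <- S["C", "B"] <- 0.5
  S["A", "C"] <- S["C", "A"] <- 0.2
  g <- percolation_threshold(S)
  expect_equal(g$tau, 0.5)
  expect_equal(sum(g$adjacency > 0) / 2, 2)  # AB and BC only
  expect_equal(g$adjacency["A", "B"], 0.9)
  expect_equal(g$adjacency["A", "C"], 0)
})

test_that("equal weights keep every edge at tau = w", {
  S <- matrix(0.4, 5, 5); diag(S) <- 0
  g <- percolation_threshold(S)
  expect_equal(g$tau, 0.4)
  expect_equal(sum(g$adjacency > 0) / 2, choose(5, 2))
})

test_that("percolation equals descending-threshold search and is minimal", {
  for (s in 1:100) {
    n <- sample(4:12, 1)
    S <- rand_similarity(n, seed = 4000 + s)
    g <- percolation_threshold(S)
    expect_equal(g$tau, oracle_threshold(S))
    # connected at tau, disconnected strictly above it
    expect_true(bfs_connected(g$adjacency))
    above <- S * (S > g$tau)
    expect_false(bfs_connected(above))
  }
})

test_that("strength matches row sums and drops additively", {
  A <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  A[1, 2:5] <- A[2:5, 1] <- 1  # star with unit weights
  g <- list(adjacency = A, labels = letters[1:5], tau = 1,
            graph = igraph::graph_from_adjacency_matrix(A, "undirected",
                                                        weighted = TRUE))
  class(g) <- "thresholded_graph"
  expect_equal(unname(degree_strength(g)), c(4, 1, 1, 1, 1))
  expect_equal(unname(degree_strength(g, weighted = FALSE)), c(4, 1, 1, 1, 1))

  S <- rand_similarity(9, seed = 99)
  gt <- percolation_threshold(S)
  expect_equal(unname(degree_strength(gt)), unname(rowSums(gt$adjacency)))
})

test_that("Onnela clustering on canonical graphs and against the oracle", {
  # complete triangle with equal weights: all coefficients 1
  A <- matrix(0.7, 3, 3); diag(A) <- 0
  rownames(A) <- colnames(A) <- c("x", "y", "z")
  g <- percolation_threshold(A)
  expect_equal(unname(clustering_weighted(g)), rep(1, 3))

  # 3-node path: no triangle anywhere
  P <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P["A", "B"] <- P["B", "A"] <- 0.8
  P["B", "C"] <- P["C", "B"] <- 0.6
  gp <- list(adjacency = P, labels = rownames(P), tau = 0.6,
             graph = igraph::graph_from_adjacency_matrix(P, "undirected",
                                                         weighted = TRUE))
  class(gp) <- "thresholded_graph"
  expect_equal(unname(clustering_weighted(gp)), c(0, 0, 0))

  for (s in 1:25) {
    S <- rand_similarity(6, seed = 600 + s)
    gt <- percolation_threshold(S)
    expect_equal(unname(clustering_weighted(gt)),
                 oracle_clustering(gt$adjacency), tolerance = 1e-12)
  }
})

test_that("weighted betweenness on canonical graphs and against the oracle", {
  # path A-B-C: B mediates the single A-C shortest path
  P <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  P["A", "B"] <- P["B", "A"] <- 0.8
  P["B", "C"] <- P["C", "B"] <- 0.6
  gp <- list(adjacency = P, labels = rownames(P), tau = 0.6,
             graph = igraph::graph_from_adjacency_matrix(P, "undirected",
                                                         weighted = TRUE))
  class(gp) <- "thresholded_graph"
  bc <- betweenness_weighted(gp)
  expect_equal(unname(bc), c(0, 1, 0))

  # star: center on every leaf pair's path
  A <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  A[1, 2:5] <- A[2:5, 1] <- 0.5
  gs <- list(adjacency = A, labels = letters[1:5], tau = 0.5,
             graph = igraph::graph_from_adjacency_matrix(A, "undirected",
                                                         weighted = TRUE))
  class(gs) <- "thresholded_graph"
  bcs <- betweenness_weighted(gs)
  expect_equal(unname(bcs), c(1, 0, 0, 0, 0))

  for (s in 1:25) {
    S <- rand_similarity(7, seed = 7000 + s)
    gt <- percolation_threshold(S)
    expect_equal(unname(betweenness_weighted(gt)),
                 oracle_betweenness(gt$adjacency), tolerance = 1e-8)
  }
})

test_that("metrics are equivariant under node relabelling", {
  S <- rand_similarity(8, seed = 321)
  g1 <- percolation_threshold(S)
  perm <- sample(8)
  S2 <- S[perm, perm]
  g2 <- percolation_threshold(S2)
  expect_equal(g2$tau, g1$tau)
  for (f in list(degree_strength, clustering_weighted, betweenness_weighted)) {
    v1 <- f(g1); v2 <- f(g2)
    expect_equal(v2[names(v1)], v1, tolerance = 1e-10)
  }
})

test_that("connectome_metrics runs the full per-subject stage", {
  set.seed(2)
  X <- matrix(rnorm(120 * 12), ncol = 12)
  m <- connectome_metrics(make_ts(X))
  expect_equal(nrow(m), 12)
  expect_true(all(c("degree", "clustering", "betweenness") %in% names(m)))
  expect_true(is.numeric(attr(m, "tau")))
  m2 <- connectome_metrics(make_ts(X), metrics = "degree")
  expect_false("betweenness" %in% names(m2))
  expect_equal(m2$degree, m$degree)
})
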