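# Independent brute-force oracles used across the suite. These deliberately
# avoid igraph and the package's own code paths.

# random symmetric similarity matrix with weights in (0, 1), zero diagonal
rand_similarity <- function(n, seed) {
  set.seed(seed)
  S <- matrix(0, n, n)
  w <- runif(n * (n - 1) / 2, 0.01, 0.99)
  S[upper.tri(S)] <- w
  S <- S + t(S)
  rownames(S) <- colnames(S) <- sprintf("n%02d", seq_len(n))
  S
}

# connectivity of the graph with edges A > 0, by hand-rolled BFS
bfs_connected <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(A[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# percolation point by descending-threshold search over the distinct weights
oracle_threshold <- function(S) {
  diag(S) <- 0
  cand <- sort(unique(S[upper.tri(S)]), decreasing = TRUE)
  for (tau in cand) {
    A <- S * (S >= tau)
    if (bfs_connected(A)) return(tau)
  }
  stop("no connecting threshold found")
}

# Onnela weighted clustering by explicit triangle loops
oracle_clustering <- function(A) {
  n <- nrow(A)
  wmax <- max(A)
  W <- if (wmax > 0) (A / wmax)^(1 / 3) else A
  k <- rowSums(A > 0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] < 2) next
    s <- 0
    nb <- which(A[i, ] > 0)
    for (j in nb) for (h in nb) {
      if (j >= h) next
      s <- s + W[i, j] * W[i, h] * W[j, h]
    }
    cc[i] <- 2 * s / (k[i] * (k[i] - 1))
  }
  cc
}

# weighted betweenness with edge length 1/w: Floyd-Warshall distances plus
# shortest-path counting via the predecessor criterion
oracle_betweenness <- function(A, tol = 1e-10) {
  n <- nrow(A)
  L <- ifelse(A > 0, 1 / A, Inf)
  diag(L) <- 0
  D <- L
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # sigma[s, t]: number of shortest s-t paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(L[, t] < Inf &
                      abs(D[s, ] + L[, t] - D[s, t]) < tol * (1 + D[s, t]))
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  bc <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < tol * (1 + D[s, t]) &&
          sigma[s, t] > 0)
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- acc
  }
  bc / ((n - 1) * (n - 2) / 2)
}

# dense grid search for the 3-parameter Gaussian least-squares fit
oracle_gauss_grid <- function(d, y,
                              a_grid = seq(0.01, 0.6, length.out = 40),
                              mu_grid = seq(90, 1620, by = 15),
                              s_grid = seq(30, 600, by = 10)) {
  best <- c(NA, NA, NA); best_sse <- Inf
  for (s in s_grid) {
    E <- exp(-outer(d, mu_grid, "-")^2 / (2 * s^2))  # length(d) x length(mu)
    for (ai in a_grid) {
      R <- y - ai * E
      sse <- colSums(R^2)
      j <- which.min(sse)
      if (sse[j] < best_sse) {
        best_sse <- sse[j]
        best <- c(ai, mu_grid[j], s)
      }
    }
  }
  list(a = best[1], mu = best[2], sigma = best[3], sse = best_sse)
}

# squared multiple correlation of column j on the remaining columns,
# via normal equations (independent of lm)
oracle_multiple_r2 <- function(X, j) {
  yv <- X[, j]
  Z <- cbind(1, X[, -j, drop = FALSE])
  beta <- solve(crossprod(Z), crossprod(Z, yv))
  fitv <- Z %*% beta
  1 - sum((yv - fitv)^2) / sum((yv - mean(yv))^2)
}
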