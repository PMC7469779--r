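#' Construct an ROI time-series object
#'
#' @param matrix Numeric matrix, timepoints x ROIs.
#' @param labels ROI labels (default column names, else ROI_001...).
#' @param tr_seconds Repetition time (sampling interval) in seconds.
#' @return An object of class \code{roi_timeseries}.
#' @export
roi_timeseries <- function(matrix, labels = colnames(matrix),
                           tr_seconds = 3) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("time series must be numeric", call. = FALSE)
  if (ncol(matrix) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  if (nrow(matrix) < 8L) stop("need at least 8 timepoints", call. = FALSE)
  if (anyNA(matrix)) stop("time series contain missing values", call. = FALSE)
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(ncol(matrix)))
  colnames(matrix) <- labels
  structure(list(matrix = matrix, labels = labels,
                 tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d timepoints x %d ROIs, TR = %g s\n",
              nrow(x$matrix), ncol(x$matrix), x$tr_seconds))
  invisible(x)
}

#' Temporal preprocessing: demean, detrend, despike, band-pass
#'
#' Each ROI column is demeaned, linearly detrended, despiked by robust
#' winsorization (clipped at median +/- 4 MAD), and band-pass filtered.
#' The filter is applied in the frequency domain (discrete Fourier
#' transform bins outside \[low, high\] zeroed), which is zero-phase by
#' construction. The upper band edge is capped at the Nyquist frequency
#' 1/(2 TR); at TR = 3 s the Nyquist is ~0.167 Hz, so a nominal 0.25 Hz
#' upper edge reduces to a high-pass at the lower edge.
#'
#' @param ts A \code{\link{roi_timeseries}}.
#' @param band Length-2 numeric, (low, high) in Hz; low < high.
#' @return A preprocessed \code{roi_timeseries} of the same dimensions.
#' @export
preprocess_timeseries <- function(ts, band = c(0.01, 0.25)) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (length(band) != 2L || band[1] >= band[2])
    stop("`band` must be (low, high) with low < high", call. = FALSE)
  nyq <- 1 / (2 * ts$tr_seconds)
  if (band[1] >= nyq)
    stop("band lies entirely above the Nyquist frequency ",
         signif(nyq, 3), " Hz", call. = FALSE)
  high <- min(band[2], nyq)
  n <- nrow(ts$matrix)
  t_idx <- seq_len(n)
  freqs <- (seq_len(n) - 1) / (n * ts$tr_seconds)
  # two-sided spectrum: mirror frequencies above Nyquist
  freqs <- pmin(freqs, 1 / ts$tr_seconds - freqs)
  keep <- freqs >= band[1] & freqs <= high

  out <- apply(ts$matrix, 2, function(x) {
    x <- x - mean(x)
    fit <- stats::lm.fit(cbind(1, t_idx), x)
    x <- fit$residuals
    med <- stats::median(x)
    mad_ <- stats::mad(x)
    if (mad_ > 0) x <- pmin(pmax(x, med - 4 * mad_), med + 4 * mad_)
    xf <- stats::fft(x)
    xf[!keep] <- 0
    Re(stats::fft(xf, inverse = TRUE)) / n
  })
  roi_timeseries(out, labels = ts$labels, tr_seconds = ts$tr_seconds)
}

#' Squared-correlation similarity matrix
#'
#' Functional connections are weighted by the square of the Pearson
#' correlation between ROI time courses, so that strong negative and strong
#' positive coupling count alike as similarity. The diagonal is set to 0
#' for graph purposes.
#'
#' @param ts A (preprocessed) \code{\link{roi_timeseries}}.
#' @return Symmetric matrix of squared correlations in \[0, 1\] with ROI
#'   labels as dimnames and a zero diagonal.
#' @export
similarity_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$matrix, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI column(s): ",
         paste(ts$labels[sds == 0], collapse = ", "), call. = FALSE)
  S <- stats::cor(ts$matrix)^2
  diag(S) <- 0
  dimnames(S) <- list(ts$labels, ts$labels)
  S
}

#' Percolation threshold: maximal cutoff keeping the graph connected
#'
#' Finds the largest edge-weight threshold tau at which the similarity
#' graph remains a single connected component, and returns the graph
#' retaining every edge with weight >= tau (ties at tau are kept). tau is
#' computed as the bottleneck (minimum) edge weight of the maximum
#' spanning tree, which equals the descending-threshold percolation point.
#'
#' @param S Symmetric similarity matrix (zero or ignored diagonal).
#' @return A list of class \code{thresholded_graph}: \code{graph} (an
#'   igraph object with a \code{weight} edge attribute), \code{adjacency}
#'   (thresholded weight matrix), \code{tau}, \code{labels}.
#' @export
percolation_threshold <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S) || nrow(S) < 2L)
    stop("similarity matrix must be square with >= 2 nodes", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8)
    stop("similarity matrix must be symmetric", call. = FALSE)
  labels <- rownames(S)
  if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(nrow(S)))
  diag(S) <- 0
  g_full <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                                weighted = TRUE)
  # maximum spanning tree = minimum spanning tree on negated weights
  mst <- igraph::mst(g_full, weights = -igraph::E(g_full)$weight)
  tau <- min(igraph::E(mst)$weight)
  A <- S
  A[A < tau] <- 0
  dimnames(A) <- list(labels, labels)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- labels
  structure(list(graph = g, adjacency = A, tau = tau, labels = labels),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf(
    "Thresholded similarity graph: %d nodes, %d edges, tau = %.4g\n",
    length(x$labels), igraph::ecount(x$graph), x$tau))
  invisible(x)
}

#' Node strength (weighted degree centrality)
#'
#' Sum of the retained edge weights incident to each node; with
#' \code{weighted = FALSE}, the binary edge count.
#'
#' @param g A \code{\link{percolation_threshold}} result.
#' @param weighted Use edge weights (default) or binary degree.
#' @return Named numeric vector, one value per node.
#' @export
degree_strength <- function(g, weighted = TRUE) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (weighted) {
    stats::setNames(rowSums(g$adjacency), g$labels)
  } else {
    stats::setNames(rowSums(g$adjacency > 0), g$labels)
  }
}

#' Weighted clustering coefficient (Onnela geometric-mean variant)
#'
#' For node i with binary degree k_i >= 2,
#' \deqn{\hat c_i = \frac{2}{k_i (k_i - 1)} \sum_{j < h}
#'   (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}}
#' with weights normalized by the maximum retained weight; nodes of degree
#' below 2 get 0. With \code{weighted = FALSE} the binary (Watts-Strogatz)
#' coefficient is returned instead.
#'
#' @param g A \code{\link{percolation_threshold}} result.
#' @param weighted Onnela weighted variant (default) or binary.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_weighted <- function(g, weighted = TRUE) {
  stopifnot(inherits(g, "thresholded_graph"))
  A <- g$adjacency
  k <- rowSums(A > 0)
  W <- if (weighted) {
    wm <- max(A)
    if (wm > 0) (A / wm)^(1 / 3) else A
  } else {
    (A > 0) * 1
  }
  tri <- diag(W %*% W %*% W)  # 2 * sum over unordered triangle pairs at i
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(cc, g$labels)
}

#' Weighted betweenness centrality
#'
#' Shortest-path betweenness with edge length the reciprocal of the
#' similarity weight (stronger connections are shorter), equal-length path
#' multiplicities split fractionally, normalized by (n-1)(n-2)/2.
#'
#' @param g A connected \code{\link{percolation_threshold}} result.
#' @param distance How edge weights map to lengths: \code{"inverse"}
#'   (1/w, default) or \code{"one_minus"} (1 - w).
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_weighted <- function(g, distance = c("inverse", "one_minus")) {
  stopifnot(inherits(g, "thresholded_graph"))
  distance <- match.arg(distance)
  if (igraph::components(g$graph)$no > 1L)
    stop("graph is disconnected; betweenness requires a connected graph",
         call. = FALSE)
  w <- igraph::E(g$graph)$weight
  len <- if (distance == "inverse") 1 / w else 1 - w
  if (any(len <= 0)) len <- pmax(len, .Machine$double.eps)
  b <- igraph::betweenness(g$graph, weights = len, normalized = TRUE)
  stats::setNames(as.numeric(b), g$labels)
}

#' All node metrics for one subject's similarity graph
#'
#' @param g A \code{\link{percolation_threshold}} result.
#' @return Data.frame: \code{node}, \code{degree}, \code{clustering},
#'   \code{betweenness}, with the threshold tau as an attribute.
#' @export
node_metrics <- function(g) {
  out <- data.frame(node = g$labels,
                    degree = unname(degree_strength(g)),
                    clustering = unname(clustering_weighted(g)),
                    betweenness = unname(betweenness_weighted(g)))
  attr(out, "tau") <- g$tau
  out
}

#' ROI time series to node metrics in one call
#'
#' Preprocess, correlate, threshold and measure: the full per-subject
#' connectome stage.
#'
#' @param ts A \code{\link{roi_timeseries}}.
#' @param band Band-pass limits in Hz.
#' @param metrics Which metrics to compute (subset of degree, clustering,
#'   betweenness); restricting the set skips unneeded computation.
#' @return Data.frame as \code{\link{node_metrics}} restricted to the
#'   requested columns.
#' @export
connectome_metrics <- function(ts, band = c(0.01, 0.25),
                               metrics = c("degree", "clustering",
                                           "betweenness")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  pre <- preprocess_timeseries(ts, band = band)
  g <- percolation_threshold(similarity_matrix(pre))
  out <- data.frame(node = g$labels)
  if ("degree" %in% metrics) out$degree <- unname(degree_strength(g))
  if ("clustering" %in% metrics)
    out$clustering <- unname(clustering_weighted(g))
  if ("betweenness" %in% metrics)
    out$betweenness <- unname(betweenness_weighted(g))
  attr(out, "tau") <- g$tau
  out
}
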