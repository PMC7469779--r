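#' Configuration of the screened stepwise brain-behavior regression
#'
#' @param f_enter Partial F a candidate must exceed to enter the stepwise
#'   model (default 4).
#' @param p_screen Simple-regression significance cutoff for the
#'   preliminary screen (default .05).
#' @param tolerance_min Minimum tolerance (1 - R2 of a predictor regressed
#'   on the other candidates) to survive the multicollinearity filter
#'   (default 0.30).
#' @return List of class \code{stepwise_config}.
#' @export
stepwise_config <- function(f_enter = 4, p_screen = 0.05,
                            tolerance_min = 0.30) {
  if (f_enter <= 0 || p_screen <= 0 || tolerance_min <= 0)
    stop("all stepwise configuration values must be positive", call. = FALSE)
  structure(list(f_enter = f_enter, p_screen = p_screen,
                 tolerance_min = tolerance_min),
            class = "stepwise_config")
}

#' Simple-regression screen of node metrics against a behavioural index
#'
#' Regresses the behavioural index on each node's metric separately
#' (variables z-scored, so beta is the standardized coefficient and
#' beta^2 = R2). Reports, per node: standardized beta, R2, adjusted R2
#' (= 1 - (1 - R2)(n - 1)/(n - 2)), F with (1, n - 2) df, and p. Nodes
#' with p below the screen cutoff are flagged \code{passed}. Constant
#' columns are excluded with a warning.
#'
#' @param metrics Numeric matrix or data.frame, subjects x nodes, of one
#'   metric type (never pool metric types in one screen).
#' @param behavior Numeric vector, one behavioural index value per subject.
#' @param cfg A \code{\link{stepwise_config}}.
#' @return Data.frame: \code{node}, \code{beta}, \code{r2}, \code{adj_r2},
#'   \code{f_stat}, \code{p}, \code{passed}.
#' @export
screen_simple <- function(metrics, behavior, cfg = stepwise_config()) {
  X <- as.matrix(metrics)
  if (is.null(colnames(X))) colnames(X) <- sprintf("node_%03d", seq_len(ncol(X)))
  n <- length(behavior)
  if (nrow(X) != n) stop("metrics rows must match behavior length", call. = FALSE)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant node column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  r <- as.numeric(stats::cor(X, behavior))
  r2 <- r^2
  f <- r2 / (1 - r2) * (n - 2)
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  out <- data.frame(node = colnames(X),
                    beta = r, r2 = r2,
                    adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                    f_stat = f, p = p,
                    passed = p < cfg$p_screen)
  rownames(out) <- NULL
  out
}

#' Tolerance-based multicollinearity filter
#'
#' Tolerance of a candidate is 1 minus the R2 of regressing it on all the
#' other candidates. Candidates whose tolerance falls below the cutoff are
#' dropped; every member of a zero-tolerance (exactly collinear) set is
#' dropped, never an arbitrary survivor. A single candidate has tolerance
#' 1 by convention.
#'
#' @param candidates Numeric matrix, subjects x screened candidate columns.
#' @param cfg A \code{\link{stepwise_config}}.
#' @return List: \code{tolerance} (named vector over all candidates) and
#'   \code{kept} (character vector of retained column names).
#' @export
tolerance_filter <- function(candidates, cfg = stepwise_config()) {
  X <- as.matrix(candidates)
  if (ncol(X) == 0L) stop("need at least one candidate", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- sprintf("cand_%03d", seq_len(ncol(X)))
  if (ncol(X) == 1L)
    return(list(tolerance = stats::setNames(1, colnames(X)),
                kept = colnames(X)))
  tol <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    ssr <- sum(fit$residuals^2)
    sst <- sum((X[, j] - mean(X[, j]))^2)
    if (sst == 0) 0 else ssr / sst
  }, numeric(1))
  names(tol) <- colnames(X)
  list(tolerance = tol, kept = colnames(X)[tol >= cfg$tolerance_min])
}

#' Forward stepwise regression with an F-to-enter rule
#'
#' Starts from the empty model; at each step computes every remaining
#' candidate's partial F (the F statistic for adding it to the current
#' model) and enters the candidate with the largest partial F provided it
#' exceeds \code{f_enter}; stops otherwise. Ties are broken by candidate
#' label order. Variables are z-scored internally so reported coefficients
#' are standardized betas. An empty model (no candidate ever enters) is a
#' valid result.
#'
#' @param candidates Numeric matrix, subjects x candidate columns
#'   (screened and tolerance-filtered upstream).
#' @param behavior Numeric behavioural index vector.
#' @param cfg A \code{\link{stepwise_config}}.
#' @return Object of class \code{stepwise_model}: \code{selected} (ordered
#'   labels), \code{coefficients} (standardized betas of the final model),
#'   \code{r2}, \code{adj_r2}, \code{f_stat}, \code{df} (c(k, n - k - 1)),
#'   \code{p}, \code{entry_history} (data.frame of step, node, partial F,
#'   model R2), \code{n}.
#' @export
forward_stepwise <- function(candidates, behavior, cfg = stepwise_config()) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- sprintf("cand_%03d", seq_len(ncol(X)))
  n <- length(behavior)
  stopifnot(nrow(X) == n)
  Xs <- scale(X)
  ys <- as.numeric(scale(behavior))
  remaining <- colnames(X)[order(colnames(X))]
  selected <- character(0)
  history <- list()
  rss_curr <- sum((ys - mean(ys))^2)  # ys is centered: = n - 1

  repeat {
    if (length(remaining) == 0L) break
    k_new <- length(selected) + 1L
    df_resid <- n - k_new - 1L
    if (df_resid < 1L) break
    partial_f <- vapply(remaining, function(cand) {
      cols <- cbind(1, Xs[, c(selected, cand), drop = FALSE])
      fit <- stats::lm.fit(cols, ys)
      rss_new <- sum(fit$residuals^2)
      if (rss_new <= 0) return(Inf)
      (rss_curr - rss_new) / (rss_new / df_resid)
    }, numeric(1))
    best <- which.max(partial_f)  # ties: first in label order
    if (!(partial_f[best] > cfg$f_enter)) break
    cand <- remaining[best]
    selected <- c(selected, cand)
    fit <- stats::lm.fit(cbind(1, Xs[, selected, drop = FALSE]), ys)
    rss_curr <- sum(fit$residuals^2)
    r2_curr <- 1 - rss_curr / sum((ys - mean(ys))^2)
    history[[length(history) + 1L]] <- data.frame(
      step = length(selected), node = cand,
      f_enter = unname(partial_f[best]), model_r2 = r2_curr)
    remaining <- setdiff(remaining, cand)
  }

  k <- length(selected)
  if (k == 0L) {
    r2 <- 0; adj <- 0; f <- NA_real_; p <- NA_real_
    coefs <- numeric(0)
  } else {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                               Xs[, selected, drop = FALSE]), ys)
    coefs <- stats::setNames(fit$coefficients[-1], selected)
    rss <- sum(fit$residuals^2)
    sst <- sum((ys - mean(ys))^2)
    r2 <- 1 - rss / sst
    adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    f <- (r2 / k) / ((1 - r2) / (n - k - 1))
    p <- stats::pf(f, k, n - k - 1, lower.tail = FALSE)
  }
  structure(
    list(selected = selected, coefficients = coefs,
         r2 = r2, adj_r2 = adj, f_stat = f,
         df = c(k, n - k - 1L), p = p,
         entry_history = if (length(history)) do.call(rbind, history)
                         else data.frame(step = integer(0),
                                         node = character(0),
                                         f_enter = numeric(0),
                                         model_r2 = numeric(0)),
         n = n, cfg = cfg,
         scale_center = attr(Xs, "scaled:center"),
         scale_sd = attr(Xs, "scaled:scale"),
         y_center = mean(behavior), y_sd = stats::sd(behavior)),
    class = "stepwise_model"
  )
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (length(x$selected) == 0L) {
    cat("Forward stepwise model: empty (no candidate exceeded F-to-enter",
        x$cfg$f_enter, ")\n")
    return(invisible(x))
  }
  cat("Forward stepwise model (F-to-enter", x$cfg$f_enter, ")\n")
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  R2 = %.3f, adj R2 = %.3f, F(%d;%d) = %.3f, p = %.4g\n",
              x$r2, x$adj_r2, x$df[1], x$df[2], x$f_stat, x$p))
  invisible(x)
}

#' @export
summary.stepwise_model <- function(object, ...) {
  out <- list(model = object)
  class(out) <- "summary.stepwise_model"
  out
}

#' @export
print.summary.stepwise_model <- function(x, ...) {
  print(x$model)
  if (nrow(x$model$entry_history)) {
    cat("  entry history:\n")
    hist <- x$model$entry_history
    for (i in seq_len(nrow(hist)))
      cat(sprintf("    step %d: %s  (partial F = %.3f, model R2 = %.3f)\n",
                  hist$step[i], hist$node[i], hist$f_enter[i],
                  hist$model_r2[i]))
  }
  invisible(x)
}

#' @export
coef.stepwise_model <- function(object, ...) object$coefficients

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  if (length(object$selected) == 0L) {
    n_new <- if (missing(newdata)) 1L else nrow(as.matrix(newdata))
    return(rep(object$y_center, n_new))
  }
  X <- as.matrix(newdata)[, object$selected, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$scale_center[object$selected]), 2,
              object$scale_sd[object$selected], "/")
  ys_hat <- as.numeric(Xs %*% object$coefficients)
  object$y_center + object$y_sd * ys_hat
}

#' Screen, filter and select: the full brain-behavior stage
#'
#' Runs the simple-regression screen on one metric type, applies the
#' tolerance filter to the survivors, and fits the forward stepwise model.
#' One such run per (behavioural index, metric type) pair; metric types
#' are never pooled.
#'
#' @param metrics Subjects x nodes matrix of one metric type.
#' @param behavior Behavioural index vector.
#' @param cfg A \code{\link{stepwise_config}}.
#' @return List of class \code{brain_behavior_run}: \code{screen} (full
#'   screen table), \code{tolerance} (named vector over screened
#'   candidates), \code{candidates} (labels entering the stepwise stage),
#'   \code{model} (a \code{stepwise_model}, or NULL if nothing passed the
#'   screen).
#' @export
brain_behavior_run <- function(metrics, behavior, cfg = stepwise_config()) {
  screen <- screen_simple(metrics, behavior, cfg)
  passed <- screen$node[screen$passed]
  if (length(passed) == 0L) {
    out <- list(screen = screen, tolerance = numeric(0),
                candidates = character(0), model = NULL)
    class(out) <- "brain_behavior_run"
    return(out)
  }
  X <- as.matrix(metrics)[, passed, drop = FALSE]
  tf <- tolerance_filter(X, cfg)
  model <- if (length(tf$kept))
    forward_stepwise(X[, tf$kept, drop = FALSE], behavior, cfg)
  else NULL
  out <- list(screen = screen, tolerance = tf$tolerance,
              candidates = tf$kept, model = model)
  class(out) <- "brain_behavior_run"
  out
}

#' @export
print.brain_behavior_run <- function(x, ...) {
  cat(sprintf("Brain-behavior run: %d/%d nodes passed the screen, %d after tolerance filter\n",
              sum(x$screen$passed), nrow(x$screen), length(x$candidates)))
  if (!is.null(x$model)) print(x$model) else cat("  no stepwise model fit\n")
  invisible(x)
}
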