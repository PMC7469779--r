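#' Aggregate a trial log into a normalized agency curve
#'
#' Counts the "self" (full control) responses at each sampled delay and
#' normalizes by the total number of trials in the session (140 under the
#' default staircase), not by the per-delay trial count: because the
#' adaptive procedure resamples delays near the observer's uncertainty
#' region, the normalized counts form a hump whose location, height and
#' width carry the behavioural indices. Delays the staircase never visited
#' get no entry (they are not zero-filled).
#'
#' @param trials Data.frame of trial records for a single subject, as
#'   produced by \code{\link{run_session}} or \code{\link{read_trial_log}}.
#' @return A data.frame of class \code{agency_curve} with columns
#'   \code{delay_ms} (sorted ascending), \code{n_self}, \code{n_total}
#'   (trials at that delay) and \code{y} (= n_self / total session trials).
#' @export
aggregate_curve <- function(trials) {
  req <- c("subject_id", "delay_ms", "response")
  if (!all(req %in% names(trials)))
    stop("trial log must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0L) stop("empty trial log", call. = FALSE)
  if (length(unique(trials$subject_id)) > 1L)
    stop("trial log mixes multiple subjects; aggregate one subject at a time",
         call. = FALSE)
  if (!all(trials$response %in% c("self", "computer")))
    stop("unknown response token in trial log", call. = FALSE)
  n_session <- nrow(trials)
  delays <- sort(unique(trials$delay_ms))
  n_self <- vapply(delays, function(d)
    sum(trials$delay_ms == d & trials$response == "self"), numeric(1))
  n_tot <- vapply(delays, function(d)
    sum(trials$delay_ms == d), numeric(1))
  out <- data.frame(delay_ms = delays, n_self = n_self, n_total = n_tot,
                    y = n_self / n_session)
  attr(out, "n_session") <- n_session
  class(out) <- c("agency_curve", "data.frame")
  out
}

#' Fit a Gaussian to a normalized agency curve
#'
#' Least-squares fit of \eqn{y(d) = a \exp(-(d - \mu)^2 / (2\sigma^2))} to
#' the per-delay normalized self-response counts. The three parameters are
#' the behavioural indices: \eqn{\mu} is the point of subjective equality
#' (t_PSE, ms), \eqn{a} the curve peak value (consistency of
#' self-attribution) and \eqn{\sigma} the curve SD (width of the
#' self-agency time window, ms). Goodness of fit is
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} over the sampled delays.
#'
#' Initialisation: a0 = max y, mu0 = delay of the maximum, sigma0 = the
#' y-weighted standard deviation of the delays; bounds a in \[0, 1\],
#' mu in \[0, 2000\] ms, sigma in \[30, 2000\] ms. Non-convergence is
#' flagged on the returned object rather than raised.
#'
#' @param curve An \code{\link{aggregate_curve}} result, or any data.frame
#'   with columns \code{delay_ms} and \code{y}.
#' @return An object of class \code{agency_fit}: list with \code{amplitude},
#'   \code{mu}, \code{sigma}, \code{r_squared}, \code{converged},
#'   \code{raw_peak} (maximum of the raw normalized counts, reported for
#'   transparency alongside the fitted amplitude) and the fitted curve data.
#' @export
fit_agency_curve <- function(curve) {
  if (!all(c("delay_ms", "y") %in% names(curve)))
    stop("curve must have columns delay_ms and y", call. = FALSE)
  d <- curve$delay_ms
  y <- curve$y
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(unique(d)) < 4L)
    stop("need at least 4 distinct sampled delays to fit", call. = FALSE)
  if (all(y == 0))
    stop("all-zero curve: no self responses to fit", call. = FALSE)

  a0 <- max(y)
  mu0 <- d[which.max(y)]
  w <- y / sum(y)
  sigma0 <- sqrt(sum(w * (d - sum(w * d))^2))
  sigma0 <- min(max(sigma0, 30), 2000)
  lower <- c(a = 0, mu = 0, sigma = 30)
  upper <- c(a = 1, mu = 2000, sigma = 2000)
  start <- c(a = a0, mu = min(max(mu0, 0), 2000), sigma = sigma0)

  gauss <- function(p, d) p[1] * exp(-(d - p[2])^2 / (2 * p[3]^2))
  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      y ~ a * exp(-(delay_ms - mu)^2 / (2 * sigma^2)),
      data = data.frame(delay_ms = d, y = y),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(par = stats::coef(m), converged = TRUE)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to bounded quasi-Newton on the residual sum of squares
    obj <- function(p) sum((y - gauss(p, d))^2)
    o <- stats::optim(start, obj, method = "L-BFGS-B",
                      lower = lower, upper = upper)
    fit <- list(par = stats::setNames(o$par, c("a", "mu", "sigma")),
                converged = o$convergence == 0)
  }
  p <- fit$par
  yhat <- gauss(p, d)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(amplitude = unname(p["a"]), mu = unname(p["mu"]),
         sigma = unname(p["sigma"]), r_squared = r2,
         converged = isTRUE(fit$converged), raw_peak = max(y),
         data = data.frame(delay_ms = d, y = y, fitted = yhat)),
    class = "agency_fit"
  )
}

#' @export
print.agency_fit <- function(x, ...) {
  cat("Gaussian agency-curve fit\n")
  cat(sprintf("  t_PSE (mu)   : %.1f ms\n", x$mu))
  cat(sprintf("  peak value a : %.4f  (raw curve max %.4f)\n",
              x$amplitude, x$raw_peak))
  cat(sprintf("  curve SD     : %.1f ms\n", x$sigma))
  cat(sprintf("  R-squared    : %.4f%s\n", x$r_squared,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
summary.agency_fit <- function(object, ...) {
  res <- object$data$y - object$data$fitted
  out <- list(fit = object, n_delays = nrow(object$data),
              rmse = sqrt(mean(res^2)))
  class(out) <- "summary.agency_fit"
  out
}

#' @export
print.summary.agency_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d sampled delays, residual RMSE %.4f\n",
              x$n_delays, x$rmse))
  invisible(x)
}

#' @export
coef.agency_fit <- function(object, ...) {
  c(amplitude = object$amplitude, mu = object$mu, sigma = object$sigma)
}

#' @export
fitted.agency_fit <- function(object, ...) object$data$fitted

#' @export
residuals.agency_fit <- function(object, ...)
  object$data$y - object$data$fitted

#' @export
predict.agency_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$delay_ms else {
    if (is.data.frame(newdata)) newdata$delay_ms else as.numeric(newdata)
  }
  object$amplitude * exp(-(d - object$mu)^2 / (2 * object$sigma^2))
}

#' @export
plot.agency_fit <- function(x, ...) {
  d <- x$data$delay_ms
  grid <- seq(min(d), max(d), length.out = 200)
  plot(d, x$data$y, xlab = "action-effect delay (ms)",
       ylab = "normalized self responses", pch = 19, ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue", lwd = 2)
  graphics::abline(v = x$mu, lty = 2, col = "grey50")
  invisible(x)
}

#' Derive the behavioural indices from a fitted agency curve
#'
#' Copies t_PSE (mu), the curve peak value (fitted amplitude) and the curve
#' SD out of the fit and applies the goodness-of-fit exclusion rule:
#' subjects whose curve fits below \code{r2_min} are flagged invalid and
#' dropped from downstream correlation and regression analyses.
#'
#' @param fit An \code{agency_fit}.
#' @param r2_min Minimum R-squared for a subject to be retained
#'   (default 0.30).
#' @return A one-row data.frame: \code{t_pse_ms}, \code{peak_value},
#'   \code{curve_sd_ms}, \code{raw_peak}, \code{r_squared}, \code{valid}.
#' @export
derive_indices <- function(fit, r2_min = 0.30) {
  stopifnot(inherits(fit, "agency_fit"))
  data.frame(t_pse_ms = fit$mu,
             peak_value = fit$amplitude,
             curve_sd_ms = fit$sigma,
             raw_peak = fit$raw_peak,
             r_squared = fit$r_squared,
             valid = isTRUE(fit$converged) &&
               is.finite(fit$r_squared) && fit$r_squared >= r2_min)
}

#' Behavioural indices for every subject in a trial log
#'
#' Convenience wrapper: splits a multi-subject trial log, aggregates and
#' fits each subject's curve, and derives the indices.
#'
#' @param trials Trial log data.frame (any number of subjects).
#' @param r2_min Exclusion threshold passed to \code{\link{derive_indices}}.
#' @return Data.frame with one row per subject (column \code{subject_id}
#'   first), ordered by subject id.
#' @export
behavioral_indices <- function(trials, r2_min = 0.30) {
  parts <- split(trials, trials$subject_id)
  rows <- lapply(names(parts), function(sid) {
    fit <- fit_agency_curve(aggregate_curve(parts[[sid]]))
    cbind(subject_id = sid, derive_indices(fit, r2_min = r2_min))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
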