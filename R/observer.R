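#' Construct a logistic observer for the agency attribution task
#'
#' An observer model maps an action-effect delay to the probability of a
#' "self" (full control) attribution in the two-alternative forced-choice
#' task. The psychometric function is a decreasing logistic with an optional
#' lapse rate:
#' \deqn{P(\mathrm{self} \mid d) = (1 - \lambda)\,
#'   \frac{1}{1 + e^{(d - \mathrm{pse})/\beta}} + \lambda/2}
#' so that at \code{d = pse_obs} (with no lapse) the observer attributes the
#' effect to itself with probability one half.
#'
#' @param pse_obs Delay in ms at which P(self) = 0.5 (the observer's
#'   subjective point of equality).
#' @param slope_beta Logistic scale parameter in ms; must be positive.
#'   Smaller values give steeper attenuation of the sense of agency.
#' @param lapse Probability in \[0, 0.1\] of a uniformly random response
#'   (half of which lands on each alternative).
#' @return An object of class \code{observer_model}.
#' @examples
#' obs <- make_observer(625, 100)
#' p_self(obs, 625)   # 0.5 by definition
#' p_self(obs, 1620)  # near 0: long delays are attributed to the computer
#' @export
make_observer <- function(pse_obs, slope_beta, lapse = 0) {
  stopifnot(is.numeric(pse_obs), length(pse_obs) == 1L, is.finite(pse_obs))
  if (!is.numeric(slope_beta) || length(slope_beta) != 1L || slope_beta <= 0)
    stop("`slope_beta` must be a single positive number (ms)", call. = FALSE)
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse > 0.1)
    stop("`lapse` must be a probability in [0, 0.1]", call. = FALSE)
  structure(
    list(pse_obs = as.numeric(pse_obs),
         slope_beta = as.numeric(slope_beta),
         lapse = as.numeric(lapse)),
    class = "observer_model"
  )
}

#' Probability of a self attribution at given delays
#'
#' @param observer An \code{observer_model}.
#' @param delay_ms Numeric vector of action-effect delays in ms.
#' @return Probabilities in (0, 1), strictly decreasing in delay for
#'   \code{lapse < 1}.
#' @export
p_self <- function(observer, delay_ms) {
  stopifnot(inherits(observer, "observer_model"))
  core <- 1 / (1 + exp((delay_ms - observer$pse_obs) / observer$slope_beta))
  (1 - observer$lapse) * core + observer$lapse / 2
}

#' Delay at which the observer's P(self) equals a target probability
#'
#' Inverts the lapse-corrected logistic. Used to locate the staircase
#' equilibrium delay d* where P(self | d*) equals the weighted up-down
#' convergence probability.
#'
#' @param observer An \code{observer_model}.
#' @param p Target probability; must lie strictly inside the observer's
#'   attainable range \code{(lapse/2, 1 - lapse/2)}.
#' @return Delay in ms.
#' @export
delay_at_p <- function(observer, p) {
  stopifnot(inherits(observer, "observer_model"))
  lo <- observer$lapse / 2
  hi <- 1 - observer$lapse / 2
  if (any(p <= lo | p >= hi))
    stop("target probability outside the observer's attainable range",
         call. = FALSE)
  core <- (p - lo) / (1 - observer$lapse)
  observer$pse_obs + observer$slope_beta * log(1 / core - 1)
}

#' @export
print.observer_model <- function(x, ...) {
  cat("Logistic observer: PSE =", x$pse_obs, "ms, slope =", x$slope_beta,
      "ms, lapse =", x$lapse, "\n")
  invisible(x)
}
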