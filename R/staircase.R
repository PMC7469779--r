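#' Configuration of the interleaved weighted up-down staircase
#'
#' Defaults reproduce the agency attribution task: the action-effect delay
#' is increased by 90 ms after a "self" response and decreased by 180 ms
#' after a "computer" response, over a 90-1620 ms range, with a descending
#' procedure starting at 1620 ms and an ascending one starting at 90 ms,
#' 70 trials each (140 in total).
#'
#' @param step_up Delay increment (ms) after a self response.
#' @param step_down Delay decrement (ms) after a computer response.
#' @param start_descending,start_ascending Starting delays (ms) of the two
#'   interleaved procedures.
#' @param trials_per_procedure Trials run per procedure.
#' @param delay_min,delay_max Bounds of the delay range (ms); delays are
#'   clamped (saturated) at the bounds.
#' @return An object of class \code{staircase_config}.
#' @export
staircase_config <- function(step_up = 90, step_down = 180,
                             start_descending = 1620, start_ascending = 90,
                             trials_per_procedure = 70,
                             delay_min = 90, delay_max = 1620) {
  if (step_up <= 0 || step_down <= 0)
    stop("step sizes must be positive", call. = FALSE)
  if (delay_min > delay_max)
    stop("`delay_min` must not exceed `delay_max`", call. = FALSE)
  for (s in c(start_descending, start_ascending))
    if (s < delay_min || s > delay_max)
      stop("starting delays must lie within [delay_min, delay_max]",
           call. = FALSE)
  if (trials_per_procedure < 1)
    stop("`trials_per_procedure` must be at least 1", call. = FALSE)
  structure(
    list(step_up = step_up, step_down = step_down,
         start_descending = start_descending,
         start_ascending = start_ascending,
         trials_per_procedure = as.integer(trials_per_procedure),
         delay_min = delay_min, delay_max = delay_max),
    class = "staircase_config"
  )
}

#' One weighted up-down step
#'
#' A "self" response increases the delay by \code{step_up}; a "computer"
#' response decreases it by \code{step_down}. The result is clamped to the
#' configured delay range.
#'
#' @param current Current delay (ms), within the configured bounds.
#' @param response \code{"self"} or \code{"computer"}.
#' @param cfg A \code{staircase_config}.
#' @return Next delay (ms).
#' @examples
#' cfg <- staircase_config()
#' step_delay(900, "self", cfg)      # 990
#' step_delay(900, "computer", cfg)  # 720
#' @export
step_delay <- function(current, response, cfg = staircase_config()) {
  stopifnot(inherits(cfg, "staircase_config"))
  if (current < cfg$delay_min || current > cfg$delay_max)
    stop("`current` delay outside the configured range", call. = FALSE)
  response <- match.arg(response, c("self", "computer"))
  nxt <- if (response == "self") current + cfg$step_up else current - cfg$step_down
  min(max(nxt, cfg$delay_min), cfg$delay_max)
}

#' Equilibrium probability of a weighted up-down staircase
#'
#' The staircase drifts upward with probability p (a self response, step
#' +\code{step_up}) and downward with probability 1-p (step
#' -\code{step_down}); expected drift vanishes when
#' \eqn{p \cdot S_{up} = (1 - p) \cdot S_{down}}, i.e. at
#' \eqn{p^* = S_{down} / (S_{up} + S_{down})}. For the default 90/180 ms
#' steps this is 2/3: the track converges on the delay where the observer
#' still reports self-agency two times in three.
#'
#' @param step_up,step_down Positive step sizes (ms).
#' @return The convergence probability p*.
#' @examples
#' equilibrium_probability(90, 180)  # 2/3
#' @export
equilibrium_probability <- function(step_up = 90, step_down = 180) {
  if (step_up <= 0 || step_down <= 0)
    stop("step sizes must be positive", call. = FALSE)
  step_down / (step_up + step_down)
}

#' Run an interleaved staircase session against an observer
#'
#' Simulates the full agency attribution session: two independent weighted
#' up-down tracks (descending from 1620 ms, ascending from 90 ms), their
#' 140 trial slots interleaved by a seeded uniform shuffle. Each trial's
#' delay is determined by the previous outcome of its own track via
#' \code{\link{step_delay}}; the response is drawn from the observer's
#' psychometric function.
#'
#' @param observer An \code{\link{make_observer}} model.
#' @param cfg A \code{\link{staircase_config}}.
#' @param seed Integer seed controlling both the interleaving shuffle and
#'   the simulated responses.
#' @param subject_id Label recorded on each trial.
#' @return A data.frame of trial records with columns \code{subject_id},
#'   \code{trial_index}, \code{procedure} (\code{"ascending"} /
#'   \code{"descending"}), \code{delay_ms} and \code{response}.
#' @export
run_session <- function(observer, cfg = staircase_config(), seed,
                        subject_id = "s01") {
  stopifnot(inherits(observer, "observer_model"),
            inherits(cfg, "staircase_config"))
  if (missing(seed)) stop("`seed` is required for a reproducible session",
                          call. = FALSE)
  n <- cfg$trials_per_procedure
  total <- 2L * n
  # local RNG: sessions do not disturb the caller's RNG state
  runner <- function() {
    order_proc <- sample(rep(c("descending", "ascending"), each = n))
    state <- c(descending = cfg$start_descending,
               ascending = cfg$start_ascending)
    delay <- numeric(total)
    resp <- character(total)
    for (i in seq_len(total)) {
      pr <- order_proc[i]
      d <- state[[pr]]
      delay[i] <- d
      r <- if (stats::runif(1) < p_self(observer, d)) "self" else "computer"
      resp[i] <- r
      state[[pr]] <- step_delay(d, r, cfg)
    }
    data.frame(subject_id = subject_id,
               trial_index = seq_len(total),
               procedure = order_proc,
               delay_ms = delay,
               response = resp,
               stringsAsFactors = FALSE)
  }
  with_seed(seed, runner())
}

# Evaluate `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
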