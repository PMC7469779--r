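#' Specification of a synthetic behavioural + connectome cohort
#'
#' Bundles the ground-truth parameters of a simulated study: logistic
#' observers performing the staircase task, trait covariates with planted
#' correlations to the observers' true PSE, and per-subject ROI time
#' series with block community structure and (optionally) one node whose
#' community coupling tracks a behavioural index across subjects.
#'
#' Defaults emulate the study design this package targets: 37 analyzable
#' subjects, 100 ROIs grouped in 7 networks, 240 timepoints at TR = 3 s.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param trait_names Labels of the trait covariates.
#' @param trait_behavior_correlations Named numeric vector (one entry per
#'   trait): target Pearson correlation between the trait and the
#'   observers' true PSE.
#' @param planted_node ROI index (1-based) carrying the planted
#'   brain-behavior effect, or NA for none.
#' @param planted_metric Which node metric the effect is planted in
#'   (\code{"degree"}, \code{"clustering"} or \code{"betweenness"}; the
#'   planted mechanism shifts the node's community coupling, which moves
#'   all three, most directly degree strength).
#' @param effect_rho Target across-subject correlation between the planted
#'   node's community coupling and the behavioural index; |effect_rho| <= 1.
#' @param n_rois,n_timepoints,tr_seconds,n_modules Connectome dimensions.
#' @param r_within,r_between Within- and between-community correlation
#'   levels of the block model.
#' @param planted_amplitude Half-range (correlation units) of the planted
#'   node's community-coupling modulation across subjects.
#' @param pse_mean,pse_sd Mean and SD (ms) of observers' true PSE.
#' @param slope_mean,slope_sd Mean and SD (ms) of observers' logistic
#'   slope.
#' @param lapse Observers' lapse rate.
#' @param seed Master seed; per-subject streams are derived by fixed
#'   offsets.
#' @return List of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 37,
                        trait_names = c("harm_avoidance", "cooperativeness",
                                        "self_directedness"),
                        trait_behavior_correlations =
                          stats::setNames(c(0, 0, 0), trait_names),
                        planted_node = NA_integer_,
                        planted_metric = c("degree", "clustering",
                                           "betweenness"),
                        effect_rho = 0,
                        n_rois = 100, n_timepoints = 240, tr_seconds = 3,
                        n_modules = 7,
                        r_within = 0.30, r_between = 0.05,
                        planted_amplitude = 0.25,
                        pse_mean = 600, pse_sd = 150,
                        slope_mean = 100, slope_sd = 20,
                        lapse = 0.02,
                        seed = 1L) {
  planted_metric <- match.arg(planted_metric)
  if (n_subjects < 4) stop("need at least 4 subjects", call. = FALSE)
  if (abs(effect_rho) > 1) stop("|effect_rho| must be <= 1", call. = FALSE)
  if (length(trait_behavior_correlations) != length(trait_names))
    stop("one target correlation per trait is required", call. = FALSE)
  if (any(abs(trait_behavior_correlations) >= 1))
    stop("trait-behavior correlations must lie strictly inside (-1, 1)",
         call. = FALSE)
  if (!is.na(planted_node) &&
      (planted_node < 1 || planted_node > n_rois))
    stop("`planted_node` must be an ROI index in 1..n_rois", call. = FALSE)
  names(trait_behavior_correlations) <- trait_names
  structure(
    list(n_subjects = as.integer(n_subjects), trait_names = trait_names,
         trait_behavior_correlations = trait_behavior_correlations,
         planted_node = planted_node, planted_metric = planted_metric,
         effect_rho = effect_rho,
         n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds, n_modules = as.integer(n_modules),
         r_within = r_within, r_between = r_between,
         planted_amplitude = planted_amplitude,
         pse_mean = pse_mean, pse_sd = pse_sd,
         slope_mean = slope_mean, slope_sd = slope_sd, lapse = lapse,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Repair a symmetric matrix into a valid correlation matrix: clip
# eigenvalues at a small positive floor and rescale to unit diagonal.
psd_repair <- function(C, floor = 1e-6) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < floor) {
    v <- pmax(e$values, floor)
    C <- e$vectors %*% (v * t(e$vectors))
    C <- stats::cov2cor(C)
  }
  C
}

#' Simulate the behavioural half of a cohort
#'
#' Draws observer parameters and trait scores jointly via a Gaussian
#' copula: a latent standard normal drives the observer's true PSE, and
#' each trait is generated with the target correlation to that latent
#' (traits conditionally independent given the latent; the implied
#' correlation matrix is PSD-repaired if the targets make it indefinite).
#' Trait scores are left as standardized (z-scale) variables.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return Data.frame with one row per subject: \code{subject_id},
#'   \code{pse_obs}, \code{slope_beta}, \code{lapse}, and one column per
#'   trait.
#' @export
simulate_behavioral_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$trait_names)
  rho <- as.numeric(spec$trait_behavior_correlations)
  # latent order: (pse driver, traits...)
  C <- diag(k + 1)
  C[1, -1] <- rho
  C[-1, 1] <- rho
  C <- psd_repair(C)
  L <- chol(C)
  with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(spec$n_subjects * (k + 1)), ncol = k + 1) %*% L
    u_slope <- stats::rnorm(spec$n_subjects)
    pse <- spec$pse_mean + spec$pse_sd * Z[, 1]
    pse <- pmin(pmax(pse, 150), 1450)   # keep observers inside the task range
    slope <- pmax(spec$slope_mean + spec$slope_sd * u_slope, 40)
    out <- data.frame(subject_id = sprintf("s%03d", seq_len(spec$n_subjects)),
                      pse_obs = pse, slope_beta = slope, lapse = spec$lapse)
    for (j in seq_len(k)) out[[spec$trait_names[j]]] <- Z[, j + 1]
    out
  })
}

#' Simulate staircase trial logs for a behavioural cohort
#'
#' Runs \code{\link{run_session}} for each subject's observer, with a
#' per-subject seed derived from the master seed by a fixed offset.
#'
#' @param cohort Output of \code{\link{simulate_behavioral_cohort}}.
#' @param spec The generating \code{\link{cohort_spec}}.
#' @param cfg A \code{\link{staircase_config}}.
#' @return One trial-log data.frame covering all subjects.
#' @export
simulate_trial_logs <- function(cohort, spec, cfg = staircase_config()) {
  logs <- lapply(seq_len(nrow(cohort)), function(i) {
    obs <- make_observer(cohort$pse_obs[i], cohort$slope_beta[i],
                         cohort$lapse[i])
    run_session(obs, cfg, seed = spec$seed + 1000L + i,
                subject_id = cohort$subject_id[i])
  })
  do.call(rbind, logs)
}

#' Module (community) assignment of the ROIs
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return Integer vector of length n_rois with community ids 1..n_modules
#'   (contiguous, nearly equal blocks).
#' @export
roi_modules <- function(spec) {
  sort(rep_len(seq_len(spec$n_modules), spec$n_rois))
}

# Subject-level target correlation matrix of the block model, with the
# planted node's within-community correlations shifted by `shift`.
block_correlation <- function(spec, shift = 0) {
  mods <- roi_modules(spec)
  C <- matrix(spec$r_between, spec$n_rois, spec$n_rois)
  same <- outer(mods, mods, "==")
  C[same] <- spec$r_within
  diag(C) <- 1
  if (!is.na(spec$planted_node) && shift != 0) {
    pn <- spec$planted_node
    mates <- which(mods == mods[pn] & seq_along(mods) != pn)
    r_new <- min(max(spec$r_within + shift, 0.02), 0.90)
    C[pn, mates] <- r_new
    C[mates, pn] <- r_new
  }
  psd_repair(C)
}

#' Simulate per-subject ROI time series with a planted effect
#'
#' Each subject's series is a zero-mean multivariate normal draw whose
#' correlation matrix follows the block community model; for the planted
#' node, its within-community correlation level is shifted by
#' \code{planted_amplitude * u_j}, where \eqn{u_j = \rho z_j +
#' \sqrt{1-\rho^2}\,e_j} mixes the subject's standardized behavioural
#' index \eqn{z_j} with independent noise at mixing weight
#' \code{effect_rho}, and the result is clipped to keep the matrix a valid
#' correlation matrix (eigenvalue-floored and rescaled if needed).
#' Deterministic under the spec's seed.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param behavior Numeric vector (length n_subjects): the behavioural
#'   index values the planted effect should track.
#' @return Named list (by subject id) of \code{\link{roi_timeseries}};
#'   attribute \code{"ground_truth"} records the planted parameters and
#'   the per-subject coupling shifts.
#' @export
simulate_connectome_cohort <- function(spec, behavior) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(behavior) != spec$n_subjects)
    stop("`behavior` must have one value per subject", call. = FALSE)
  z <- as.numeric(scale(behavior))
  rho <- spec$effect_rho
  noise <- with_seed(spec$seed + 500000L,
                     stats::rnorm(spec$n_subjects))
  u <- rho * z + sqrt(max(0, 1 - rho^2)) * noise
  shifts <- if (is.na(spec$planted_node)) rep(0, spec$n_subjects)
            else spec$planted_amplitude * u
  ids <- sprintf("s%03d", seq_len(spec$n_subjects))
  labels <- sprintf("ROI_%03d", seq_len(spec$n_rois))
  out <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    C <- block_correlation(spec, shift = shifts[i])
    L <- tryCatch(chol(C), error = function(e)
      stop("subject ", ids[i],
           ": correlation matrix not positive definite after repair",
           call. = FALSE))
    X <- with_seed(spec$seed + 2000L + i, {
      matrix(stats::rnorm(spec$n_timepoints * spec$n_rois),
             ncol = spec$n_rois) %*% L
    })
    colnames(X) <- labels
    out[[i]] <- roi_timeseries(X, labels = labels,
                               tr_seconds = spec$tr_seconds)
  }
  names(out) <- ids
  attr(out, "ground_truth") <- list(
    planted_node = if (is.na(spec$planted_node)) NULL
                   else labels[spec$planted_node],
    planted_metric = spec$planted_metric,
    effect_rho = rho,
    coupling_shift = shifts,
    modules = roi_modules(spec))
  out
}
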