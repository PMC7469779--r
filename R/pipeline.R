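#' Configuration of the end-to-end pipeline
#'
#' Collects every stage's settings in one object. In simulation mode the
#' cohort spec supplies all inputs; in analysis mode the trial log, ROI
#' matrix directory and covariate table paths must point at existing
#' files. All defaults mirror the task's printed constants: 90/180 ms
#' steps, 70 + 70 trials, screen at p < .05, F-to-enter 4, tolerance
#' cutoff 0.30, FDR 0.05, exclusion at R-squared < 0.30.
#'
#' @param out_dir Output directory (created if absent).
#' @param spec A \code{\link{cohort_spec}} (simulation mode) or NULL.
#' @param trial_log,roi_dir,covariates Paths to existing inputs (analysis
#'   mode); ignored in simulation mode.
#' @param staircase A \code{\link{staircase_config}}.
#' @param stepwise A \code{\link{stepwise_config}}.
#' @param r2_min Fit-quality exclusion threshold.
#' @param fdr_q FDR level for the correlation stage.
#' @param band Band-pass limits in Hz.
#' @param behavior_index Behavioural index column driving the
#'   brain-behavior stage (default \code{"peak_value"}).
#' @param metric Node metric regressed on behaviour (default
#'   \code{"degree"}).
#' @param seed Master seed (mandatory in simulation mode).
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, spec = NULL,
                            trial_log = NULL, roi_dir = NULL,
                            covariates = NULL,
                            staircase = staircase_config(),
                            stepwise = stepwise_config(),
                            r2_min = 0.30, fdr_q = 0.05,
                            band = c(0.01, 0.25),
                            behavior_index = "peak_value",
                            metric = c("degree", "clustering",
                                       "betweenness"),
                            seed = NULL) {
  metric <- match.arg(metric)
  simulate <- !is.null(spec)
  if (simulate) {
    stopifnot(inherits(spec, "cohort_spec"))
    if (is.null(seed)) seed <- spec$seed
  } else {
    for (p in c(trial_log, covariates))
      if (!is.null(p) && !file.exists(p))
        stop("input file not found: ", p, call. = FALSE)
    if (!is.null(roi_dir) && !dir.exists(roi_dir))
      stop("ROI directory not found: ", roi_dir, call. = FALSE)
  }
  structure(
    list(out_dir = out_dir, spec = spec, simulate = simulate,
         trial_log = trial_log, roi_dir = roi_dir,
         covariates = covariates, staircase = staircase,
         stepwise = stepwise, r2_min = r2_min, fdr_q = fdr_q,
         band = band, behavior_index = behavior_index, metric = metric,
         seed = seed),
    class = "pipeline_config"
  )
}

#' Run the agency-connectome pipeline
#'
#' Stages (selectable, default all that apply):
#' \describe{
#'   \item{simulate-cohort}{generate observers, traits, trial logs and ROI
#'     matrices from the cohort spec; write them plus a ground-truth
#'     sidecar}
#'   \item{fit-behavior}{aggregate and fit each subject's agency curve,
#'     write the behavioural indices table}
#'   \item{correlate}{Fisher r-to-z correlations of indices with
#'     covariates under BH-FDR}
#'   \item{connectome-metrics}{per-subject node metrics and percolation
#'     threshold tau}
#'   \item{brain-behavior}{screen + tolerance filter + forward stepwise
#'     on the configured (index, metric) pair}
#' }
#' A manifest (JSON) recording the seed and the configuration is written
#' alongside the outputs; identical config + seed reproduce identical
#' output files.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param stages Character vector of stage names, or \code{"run-all"}.
#' @return Named list of stage results, invisibly; outputs are written
#'   under \code{config$out_dir}.
#' @export
run_pipeline <- function(config, stages = "run-all") {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate-cohort", "fit-behavior", "correlate",
                  "connectome-metrics", "brain-behavior")
  if (identical(stages, "run-all")) {
    stages <- if (config$simulate) all_stages else all_stages[-1]
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  trial_path <- file.path(config$out_dir, "trial_log.csv")
  cov_path <- file.path(config$out_dir, "covariates.csv")
  roi_dir <- file.path(config$out_dir, "roi_matrices")

  if ("simulate-cohort" %in% stages) {
    if (!config$simulate)
      stop("stage simulate-cohort requires a cohort spec", call. = FALSE)
    spec <- config$spec
    cohort <- simulate_behavioral_cohort(spec)
    logs <- simulate_trial_logs(cohort, spec, config$staircase)
    write_trial_log(logs, trial_path)
    utils::write.csv(cohort[, c("subject_id", spec$trait_names)],
                     cov_path, row.names = FALSE, quote = FALSE)
    # plant the connectome effect against the observers' true PSE
    conn <- simulate_connectome_cohort(spec, cohort$pse_obs)
    dir.create(roi_dir, showWarnings = FALSE)
    for (sid in names(conn))
      write_roi_matrix(conn[[sid]],
                       file.path(roi_dir, paste0(sid, ".tsv")))
    gt <- attr(conn, "ground_truth")
    gt$true_pse <- cohort$pse_obs
    gt$true_slope <- cohort$slope_beta
    jsonlite::write_json(gt,
                         file.path(config$out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("[simulate-cohort] seed %d: %d subjects, %d trials, %d ROI matrices",
                    config$seed, nrow(cohort), nrow(logs), length(conn)))
    res$cohort <- cohort
    res$ground_truth <- gt
    config$trial_log <- trial_path
    config$covariates <- cov_path
    config$roi_dir <- roi_dir
  }

  if ("fit-behavior" %in% stages) {
    logs <- read_trial_log(config$trial_log %||% trial_path,
                           config$staircase)
    idx <- behavioral_indices(logs, r2_min = config$r2_min)
    n_excl <- sum(!idx$valid)
    message(sprintf("[fit-behavior] %d subjects fitted, %d excluded at R2 < %.2f",
                    nrow(idx), n_excl, config$r2_min))
    utils::write.csv(format_num(idx),
                     file.path(config$out_dir, "behavioral_indices.csv"),
                     row.names = FALSE, quote = FALSE)
    res$indices <- idx
  }

  if ("correlate" %in% stages) {
    if (is.null(res$indices))
      res$indices <- utils::read.csv(
        file.path(config$out_dir, "behavioral_indices.csv"))
    covs <- utils::read.csv(config$covariates %||% cov_path)
    ct <- correlation_table(res$indices, covs, q = config$fdr_q)
    utils::write.csv(format_num(ct),
                     file.path(config$out_dir, "correlations.csv"),
                     row.names = FALSE, quote = FALSE)
    message(sprintf("[correlate] %d pairs tested, %d significant at FDR %.2f",
                    nrow(ct), sum(ct$significant), config$fdr_q))
    res$correlations <- ct
  }

  if ("connectome-metrics" %in% stages) {
    rd <- config$roi_dir %||% roi_dir
    files <- sort(list.files(rd, full.names = TRUE))
    if (!length(files)) stop("no ROI matrices found in ", rd, call. = FALSE)
    per_subject <- lapply(files, function(f) {
      ts <- read_roi_matrix(f, tr_seconds =
                              if (!is.null(config$spec))
                                config$spec$tr_seconds else 3)
      m <- connectome_metrics(ts, band = config$band)
      sid <- sub("\\.[^.]+$", "", basename(f))
      cbind(subject_id = sid, m, tau = attr(m, "tau"))
    })
    metrics <- do.call(rbind, per_subject)
    utils::write.csv(format_num(metrics),
                     file.path(config$out_dir, "node_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    message(sprintf("[connectome-metrics] %d subjects x %d nodes; mean tau %.4f",
                    length(per_subject), length(unique(metrics$node)),
                    mean(metrics$tau)))
    res$node_metrics <- metrics
  }

  if ("brain-behavior" %in% stages) {
    if (is.null(res$node_metrics))
      res$node_metrics <- utils::read.csv(
        file.path(config$out_dir, "node_metrics.csv"))
    if (is.null(res$indices))
      res$indices <- utils::read.csv(
        file.path(config$out_dir, "behavioral_indices.csv"))
    idx <- res$indices[res$indices$valid %in% c(TRUE, "TRUE"), ]
    M <- metric_matrix(res$node_metrics, config$metric,
                       subjects = idx$subject_id)
    beh <- idx[[config$behavior_index]]
    run <- brain_behavior_run(M, beh, config$stepwise)
    utils::write.csv(format_num(run$screen),
                     file.path(config$out_dir, "screen_table.csv"),
                     row.names = FALSE, quote = FALSE)
    report <- list(
      behavior_index = config$behavior_index, metric = config$metric,
      n_subjects = nrow(M),
      screened = run$screen$node[run$screen$passed],
      tolerance = as.list(run$tolerance),
      candidates = run$candidates,
      selected = if (!is.null(run$model)) run$model$selected else character(0),
      model = if (!is.null(run$model))
        list(r2 = run$model$r2, adj_r2 = run$model$adj_r2,
             f_stat = run$model$f_stat, df = run$model$df,
             p = run$model$p,
             coefficients = as.list(run$model$coefficients))
      else NULL)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "stepwise_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message(sprintf("[brain-behavior] %s ~ %s: %d screened, %d selected",
                    config$behavior_index, config$metric,
                    sum(run$screen$passed), length(report$selected)))
    res$brain_behavior <- run
  }

  manifest <- list(seed = config$seed, stages = stages,
                   simulate = config$simulate,
                   r2_min = config$r2_min, fdr_q = config$fdr_q,
                   band = config$band, metric = config$metric,
                   behavior_index = config$behavior_index,
                   staircase = unclass(config$staircase),
                   stepwise = unclass(config$stepwise),
                   cohort_spec = if (config$simulate)
                     unclass(config$spec) else NULL)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

# subjects x nodes matrix of one metric type from the long metrics table
metric_matrix <- function(node_metrics, metric, subjects = NULL) {
  wide <- stats::reshape(
    node_metrics[, c("subject_id", "node", metric)],
    idvar = "subject_id", timevar = "node", direction = "wide")
  rownames(wide) <- wide$subject_id
  wide$subject_id <- NULL
  colnames(wide) <- sub(paste0("^", metric, "\\."), "", colnames(wide))
  M <- as.matrix(wide)
  if (!is.null(subjects)) M <- M[as.character(subjects), , drop = FALSE]
  M
}

# fixed-width numeric formatting so pipeline CSVs are byte-stable
format_num <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
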