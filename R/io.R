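#' Write a trial log to CSV
#'
#' Columns: subject_id, trial_index, procedure, delay_ms, response.
#'
#' @param trials Trial-log data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials[, c("subject_id", "trial_index", "procedure",
                              "delay_ms", "response")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trial log
#'
#' Enforces the header, the response domain (self/computer), the
#' procedure domain, and the configured delay range. Delays off the
#' staircase lattice (not reachable from the start values by the step
#' sizes) raise a warning naming the rows but are kept.
#'
#' @param path CSV path.
#' @param cfg A \code{\link{staircase_config}} used for range and lattice
#'   checks.
#' @return Validated trial-log data.frame (all subjects).
#' @export
read_trial_log <- function(path, cfg = staircase_config()) {
  if (!file.exists(path)) stop("trial log not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "trial_index", "procedure", "delay_ms", "response")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("trial log missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_resp <- which(!df$response %in% c("self", "computer"))
  if (length(bad_resp))
    stop("unknown response token at row(s) ",
         paste(utils::head(bad_resp, 5), collapse = ", "), call. = FALSE)
  bad_proc <- which(!df$procedure %in% c("ascending", "descending"))
  if (length(bad_proc))
    stop("unknown procedure at row(s) ",
         paste(utils::head(bad_proc, 5), collapse = ", "), call. = FALSE)
  out_of_range <- which(df$delay_ms < cfg$delay_min |
                          df$delay_ms > cfg$delay_max)
  if (length(out_of_range))
    stop("delay outside [", cfg$delay_min, ", ", cfg$delay_max,
         "] at row(s) ", paste(utils::head(out_of_range, 5), collapse = ", "),
         call. = FALSE)
  g <- gcd2(cfg$step_up, cfg$step_down)
  off_lattice <- which((df$delay_ms - cfg$delay_min) %% g != 0)
  if (length(off_lattice))
    warning("delay off the staircase lattice at row(s) ",
            paste(utils::head(off_lattice, 5), collapse = ", "),
            "; records kept")
  df
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Write an ROI time-series matrix as delimited text
#'
#' Tab-delimited, header row of ROI labels, one row per timepoint.
#'
#' @param ts A \code{\link{roi_timeseries}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_roi_matrix <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  utils::write.table(ts$matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an ROI time-series matrix
#'
#' Expects delimited text with a header row of ROI labels and a numeric
#' body; ragged rows, non-numeric cells and NaN values are rejected.
#'
#' @param path File path.
#' @param tr_seconds Repetition time in seconds.
#' @param sep Field separator (default tab; whitespace also accepted).
#' @return A \code{\link{roi_timeseries}}.
#' @export
read_roi_matrix <- function(path, tr_seconds = 3, sep = "\t") {
  if (!file.exists(path)) stop("ROI matrix not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      check.names = FALSE, colClasses = "numeric"),
    error = function(e)
      stop("failed to parse ROI matrix ", path, ": ", conditionMessage(e),
           call. = FALSE))
  m <- as.matrix(df)
  if (anyNA(m)) stop("ROI matrix contains missing/non-numeric cells",
                     call. = FALSE)
  roi_timeseries(m, labels = colnames(m), tr_seconds = tr_seconds)
}

#' Read an ROI parcel table
#'
#' Optional metadata mapping ROI labels to networks and centroid
#' coordinates; CSV with columns label, network, x, y, z.
#'
#' @param path CSV path.
#' @return Data.frame with those columns.
#' @export
read_parcel_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "network", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("parcel table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  df
}
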