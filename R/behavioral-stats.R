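#' Fisher r-to-z test for a Pearson correlation
#'
#' Variance-stabilizing transform: \eqn{z = \mathrm{atanh}(r)\sqrt{n - 3}},
#' compared against the standard normal for a two-tailed p-value.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n Sample size, at least 4.
#' @return List with \code{z} and \code{p}. For |r| = 1 the statistic is
#'   infinite and p = 0.
#' @examples
#' fisher_r_to_z(0.9, 12)   # z = atanh(0.9) * 3
#' @export
fisher_r_to_z <- function(r, n) {
  if (!is.numeric(r) || abs(r) > 1) stop("|r| must be <= 1", call. = FALSE)
  if (n < 4) stop("need n >= 4 for the Fisher transform", call. = FALSE)
  z <- atanh(r) * sqrt(n - 3)
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(z = z, p = p)
}

#' Benjamini-Hochberg adjusted p-values and rejections
#'
#' Standard step-up false discovery rate control; adjusted p-values via
#' \code{stats::p.adjust(method = "BH")}, rejections at adjusted p <= q.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with \code{p_fdr} (adjusted p-values, monotone-enforced)
#'   and \code{reject} (logical flags).
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L)
    return(list(p_fdr = numeric(0), reject = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p_fdr <- stats::p.adjust(pvals, method = "BH")
  list(p_fdr = p_fdr, reject = !is.na(p_fdr) & p_fdr <= q)
}

#' Correlate behavioural indices with covariates under FDR control
#'
#' Pearson correlation of each behavioural index with each covariate,
#' tested with the Fisher r-to-z transform; all index-by-covariate pairs
#' submitted in one call form a single Benjamini-Hochberg family (the
#' family scope is whatever the caller passes). Only subjects flagged
#' \code{valid} enter; missing data are handled pairwise-complete.
#' Degenerate pairs (a constant covariate, or |r| numerically 1) are
#' reported but excluded from the FDR family.
#'
#' @param indices Data.frame from \code{\link{behavioral_indices}} (needs
#'   \code{subject_id}, \code{valid}, and the index columns).
#' @param covariates Data.frame with \code{subject_id} and numeric
#'   covariate columns (trait scores, task accuracies, ...).
#' @param index_cols Index columns to test (default the three behavioural
#'   indices).
#' @param q FDR level.
#' @return Data.frame with one row per pair: \code{index}, \code{covariate},
#'   \code{n}, \code{r}, \code{z}, \code{p}, \code{p_fdr},
#'   \code{significant}, \code{degenerate}.
#' @export
correlation_table <- function(indices, covariates,
                              index_cols = c("t_pse_ms", "peak_value",
                                             "curve_sd_ms"),
                              q = 0.05) {
  stopifnot("subject_id" %in% names(indices),
            "subject_id" %in% names(covariates))
  if ("valid" %in% names(indices)) indices <- indices[indices$valid, ]
  merged <- merge(indices, covariates, by = "subject_id")
  cov_cols <- setdiff(names(covariates), "subject_id")
  cov_cols <- cov_cols[vapply(merged[cov_cols], is.numeric, logical(1))]

  rows <- list()
  for (ix in index_cols) {
    for (cv in cov_cols) {
      x <- merged[[ix]]; yv <- merged[[cv]]
      ok <- is.finite(x) & is.finite(yv)
      n <- sum(ok)
      if (n < 4) {
        rows[[length(rows) + 1L]] <- data.frame(
          index = ix, covariate = cv, n = n, r = NA_real_, z = NA_real_,
          p = NA_real_, degenerate = TRUE)
        next
      }
      sx <- stats::sd(x[ok]); sy <- stats::sd(yv[ok])
      if (sx == 0 || sy == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          index = ix, covariate = cv, n = n, r = NA_real_, z = NA_real_,
          p = NA_real_, degenerate = TRUE)
        next
      }
      r <- stats::cor(x[ok], yv[ok])
      if (abs(r) >= 1 - 1e-12) {
        rows[[length(rows) + 1L]] <- data.frame(
          index = ix, covariate = cv, n = n, r = r, z = Inf * sign(r),
          p = 0, degenerate = TRUE)
        next
      }
      fz <- fisher_r_to_z(r, n)
      rows[[length(rows) + 1L]] <- data.frame(
        index = ix, covariate = cv, n = n, r = r, z = fz$z, p = fz$p,
        degenerate = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  out$significant <- FALSE
  fam <- !out$degenerate & !is.na(out$p)
  if (any(fam)) {
    adj <- bh_adjust(out$p[fam], q = q)
    out$p_fdr[fam] <- adj$p_fdr
    out$significant[fam] <- adj$reject
  }
  out[, c("index", "covariate", "n", "r", "z", "p", "p_fdr",
          "significant", "degenerate")]
}
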