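#' QC thresholds for sample-level quality control
#'
#' Any metric set to `NULL` is disabled. `min_detected` applies to the count
#' of probes with detection p below `detection_alpha`; `housekeeping_ids`
#' names the probes averaged into the housekeeping signal (the probe list is
#' platform-specific and therefore a configuration item).
#'
#' @param min_detected minimum number of significantly detected probes.
#' @param min_mean_signal minimum per-sample mean signal.
#' @param min_p95_signal minimum per-sample 95th-percentile signal.
#' @param min_housekeeping minimum mean signal over `housekeeping_ids`.
#' @param housekeeping_ids character vector of probe ids.
#' @param detection_alpha detection p-value cutoff (default 0.01).
#' @export
qc_thresholds <- function(min_detected = NULL, min_mean_signal = NULL,
                          min_p95_signal = NULL, min_housekeeping = NULL,
                          housekeeping_ids = NULL, detection_alpha = 0.01) {
  list(min_detected = min_detected, min_mean_signal = min_mean_signal,
       min_p95_signal = min_p95_signal, min_housekeeping = min_housekeeping,
       housekeeping_ids = housekeeping_ids, detection_alpha = detection_alpha)
}

#' Sample-level quality control
#'
#' Computes per-sample QC metrics -- number of significantly detected probes,
#' mean signal, 95th-percentile signal, housekeeping signal -- and drops
#' samples failing any enabled threshold.
#'
#' @param raw expression matrix of raw intensities.
#' @param detection_p optional matrix of detection p-values (same dim as
#'   `raw`); when absent the detection metric is skipped with a warning if
#'   enabled.
#' @param thresholds a [qc_thresholds()] list.
#' @return list with `report` (per-sample metrics and pass flags) and `expr`
#'   (the matrix restricted to passing samples).
#' @export
qc_samples <- function(raw, detection_p = NULL, thresholds = qc_thresholds()) {
  th <- thresholds
  n_detected <- if (!is.null(detection_p)) {
    stopifnot(all(dim(detection_p) == dim(raw)))
    colSums(detection_p < th$detection_alpha)
  } else rep(NA_integer_, ncol(raw))
  report <- data.frame(
    sample_id = colnames(raw),
    n_detected = n_detected,
    mean_signal = colMeans(raw),
    p95_signal = apply(raw, 2, stats::quantile, probs = 0.95, names = FALSE),
    housekeeping_signal = if (!is.null(th$housekeeping_ids)) {
      ids <- intersect(th$housekeeping_ids, rownames(raw))
      if (!length(ids)) stop("no housekeeping probes found in matrix")
      colMeans(raw[ids, , drop = FALSE])
    } else NA_real_,
    stringsAsFactors = FALSE)
  pass <- function(metric, cut) {
    if (is.null(cut)) return(rep(TRUE, length(metric)))
    is.na(metric) | metric >= cut
  }
  if (!is.null(th$min_detected) && all(is.na(n_detected)))
    warning("detection threshold enabled but no detection p-values supplied; ",
            "metric skipped")
  report$pass_detected <- pass(report$n_detected, th$min_detected)
  report$pass_mean <- pass(report$mean_signal, th$min_mean_signal)
  report$pass_p95 <- pass(report$p95_signal, th$min_p95_signal)
  report$pass_housekeeping <- pass(report$housekeeping_signal,
                                   th$min_housekeeping)
  report$pass <- report$pass_detected & report$pass_mean & report$pass_p95 &
    report$pass_housekeeping
  if (!any(report$pass)) stop("all samples fail quality control")
  if (any(!report$pass))
    message("dropping ", sum(!report$pass), " sample(s) failing QC: ",
            paste(report$sample_id[!report$pass], collapse = ", "))
  expr <- raw[, report$pass, drop = FALSE]
  attr(expr, "feature_kind") <- feature_kind(raw)
  list(report = report, expr = expr)
}

#' Log-transform and quantile-normalize an expression matrix
#'
#' Applies `x -> log2(x + offset)` (the variance-stabilizing step; if
#' `x + offset` is not strictly positive the offset is raised to
#' `1 - min(x)` with a message) followed by quantile normalization against
#' the mean of the sorted per-sample vectors (ties receive the mean of their
#' tied reference values). After the step every sample's sorted value vector
#' equals the reference vector, and the operation is idempotent.
#'
#' @param raw expression matrix of raw intensities (>= 2 samples).
#' @param log_offset additive offset before `log2` (default 1).
#' @param log_transform set `FALSE` for data already on a log scale.
#' @return normalized expression matrix.
#' @export
transform_normalize <- function(raw, log_offset = 1, log_transform = TRUE) {
  if (ncol(raw) < 2)
    stop("quantile normalization needs at least 2 samples")
  if (any(is.na(raw)))
    stop("missing values present; impute (impute_missing) before normalizing")
  x <- unclass(raw)
  if (log_transform) {
    if (min(x) + log_offset <= 0) {
      log_offset <- 1 - min(x)
      message("raising log offset to ", format(log_offset),
              " to keep arguments positive")
    }
    x <- log2(x + log_offset)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(raw)
  expression_matrix(out, feature_kind(raw))
}

#' Remove low-variance features
#'
#' Drops the fraction of features with the lowest expression variance across
#' the cohort (bottom 33% for the miRNA panel, bottom 90% for the
#' whole-genome matrix in the motivating analysis). The retained count is
#' `ceiling((1 - drop_fraction) * n_features)`; variance ties are broken by
#' feature-id lexicographic order so the result is deterministic. Input
#' feature order is preserved among retained features.
#'
#' @param expr normalized expression matrix.
#' @param drop_fraction fraction to drop, in `[0, 1)`.
#' @return filtered expression matrix.
#' @export
variance_filter <- function(expr, drop_fraction) {
  if (drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in [0, 1)")
  if (drop_fraction == 0) return(expr)
  v <- apply(expr, 1, stats::var)
  n_keep <- ceiling((1 - drop_fraction) * nrow(expr))
  ord <- order(-v, rownames(expr), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])
  out <- unclass(expr)[keep, , drop = FALSE]
  expression_matrix(out, feature_kind(expr))
}
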