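#' Univariate Cox proportional-hazards feature screening
#'
#' Fits a single-covariate Cox model (Efron tie handling) to every feature
#' and reports the log hazard ratio, HR with 95% Wald CI, Wald p-value and
#' Benjamini-Hochberg q-value. Features with zero variance are skipped with
#' a warning. Selection keeps features with `wald_p < p_threshold`.
#'
#' @param expr expression matrix (features x samples), normalized.
#' @param times event/censoring times (length = samples, strictly positive).
#' @param events 0/1 event indicators; at least 2 events required.
#' @param p_threshold Wald p-value selection cutoff (default 0.01, the
#'   screening level of the motivating recurrence/survival analysis).
#' @return data.frame of class `"feature_surv_stats"`: `feature_id`, `coef`,
#'   `hr`, `hr_lo`, `hr_hi`, `wald_p`, `fdr_q`, `selected`, ordered as the
#'   input features; attribute `"selected"` carries the selected ids.
#' @export
cox_univariate_screen <- function(expr, times, events, p_threshold = 0.01) {
  stopifnot(length(times) == ncol(expr), length(events) == ncol(expr))
  if (sum(events) < 2) stop("need at least 2 events for Cox screening")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0))
    warning(sum(v == 0), " zero-variance feature(s) skipped: ",
            paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  y <- survival::Surv(times, events)
  ctrl <- survival::coxph.control()
  fit_one <- function(x) {
    # near-separation draws a routine "coefficient may be infinite" warning
    # at screening scale; such features get p ~ 1 from the flat Wald test
    f <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(matrix(x, ncol = 1), y, strata = NULL,
                            offset = NULL, init = 0, control = ctrl,
                            weights = NULL, method = "efron",
                            rownames = NULL)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$coefficients) || !is.finite(f$var[1]))
      return(c(NA_real_, NA_real_))
    c(f$coefficients[1], sqrt(f$var[1, 1]))
  }
  res <- matrix(NA_real_, nrow(expr), 2)
  idx <- which(v > 0)
  for (i in idx) res[i, ] <- fit_one(expr[i, ])
  coef <- res[, 1]; se <- res[, 2]
  wald_p <- stats::pchisq((coef / se)^2, df = 1, lower.tail = FALSE)
  out <- data.frame(
    feature_id = rownames(expr),
    coef = coef, hr = exp(coef),
    hr_lo = exp(coef - 1.96 * se), hr_hi = exp(coef + 1.96 * se),
    wald_p = wald_p,
    fdr_q = NA_real_,
    stringsAsFactors = FALSE)
  tested <- !is.na(wald_p)
  out$fdr_q[tested] <- stats::p.adjust(wald_p[tested], method = "BH")
  out$selected <- tested & wald_p < p_threshold
  attr(out, "selected") <- out$feature_id[out$selected]
  attr(out, "p_threshold") <- p_threshold
  class(out) <- c("feature_surv_stats", "data.frame")
  out
}
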