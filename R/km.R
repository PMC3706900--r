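#' Kaplan-Meier curves, median survival and log-rank test
#'
#' Product-limit estimates per group, the group medians (smallest time at
#' which estimated survival drops to 0.5 or below, `NA` = "not reached"),
#' and the log-rank test (2 or more groups).
#'
#' @param groups factor of group labels (>= 2 non-empty groups).
#' @param times,events survival outcome.
#' @return list with `fit` (a `survfit`), `median` (named vector, `NA` for
#'   "not reached"), `chisq`, `df`, `p`.
#' @export
km_logrank <- function(groups, times, events) {
  groups <- droplevels(factor(groups))
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need at least 2 non-empty groups")
  y <- survival::Surv(times, events)
  fit <- survival::survfit(y ~ groups)
  tab <- summary(fit)$table
  med <- if (is.matrix(tab)) tab[, "median"] else tab[["median"]]
  names(med) <- sub("^groups=", "", names(med) %||% levels(groups))
  sd <- tryCatch(survival::survdiff(y ~ groups), error = function(e) NULL)
  if (is.null(sd)) {
    chisq <- 0; df <- nlevels(groups) - 1
  } else {
    chisq <- unname(sd$chisq)
    df <- length(sd$n) - 1
  }
  list(fit = fit, median = med, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox model of risk group and clinical covariates
#'
#' Adjusted hazard ratios for the dichotomized expression risk group in the
#' presence of known prognostic factors (chemoresponse, metastasis at
#' diagnosis, regimen, ...). Complete confounding -- the risk group constant
#' within the strata of a categorical covariate -- is reported as an error
#' naming the collinear term.
#'
#' @param risk_group factor with levels `low`/`high` (or any 2 levels,
#'   first = reference).
#' @param covariates data.frame of covariates (binary/continuous/factor).
#' @param times,events survival outcome.
#' @return data.frame: `term`, `hr`, `hr_lo`, `hr_hi`, `p` (Wald).
#' @export
cox_groups_multivariate <- function(risk_group, covariates, times, events) {
  risk_group <- droplevels(factor(risk_group))
  if (nlevels(risk_group) != 2) stop("risk_group must be binary")
  df <- data.frame(risk_group = risk_group, covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    vf <- if (is.numeric(v) && length(unique(v)) > 2) NULL else factor(v)
    if (!is.null(vf)) {
      tab <- table(risk_group, vf)
      if (any(rowSums(tab > 0) <= 1) || any(colSums(tab > 0) <= 1))
        stop("complete confounding between risk_group and '", nm, "'")
    }
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ .,
                         data = df, ties = "efron")
  beta <- stats::coef(fit)
  if (any(is.na(beta)))
    stop("collinear term(s) in multivariate Cox model: ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  data.frame(term = names(beta), hr = exp(beta),
             hr_lo = exp(beta - 1.96 * se), hr_hi = exp(beta + 1.96 * se),
             p = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine expression risk group and chemoresponse into a 3-level category
#'
#' `poor` = high-risk profile and unfavorable (suboptimal) chemoresponse;
#' `good` = low-risk profile and favorable (optimal) chemoresponse;
#' `intermediate` = exactly one adverse factor. Samples missing either label
#' are excluded with a message.
#'
#' @param risk_group factor `low`/`high`.
#' @param chemoresponse ordered factor `suboptimal`/`optimal`.
#' @return factor with levels `poor < intermediate < good` (`NA` where a
#'   label was missing).
#' @export
combine_risk_chemo <- function(risk_group, chemoresponse) {
  risk_group <- factor(risk_group, levels = c("low", "high"))
  chemoresponse <- factor(chemoresponse, levels = c("suboptimal", "optimal"))
  adverse <- (risk_group == "high") + (chemoresponse == "suboptimal")
  out <- factor(c("good", "intermediate", "poor")[adverse + 1],
                levels = c("poor", "intermediate", "good"), ordered = TRUE)
  if (anyNA(out))
    message(sum(is.na(out)), " sample(s) missing a label excluded from the ",
            "combined category")
  out
}

#' Kaplan-Meier / log-rank analysis on a cohort subset
#'
#' Applies [km_logrank()] to the samples satisfying `keep` (e.g. the
#' non-metastatic stratum, or patients on a single regimen).
#'
#' @param groups,times,events as in [km_logrank()].
#' @param keep logical vector selecting the subset.
#' @return the [km_logrank()] result on the restricted cohort.
#' @export
subset_km <- function(groups, times, events, keep) {
  stopifnot(length(keep) == length(times))
  keep <- keep & !is.na(keep)
  if (!any(keep)) stop("restriction leaves no samples")
  if (sum(keep) < 2) stop("restriction leaves fewer than 2 samples")
  if (sum(events[keep]) < 2) stop("restriction leaves fewer than 2 events")
  km_logrank(groups[keep], times[keep], events[keep])
}
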