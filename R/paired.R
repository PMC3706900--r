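#' Paired pre/post-chemotherapy differential expression
#'
#' Per-feature paired t-test on the (post - pre) differences across
#' biopsy/resection pairs, with BH FDR. Features with zero difference
#' variance are assigned p = 1 (with a warning) when the mean difference is
#' also zero; a zero-variance nonzero shift is reported as p = 0 and
#' flagged. Samples without a complete pair are ignored with a warning.
#'
#' @param pre_expr,post_expr expression matrices (features x samples) sharing
#'   their feature space.
#' @param pairs data.frame with columns `biopsy` and `resection` naming the
#'   paired columns (see [clinical_pairs()]).
#' @param alpha significance level for the reported hit list (default 0.001,
#'   the level of the motivating paired analysis).
#' @return data.frame `feature_id`, `mean_diff`, `statistic`, `p`, `fdr_q`,
#'   `direction`, `significant`, `flagged`; attribute `"n_pairs"`.
#' @export
paired_differential <- function(pre_expr, post_expr, pairs, alpha = 0.001) {
  stopifnot(identical(rownames(pre_expr), rownames(post_expr)))
  ok <- pairs$biopsy %in% colnames(pre_expr) &
    pairs$resection %in% colnames(post_expr)
  if (any(!ok))
    warning(sum(!ok), " pair(s) with missing samples ignored")
  pairs <- pairs[ok, , drop = FALSE]
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 complete pairs")
  d <- unclass(post_expr)[, pairs$resection, drop = FALSE] -
    unclass(pre_expr)[, pairs$biopsy, drop = FALSE]
  md <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  stat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(stat), df = n - 1, lower.tail = FALSE)
  flagged <- sdd == 0
  if (any(flagged)) {
    warning(sum(flagged), " feature(s) with zero difference variance")
    stat[flagged] <- ifelse(md[flagged] == 0, 0, sign(md[flagged]) * Inf)
    p[flagged] <- ifelse(md[flagged] == 0, 1, 0)
  }
  out <- data.frame(feature_id = rownames(d), mean_diff = md,
                    statistic = stat, p = p,
                    fdr_q = stats::p.adjust(p, "BH"),
                    direction = ifelse(md >= 0, "up", "down"),
                    significant = p < alpha, flagged = flagged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- n
  out
}
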