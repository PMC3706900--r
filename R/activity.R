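#' Per-gene outcome-group statistics
#'
#' Welch two-sample t statistic and p-value for every gene between two
#' outcome groups (e.g. high vs low predicted recurrence risk), with BH FDR.
#' Genes with zero variance in both groups receive statistic 0, p 1, and a
#' flag.
#'
#' @param mrna expression matrix (genes x samples).
#' @param groups factor with exactly 2 non-empty levels; the statistic is
#'   oriented as `level2 - level1`.
#' @return data.frame of class `"gene_outcome_stats"`: `gene_id`,
#'   `statistic`, `df`, `p`, `fdr_q`, `flagged`.
#' @export
gene_outcome_stats <- function(mrna, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2 || any(table(groups) < 2))
    stop("need 2 groups with at least 2 samples each")
  g1 <- unclass(mrna)[, groups == levels(groups)[1], drop = FALSE]
  g2 <- unclass(mrna)[, groups == levels(groups)[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((g2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  flagged <- se2 == 0
  stat[flagged] <- 0; p[flagged] <- 1; df[flagged] <- NA
  out <- data.frame(gene_id = rownames(mrna), statistic = stat, df = df,
                    p = p, fdr_q = stats::p.adjust(p, "BH"),
                    flagged = flagged, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_outcome_stats", "data.frame")
  out
}

#' Regulatory-effects (RE) score of one miRNA
#'
#' Contrasts the outcome association of a miRNA's target genes against all
#' non-target genes: the score is the standardized difference between the
#' mean per-gene statistic of the (measured) targets and that of the
#' background,
#' `(mean(t_targets) - mean(t_background)) / (sd(t_all) * sqrt(1/nT + 1/nB))`,
#' with a two-sided permutation p-value from `n_perm` random reassignments
#' of target membership over the measured genes (add-one convention).
#'
#' @param target_genes character vector of target gene ids (pre- or
#'   post-intersection; intersected with the measured genes here).
#' @param stats_tab a [gene_outcome_stats()] table.
#' @param n_perm membership permutations (default 1000).
#' @param seed RNG seed.
#' @param min_set_size minimum post-intersection set size (default 5;
#'   permutation nulls are unstable below this).
#' @return list `re_score`, `p`, `set_size` (post-intersection).
#' @export
re_score <- function(target_genes, stats_tab, n_perm = 1000, seed = 1,
                     min_set_size = 5) {
  t_all <- stats_tab$statistic
  is_t <- stats_tab$gene_id %in% target_genes
  nT <- sum(is_t); nB <- sum(!is_t)
  if (nT < min_set_size)
    stop("target set below min_set_size after intersection (", nT, " < ",
         min_set_size, ")")
  if (nB == 0) stop("target set covers every measured gene; no background")
  score_fun <- function(mask) {
    (mean(t_all[mask]) - mean(t_all[!mask])) /
      (stats::sd(t_all) * sqrt(1 / nT + 1 / nB))
  }
  obs <- score_fun(is_t)
  set.seed(seed)
  perm <- replicate(n_perm, {
    mask <- logical(length(t_all))
    mask[sample(length(t_all), nT)] <- TRUE
    score_fun(mask)
  })
  list(re_score = obs, p = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm),
       set_size = nT)
}

#' RE scores for a whole target-set collection
#'
#' Applies [re_score()] to every set (sets below `min_set_size` after
#' intersection are skipped with a message) and controls the FDR across the
#' scored miRNAs by BH. A miRNA is called significantly differentially
#' activated when `p < 0.05` and `fdr_q < 0.1`.
#'
#' @param sets a [target_sets()] collection.
#' @inheritParams re_score
#' @return data.frame of class `"re_result"`: `mirna`, `source`, `set_size`,
#'   `re_score`, `p`, `fdr_q`, `significant`.
#' @export
re_score_all <- function(sets, stats_tab, n_perm = 1000, seed = 1,
                         min_set_size = 5) {
  sets <- intersect_target_sets(sets, stats_tab$gene_id, min_set_size)
  if (!length(sets)) stop("no target set survives the size filter")
  rows <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    r <- re_score(s$genes, stats_tab, n_perm, seed = seed + i,
                  min_set_size = min_set_size)
    data.frame(mirna = s$mirna, source = s$source, set_size = r$set_size,
               re_score = r$re_score, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$p < 0.05 & out$fdr_q < 0.1
  class(out) <- c("re_result", "data.frame")
  out
}

#' Random-set gene set analysis (GSA) of target sets
#'
#' For each target set, the LS statistic (mean of `-log(p_g)` over the set)
#' and the KS statistic (Kolmogorov-Smirnov distance of the set's p-values
#' from uniform), each with a random-set significance level: the fraction of
#' `n_null_sets` same-size gene sets drawn from the measured universe whose
#' statistic is at least the observed one.
#'
#' @param sets a [target_sets()] collection.
#' @param stats_tab a [gene_outcome_stats()] table.
#' @param n_null_sets random sets per observed set (default 1000).
#' @param seed RNG seed.
#' @param min_set_size minimum post-intersection set size.
#' @return data.frame: `mirna`, `source`, `set_size`, `ls`, `ls_p`, `ks`,
#'   `ks_p`.
#' @export
gsa_target_sets <- function(sets, stats_tab, n_null_sets = 1000, seed = 1,
                            min_set_size = 5) {
  sets <- intersect_target_sets(sets, stats_tab$gene_id, min_set_size)
  if (!length(sets)) stop("no target set survives the size filter")
  pg <- stats::setNames(stats_tab$p, stats_tab$gene_id)
  ls_stat <- function(p) mean(-log(pmax(p, 1e-300)))
  ks_stat <- function(p) {
    s <- sort(p); n <- length(s)
    max(pmax(seq_len(n) / n - s, s - (seq_len(n) - 1) / n))
  }
  set.seed(seed)
  rows <- lapply(sets, function(s) {
    p_set <- pg[s$genes]
    obs_ls <- ls_stat(p_set); obs_ks <- ks_stat(p_set)
    null_ls <- numeric(n_null_sets); null_ks <- numeric(n_null_sets)
    for (b in seq_len(n_null_sets)) {
      draw <- pg[sample(length(pg), length(p_set))]
      null_ls[b] <- ls_stat(draw); null_ks[b] <- ks_stat(draw)
    }
    data.frame(mirna = s$mirna, source = s$source, set_size = length(p_set),
               ls = obs_ls, ls_p = mean(null_ls >= obs_ls),
               ks = obs_ks, ks_p = mean(null_ks >= obs_ks),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Cluster samples on target-gene expression and test risk-group association
#'
#' Agglomerative hierarchical clustering of the samples restricted to the
#' given target genes (distance 1 - Pearson correlation, average linkage by
#' default -- the common expression-profile convention), cut into `k`
#' clusters, followed by Fisher's exact test of cluster membership against
#' the risk-group labels.
#'
#' @param mrna expression matrix (genes x samples).
#' @param target_genes gene ids defining the submatrix (intersected with the
#'   measured genes).
#' @param risk_group factor of per-sample labels.
#' @param k number of clusters (default 2).
#' @param linkage `hclust` agglomeration method (default `"average"`).
#' @return list `cluster` (integer labels), `fisher_p`, `table`, `hclust`.
#' @export
cluster_samples_on_targets <- function(mrna, target_genes, risk_group, k = 2,
                                       linkage = "average") {
  genes <- intersect(target_genes, rownames(mrna))
  if (!length(genes)) stop("no target genes measured")
  if (k > ncol(mrna)) stop("k exceeds the number of samples")
  sub <- unclass(mrna)[genes, , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(sub))
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  tab <- table(cluster = cl, risk = risk_group)
  ft <- stats::fisher.test(tab)
  list(cluster = cl, fisher_p = ft$p.value, table = tab, hclust = hc)
}

#' Supervised risk model on miRNA target genes
#'
#' Runs the supervised principal-components machinery on the mRNA matrix
#' restricted to a set of target genes -- the "do the targets carry the
#' signal" counterpart of the miRNA risk model.
#'
#' @param mrna expression matrix (genes x samples).
#' @param target_genes gene ids to restrict to.
#' @param times,events survival outcome.
#' @param cross_validate fit via [cross_validated_risk()] (default) or a
#'   single [fit_spc()] model.
#' @param ... passed through to the fitting routine.
#' @return the [cross_validated_risk()] or [fit_spc()] result.
#' @export
target_gene_risk_model <- function(mrna, target_genes, times, events,
                                   cross_validate = TRUE, ...) {
  genes <- intersect(target_genes, rownames(mrna))
  if (!length(genes)) stop("no target genes measured")
  sub <- expression_matrix(unclass(mrna)[genes, , drop = FALSE], "mRNA")
  if (cross_validate) cross_validated_risk(sub, times, events, ...)
  else fit_spc(sub, times, events, ...)
}
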