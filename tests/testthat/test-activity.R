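test_that("gene statistics vanish when the two groups are identical", {
  x <- unclass(rand_expr(20, 6, seed = 1, kind = "mRNA", prefix = "G"))
  both <- cbind(x, x)
  colnames(both) <- sprintf("S%03d", 1:12)
  both <- expression_matrix(both, "mRNA")
  g <- factor(rep(c("low", "high"), each = 6), levels = c("low", "high"))
  st <- gene_outcome_stats(both, g)
  expect_true(all(abs(st$statistic) < 1e-12))
  expect_true(all(st$p == 1))
})

test_that("the Welch statistic matches the reference implementation", {
  set.seed(2)
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  g <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  st <- gene_outcome_stats(expression_matrix(m, "mRNA"), g)
  for (i in 1:2) {
    tt <- t.test(m[i, 3:4], m[i, 1:2])  # high minus low, Welch
    expect_lt(abs(st$statistic[i] - unname(tt$statistic)), 1e-9)
    expect_lt(abs(st$p[i] - tt$p.value), 1e-9)
  }
})

test_that("planted between-group shifts are detected at the study's mRNA scale", {
  power <- vapply(1:25, function(s) {
    set.seed(s)
    n <- 37  # biopsies passing whole-genome QC
    g <- factor(rep(c("low", "high"), length.out = n),
                levels = c("low", "high"))
    m <- matrix(rnorm(500 * n), 500, n,
                dimnames = list(sprintf("G%03d", 1:500), sprintf("S%02d", 1:n)))
    m[1:30, g == "high"] <- m[1:30, g == "high"] + 1
    st <- gene_outcome_stats(expression_matrix(m, "mRNA"), g)
    mean(st$p[1:30] < 0.05)
  }, numeric(1))
  expect_gte(mean(power), 0.7)
})

test_that("the RE score is invariant to relabeling of non-target genes", {
  set.seed(3)
  stats_tab <- data.frame(gene_id = sprintf("G%03d", 1:100),
                          statistic = rnorm(100), p = runif(100))
  targets <- sprintf("G%03d", 1:10)
  r1 <- re_score(targets, stats_tab, n_perm = 200, seed = 5)
  # permute the identities (and statistics) of background genes only
  perm <- stats_tab
  bg <- 11:100
  shuffle <- sample(bg)
  perm$statistic[bg] <- stats_tab$statistic[shuffle]
  r2 <- re_score(targets, perm, n_perm = 200, seed = 5)
  expect_equal(r1$re_score, r2$re_score, tolerance = 1e-12)
})

test_that("degenerate target sets are routed to errors", {
  stats_tab <- data.frame(gene_id = sprintf("G%03d", 1:50),
                          statistic = rnorm(50), p = runif(50))
  expect_error(re_score(stats_tab$gene_id, stats_tab), "background")
  expect_error(re_score(stats_tab$gene_id[1:3], stats_tab), "min_set_size")
})

test_that("decoy sets are calibrated and planted repression is detected", {
  set.seed(6)
  n_genes <- 800
  stats_tab <- data.frame(gene_id = sprintf("G%04d", 1:n_genes),
                          statistic = rnorm(n_genes),
                          p = runif(n_genes))
  # calibration: 60 random decoy sets of size 40
  ps <- vapply(1:60, function(i) {
    re_score(sample(stats_tab$gene_id, 40), stats_tab, n_perm = 200,
             seed = i)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0)
  expect_lte(mean(ps < 0.05), 0.15)
  # power: targets shifted by -0.5 SD
  hits <- vapply(1:20, function(i) {
    set.seed(100 + i)
    tab <- stats_tab
    idx <- sample(n_genes, 50)
    tab$statistic[idx] <- tab$statistic[idx] - 0.5
    re_score(tab$gene_id[idx], tab, n_perm = 200, seed = i)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.75)
})

test_that("RE significance combines the p and FDR rules across a collection", {
  co <- small_cohort(seed = 7)
  b <- biopsies(co)
  idx <- co$truth$prognostic_index
  g <- factor(ifelse(idx > median(idx), "high", "low"),
              levels = c("low", "high"))
  st <- gene_outcome_stats(co$mrna, g)
  suppressMessages(re <- re_score_all(co$target_sets, st, n_perm = 200,
                                      seed = 1))
  expect_true(all(re$p > 0 & re$p <= 1))
  expect_identical(re$significant, re$p < 0.05 & re$fdr_q < 0.1)
  # the planted (repression-coupled) sets should dominate the significant calls
  if (any(re$significant))
    expect_gte(mean(re$mirna[re$significant] %in% co$truth$prognostic_ids),
               0.5)
})

test_that("GSA returns zero LS for uninformative sets and enumerates correctly", {
  genes <- sprintf("G%02d", 1:10)
  stats_tab <- data.frame(gene_id = genes, statistic = 0, p = rep(1, 10))
  sets <- target_sets(list(s1 = genes[1:3]))
  res <- suppressMessages(gsa_target_sets(sets, stats_tab, n_null_sets = 50,
                                          seed = 1, min_set_size = 3))
  expect_equal(res$ls, 0, tolerance = 1e-12)
  expect_gte(res$ls_p, 0.99)

  # tiny-universe agreement with exhaustive enumeration
  set.seed(8)
  p_named <- setNames(runif(10)^2, genes)
  stats_tab2 <- data.frame(gene_id = genes, statistic = rnorm(10),
                           p = unname(p_named))
  sets2 <- target_sets(list(s1 = genes[c(1, 4, 7)]))
  res2 <- suppressMessages(gsa_target_sets(sets2, stats_tab2,
                                           n_null_sets = 4000, seed = 2,
                                           min_set_size = 3))
  exact <- ls_enumeration_p(genes[c(1, 4, 7)], p_named)
  mc_se <- sqrt(max(exact * (1 - exact), 0.25 / 4000) / 4000)
  expect_lt(abs(res2$ls_p - exact), 2 * max(mc_se, 0.02))
})

test_that("Fisher exact association matches the hypergeometric closed form", {
  cl <- rep(1:2, each = 10)
  risk <- rep(c("low", "high"), each = 10)
  tab <- table(cl, risk)
  p_pkg <- fisher.test(tab)$p.value
  expect_lt(abs(p_pkg - 2 / choose(20, 10)), 1e-12)
})

test_that("clustering recovers planted sample blobs aligned with risk", {
  set.seed(9)
  n_genes <- 60
  # each blob carries its own gene signature; the signatures are opposite,
  # so within-blob correlation is high and across-blob correlation negative
  m <- matrix(rnorm(n_genes * 20), n_genes, 20)
  pattern <- rep(c(3, -3), each = n_genes / 2)
  m[, 1:10] <- m[, 1:10] + pattern
  m[, 11:20] <- m[, 11:20] - pattern
  dimnames(m) <- list(sprintf("G%03d", 1:n_genes), sprintf("S%02d", 1:20))
  risk <- factor(rep(c("low", "high"), each = 10), levels = c("low", "high"))
  res <- cluster_samples_on_targets(expression_matrix(m, "mRNA"),
                                    rownames(m), risk, k = 2)
  expect_equal(length(unique(res$cluster[1:10])), 1)
  expect_equal(length(unique(res$cluster[11:20])), 1)
  expect_lt(res$fisher_p, 0.01)
  expect_error(cluster_samples_on_targets(expression_matrix(m, "mRNA"),
                                          rownames(m), risk, k = 25),
               "exceeds")
})

test_that("target-gene risk models run on the coupled submatrix", {
  co <- small_cohort(seed = 11)
  b <- biopsies(co)
  target_genes <- unique(unlist(lapply(co$truth$prognostic_ids, function(m)
    co$target_sets[[m]]$genes)))
  model <- target_gene_risk_model(co$mrna, target_genes, b$rfs_time,
                                  b$rfs_event, cross_validate = FALSE,
                                  p_threshold = 0.05)
  expect_s3_class(model, "spc_model")
  expect_true(all(model$features %in% target_genes))
  # submatrix restriction preserves sample order
  cv <- suppressMessages(
    target_gene_risk_model(co$mrna, target_genes, b$rfs_time, b$rfs_event,
                           p_threshold = 0.05, n_folds = 5, seed = 2))
  expect_identical(cv$sample_id, colnames(co$mrna))
})

test_that("coupled target genes carry a weaker but real prognostic signal", {
  hits <- vapply(1:10, function(s) {
    co <- small_cohort(seed = 300 + s)
    b <- biopsies(co)
    target_genes <- unique(unlist(lapply(co$truth$prognostic_ids, function(m)
      co$target_sets[[m]]$genes)))
    cv <- suppressMessages(
      target_gene_risk_model(co$mrna, target_genes, b$rfs_time, b$rfs_event,
                             p_threshold = 0.01, n_folds = 5, seed = s))
    km_logrank(cv$risk_group, b$rfs_time, b$rfs_event)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.3)
})
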