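test_that("AP with m = 1 equals the single best univariate model per split", {
  co <- small_cohort(seed = 2)
  b <- biopsies(co)
  ap1 <- suppressMessages(ap_predict(b$chemoresponse, co$mirna, n_splits = 15,
                                     m = 1, seed = 7))
  mv1 <- suppressMessages(multivariate_olr_predict(b$chemoresponse, co$mirna,
                                                   n_features = 1,
                                                   n_splits = 15, seed = 7))
  expect_equal(ap1$accuracy, mv1$accuracy, tolerance = 1e-12)
})

test_that("the geometric mean is order-invariant and idempotent for equal models", {
  p1 <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, byrow = TRUE,
               dimnames = list(NULL, c("suboptimal", "optimal")))
  p2 <- matrix(c(0.5, 0.5, 0.1, 0.9), 2, byrow = TRUE,
               dimnames = list(NULL, c("suboptimal", "optimal")))
  g12 <- osteomir:::geometric_mean_probs(list(p1, p2))
  g21 <- osteomir:::geometric_mean_probs(list(p2, p1))
  expect_equal(g12, g21, tolerance = 1e-14)
  expect_equal(osteomir:::geometric_mean_probs(list(p1, p1, p1)), p1,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(g12)), c(1, 1), tolerance = 1e-14)
})

test_that("a zero probability cannot annihilate the ensemble", {
  p1 <- matrix(c(0, 1), 1, dimnames = list(NULL, c("a", "b")))
  p2 <- matrix(c(0.9, 0.1), 1, dimnames = list(NULL, c("a", "b")))
  g <- osteomir:::geometric_mean_probs(list(p1, p2))
  expect_true(all(is.finite(g)) && all(g > 0))
})

test_that("AP accuracy is near chance on a null cohort and high with planted signal", {
  null_co <- small_cohort(seed = 3, chemo_beta = 0)
  nb <- biopsies(null_co)
  ap_null <- suppressMessages(ap_predict(nb$chemoresponse, null_co$mirna,
                                         n_splits = 60, m = 5, seed = 1))
  expect_gte(ap_null$mean_accuracy, 0.35)
  expect_lte(ap_null$mean_accuracy, 0.65)

  co <- small_cohort(seed = 3)
  b <- biopsies(co)
  ap <- suppressMessages(ap_predict(b$chemoresponse, co$mirna,
                                    n_splits = 60, m = 5, seed = 1))
  expect_gte(ap$mean_accuracy, 0.70)
  expect_gte(mean(co$truth$chemo_ids %in%
                    names(sort(ap$selection_fraction, decreasing = TRUE)[1:5])),
             0.6)
})

test_that("aggregated per-sample probabilities are renormalized and complete", {
  co <- small_cohort(seed = 4)
  b <- biopsies(co)
  ap <- suppressMessages(ap_predict(b$chemoresponse, co$mirna, n_splits = 40,
                                    m = 3, seed = 2))
  covered <- !is.na(ap$sample_prob[, 1])
  expect_gt(mean(covered), 0.9)
  expect_equal(unname(rowSums(ap$sample_prob[covered, ])),
               rep(1, sum(covered)), tolerance = 1e-12)
  expect_true(all(ap$accuracy >= 0 & ap$accuracy <= 1))
})

test_that("AP input validation and determinism hold", {
  co <- small_cohort(seed = 5)
  b <- biopsies(co)
  expect_error(ap_predict(b$chemoresponse, co$mirna, train_fraction = 1.2),
               "train_fraction")
  a1 <- suppressMessages(ap_predict(b$chemoresponse, co$mirna, n_splits = 10,
                                    seed = 11))
  a2 <- suppressMessages(ap_predict(b$chemoresponse, co$mirna, n_splits = 10,
                                    seed = 11))
  expect_identical(a1$accuracy, a2$accuracy)
})

test_that("the two-feature multivariate model performs close to the AP ensemble", {
  co <- small_cohort(seed = 6)
  b <- biopsies(co)
  ap <- suppressMessages(ap_predict(b$chemoresponse, co$mirna, n_splits = 60,
                                    m = 5, seed = 3))
  mv <- suppressMessages(multivariate_olr_predict(b$chemoresponse, co$mirna,
                                                  n_features = 2,
                                                  n_splits = 60, seed = 3))
  # "almost as well": the small joint model tracks the ensemble and stays
  # well above chance, though two features recover a little less of the
  # correlated block than five averaged models
  expect_lt(abs(mv$mean_accuracy - ap$mean_accuracy), 0.15)
  expect_gte(mv$mean_accuracy, 0.7)
})

test_that("feature stability separates planted from noise features", {
  co <- small_cohort(seed = 7)
  b <- biopsies(co)
  st <- feature_stability(b$chemoresponse, co$mirna, n_subsets = 30, m = 5,
                          seed = 4)
  top_planted <- st$stability[st$feature_id %in% co$truth$chemo_ids]
  expect_gte(max(top_planted), 0.8)
  st2 <- feature_stability(b$chemoresponse, co$mirna, n_subsets = 30, m = 5,
                           seed = 4)
  expect_identical(st$stability, st2$stability)
  expect_error(feature_stability(b$chemoresponse, co$mirna, n_subsets = 5),
               "at least 10")
})

test_that("null-cohort stability spreads evenly at about m over n features", {
  co <- small_cohort(seed = 8, chemo_beta = 0)
  b <- biopsies(co)
  st <- feature_stability(b$chemoresponse, co$mirna, n_subsets = 30, m = 10,
                          seed = 5)
  expect_lt(abs(mean(st$stability) - 10 / nrow(co$mirna)), 0.03)
})

test_that("paired analysis is null on identical pre/post and detects planted shifts", {
  co <- small_cohort(seed = 9)
  pairs <- clinical_pairs(co$clinical)
  pre <- co$mirna
  same <- expression_matrix(unclass(pre)[, pairs$biopsy, drop = FALSE],
                            "miRNA")
  colnames(same) <- pairs$resection
  expect_warning(res0 <- paired_differential(pre, same, pairs),
                 "zero difference variance")
  expect_true(all(res0$p == 1))
  expect_false(any(res0$significant))

  res <- paired_differential(pre, co$mirna_post, pairs)
  expect_equal(attr(res, "n_pairs"), 26)
  planted <- res$significant[res$feature_id %in% co$truth$paired_shift_ids]
  expect_gte(mean(planted), 0.7)
  # type-I control on the unshifted features
  null_hits <- sum(res$significant[!res$feature_id %in%
                                     co$truth$paired_shift_ids])
  expect_lte(null_hits, qbinom(0.995, nrow(pre) - 20, 0.001) + 1)
})

test_that("incomplete pairs are ignored with a warning", {
  co <- small_cohort(seed = 10)
  pairs <- clinical_pairs(co$clinical)
  pairs$resection[1] <- "MISSING"
  expect_warning(res <- paired_differential(co$mirna, co$mirna_post, pairs),
                 "ignored")
  expect_equal(attr(res, "n_pairs"), 25)
  expect_error(paired_differential(co$mirna, co$mirna_post, pairs[1:3, ][0, ]),
               "at least 3")
})
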