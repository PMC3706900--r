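test_that("parameter validation rejects impossible configurations", {
  expect_error(sim_params(block_correlation = 1), "\\[0, 1\\)")
  expect_error(sim_params(n_prognostic = 10, n_mirna = 5), "exceeds")
  expect_error(sim_params(target_coupling = 0.2), "<= 0")
  expect_error(sim_params(baseline_rate = 0), "positive")
  expect_error(sim_params(n_categories = 1), "at least 2")
})

test_that("the prognostic block has the requested equicorrelation", {
  mean_block_cor <- function(rho, seed) {
    set.seed(seed)
    ex <- simulate_expression(sim_params(n_samples = 500, n_mirna = 50,
                                         n_mrna = 20, targets_per_mirna = 2,
                                         n_decoy_sets = 0,
                                         block_correlation = rho, seed = seed))
    cm <- cor(t(unclass(ex$mirna)[ex$truth$prognostic_ids, ]))
    mean(cm[upper.tri(cm)])
  }
  expect_lt(abs(mean_block_cor(0, 21)), 0.1)
  expect_lt(abs(mean_block_cor(0.6, 22) - 0.6), 0.05)
})

test_that("target genes are repressed by their planted miRNAs", {
  meds <- vapply(1:10, function(s) {
    set.seed(s)
    ex <- simulate_expression(small_params(seed = s))
    cors <- unlist(lapply(ex$truth$prognostic_ids, function(m) {
      tg <- ex$truth$target_sets[[m]]$genes
      cor(unclass(ex$mirna)[m, ], t(unclass(ex$mrna)[tg, ]))
    }))
    median(cors)
  }, numeric(1))
  expect_true(all(meds < 0))
  expect_lt(abs(median(meds) - (-0.5)), 0.1)
})

test_that("a univariate Cox fit on the true index recovers the planted log HR", {
  p <- sim_params(n_samples = 500, n_mirna = 30, n_mrna = 20,
                  targets_per_mirna = 2, n_decoy_sets = 0,
                  chemo_log_hr = 0, met_log_hr = 0, seed = 31)
  set.seed(p$seed)
  ex <- simulate_expression(p)
  sv <- simulate_survival(ex$mirna, p)
  fit <- survival::coxph(survival::Surv(sv$rfs_time, sv$rfs_event) ~
                           sv$prognostic_index, ties = "efron")
  expect_lt(abs(unname(coef(fit)) - log(2.5)), 0.3)
})

test_that("event counts are calibrated to the cohort the generator emulates", {
  ev <- vapply(1:30, function(s) {
    b <- biopsies(small_cohort(seed = s))
    c(sum(b$rfs_event), sum(b$os_event))
  }, numeric(2))
  expect_gte(mean(ev[1, ]), 18); expect_lte(mean(ev[1, ]), 28)
  expect_gte(mean(ev[2, ]), 10); expect_lte(mean(ev[2, ]), 18)
  expect_true(all(ev[2, ] <= ev[1, ]))  # deaths follow recurrences
})

test_that("overall survival dominates recurrence-free survival per sample", {
  b <- biopsies(small_cohort(seed = 4))
  expect_true(all(b$os_time >= b$rfs_time))
})

test_that("chemoresponse prevalence matches the intercept-implied target", {
  prev_null <- vapply(1:20, function(s) {
    b <- biopsies(small_cohort(seed = s, chemo_beta = 0))
    mean(b$chemoresponse == "optimal")
  }, numeric(1))
  expect_lt(abs(mean(prev_null) - 32 / 65), 0.05)
  prev_planted <- vapply(1:20, function(s) {
    b <- biopsies(small_cohort(seed = s))
    mean(b$chemoresponse == "optimal")
  }, numeric(1))
  expect_lt(abs(mean(prev_planted) - 32 / 65), 0.05)
})

test_that("necrosis percentages are consistent with the labels and cutoff", {
  b <- biopsies(small_cohort(seed = 6))
  expect_identical(as.character(binarize_necrosis(b$necrosis_pct, 80)),
                   as.character(b$chemoresponse))
})

test_that("the proportional-odds fit recovers the planted chemoresponse effect", {
  # joint fit over the (correlated) block is unbiased for the per-feature beta
  p <- sim_params(n_samples = 500, n_mirna = 30, n_mrna = 20,
                  targets_per_mirna = 2, n_decoy_sets = 0, seed = 41)
  set.seed(p$seed)
  ex <- simulate_expression(p)
  ch <- simulate_chemoresponse(ex$mirna, p)
  fit <- olr_fit(ch$chemoresponse,
                 t(unclass(ex$mirna)[ex$truth$chemo_ids, ]))
  # the block is correlated, so individual coefficients are noisy; the mean
  # over the block is the stable estimate of the common planted effect
  expect_lt(abs(mean(fit$betas) - 1), 0.3)
  expect_lt(max(abs(fit$betas - 1)), 0.75)

  # with a single planted feature the univariate fit is unbiased too
  p1 <- sim_params(n_samples = 500, n_mirna = 30, n_mrna = 20,
                   targets_per_mirna = 2, n_decoy_sets = 0,
                   n_chemo_features = 1, seed = 42)
  set.seed(p1$seed)
  ex1 <- simulate_expression(p1)
  ch1 <- simulate_chemoresponse(ex1$mirna, p1)
  fit1 <- olr_fit(ch1$chemoresponse,
                  unclass(ex1$mirna)[ex1$truth$chemo_ids, ])
  expect_lt(abs(fit1$betas - 1), 0.3)
})

test_that("planted feature blocks are disjoint and recorded in the truth", {
  co <- small_cohort(seed = 8)
  expect_length(intersect(co$truth$prognostic_ids, co$truth$chemo_ids), 0)
  expect_length(intersect(co$truth$paired_shift_ids,
                          c(co$truth$prognostic_ids, co$truth$chemo_ids)), 0)
  expect_equal(sort(names(co$target_sets))[1:2],
               sort(names(co$target_sets))[1:2])  # named collection
})

test_that("the generator is deterministic under a fixed seed", {
  a <- small_cohort(seed = 12)
  b <- small_cohort(seed = 12)
  expect_identical(unclass(a$mirna), unclass(b$mirna))
  expect_identical(a$clinical$rfs_time, b$clinical$rfs_time)
  expect_identical(as.character(a$clinical$chemoresponse),
                   as.character(b$clinical$chemoresponse))
})
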