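# shared fixture builders; everything is generated in code at test time

# desk-scale cohort: full sample size, reduced feature space
small_params <- function(seed = 1, ...) {
  args <- list(n_mirna = 150, n_mrna = 400, targets_per_mirna = 20,
               n_decoy_sets = 5, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}

small_cohort <- function(seed = 1, ...) {
  suppressMessages(simulate_cohort(small_params(seed = seed, ...)))
}

biopsies <- function(cohort) {
  cohort$clinical[cohort$clinical$specimen_type == "biopsy", ]
}

# tiny single-feature survival fixture for Cox oracle comparisons
tiny_surv <- function(n = 20, seed = 1, beta = 0.8, tie_fraction = 0) {
  set.seed(seed)
  x <- rnorm(n)
  time <- rexp(n, exp(beta * x))
  if (tie_fraction > 0) time <- round(time * 10) / 10  # month-style ties
  status <- rbinom(n, 1, 0.7)
  if (sum(status) < 3) status[sample(n, 3)] <- 1
  list(x = x, time = time, status = status)
}

rand_expr <- function(n_feat, n_samp, seed = 1, kind = "miRNA",
                      prefix = "f") {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_feat * n_samp), nrow = n_feat,
           dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                           sprintf("S%03d", seq_len(n_samp)))),
    kind)
}
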