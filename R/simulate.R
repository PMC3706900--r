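#' Simulation parameters for a synthetic FFPE tumor cohort
#'
#' Defaults emulate the shape of a 65-biopsy osteosarcoma cohort profiled on
#' a 1,146-probe miRNA panel: about 23 recurrences and 14 deaths, roughly 49%
#' chemosensitive tumors, 26 paired post-chemotherapy resections, an
#' 11/65 metastasis-at-diagnosis rate, and regimen assignment strongly
#' confounded with metastasis. Planted structure: an equicorrelated
#' prognostic miRNA block driving recurrence hazard, a disjoint chemoresponse
#' feature block entering a proportional-odds label model, and mRNA target
#' genes negatively coupled to the prognostic miRNAs.
#'
#' @param n_samples number of diagnostic biopsies (default 65).
#' @param n_mirna miRNA features (default 1146).
#' @param n_mrna mRNA features (default 2000, a desk-scale stand-in for a
#'   29,285-transcript array; configurable up to full size).
#' @param n_prognostic size of the correlated prognostic miRNA block.
#' @param block_correlation equicorrelation rho of the prognostic block,
#'   in `[0, 1)`.
#' @param hazard_log_hr_per_sd log hazard ratio per SD of the prognostic
#'   index (default `log(2.5)`).
#' @param n_chemo_features size of the chemoresponse block (disjoint from the
#'   prognostic block).
#' @param chemo_beta proportional-odds coefficient on each chemoresponse
#'   feature.
#' @param chemo_log_hr log hazard ratio for suboptimal chemoresponse
#'   (default `log(3.7)`, the scale of the clinical effect the model
#'   adjusts for).
#' @param met_log_hr log hazard ratio for metastasis at diagnosis.
#' @param target_coupling gamma <= 0: correlation between a planted miRNA and
#'   each of its target genes (default -0.5, repression).
#' @param targets_per_mirna genes per planted target set.
#' @param n_decoy_sets additional random target sets of matched size, named
#'   after non-planted miRNAs.
#' @param baseline_rate exponential baseline hazard lambda, per month.
#' @param rfs_event_target expected fraction of recurrence events; the
#'   uniform censoring horizon is calibrated to hit it.
#' @param os_event_target expected fraction of deaths; the post-recurrence
#'   survival rate is calibrated to hit it.
#' @param optimal_fraction target prevalence of optimal chemoresponse
#'   (default 32/65).
#' @param necrosis_cutoff necrosis percentage dichotomizing chemoresponse.
#' @param metastasis_rate Bernoulli rate of metastasis at diagnosis.
#' @param n_pairs number of biopsies with a paired post-chemotherapy
#'   resection.
#' @param n_paired_shift_features miRNAs shifted post-chemotherapy.
#' @param paired_shift size of the post-chemotherapy shift (SD units).
#' @param n_categories ordinal chemoresponse categories (>= 2; default 2).
#' @param seed RNG seed consumed by [simulate_cohort()].
#' @return a list of validated parameters, class `"sim_params"`.
#' @export
sim_params <- function(n_samples = 65, n_mirna = 1146, n_mrna = 2000,
                       n_prognostic = 5, block_correlation = 0.6,
                       hazard_log_hr_per_sd = log(2.5),
                       n_chemo_features = 5, chemo_beta = 1,
                       chemo_log_hr = log(3.7), met_log_hr = log(3),
                       target_coupling = -0.5, targets_per_mirna = 40,
                       n_decoy_sets = 20, baseline_rate = 0.01,
                       rfs_event_target = 23 / 65, os_event_target = 14 / 65,
                       optimal_fraction = 32 / 65, necrosis_cutoff = 80,
                       metastasis_rate = 11 / 65, n_pairs = 26,
                       n_paired_shift_features = 20, paired_shift = 1,
                       n_categories = 2, seed = 1L) {
  p <- as.list(environment())
  if (p$block_correlation < 0 || p$block_correlation >= 1)
    stop("block_correlation must lie in [0, 1)")
  if (p$n_prognostic > p$n_mirna) stop("n_prognostic exceeds n_mirna")
  if (p$n_prognostic + p$n_chemo_features > p$n_mirna)
    stop("prognostic and chemoresponse blocks do not fit in n_mirna")
  if (p$target_coupling > 0) stop("target_coupling must be <= 0")
  if (p$baseline_rate <= 0) stop("baseline_rate must be positive")
  if (p$n_categories < 2) stop("at least 2 chemoresponse categories required")
  if (p$n_pairs > p$n_samples) stop("n_pairs exceeds n_samples")
  structure(p, class = "sim_params")
}

#' Null simulation parameters
#'
#' Same cohort shape as [sim_params()] with every planted effect set to zero;
#' used for type-I calibration of the downstream tests.
#' @param ... overrides passed to [sim_params()].
#' @export
null_sim_params <- function(...) {
  sim_params(hazard_log_hr_per_sd = 0, chemo_beta = 0, chemo_log_hr = 0,
             met_log_hr = 0, target_coupling = 0, paired_shift = 0, ...)
}

#' Simulate miRNA and mRNA expression matrices
#'
#' Background features are i.i.d. standard normal on the normalized
#' (post-transform) scale. The prognostic and chemoresponse blocks are each
#' equicorrelated multivariate normal
#' (`x_i = sqrt(rho) * shared + sqrt(1 - rho) * noise`), with independent
#' shared factors and disjoint feature sets (clustered-signature structure);
#' each target gene of a planted miRNA is `gamma * miRNA + sqrt(1 - gamma^2)
#' * noise`, so its correlation with the miRNA equals `gamma`.
#'
#' @param params a [sim_params()] list.
#' @param planted optional list with `prognostic_ids` and `chemo_ids`
#'   (feature ids) fixing where the signal blocks sit — used to simulate an
#'   independent cohort sharing a discovery cohort's planted features, as an
#'   external validation scenario requires. Defaults to fresh random
#'   positions.
#' @return list with elements `mirna` and `mrna` (expression matrices) and
#'   `truth` (planted feature ids and target sets). Planted ids are also
#'   attached to `mirna` as attribute `"planted"`.
#' @export
simulate_expression <- function(params, planted = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- p$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  mirna_ids <- sprintf("miR-%04d", seq_len(p$n_mirna))
  gene_ids <- sprintf("GENE%05d", seq_len(p$n_mrna))

  if (is.null(planted)) {
    idx <- sample(p$n_mirna, p$n_prognostic + p$n_chemo_features)
    prog_idx <- idx[seq_len(p$n_prognostic)]
    chemo_idx <- idx[p$n_prognostic + seq_len(p$n_chemo_features)]
  } else {
    prog_idx <- match(planted$prognostic_ids, mirna_ids)
    chemo_idx <- match(planted$chemo_ids, mirna_ids)
    if (anyNA(prog_idx) || anyNA(chemo_idx))
      stop("planted ids not present among the simulated features")
    if (length(intersect(prog_idx, chemo_idx)))
      stop("planted prognostic and chemoresponse ids must be disjoint")
    if (length(prog_idx) != p$n_prognostic ||
        length(chemo_idx) != p$n_chemo_features)
      stop("planted id counts disagree with n_prognostic/n_chemo_features")
  }
  planted_all <- c(prog_idx, chemo_idx)

  X <- matrix(stats::rnorm(p$n_mirna * n), nrow = p$n_mirna,
              dimnames = list(mirna_ids, samples))
  equicorrelated_block <- function(size) {
    shared <- stats::rnorm(n)
    rho <- p$block_correlation
    sqrt(rho) * rep(shared, each = size) +
      sqrt(1 - rho) * matrix(stats::rnorm(size * n), nrow = size)
  }
  # both planted signatures are correlated blocks (clustered-signature
  # structure); their shared factors are independent of each other
  if (p$n_prognostic > 0)
    X[prog_idx, ] <- equicorrelated_block(p$n_prognostic)
  if (p$n_chemo_features > 0)
    X[chemo_idx, ] <- equicorrelated_block(p$n_chemo_features)

  G <- matrix(stats::rnorm(p$n_mrna * n), nrow = p$n_mrna,
              dimnames = list(gene_ids, samples))
  n_target_genes <- p$targets_per_mirna * p$n_prognostic
  if (n_target_genes > p$n_mrna)
    stop("not enough mRNA features for the requested target sets")
  target_gene_idx <- sample(p$n_mrna, n_target_genes)
  sets <- list()
  gamma <- p$target_coupling
  for (j in seq_len(p$n_prognostic)) {
    gi <- target_gene_idx[(j - 1) * p$targets_per_mirna +
                            seq_len(p$targets_per_mirna)]
    G[gi, ] <- gamma * rep(X[prog_idx[j], ], each = length(gi)) +
      sqrt(1 - gamma^2) * matrix(stats::rnorm(length(gi) * n),
                                 nrow = length(gi))
    sets[[mirna_ids[prog_idx[j]]]] <- gene_ids[gi]
  }
  # decoy sets named after non-planted miRNAs: predicted targets, no signal
  decoy_mirnas <- sample(setdiff(seq_len(p$n_mirna), planted_all),
                         p$n_decoy_sets)
  for (d in decoy_mirnas)
    sets[[mirna_ids[d]]] <- gene_ids[sample(p$n_mrna, p$targets_per_mirna)]
  truth <- list(
    prognostic_ids = mirna_ids[prog_idx],
    chemo_ids = mirna_ids[chemo_idx],
    target_sets = if (length(sets)) target_sets(sets, source = "synthetic"))
  mirna <- expression_matrix(X, "miRNA")
  attr(mirna, "planted") <- truth[c("prognostic_ids", "chemo_ids")]
  list(mirna = mirna, mrna = expression_matrix(G, "mRNA"), truth = truth)
}

## --- proportional-odds label generation -----------------------------------

# solve intercept a such that E[plogis(a + s*u)] over u ~ N(0,1) hits `target`
solve_logit_intercept <- function(target, s) {
  if (abs(s) < 1e-12) return(stats::qlogis(target))
  f <- function(a) {
    stats::integrate(function(u) stats::dnorm(u) * stats::plogis(a + s * u),
                     -8, 8, rel.tol = 1e-10)$value - target
  }
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate ordinal chemoresponse labels and necrosis percentages
#'
#' Labels are drawn from a proportional-odds model whose linear predictor is
#' `chemo_beta` times the sum of the chemoresponse block features
#' (equivalently, a latent logistic variable cut at calibrated thresholds);
#' intercepts are calibrated by quadrature so the marginal prevalence of an
#' optimal response matches `optimal_fraction`. Necrosis percentages are
#' back-filled uniformly on the side of `necrosis_cutoff` consistent with
#' the label.
#'
#' @param mirna miRNA expression matrix carrying a `"planted"` attribute (as
#'   produced by [simulate_expression()]), or supply `chemo_ids`.
#' @param params a [sim_params()] list.
#' @param chemo_ids optional explicit chemoresponse feature ids.
#' @return data.frame with `sample_id`, `chemoresponse` (ordered factor),
#'   `necrosis_pct`, and the latent linear predictor `chemo_eta`.
#' @export
simulate_chemoresponse <- function(mirna, params, chemo_ids = NULL) {
  p <- params
  if (p$n_categories < 2) stop("at least 2 chemoresponse categories required")
  if (p$n_categories != 2)
    stop("only the 2-category (suboptimal/optimal) generator is implemented")
  chemo_ids <- chemo_ids %||% attr(mirna, "planted")$chemo_ids
  eta <- if (length(chemo_ids) && p$chemo_beta != 0) {
    p$chemo_beta * colSums(mirna[chemo_ids, , drop = FALSE])
  } else rep(0, ncol(mirna))
  K <- max(length(chemo_ids), 0)
  # sd of the block sum under the equicorrelated construction
  s <- p$chemo_beta * sqrt(K * (1 + (K - 1) * p$block_correlation))
  a <- solve_logit_intercept(p$optimal_fraction, s)
  optimal <- stats::runif(ncol(mirna)) < stats::plogis(a + eta)
  label <- factor(ifelse(optimal, "optimal", "suboptimal"),
                  levels = c("suboptimal", "optimal"), ordered = TRUE)
  cutoff <- p$necrosis_cutoff
  necrosis <- ifelse(optimal,
                     stats::runif(ncol(mirna), cutoff, 100),
                     stats::runif(ncol(mirna), 0, cutoff))
  data.frame(sample_id = colnames(mirna), chemoresponse = label,
             necrosis_pct = necrosis, chemo_eta = eta,
             stringsAsFactors = FALSE)
}

## --- survival generation ---------------------------------------------------

# expected event fraction under exponential event times with rate
# lambda*exp(linpred) and Uniform(0, cmax) censoring, integrating the
# prognostic index over N(0,1) and the binary covariate states
expected_event_fraction <- function(cmax, lambda, beta, states) {
  prob_one <- function(theta) {
    tc <- theta * cmax
    1 - (1 - exp(-tc)) / tc
  }
  tot <- 0
  for (i in seq_len(nrow(states))) {
    f <- stats::integrate(function(z) {
      stats::dnorm(z) * prob_one(lambda * exp(beta * z + states$offset[i]))
    }, -8, 8, rel.tol = 1e-9)$value
    tot <- tot + states$prob[i] * f
  }
  tot
}

censor_states <- function(p) {
  g <- expand.grid(sub = c(0, 1), met = c(0, 1))
  g$prob <- ifelse(g$sub == 1, 1 - p$optimal_fraction, p$optimal_fraction) *
    ifelse(g$met == 1, p$metastasis_rate, 1 - p$metastasis_rate)
  g$offset <- g$sub * p$chemo_log_hr + g$met * p$met_log_hr
  g
}

# censoring horizon such that the expected recurrence-event fraction matches
# the target, given all hazard components of the generative model
calibrate_censoring <- function(p) {
  states <- censor_states(p)
  f <- function(cm) expected_event_fraction(cm, p$baseline_rate,
                                            p$hazard_log_hr_per_sd, states) -
    p$rfs_event_target
  stats::uniroot(f, c(1e-3, 1e5), tol = 1e-8)$root
}

# post-recurrence death rate such that the expected death fraction matches
# the target; fixed-seed internal Monte Carlo, RNG state restored
calibrate_post_recurrence <- function(p, cmax, n_mc = 2e5) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20130122L)
  states <- censor_states(p)
  st <- sample(nrow(states), n_mc, replace = TRUE, prob = states$prob)
  theta <- p$baseline_rate *
    exp(p$hazard_log_hr_per_sd * stats::rnorm(n_mc) + states$offset[st])
  t_rec <- stats::rexp(n_mc, theta)
  cens <- stats::runif(n_mc, 0, cmax)
  slack <- cens - t_rec              # follow-up remaining after recurrence
  obs <- slack > 0
  if (mean(obs) <= p$os_event_target)
    stop("os_event_target unreachable: fewer expected recurrences than deaths")
  # the same unit exponentials are rescaled inside uniroot so the objective
  # is a deterministic, monotone function of the rate
  e_unit <- stats::rexp(n_mc)
  f <- function(log_rate) mean(obs & (e_unit / exp(log_rate) < slack)) -
    p$os_event_target
  exp(stats::uniroot(f, c(-12, 6), tol = 1e-8)$root)
}

#' Simulate recurrence-free and overall survival outcomes
#'
#' Recurrence times are exponential by inverse transform with rate
#' `lambda * exp(beta * index + chemo + metastasis effects)`, where the
#' prognostic index is the standardized mean of the planted miRNA block.
#' Censoring is uniform on a horizon calibrated so the expected number of
#' observed recurrences matches `rfs_event_target`. Death follows recurrence
#' after an exponential post-recurrence increment whose rate is calibrated to
#' `os_event_target`; this guarantees `os_time >= rfs_time` and fewer deaths
#' than recurrences.
#'
#' @param mirna miRNA matrix with planted ids attached (or pass
#'   `prognostic_ids`).
#' @param params a [sim_params()] list.
#' @param chemoresponse optional ordered factor from
#'   [simulate_chemoresponse()]; enters the hazard via `chemo_log_hr`.
#' @param metastasis_dx optional 0/1 vector; drawn Bernoulli
#'   (`metastasis_rate`) when absent; enters the hazard via `met_log_hr`.
#' @param prognostic_ids optional explicit prognostic feature ids.
#' @return data.frame with `sample_id`, `rfs_time`, `rfs_event`, `os_time`,
#'   `os_event`, `metastasis_dx` and the true `prognostic_index`.
#' @export
simulate_survival <- function(mirna, params, chemoresponse = NULL,
                              metastasis_dx = NULL, prognostic_ids = NULL) {
  p <- params
  if (p$baseline_rate <= 0) stop("baseline_rate must be positive")
  n <- ncol(mirna)
  prognostic_ids <- prognostic_ids %||% attr(mirna, "planted")$prognostic_ids
  index <- if (length(prognostic_ids)) {
    as.numeric(scale(colMeans(mirna[prognostic_ids, , drop = FALSE])))
  } else rep(0, n)
  if (is.null(metastasis_dx))
    metastasis_dx <- stats::rbinom(n, 1, p$metastasis_rate)
  chemo_off <- if (!is.null(chemoresponse)) {
    p$chemo_log_hr * (chemoresponse == "suboptimal")
  } else rep(0, n)
  cmax <- calibrate_censoring(p)
  lambda_post <- calibrate_post_recurrence(p, cmax)
  theta <- p$baseline_rate *
    exp(p$hazard_log_hr_per_sd * index + chemo_off + p$met_log_hr * metastasis_dx)
  t_rec <- -log(stats::runif(n)) / theta
  cens <- stats::runif(n, 0, cmax)
  rfs_event <- as.integer(t_rec <= cens)
  rfs_time <- pmin(t_rec, cens)
  t_death <- t_rec + stats::rexp(n, lambda_post)
  os_event <- as.integer(rfs_event == 1 & t_death <= cens)
  os_time <- ifelse(os_event == 1, t_death, cens)
  os_time <- pmax(os_time, rfs_time)   # censored-before-recurrence samples
  data.frame(sample_id = colnames(mirna),
             rfs_time = rfs_time, rfs_event = rfs_event,
             os_time = os_time, os_event = os_event,
             metastasis_dx = metastasis_dx, prognostic_index = index,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [simulate_expression()], [simulate_chemoresponse()] and
#' [simulate_survival()], draws regimen labels confounded with metastasis at
#' diagnosis, and generates paired post-chemotherapy resection miRNA profiles
#' with a planted expression shift in a feature set disjoint from both the
#' prognostic and the chemoresponse blocks.
#'
#' @param params a [sim_params()] list (its `seed` drives all randomness).
#' @param planted optional planted feature identities shared with another
#'   cohort (see [simulate_expression()]).
#' @return list with `mirna`, `mrna`, `mirna_post` (resection profiles),
#'   `clinical` (a [clinical_table()] covering biopsies and resections),
#'   `target_sets`, `truth` and `params`.
#' @export
simulate_cohort <- function(params = sim_params(), planted = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  ex <- simulate_expression(p, planted = planted)
  chemo <- simulate_chemoresponse(ex$mirna, p)
  surv <- simulate_survival(ex$mirna, p, chemoresponse = chemo$chemoresponse)
  ex$truth$prognostic_index <- surv$prognostic_index
  ex$truth$chemo_eta <- chemo$chemo_eta
  # regimen strongly confounded with metastasis at diagnosis
  other <- stats::rbinom(p$n_samples, 1,
                         ifelse(surv$metastasis_dx == 1, 0.9, 0.25))
  regimen <- ifelse(other == 1, "MAPIE", "MAP")

  clin <- data.frame(sample_id = surv$sample_id, specimen_type = "biopsy",
                     pair_id = NA_character_,
                     rfs_time = surv$rfs_time, rfs_event = surv$rfs_event,
                     os_time = surv$os_time, os_event = surv$os_event,
                     necrosis_pct = chemo$necrosis_pct,
                     chemoresponse = chemo$chemoresponse,
                     metastasis_dx = surv$metastasis_dx, regimen = regimen,
                     stringsAsFactors = FALSE)

  mirna_post <- NULL
  truth <- ex$truth
  if (p$n_pairs > 0) {
    paired <- sort(sample(p$n_samples, p$n_pairs))
    clin$pair_id[paired] <- sprintf("P%02d", seq_len(p$n_pairs))
    used <- match(c(truth$prognostic_ids, truth$chemo_ids), rownames(ex$mirna))
    shift_idx <- sample(setdiff(seq_len(p$n_mirna), used),
                        p$n_paired_shift_features)
    pre <- unclass(ex$mirna)[, paired, drop = FALSE]
    post <- pre + matrix(stats::rnorm(length(pre)), nrow = nrow(pre))
    post[shift_idx, ] <- post[shift_idx, ] + p$paired_shift
    colnames(post) <- sprintf("R%03d", seq_len(p$n_pairs))
    mirna_post <- expression_matrix(post, "miRNA")
    truth$paired_shift_ids <- rownames(ex$mirna)[shift_idx]
    res_rows <- clin[paired, ]
    res_rows$sample_id <- colnames(post)
    res_rows$specimen_type <- "resection"
    clin <- rbind(clin, res_rows)
  }
  list(mirna = ex$mirna, mrna = ex$mrna, mirna_post = mirna_post,
       clinical = clinical_table(clin), target_sets = truth$target_sets,
       truth = truth, params = p)
}

#' Map normalized-scale expression onto a raw intensity scale
#'
#' Convenience for exercising the preprocessing stage: returns
#' `2^(center + x)`, a strictly positive raw-intensity surrogate whose
#' `log2` transform recovers the input up to the additive center.
#'
#' @param x expression matrix on the normalized scale.
#' @param center log2 center of the intensity distribution (default 8).
#' @export
raw_intensities <- function(x, center = 8) {
  out <- 2^(center + unclass(x))
  expression_matrix(out, feature_kind(x))
}

#' Write a simulated cohort to disk
#'
#' Emits `mirna.tsv`, `mrna.tsv`, `mirna_post.tsv` (if pairs were simulated),
#' `clinical.tsv` and `targets.gmt` in `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_expression_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  if (!is.null(cohort$mirna_post))
    write_expression_matrix(cohort$mirna_post, file.path(dir, "mirna_post.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  if (!is.null(cohort$target_sets))
    write_gene_sets(cohort$target_sets, file.path(dir, "targets.gmt"))
  invisible(dir)
}
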