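#' Averaged univariate prediction (AP) of chemoresponse
#'
#' The cohort is split `n_splits` times into training and test sets. Within
#' each training set only: features are ranked by univariate ordinal
#' concordance, the top `m` are fitted as univariate proportional-odds
#' models, and each test sample's per-category probability is the geometric
#' mean of the `m` model probabilities (clipped at `prob_floor` so a single
#' zero cannot annihilate the product, then renormalized). The assigned
#' category is the argmax; per-split accuracy is the fraction of correct
#' test assignments. Training splits missing a category are redrawn
#' (logged); models flagged as separated are excluded from the ensemble.
#'
#' @param y ordinal chemoresponse labels.
#' @param expr expression matrix (features x samples).
#' @param n_splits number of random splits (default 500).
#' @param train_fraction fraction of the cohort used for training (default
#'   0.9; 0.95 reproduces the alternative split scheme).
#' @param m number of top univariate models averaged (5 to 20 in the
#'   motivating analysis; default 5).
#' @param seed RNG seed.
#' @param prob_floor probability clip before the geometric mean.
#' @return object of class `"ap_result"`: per-split accuracies (`accuracy`),
#'   their mean and SD, per-feature selection fractions
#'   (`selection_fraction`), and per-sample aggregated category
#'   probabilities (`sample_prob`, renormalized means over the splits in
#'   which the sample was held out).
#' @export
ap_predict <- function(y, expr, n_splits = 500, train_fraction = 0.9, m = 5,
                       seed = 1, prob_floor = 1e-12) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (m < 1) stop("m must be at least 1")
  y <- droplevels(as.ordered(y))
  keep <- !is.na(y)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) without a label excluded")
    expr <- expr[, keep, drop = FALSE]; y <- droplevels(y[keep])
  }
  n <- length(y)
  n_train <- max(2, round(train_fraction * n))
  if (n_train >= n) stop("train_fraction leaves no test samples")
  set.seed(seed)
  K <- nlevels(y)
  acc <- rep(NA_real_, n_splits)
  sel_count <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  prob_sum <- matrix(0, n, K, dimnames = list(colnames(expr), levels(y)))
  prob_n <- numeric(n)
  for (b in seq_len(n_splits)) {
    tr <- draw_training_split(y, n_train)
    if (is.null(tr)) { message("split ", b, ": no valid training draw, skipped")
      next }
    ranks <- rank_features_by_concordance(y[tr], expr[, tr, drop = FALSE])
    top <- utils::head(ranks$feature_id, m)
    models <- list()
    for (f in top) {
      fit <- tryCatch(olr_fit(y[tr], expr[f, tr]), error = function(e) NULL)
      if (!is.null(fit) && !fit$separated) models[[f]] <- fit
    }
    if (!length(models)) { message("split ", b,
                                   ": every model separated, skipped")
      next }
    te <- setdiff(seq_len(n), tr)
    agg <- geometric_mean_probs(lapply(names(models), function(f)
      predict(models[[f]], expr[f, te])$prob), prob_floor)
    assigned <- max.col(agg, ties.method = "first")
    acc[b] <- mean(assigned == as.integer(y[te]))
    sel_count[top] <- sel_count[top] + 1
    prob_sum[te, ] <- prob_sum[te, ] + agg
    prob_n[te] <- prob_n[te] + 1
  }
  valid <- !is.na(acc)
  sample_prob <- prob_sum / pmax(prob_n, 1)
  sample_prob <- sample_prob / rowSums(sample_prob)
  sample_prob[prob_n == 0, ] <- NA_real_
  structure(list(accuracy = acc[valid], n_valid_splits = sum(valid),
                 mean_accuracy = mean(acc[valid]),
                 sd_accuracy = stats::sd(acc[valid]),
                 selection_fraction = sel_count / max(sum(valid), 1),
                 sample_prob = sample_prob,
                 m = m, n_splits = n_splits,
                 train_fraction = train_fraction),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf("<ap_result> %d/%d valid splits, mean accuracy %.3f (sd %.3f)\n",
              x$n_valid_splits, x$n_splits, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

# training split containing every category; up to 50 redraws, else NULL
draw_training_split <- function(y, n_train, max_redraw = 50) {
  for (i in seq_len(max_redraw)) {
    tr <- sample(length(y), n_train)
    if (all(levels(y) %in% y[tr])) return(tr)
  }
  NULL
}

# geometric-mean aggregation of category-probability matrices; clip then
# renormalize rows. Invariant to the order of the models.
geometric_mean_probs <- function(prob_list, prob_floor = 1e-12) {
  logs <- lapply(prob_list, function(p) log(pmax(p, prob_floor)))
  g <- exp(Reduce(`+`, logs) / length(logs))
  g / rowSums(g)
}

#' Multivariate ordinal-logistic chemoresponse prediction
#'
#' Per split, the top `n_features` training features by univariate
#' concordance are fitted jointly in a single proportional-odds model and
#' the test samples classified by probability argmax. Splits where the joint
#' fit separates are skipped (logged) and accuracy is averaged over valid
#' splits. With `n_features = 1` the procedure coincides with
#' [ap_predict()] at `m = 1`.
#'
#' @inheritParams ap_predict
#' @param n_features number of jointly modeled features (<= 5).
#' @return list with per-split `accuracy`, `mean_accuracy`, `sd_accuracy`,
#'   `n_valid_splits`.
#' @export
multivariate_olr_predict <- function(y, expr, n_features = 2, n_splits = 500,
                                     train_fraction = 0.9, seed = 1) {
  if (n_features > 5) stop("n_features must be small (<= 5)")
  y <- droplevels(as.ordered(y))
  keep <- !is.na(y)
  expr <- expr[, keep, drop = FALSE]; y <- droplevels(y[keep])
  n <- length(y)
  n_train <- max(2, round(train_fraction * n))
  if (n_train >= n) stop("train_fraction leaves no test samples")
  set.seed(seed)
  acc <- rep(NA_real_, n_splits)
  for (b in seq_len(n_splits)) {
    tr <- draw_training_split(y, n_train)
    if (is.null(tr)) next
    ranks <- rank_features_by_concordance(y[tr], expr[, tr, drop = FALSE])
    top <- utils::head(ranks$feature_id, n_features)
    fit <- tryCatch(olr_fit(y[tr], t(expr[top, tr, drop = FALSE])),
                    error = function(e) NULL)
    if (is.null(fit) || fit$separated) {
      message("split ", b, ": joint model separated or failed, skipped")
      next
    }
    te <- setdiff(seq_len(n), tr)
    pred <- predict(fit, t(expr[top, te, drop = FALSE]))
    acc[b] <- mean(as.integer(pred$category) == as.integer(y[te]))
  }
  valid <- !is.na(acc)
  list(accuracy = acc[valid], mean_accuracy = mean(acc[valid]),
       sd_accuracy = stats::sd(acc[valid]), n_valid_splits = sum(valid))
}

#' Stability of the top-ranked predictor features under resampling
#'
#' For `n_subsets` random subsets of the cohort, features are re-ranked by
#' univariate concordance; each feature's stability is the fraction of
#' subsets in which it stays among the top `m`.
#'
#' @inheritParams ap_predict
#' @param subset_fraction fraction of samples drawn per subset.
#' @param n_subsets number of random subsets (>= 10).
#' @return data.frame `feature_id`, `stability`, sorted descending.
#' @export
feature_stability <- function(y, expr, subset_fraction = 0.8, n_subsets = 100,
                              m = 10, seed = 1) {
  if (n_subsets < 10) stop("n_subsets must be at least 10")
  y <- droplevels(as.ordered(y))
  n <- length(y)
  n_sub <- max(4, round(subset_fraction * n))
  set.seed(seed)
  counts <- stats::setNames(numeric(nrow(expr)), rownames(expr))
  done <- 0
  for (b in seq_len(n_subsets)) {
    idx <- draw_training_split(y, n_sub)
    if (is.null(idx)) next
    ranks <- rank_features_by_concordance(y[idx], expr[, idx, drop = FALSE])
    counts[utils::head(ranks$feature_id, m)] <-
      counts[utils::head(ranks$feature_id, m)] + 1
    done <- done + 1
  }
  out <- data.frame(feature_id = names(counts), stability = counts / done,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$stability, out$feature_id, method = "radix"), , drop = FALSE]
}
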