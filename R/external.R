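#' Map a discovery signature onto an external platform
#'
#' Case-normalized exact-string intersection of the signature ids with the
#' external platform's feature universe; duplicates in the signature are
#' removed with a warning and unmapped ids are reported.
#'
#' @param signature character vector of discovery-cohort feature ids.
#' @param universe character vector of external-platform feature ids.
#' @return list `mapped` (ids as spelled in the universe), `unmapped`.
#' @export
map_signature <- function(signature, universe) {
  if (anyDuplicated(signature)) {
    warning("duplicate signature ids removed: ",
            paste(unique(signature[duplicated(signature)]), collapse = ", "))
    signature <- unique(signature)
  }
  hit <- match(tolower(signature), tolower(universe))
  mapped <- universe[hit[!is.na(hit)]]
  unmapped <- signature[is.na(hit)]
  if (!length(mapped))
    stop("no signature feature maps to the external platform")
  list(mapped = mapped, unmapped = unmapped)
}

#' Count signature features significant in the external cohort
#'
#' @param mapped character vector of mapped feature ids.
#' @param external_p named numeric vector of per-feature p-values from the
#'   external cohort (must cover every mapped id).
#' @param alpha_strict significance threshold (default 0.05).
#' @param alpha_trend trend threshold (default 0.1, must be
#'   >= `alpha_strict`); the trend count includes the strictly significant
#'   features ("significant or a trend to significance").
#' @return list `n_strict`, `n_trend`, `table` (per-id p and calls).
#' @export
count_significant <- function(mapped, external_p, alpha_strict = 0.05,
                              alpha_trend = 0.1) {
  if (alpha_trend < alpha_strict)
    stop("alpha_trend must be >= alpha_strict")
  miss <- setdiff(mapped, names(external_p))
  if (length(miss))
    stop("feature(s) missing from the external table: ",
         paste(miss, collapse = ", "))
  p <- external_p[mapped]
  tab <- data.frame(feature_id = mapped, p = unname(p),
                    strict = unname(p < alpha_strict),
                    trend = unname(p < alpha_trend),
                    stringsAsFactors = FALSE)
  list(n_strict = sum(tab$strict), n_trend = sum(tab$trend), table = tab)
}

#' Overlap permutation test for external signature support
#'
#' Draws `n_draws` random feature lists of size `list_size` (without
#' replacement) from the external platform universe and computes the
#' fraction containing at least `k_observed` features significant at
#' `alpha` -- the chance of seeing the observed external support with a
#' random signature. The plain-fraction convention mirrors the "4 out of
#' 100 random lists" style of reporting; `add_one = TRUE` gives the
#' (recommended) add-one estimator `(1 + #) / (1 + n_draws)`.
#'
#' @param k_observed observed count of significant mapped features.
#' @param list_size signature size drawn per permutation.
#' @param external_p named numeric vector of per-feature p-values over the
#'   whole external universe.
#' @param alpha significance level applied to the drawn lists (the same
#'   level used for the observed count; default 0.1, the strict-or-trend
#'   level).
#' @param n_draws number of random lists (default 100).
#' @param seed RNG seed.
#' @param add_one use the add-one p-value convention.
#' @return list `p`, `k_observed`, `draw_counts`.
#' @export
overlap_permutation_test <- function(k_observed, list_size, external_p,
                                     alpha = 0.1, n_draws = 100, seed = 1,
                                     add_one = FALSE) {
  if (k_observed > list_size) stop("k_observed exceeds list_size")
  if (list_size > length(external_p))
    stop("list_size exceeds the external universe")
  sig <- external_p < alpha
  set.seed(seed)
  counts <- replicate(n_draws, sum(sig[sample(length(sig), list_size)]))
  hits <- sum(counts >= k_observed)
  p <- if (add_one) (1 + hits) / (1 + n_draws) else hits / n_draws
  list(p = p, k_observed = k_observed, draw_counts = counts)
}

#' Refit a frozen signature as a risk model on an external cohort
#'
#' Fits the supervised principal-components model restricted to features
#' preselected on the discovery cohort -- no re-screening on the external
#' data -- and reports the Kaplan-Meier / log-rank separation of the
#' resulting risk groups. With few events this output is descriptive.
#'
#' @param expr external expression matrix.
#' @param times,events external survival outcome.
#' @param features frozen signature (discovery-cohort feature ids).
#' @param k number of principal components.
#' @param cutoff_quantile risk-group cutoff quantile.
#' @return list `model` (an `spc_model`), `assignment`, `km`
#'   (a [km_logrank()] result, `NULL` if a group is empty).
#' @export
external_risk_model <- function(expr, times, events, features, k = 1,
                                cutoff_quantile = 0.5) {
  mp <- map_signature(features, rownames(expr))
  model <- fit_spc(expr, times, events, k = k, features = mp$mapped,
                   cutoff_quantile = cutoff_quantile)
  assignment <- predict(model, expr)
  km <- if (nlevels(droplevels(assignment$risk_group)) == 2)
    km_logrank(assignment$risk_group, times, events)
  list(model = model, assignment = assignment, km = km)
}
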