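# Independent oracles, implemented from first principles and kept separate
# from the package code paths they check.

# Efron-tie Cox log partial likelihood for a single covariate
efron_loglik <- function(beta, x, time, status) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(x[R] * beta))
    sD <- sum(exp(x[D] * beta))
    ll <- ll + sum(x[D]) * beta -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
    }
  ll
}

# Newton-Raphson maximization with central-difference derivatives
cox_nr_oracle <- function(x, time, status, tol = 1e-10, h = 1e-5) {
  beta <- 0
  for (it in 1:100) {
    f1 <- (efron_loglik(beta + h, x, time, status) -
             efron_loglik(beta - h, x, time, status)) / (2 * h)
    f2 <- (efron_loglik(beta + h, x, time, status) -
             2 * efron_loglik(beta, x, time, status) +
             efron_loglik(beta - h, x, time, status)) / h^2
    step <- f1 / f2
    beta <- beta - step
    if (abs(step) < tol) break
  }
  beta
}

# chi-square log-rank statistic from the per-event-time 2xK risk tables
logrank_oracle <- function(groups, time, status) {
  groups <- factor(groups)
  lv <- levels(groups)
  O <- E <- stats::setNames(numeric(length(lv)), lv)
  Vg <- 0  # variance of group-1 observed-minus-expected
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & status == 1)
    for (g in lv) {
      ng <- sum(at_risk & groups == g)
      dg <- sum(time == t & status == 1 & groups == g)
      O[g] <- O[g] + dg
      E[g] <- E[g] + d * ng / n
    }
    n1 <- sum(at_risk & groups == lv[1])
    if (n > 1)
      Vg <- Vg + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O[lv[1]] - E[lv[1]])^2 / Vg
}

# two-sided hypergeometric tail P(X >= k), X ~ Hypergeom(N, S, n)
hyper_tail <- function(k, N, S, n) {
  stats::phyper(k - 1, S, N - S, n, lower.tail = FALSE)
}

# exhaustive random-set null for the LS statistic on a tiny gene universe
ls_enumeration_p <- function(set_genes, p_named) {
  ls <- function(p) mean(-log(p))
  obs <- ls(p_named[set_genes])
  combos <- utils::combn(names(p_named), length(set_genes))
  null_ls <- apply(combos, 2, function(g) ls(p_named[g]))
  mean(null_ls >= obs)
}
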