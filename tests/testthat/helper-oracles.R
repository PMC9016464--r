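# Independent brute-force oracles used to pin down expected values.
# These deliberately use naive enumeration, not the package's algorithms.

# AUROC by O(n^2) pair counting: concordant pairs 1, ties 1/2
oracle_auroc <- function(scores, condition) {
  pos <- scores[condition]
  neg <- scores[!condition]
  tot <- 0
  for (x in pos) for (y in neg) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(pos) * length(neg))
}

# Obuchowski measure by exhaustive weighted pair enumeration
oracle_obuchowski <- function(scores, stages, penalty = 0.25) {
  n <- length(scores)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stages[i] == stages[j]) next
    w <- penalty * abs(stages[i] - stages[j])
    conc <- sign(scores[j] - scores[i]) * sign(stages[j] - stages[i])
    num <- num + w * (if (conc > 0) 1 else if (conc == 0) 0.5 else 0)
    den <- den + w
  }
  num / den
}

# exhaustive cutoff search over midpoints (positive iff score >= cutoff)
oracle_cutoff_search <- function(scores, condition, se_target, sp_target) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  se <- sapply(cand, function(cc) mean(scores[condition] >= cc))
  sp <- sapply(cand, function(cc) mean(scores[!condition] < cc))
  youden <- se + sp - 1
  best <- cand[which(youden == max(youden))[1]]
  ro_ok <- which(se >= se_target)
  rule_out <- if (length(ro_ok) == 0) NA_real_ else {
    sub <- ro_ok[sp[ro_ok] == max(sp[ro_ok])]
    cand[sub[1]]
  }
  ri_ok <- which(sp >= sp_target)
  rule_in <- if (length(ri_ok) == 0) NA_real_ else {
    sub <- ri_ok[se[ri_ok] == max(se[ri_ok])]
    cand[sub[1]]
  }
  list(best_single = best, rule_out = rule_out, rule_in = rule_in)
}

# permutation oracle for the paired AUROC comparison: swap the two scores
# within random subjects (labels fixed), two-sided p on |AUROC difference|
oracle_delong_permutation <- function(a, b, condition, n_perm = 4000,
                                      seed = 1) {
  obs <- abs(oracle_auroc(a, condition) - oracle_auroc(b, condition))
  withr::with_seed(seed, {
    hits <- 0
    n <- length(a)
    for (k in seq_len(n_perm)) {
      swap <- runif(n) < 0.5
      a2 <- ifelse(swap, b, a)
      b2 <- ifelse(swap, a, b)
      d <- abs(oracle_auroc(a2, condition) - oracle_auroc(b2, condition))
      if (d >= obs - 1e-12) hits <- hits + 1
    }
    hits / n_perm
  })
}

# bootstrap oracle for predictive-value differences: resample subjects,
# two-sided p from the bootstrap distribution of the difference centred at 0
oracle_pv_bootstrap <- function(t1, t2, d, metric = "ppv", n_boot = 4000,
                                seed = 1) {
  pv <- function(t, dd) {
    if (metric == "ppv") sum(dd[t]) / sum(t) else sum(!dd[!t]) / sum(!t)
  }
  obs <- pv(t1, d) - pv(t2, d)
  withr::with_seed(seed, {
    n <- length(t1)
    diffs <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      denom1 <- if (metric == "ppv") sum(t1[idx]) else sum(!t1[idx])
      denom2 <- if (metric == "ppv") sum(t2[idx]) else sum(!t2[idx])
      if (denom1 == 0 || denom2 == 0) return(NA_real_)
      pv(t1[idx], d[idx]) - pv(t2[idx], d[idx])
    })
    diffs <- diffs[!is.na(diffs)]
    se <- sd(diffs)
    2 * pnorm(-abs(obs) / se)
  })
}

# deterministic toy cohort for hand-traceable cases
toy_scores <- function() {
  tibble::tibble(
    score = c(0.1, 0.2, 0.35, 0.4, 0.45, 0.5, 0.52, 0.6, 0.61, 0.7,
              0.75, 0.8, 0.85, 0.9, 0.95, 1.1, 1.2, 1.3, 1.5, 2.0),
    condition = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                  TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, TRUE)
  )
}
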