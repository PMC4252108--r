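## Independent oracles used across the suite. They deliberately avoid the
## code paths they check: exact tests are enumerated from log-binomial
## coefficients, the Viterbi check enumerates every state path.

## Two-sided Fisher p on [[a, b], [c, d]] by full hypergeometric enumeration
## with the minimum-likelihood two-sided rule (ties accepted up to a 1e-7
## relative slack, the customary numerical tie-break).
fisher_enum_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- exp(logp[support == a])
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

## One-tailed (enrichment) hypergeometric p: P(overlap >= k) by enumeration.
hyper_enum_ge <- function(k, size1, size2, n_universe) {
  support <- max(0, size1 + size2 - n_universe):min(size1, size2)
  logp <- lchoose(size1, support) + lchoose(n_universe - size1, size2 - support) -
    lchoose(n_universe, size2)
  sum(exp(logp)[support >= k])
}

## Exact two-sided Wilcoxon rank-sum p by enumeration of all group
## assignments (tie-free data, both groups small).
wilcox_enum_two_sided <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

## Exhaustive best state path by meet-in-the-middle enumeration: every one of
## the 5^L paths is represented as a prefix/suffix pair, so the search is
## complete without a dynamic-programming recursion.
brute_best_path <- function(log_em, log_tr, log_init) {
  n_states <- ncol(log_em)
  L <- nrow(log_em)
  enum_paths <- function(rows) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), length(rows))))
    score <- numeric(nrow(grid))
    for (j in seq_along(rows)) {
      score <- score + log_em[rows[j], grid[, j]]
      if (j > 1L) score <- score + log_tr[cbind(grid[, j - 1L], grid[, j])]
    }
    list(grid = grid, score = score)
  }
  if (L == 1L) {
    s <- log_init + log_em[1, ]
    return(which.max(s))
  }
  half <- L %/% 2L
  pre <- enum_paths(seq_len(half))
  pre$score <- pre$score + log_init[pre$grid[, 1L]]
  suf <- enum_paths((half + 1L):L)
  best <- -Inf; best_path <- NULL
  for (s1 in seq_len(n_states)) {
    for (s2 in seq_len(n_states)) {
      i1 <- pre$grid[, half] == s1
      i2 <- suf$grid[, 1L] == s2
      m1 <- which.max(ifelse(i1, pre$score, -Inf))
      m2 <- which.max(ifelse(i2, suf$score, -Inf))
      tot <- pre$score[m1] + log_tr[s1, s2] + suf$score[m2]
      if (tot > best) {
        best <- tot
        best_path <- c(pre$grid[m1, ], suf$grid[m2, ])
      }
    }
  }
  unname(best_path)
}

## Small standard cohort used by several files (kept light for test runtime).
make_test_cohort <- function(seed = 42, ...) {
  defaults <- list(n_samples = 12L, fraction_st1 = 0.25, n_chrom = 4L,
                   n_probes_per_chrom = 150L, n_expr_probes = 300L,
                   n_shifted_probes = 24L, n_shifted_genes = 18L,
                   n_genes = 120L, n_terms = 15L, n_planted_terms = 3L,
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  simulate_cohort(do.call(cohort_config, args))
}
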