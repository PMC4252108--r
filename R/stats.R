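#' Two-sided Wilcoxon rank sum p-value
#'
#' Exact enumeration of the rank-sum null when both groups are below
#' `exact_below` and no ties are present; otherwise the normal approximation
#' with the tie-corrected variance (and continuity correction).
#'
#' @param x,y numeric group vectors (both non-empty).
#' @param exact_below use the exact distribution when both group sizes are
#'   below this bound and the data are tie-free (default 50).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 50L) {
  if (!length(x) || !length(y)) stopf("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)  # all observations tied
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) < exact_below && length(y) < exact_below
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Compare an alteration frequency between two cohorts
#'
#' Two-sided Fisher's exact test of `x1/n1` versus `x2/n2` carriers (e.g. the
#' TP53 mutation frequency of one cohort against a reference cohort).
#'
#' @param x1,n1 carriers and cohort size of the first cohort.
#' @param x2,n2 carriers and cohort size of the second cohort.
#' @return list with `p` (two-sided exact p), `odds_ratio`, and the 2x2
#'   `table` `[[x1, n1 - x1], [x2, n2 - x2]]`.
#' @export
frequency_fisher_test <- function(x1, n1, x2, n2) {
  if (x1 > n1 || x2 > n2 || min(x1, x2, n1, n2) < 0)
    stopf("carrier counts must be non-negative and at most the cohort size")
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' False discovery rate adjustment (Benjamini-Hochberg or Storey)
#'
#' BH: the usual step-up `q_i = min_{j >= i} m p_(j) / j`. Storey: the BH
#' step-up rescaled by the estimated null proportion
#' `pi0 = min(1, #{p > lambda} / ((1 - lambda) m))` with a fixed lambda
#' (default 0.5), so Storey q-values are never larger than BH q-values.
#'
#' @param p p-values in `[0, 1]`.
#' @param method "BH" (default) or "storey".
#' @param lambda tuning point of the Storey pi0 estimate.
#' @return list with `q` (adjusted values, input order) and `pi0` (1 for BH).
#' @export
fdr_adjust <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie within [0, 1]")
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "BH") return(list(q = bh, pi0 = 1))
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * length(p)))
  pi0 <- max(pi0, 1 / length(p))  # guard against a degenerate zero estimate
  list(q = pmin(1, pi0 * bh), pi0 = pi0)
}

#' Compare per-sample alteration burdens between subtypes
#'
#' Wilcoxon rank sum comparison of a per-sample statistic (e.g. mutation
#' count) between ST1 and ST2, plus an optional per-autosome comparison of
#' copy-number segment counts with Storey FDR correction across the 22
#' autosomes.
#'
#' @param values named numeric vector (names = sample ids) of the per-sample
#'   statistic.
#' @param assignments assignment data frame (sample_id, subtype).
#' @param per_chrom_counts optional sample x chromosome matrix
#'   ([cnv_segment_counts()] with `per_chromosome = TRUE`).
#' @return list with `statistic` summaries per group, `wilcoxon_p`, and (when
#'   per-chromosome counts are given) a `per_chromosome` data frame with
#'   chrom, wilcoxon_p, q_value and the estimated pi0.
#' @export
compare_burden <- function(values, assignments, per_chrom_counts = NULL) {
  assert_columns(assignments, c("sample_id", "subtype"), "assignments")
  v <- values[assignments$sample_id]
  st1 <- v[assignments$subtype == "ST1"]
  st2 <- v[assignments$subtype == "ST2"]
  out <- list(
    group_summary = data.frame(subtype = c("ST1", "ST2"),
                               n = c(length(st1), length(st2)),
                               mean = c(mean(st1), mean(st2)),
                               median = c(stats::median(st1), stats::median(st2))),
    wilcoxon_p = wilcoxon_rank_sum(st1, st2))
  if (!is.null(per_chrom_counts)) {
    idx1 <- intersect(rownames(per_chrom_counts),
                      assignments$sample_id[assignments$subtype == "ST1"])
    idx2 <- intersect(rownames(per_chrom_counts),
                      assignments$sample_id[assignments$subtype == "ST2"])
    pv <- vapply(colnames(per_chrom_counts), function(ch)
      wilcoxon_rank_sum(per_chrom_counts[idx1, ch], per_chrom_counts[idx2, ch]), 0)
    fdr <- fdr_adjust(pv, method = "storey")
    out$per_chromosome <- data.frame(chrom = colnames(per_chrom_counts),
                                     wilcoxon_p = pv, q_value = fdr$q,
                                     row.names = NULL)
    out$pi0 <- fdr$pi0
  }
  out
}
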