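#' Call somatic point mutations from paired tumor/normal allele counts
#'
#' A heuristic caller over candidate sites: a site is emitted as somatic iff
#' the normal variant allele fraction is at most `max_normal_vaf` (default 0,
#' i.e. a normal VAF of exactly 0%), the two-sided Fisher's exact test on the
#' 2x2 table `[[tumor_ref, tumor_alt], [normal_ref, normal_alt]]` has
#' `p < p_threshold`, and at least one alternate read is present in the tumor.
#' Sites with zero total depth in either sample are skipped (and reported in
#' the `skipped` attribute with a reason).
#'
#' @param sites data frame of candidate sites with columns sample_id, chrom,
#'   pos, ref_allele, alt_allele, gene_symbol, consequence,
#'   tumor_ref_count, tumor_alt_count, normal_ref_count, normal_alt_count and
#'   optionally fis.
#' @param p_threshold Fisher p-value threshold (default 1e-5).
#' @param max_normal_vaf maximum tolerated normal VAF (default 0).
#' @param fis_threshold functional-impact score above which a missense call is
#'   deleterious (default 2.0, strict).
#' @param alternative sidedness of the exact test; two-sided by the
#'   minimum-likelihood rule, as in standard exact-test implementations.
#' @return data frame of calls with fisher_p, tumor_vaf, normal_vaf and
#'   is_deleterious columns; skipped sites in `attr(, "skipped")`.
#' @export
call_somatic <- function(sites, p_threshold = 1e-5, max_normal_vaf = 0,
                         fis_threshold = 2.0, alternative = "two.sided") {
  assert_columns(sites, c("sample_id", "tumor_ref_count", "tumor_alt_count",
                          "normal_ref_count", "normal_alt_count"), "sites")
  if (!nrow(sites)) return(sites[0, , drop = FALSE])
  td <- sites$tumor_ref_count + sites$tumor_alt_count
  nd <- sites$normal_ref_count + sites$normal_alt_count
  ok_depth <- td > 0 & nd > 0
  skipped <- sites[!ok_depth, , drop = FALSE]
  if (nrow(skipped)) {
    skipped$skip_reason <- ifelse(td[!ok_depth] == 0,
                                  "zero tumor depth", "zero normal depth")
    message(sprintf("call_somatic: skipped %d site(s) with zero depth", nrow(skipped)))
  }
  x <- sites[ok_depth, , drop = FALSE]
  td <- td[ok_depth]; nd <- nd[ok_depth]
  tumor_vaf <- x$tumor_alt_count / td
  normal_vaf <- x$normal_alt_count / nd
  fisher_p <- fisher_p2(x$tumor_ref_count, x$tumor_alt_count,
                        x$normal_ref_count, x$normal_alt_count,
                        alternative = alternative)
  keep <- normal_vaf <= max_normal_vaf & fisher_p < p_threshold & x$tumor_alt_count > 0
  calls <- x[keep, , drop = FALSE]
  calls$fisher_p <- fisher_p[keep]
  calls$tumor_vaf <- tumor_vaf[keep]
  calls$normal_vaf <- normal_vaf[keep]
  if (is.null(calls$fis)) calls$fis <- NA_real_
  calls$is_deleterious <- classify_deleterious(calls$fis, fis_threshold)
  rownames(calls) <- NULL
  attr(calls, "skipped") <- skipped
  calls
}

#' Classify functional impact scores as deleterious
#'
#' A missense change is deleterious iff its functional impact score strictly
#' exceeds the threshold (default 2.0). Absent scores are classified as
#' not-deleterious and flagged via the `missing` attribute.
#'
#' @param fis numeric vector of functional impact scores (NA = absent).
#' @param threshold strict lower bound (default 2.0).
#' @return logical vector; `attr(, "missing")` marks absent scores.
#' @export
classify_deleterious <- function(fis, threshold = 2.0) {
  out <- !is.na(fis) & fis > threshold
  attr(out, "missing") <- is.na(fis)
  out
}

#' Scan for candidate driver genes by accumulation of high functional impact
#'
#' For each gene mutated in at least two samples (and carrying at least two
#' scored mutations), compares the observed mean functional impact score of
#' its mutations with a permutation null in which scores are shuffled across
#' all scored calls. The permutation p-value uses the add-one estimator
#' `p = (1 + #{permuted statistic >= observed}) / (1 + n_permutations)`;
#' Benjamini-Hochberg q-values are attached across tested genes.
#'
#' @param calls somatic call data frame (needs gene_symbol, sample_id, fis).
#' @param n_permutations number of permutations (>= 100), or `"exhaustive"`
#'   to enumerate all score subsets per gene (small pools only).
#' @param seed integer seed for the permutation stream.
#' @param statistic summary of a gene's scores: "mean" (default), "max" or
#'   "median".
#' @return data frame with gene_symbol, n_mutations, n_samples,
#'   observed_stat, permutation_p, q_value.
#' @export
driver_scan <- function(calls, n_permutations = 1000L, seed = 1L,
                        statistic = c("mean", "max", "median")) {
  statistic <- match.arg(statistic)
  exhaustive <- identical(n_permutations, "exhaustive")
  if (!exhaustive) {
    n_permutations <- assert_count(n_permutations, "n_permutations")
    if (n_permutations < 100L) stopf("'n_permutations' must be at least 100")
  }
  assert_columns(calls, c("gene_symbol", "sample_id", "fis"), "calls")
  scored <- calls[!is.na(calls$fis), , drop = FALSE]
  if (!nrow(scored))
    return(data.frame(gene_symbol = character(0), n_mutations = integer(0),
                      n_samples = integer(0), observed_stat = numeric(0),
                      permutation_p = numeric(0), q_value = numeric(0)))
  stat_fun <- switch(statistic, mean = mean, max = max, median = stats::median)
  pool <- scored$fis
  by_gene <- split(scored, scored$gene_symbol)
  by_gene <- by_gene[vapply(by_gene, function(g)
    nrow(g) >= 2L && length(unique(g$sample_id)) >= 2L, TRUE)]
  if (!length(by_gene))
    return(data.frame(gene_symbol = character(0), n_mutations = integer(0),
                      n_samples = integer(0), observed_stat = numeric(0),
                      permutation_p = numeric(0), q_value = numeric(0)))
  set.seed(stage_seed(seed, "driver_scan"))
  res <- lapply(names(by_gene), function(g) {
    gcalls <- by_gene[[g]]
    k <- nrow(gcalls)
    obs <- stat_fun(gcalls$fis)
    if (exhaustive) {
      if (choose(length(pool), k) > 2e5)
        stopf("exhaustive null infeasible for gene '%s' (choose(%d, %d) subsets)",
              g, length(pool), k)
      subsets <- utils::combn(pool, k)
      null_stats <- apply(subsets, 2, stat_fun)
      n_null <- ncol(subsets)
    } else {
      null_stats <- vapply(seq_len(n_permutations), function(i)
        stat_fun(sample(pool, k)), 0)
      n_null <- n_permutations
    }
    data.frame(gene_symbol = g, n_mutations = k,
               n_samples = length(unique(gcalls$sample_id)),
               observed_stat = obs,
               permutation_p = (1 + sum(null_stats >= obs)) / (1 + n_null))
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$permutation_p, method = "BH")
  out[order(out$permutation_p, out$gene_symbol), ]
}

#' Per-gene and per-sample mutation frequency tables
#'
#' Counts only nonsynonymous and splice-site classes (missense, nonsense,
#' splice_site, frameshift_indel); synonymous and other consequences are
#' excluded. A sample contributes at most once to a gene's mutated-sample
#' count.
#'
#' @param calls somatic call data frame (needs gene_symbol, sample_id,
#'   consequence).
#' @return list with `gene_counts` (gene_symbol, n_samples) sorted by
#'   decreasing count, and `sample_counts` (sample_id, n_mutations).
#' @export
mutation_frequency_table <- function(calls) {
  assert_columns(calls, c("gene_symbol", "sample_id", "consequence"), "calls")
  x <- calls[calls$consequence %in% NONSYN_CLASSES, , drop = FALSE]
  if (!nrow(x))
    return(list(gene_counts = data.frame(gene_symbol = character(0),
                                         n_samples = integer(0)),
                sample_counts = data.frame(sample_id = character(0),
                                           n_mutations = integer(0))))
  pairs <- unique(x[, c("gene_symbol", "sample_id")])
  gc <- as.data.frame(table(pairs$gene_symbol), stringsAsFactors = FALSE)
  names(gc) <- c("gene_symbol", "n_samples")
  gc <- gc[order(-gc$n_samples, gc$gene_symbol), ]
  rownames(gc) <- NULL
  sc <- as.data.frame(table(x$sample_id), stringsAsFactors = FALSE)
  names(sc) <- c("sample_id", "n_mutations")
  rownames(sc) <- NULL
  list(gene_counts = gc, sample_counts = sc)
}
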