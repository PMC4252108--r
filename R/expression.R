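#' Normalize a probe-level expression matrix
#'
#' Raw signals are floored at `floor` (default 1.0), log2-transformed, and
#' each sample (column) is shifted so that its 75th percentile (linear
#' interpolation between order statistics) equals zero. The shift makes the
#' result invariant to per-sample positive scaling of the raw signals. A
#' linear-scale variant (`percentile_scale = TRUE`) divides each sample by its
#' 75th percentile before the log transform instead.
#'
#' @param mat positive numeric matrix, probes x samples.
#' @param floor raw signal threshold.
#' @param percentile percentile used for centering (default 0.75).
#' @param percentile_scale use the linear-scale division variant.
#' @return normalized log2 matrix with the same dimnames.
#' @export
normalize_expression <- function(mat, floor = 1.0, percentile = 0.75,
                                 percentile_scale = FALSE) {
  if (!is.matrix(mat) || !nrow(mat) || !ncol(mat)) stopf("'mat' must be a non-empty matrix")
  x <- pmax(mat, floor)
  if (percentile_scale) {
    q <- apply(x, 2, stats::quantile, probs = percentile, names = FALSE)
    return(log2(sweep(x, 2, q, `/`)))
  }
  y <- log2(x)
  percentile_shift(y, percentile)
}

## shift each column so its given percentile is zero (idempotent)
percentile_shift <- function(y, percentile = 0.75) {
  q <- apply(y, 2, stats::quantile, probs = percentile, names = FALSE)
  sweep(y, 2, q, `-`)
}

#' Probe-wise differential expression between subtypes
#'
#' Two-sample t-test (Welch by default) of normalized signals per probe,
#' ST1 versus ST2, with Benjamini-Hochberg q-values across all tested probes.
#' Probes with zero variance in both groups carry no evidence; they are
#' reported with p = 1 and flagged. Results are sorted by q then p.
#'
#' @param mat normalized matrix, probes x samples.
#' @param assignments assignment data frame (sample_id, subtype) covering the
#'   matrix columns; each subtype needs at least two samples.
#' @param probe_map optional data frame probe_id, gene.
#' @param var_equal pool variances (classic t) instead of Welch.
#' @param fdr significance threshold on q (stored in the result's
#'   `significant` column; default 0.1).
#' @return data frame: probe_id, gene, mean_st1, mean_st2, t_statistic, p, q,
#'   direction, constant, significant.
#' @export
differential_expression <- function(mat, assignments, probe_map = NULL,
                                    var_equal = FALSE, fdr = 0.1) {
  assert_columns(assignments, c("sample_id", "subtype"), "assignments")
  assignments <- assignments[assignments$sample_id %in% colnames(mat), , drop = FALSE]
  g1 <- assignments$sample_id[assignments$subtype == "ST1"]
  g2 <- assignments$sample_id[assignments$subtype == "ST2"]
  if (length(g1) < 2L || length(g2) < 2L)
    stopf("each subtype needs at least two samples (ST1: %d, ST2: %d)",
          length(g1), length(g2))
  m1 <- mat[, g1, drop = FALSE]
  m2 <- mat[, g2, drop = FALSE]
  n <- nrow(mat)
  t_stat <- numeric(n); pv <- numeric(n); constant <- logical(n)
  for (i in seq_len(n)) {
    x <- m1[i, ]; y <- m2[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      t_stat[i] <- 0; pv[i] <- 1; constant[i] <- TRUE
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      t_stat[i] <- unname(tt$statistic); pv[i] <- tt$p.value
    }
  }
  q <- fdr_adjust(pv, method = "BH")$q
  res <- data.frame(
    probe_id = rownames(mat) %||% as.character(seq_len(n)),
    gene = NA_character_,
    mean_st1 = rowMeans(m1), mean_st2 = rowMeans(m2),
    t_statistic = t_stat, p = pv, q = q,
    direction = ifelse(rowMeans(m1) >= rowMeans(m2), "higher_in_ST1", "lower_in_ST1"),
    constant = constant,
    significant = q < fdr & !constant,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(probe_map))
    res$gene <- probe_map$gene[match(res$probe_id, probe_map$probe_id)]
  res[order(res$q, res$p, res$probe_id), ]
}

#' Collapse probe-level differential expression records to genes
#'
#' Each gene is reported once through its minimum-q probe, with the number of
#' probes and of significant probes; probes without a gene are carried
#' through under their probe id. A gene whose significant probes disagree in
#' direction is flagged discordant.
#'
#' @param records data frame from [differential_expression()].
#' @return per-gene data frame: gene, probe_id (best probe), n_probes,
#'   n_significant, mean_st1, mean_st2, t_statistic, p, q, direction,
#'   significant, discordant.
#' @export
collapse_to_genes <- function(records) {
  assert_columns(records, c("probe_id", "gene", "q", "direction", "significant"),
                 "records")
  key <- ifelse(is.na(records$gene) | records$gene == "",
                paste0("probe:", records$probe_id), records$gene)
  by_gene <- split(records, key)
  rows <- lapply(by_gene, function(g) {
    best <- g[order(g$q, g$p, g$probe_id), ][1, ]
    sig <- g[g$significant, , drop = FALSE]
    data.frame(
      gene = if (is.na(g$gene[1]) || g$gene[1] == "") NA_character_ else g$gene[1],
      probe_id = best$probe_id,
      n_probes = nrow(g),
      n_significant = nrow(sig),
      mean_st1 = best$mean_st1, mean_st2 = best$mean_st2,
      t_statistic = best$t_statistic, p = best$p, q = best$q,
      direction = best$direction,
      significant = best$significant,
      discordant = nrow(sig) >= 2L && length(unique(sig$direction)) > 1L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$q, out$p, out$probe_id), ]
  rownames(out) <- NULL
  out
}
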