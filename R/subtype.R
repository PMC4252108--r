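#' Build per-sample p53-pathway alteration profiles
#'
#' Resolves, for every sample, the four facts consumed by the subtype rule:
#' whether TP53 carries a somatic nonsynonymous/splice mutation, the decoded
#' copy-number state over the TP53 and MDM2 loci, and any nonsynonymous hits
#' in the supplied list of direct p53 target genes. Samples without
#' copy-number data (no segments) are treated as diploid at both loci, with a
#' warning.
#'
#' @param calls somatic call data frame ([call_somatic()]).
#' @param segments concatenated segment data frame ([segment_cnv()]); may be
#'   empty.
#' @param p53_targets character vector of direct p53 target gene symbols.
#' @param gene_map data frame gene, chrom, start, end locating at least TP53
#'   and MDM2.
#' @param samples sample universe (default: samples seen in calls/segments).
#' @return data frame with sample_id, tp53_mutated, tp53_cn, mdm2_cn,
#'   p53_target_hits (comma-separated `gene:consequence` pairs, "" if none).
#' @export
build_alteration_profiles <- function(calls, segments, p53_targets, gene_map,
                                      samples = NULL) {
  assert_columns(gene_map, c("gene", "chrom", "start", "end"), "gene_map")
  samples <- samples %||% sort(unique(c(calls$sample_id, segments$sample_id)))
  tp53 <- gene_map[gene_map$gene == "TP53", ]
  mdm2 <- gene_map[gene_map$gene == "MDM2", ]
  if (!nrow(tp53) || !nrow(mdm2)) stopf("'gene_map' must locate TP53 and MDM2")
  nonsyn <- calls[calls$consequence %in% NONSYN_CLASSES, , drop = FALSE]
  no_cn <- setdiff(samples, unique(segments$sample_id))
  if (length(no_cn))
    warning(sprintf("no copy-number data for %d sample(s); assuming CN 2: %s",
                    length(no_cn), paste(no_cn, collapse = ", ")))
  cn_at <- function(sid, locus, worst) {
    s <- segments[segments$sample_id == sid & segments$chrom == locus$chrom &
                    intervals_overlap(segments$start, segments$end,
                                      locus$start, locus$end), , drop = FALSE]
    if (!nrow(s)) 2L else as.integer(worst(s$cn_state))
  }
  data.frame(
    sample_id = samples,
    tp53_mutated = samples %in% nonsyn$sample_id[nonsyn$gene_symbol == "TP53"],
    tp53_cn = vapply(samples, cn_at, 0L, locus = tp53, worst = min),
    mdm2_cn = vapply(samples, cn_at, 0L, locus = mdm2, worst = max),
    p53_target_hits = vapply(samples, function(sid) {
      h <- nonsyn[nonsyn$sample_id == sid & nonsyn$gene_symbol %in% p53_targets, ]
      if (!nrow(h)) "" else
        paste(sort(paste0(h$gene_symbol, ":", h$consequence)), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign the p53-pathway-integrity subtype to one sample
#'
#' A sample is ST2 (pathway impaired) iff any of: a somatic TP53
#' nonsynonymous/splice mutation; TP53 copy-number loss (CN < 2); MDM2
#' amplification (CN >= `mdm2_amp_cn`); or a nonsynonymous mutation in a
#' direct p53 target gene. Otherwise it is ST1 (pathway intact). The returned
#' reasons list every triggered criterion and is empty exactly for ST1.
#'
#' @param profile a one-row profile (data frame or list) with tp53_mutated,
#'   tp53_cn, mdm2_cn, p53_target_hits.
#' @param mdm2_amp_cn copy-number state treated as MDM2 amplification
#'   (default 4, i.e. high-level gain; set 3 to count any gain).
#' @return list with elements `subtype` ("ST1"/"ST2") and `reasons`
#'   (character vector).
#' @export
assign_subtype <- function(profile, mdm2_amp_cn = 4L) {
  tp53_cn <- if (is.na(profile$tp53_cn %||% NA)) 2L else profile$tp53_cn
  mdm2_cn <- if (is.na(profile$mdm2_cn %||% NA)) 2L else profile$mdm2_cn
  hits <- profile$p53_target_hits %||% ""
  reasons <- c(
    if (isTRUE(profile$tp53_mutated)) "tp53_mutation",
    if (tp53_cn < 2L) "tp53_deletion",
    if (mdm2_cn >= mdm2_amp_cn) "mdm2_amplification",
    if (!is.na(hits) && nzchar(hits)) "p53_target_mutation")
  list(subtype = if (length(reasons)) "ST2" else "ST1",
       reasons = as.character(reasons))
}

#' Assign subtypes across a cohort
#'
#' @param profiles profile data frame ([build_alteration_profiles()]).
#' @param mdm2_amp_cn see [assign_subtype()].
#' @return list with `assignments` (sample_id, subtype, reasons) and `counts`
#'   (named vector, ST1 and ST2).
#' @export
assign_cohort <- function(profiles, mdm2_amp_cn = 4L) {
  if (!nrow(profiles)) stopf("at least one profile is required")
  if (anyDuplicated(profiles$sample_id))
    stopf("duplicate sample_id in profiles: %s",
          paste(unique(profiles$sample_id[duplicated(profiles$sample_id)]),
                collapse = ", "))
  res <- lapply(seq_len(nrow(profiles)), function(i)
    assign_subtype(profiles[i, ], mdm2_amp_cn))
  assignments <- data.frame(
    sample_id = profiles$sample_id,
    subtype = vapply(res, `[[`, "", "subtype"),
    reasons = vapply(res, function(r) paste(r$reasons, collapse = ","), ""),
    stringsAsFactors = FALSE)
  counts <- c(ST1 = sum(assignments$subtype == "ST1"),
              ST2 = sum(assignments$subtype == "ST2"))
  list(assignments = assignments, counts = counts)
}
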