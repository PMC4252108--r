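#' Detect recurrent case-control copy-number variable regions
#'
#' Per probe and per direction (deletion = any overlapping segment with
#' CN < 2; amplification = CN > 2), carriers are counted in the case and
#' control cohorts and a two-sided Fisher's exact test is applied to the
#' carrier/non-carrier 2x2 table. Probes with `p < p_threshold` in the same
#' direction are merged into regions when consecutive on the probe map,
#' tolerating at most one intervening non-significant probe. Regions
#' overlapping the exclusion track (structural variants seen in healthy
#' subjects) by >= 1 bp are removed; surviving regions are annotated with
#' overlapping genes.
#'
#' @param case_segments,control_segments concatenated segment data frames
#'   ([segment_cnv()] output) for tumors and matched normals.
#' @param probe_map data frame probe_id, chrom, pos shared by both cohorts.
#' @param exclusion_bed optional data frame chrom, start, end of regions to
#'   exclude (0-based half-open).
#' @param gene_bed optional data frame chrom, start, end, name for annotation.
#' @param p_threshold per-probe significance threshold (default 0.0005).
#' @param case_samples,control_samples sample universes; default: samples
#'   present in the respective segment tables (which must then include the
#'   diploid rows of unaltered samples).
#' @return data frame of regions: chrom, start, end, direction, fisher_p
#'   (minimum probe p), n_probes, n_case_carriers, n_control_carriers, genes.
#' @export
detect_recurrent_cnvr <- function(case_segments, control_segments, probe_map,
                                  exclusion_bed = NULL, gene_bed = NULL,
                                  p_threshold = 0.0005,
                                  case_samples = NULL, control_samples = NULL) {
  assert_columns(probe_map, c("probe_id", "chrom", "pos"), "probe_map")
  case_samples <- case_samples %||% unique(case_segments$sample_id)
  control_samples <- control_samples %||% unique(control_segments$sample_id)
  if (!length(control_samples)) stopf("control cohort is empty")
  if (!length(case_samples)) stopf("case cohort is empty")

  carrier_matrix <- function(segments, samples, direction) {
    keep <- if (direction == "deletion") segments$cn_state < 2L else segments$cn_state > 2L
    segs <- segments[keep, , drop = FALSE]
    m <- matrix(FALSE, length(samples), nrow(probe_map),
                dimnames = list(samples, probe_map$probe_id))
    for (i in seq_len(nrow(segs))) {
      hit <- probe_map$chrom == segs$chrom[i] &
        probe_map$pos >= segs$start[i] & probe_map$pos < segs$end[i]
      if (any(hit)) m[segs$sample_id[i], hit] <- TRUE
    }
    m
  }

  regions <- list()
  for (direction in c("deletion", "amplification")) {
    case_m <- carrier_matrix(case_segments, case_samples, direction)
    ctrl_m <- carrier_matrix(control_segments, control_samples, direction)
    cc <- colSums(case_m)
    kc <- colSums(ctrl_m)
    pv <- rep(1, nrow(probe_map))
    todo <- cc + kc > 0
    if (any(todo))
      pv[todo] <- fisher_p2(cc[todo], length(case_samples) - cc[todo],
                            kc[todo], length(control_samples) - kc[todo])
    sig <- pv < p_threshold
    for (ch in unique(probe_map$chrom)) {
      idx <- which(probe_map$chrom == ch)
      idx <- idx[order(probe_map$pos[idx])]
      sig_idx <- idx[sig[idx]]
      if (!length(sig_idx)) next
      ## group significant probes separated by <= 1 non-significant probe
      rank_in_chrom <- match(sig_idx, idx)
      grp <- cumsum(c(1L, diff(rank_in_chrom) > 2L))
      for (g in unique(grp)) {
        members <- sig_idx[grp == g]
        pos <- probe_map$pos[members]
        spacing <- if (length(idx) > 1L)
          stats::median(diff(probe_map$pos[idx])) else 1L
        in_reg <- probe_map$chrom == ch &
          probe_map$pos >= min(pos) & probe_map$pos <= max(pos)
        regions[[length(regions) + 1L]] <- data.frame(
          chrom = ch, start = min(pos), end = max(pos) + spacing,
          direction = direction,
          fisher_p = min(pv[members]),
          n_probes = length(members),
          n_case_carriers = max(0L, sum(rowSums(case_m[, in_reg, drop = FALSE]) > 0L)),
          n_control_carriers = max(0L, sum(rowSums(ctrl_m[, in_reg, drop = FALSE]) > 0L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(regions))
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      direction = character(0), fisher_p = numeric(0),
                      n_probes = integer(0), n_case_carriers = integer(0),
                      n_control_carriers = integer(0), genes = character(0)))
  out <- do.call(rbind, regions)
  if (!is.null(exclusion_bed) && nrow(exclusion_bed)) {
    drop <- vapply(seq_len(nrow(out)), function(i)
      any(exclusion_bed$chrom == out$chrom[i] &
            intervals_overlap(exclusion_bed$start, exclusion_bed$end,
                              out$start[i], out$end[i])), TRUE)
    out <- out[!drop, , drop = FALSE]
  }
  out$genes <- rep("", nrow(out))
  if (!is.null(gene_bed) && nrow(gene_bed) && nrow(out)) {
    out$genes <- vapply(seq_len(nrow(out)), function(i) {
      hit <- gene_bed$chrom == out$chrom[i] &
        intervals_overlap(gene_bed$start, gene_bed$end, out$start[i], out$end[i])
      paste(sort(gene_bed$name[hit]), collapse = ",")
    }, "")
  }
  out <- out[order(out$chrom, out$start, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
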