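#' Estimate tumor purity from segmented LRR/BAF data
#'
#' Allele-specific grid search: for each candidate purity `rho`, every
#' non-diploid segment's mean LRR `r` and mirrored mean heterozygous BAF `b`
#' are inverted to continuous allele-specific copy numbers via
#' `b = (1 - rho + rho * nB) / (2 (1 - rho) + rho (nA + nB))` and
#' `r = gamma * log2((2 (1 - rho) + rho (nA + nB)) / 2)`, and the fit score is
#' the probe-weighted mean squared distance of `(nA, nB)` to the nearest
#' non-negative integers. The grid minimizer is returned; ties prefer the
#' larger purity. With the LRR track normalized to the diploid baseline,
#' ploidy is a derived quantity: it is reported as the probe-weighted mean
#' rounded total copy number, snapped to a 1.0-5.5 grid.
#'
#' A sample whose segments are all balanced diploid carries no information on
#' contamination; it is reported with `identifiable = FALSE` and `rho = 1`.
#'
#' Heterozygous probes are taken from the track's `het` column (germline
#' genotypes, available in practice from the matched normal array); when the
#' column is absent a BAF heuristic (0.1 < BAF < 0.9 in a diploid mixture) is
#' used, which cannot recognize LOH heterozygotes at high purity.
#'
#' @param track probe data frame (chrom, pos, lrr, baf, optionally het).
#' @param segments segment data frame for this sample ([segment_cnv()]).
#' @param gamma LRR compression constant (default 0.66, matched to the
#'   canonical per-state LRR means used by the segmentation model).
#' @param rho_grid candidate purities (default 0.10-1.00, step 0.01).
#' @param psi_grid ploidy reporting grid (default 1.0-5.5, step 0.05).
#' @param min_het_probes minimum heterozygous probes per usable segment.
#' @param exclude optional data frame chrom, start, end of regions to drop
#'   from the fit (typically regions altered in the matched normal, i.e.
#'   germline copy-number variants, which are present in all cells and would
#'   otherwise masquerade as fully clonal aberrations).
#' @return a one-row data frame of class `purity_estimate`: sample_id, rho,
#'   psi, fit_score, gamma, identifiable, n_informative_probes.
#' @export
estimate_purity <- function(track, segments, gamma = LRR_GAMMA,
                            rho_grid = seq(0.10, 1.00, by = 0.01),
                            psi_grid = seq(1.0, 5.5, by = 0.05),
                            min_het_probes = 5L, exclude = NULL) {
  assert_columns(track, c("chrom", "pos", "lrr", "baf"), "track")
  if (!nrow(segments)) stopf("no segments supplied")
  if (!is.null(exclude) && nrow(exclude)) {
    drop <- vapply(seq_len(nrow(segments)), function(i)
      any(exclude$chrom == segments$chrom[i] &
            intervals_overlap(exclude$start, exclude$end,
                              segments$start[i], segments$end[i])), TRUE)
    segments <- segments[!drop, , drop = FALSE]
    if (!nrow(segments)) stopf("all segments excluded")
  }
  sid <- if (!is.null(segments$sample_id)) segments$sample_id[1] else NA_character_
  het <- if (!is.null(track$het)) track$het else track$baf > 0.1 & track$baf < 0.9

  seg_stats <- lapply(seq_len(nrow(segments)), function(i) {
    in_seg <- track$chrom == segments$chrom[i] &
      track$pos >= segments$start[i] & track$pos < segments$end[i]
    hp <- in_seg & het
    list(cn = segments$cn_state[i],
         n = sum(hp),
         r = mean(track$lrr[in_seg]),
         b = mean(pmax(track$baf[hp], 1 - track$baf[hp])))
  })
  usable <- vapply(seg_stats, function(s)
    s$cn != 2L && s$n >= min_het_probes && is.finite(s$r) && is.finite(s$b), TRUE)
  res <- data.frame(sample_id = sid, rho = 1, psi = 2, fit_score = NA_real_,
                    gamma = gamma, identifiable = FALSE,
                    n_informative_probes = sum(vapply(seg_stats[usable], `[[`, 0L, "n")))
  class(res) <- c("purity_estimate", class(res))
  if (!any(usable)) return(res)

  ss <- seg_stats[usable]
  r <- vapply(ss, `[[`, 0, "r")
  b <- vapply(ss, `[[`, 0, "b")
  w <- vapply(ss, `[[`, 0L, "n")
  d_tot <- 2 * 2^(r / gamma)  # 2(1-rho) + rho(nA+nB), fixed by the observation
  fit <- vapply(rho_grid, function(rho) {
    n_major <- (b * d_tot - (1 - rho)) / rho
    n_total <- (d_tot - 2 * (1 - rho)) / rho
    n_minor <- n_total - n_major
    ## nearest NON-NEGATIVE integer: a negative implied allele count is not
    ## forgiven, it is scored against 0, which rules out aliasing solutions
    t_major <- pmax(round(n_major), 0); t_minor <- pmax(round(n_minor), 0)
    sum(w * ((n_major - t_major)^2 + (n_minor - t_minor)^2)) / sum(w)
  }, 0)
  best <- max(which(fit <= min(fit) + 1e-12))  # ties -> larger purity
  rho_hat <- rho_grid[best]

  ## derived ploidy over all segments at the selected purity
  all_r <- vapply(seg_stats, `[[`, 0, "r")
  all_w <- vapply(seg_stats, function(s) max(s$n, 1L), 0)
  n_tot_all <- pmax(0, round((2 * 2^(all_r / gamma) - 2 * (1 - rho_hat)) / rho_hat))
  psi_raw <- sum(all_w * n_tot_all) / sum(all_w)
  res$rho <- rho_hat
  res$psi <- psi_grid[which.min(abs(psi_grid - psi_raw))]
  res$fit_score <- fit[best]
  res$identifiable <- TRUE
  res
}

#' Segment a track and estimate purity jointly
#'
#' Purity-aware wrapper: the HMM's emission centers depend on the
#' contamination level, so the track is decoded under a small grid of assumed
#' purities; each candidate segmentation is scored with [estimate_purity()]
#' and the candidate with the best (lowest) fit among identifiable solutions
#' is returned together with its segments.
#'
#' @param track probe data frame for one sample.
#' @param params base [hmm_params()]; its `purity` field is overridden by the
#'   candidates.
#' @param seg_purity_grid assumed purities for the decoding pass.
#' @param ... passed on to [estimate_purity()].
#' @return list with elements `estimate` (a `purity_estimate` row) and
#'   `segments` (the selected segmentation).
#' @export
estimate_purity_track <- function(track, params = hmm_params(),
                                  seg_purity_grid = c(1, 0.85, 0.7, 0.55, 0.4),
                                  ...) {
  best <- NULL
  for (w in seg_purity_grid) {
    pw <- hmm_params(state_means = params$state_means, lrr_sd = params$lrr_sd,
                     baf_sd = params$baf_sd, het_fraction = params$het_fraction,
                     stay_prob = params$stay_prob, purity = w,
                     gamma = params$gamma, min_probes = params$min_probes)
    segs <- segment_cnv(track, pw)
    if (!nrow(segs)) next
    est <- tryCatch(estimate_purity(track, segs, gamma = params$gamma, ...),
                    error = function(e) NULL)
    if (is.null(est)) next
    cand <- list(estimate = est, segments = segs, seg_purity = w)
    if (is.null(best)) { best <- cand; next }
    if (est$identifiable && (!best$estimate$identifiable ||
                             est$fit_score < best$estimate$fit_score))
      best <- cand
  }
  if (is.null(best)) stopf("track could not be segmented")
  best
}
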