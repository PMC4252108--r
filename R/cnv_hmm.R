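#' Parameters of the 5-state copy-number hidden Markov model
#'
#' States are integer copy numbers 0-4 (4 stands for >= 4). LRR emissions are
#' Gaussian around canonical per-state means; BAF emissions are Gaussian
#' mixtures over the genotype clusters implied by the state, the germline
#' heterozygote fraction and, optionally, a normal-cell contamination level
#' (`purity`), which pulls both the LRR means and the heterozygous BAF
#' clusters toward their diploid values.
#'
#' @param state_means named per-state LRR means at purity 1.
#' @param lrr_sd per-state (or scalar) LRR emission SD.
#' @param baf_sd BAF cluster SD.
#' @param het_fraction germline heterozygote fraction.
#' @param stay_prob per-probe self-transition probability.
#' @param purity assumed tumor cell fraction used to adjust emission centers.
#' @param gamma LRR compression constant used for the purity mixing.
#' @param min_probes minimum probes per emitted segment.
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(state_means = LRR_STATE_MEANS,
                       lrr_sd = c(1.0, 0.25, 0.22, 0.25, 0.3),
                       baf_sd = 0.04,
                       het_fraction = 1 / 3,
                       stay_prob = 1 - 1e-4,
                       purity = 1,
                       gamma = LRR_GAMMA,
                       min_probes = 3L) {
  if (length(lrr_sd) == 1L) lrr_sd <- rep(lrr_sd, 5L)
  if (length(lrr_sd) != 5L || any(lrr_sd <= 0)) stopf("'lrr_sd' must be 5 positive values")
  assert_proportion(purity, "purity")
  if (purity <= 0) stopf("'purity' must be within (0, 1]")
  w <- purity
  mixed_means <- gamma * log2(w * 2^(state_means / gamma) + (1 - w))
  ## heterozygous BAF cluster centers per state under contamination w
  het_centers <- list(
    `0` = 0.5,
    `1` = c((1 - w) / (2 - w), 1 / (2 - w)),
    `2` = 0.5,
    `3` = c(1 / (2 + w), (1 + w) / (2 + w)),
    `4` = c(1 / (2 + 2 * w), (1 + 2 * w) / (2 + 2 * w)))
  structure(list(state_means = state_means, mixed_means = mixed_means,
                 lrr_sd = lrr_sd, baf_sd = baf_sd,
                 het_fraction = het_fraction, het_centers = het_centers,
                 stay_prob = stay_prob, purity = purity, gamma = gamma,
                 min_probes = as.integer(min_probes)),
            class = "hmm_params")
}

## log emission density matrix (probes x 5 states)
cnv_log_emission <- function(lrr, baf, params, use_baf = TRUE) {
  n <- length(lrr)
  em <- matrix(NA_real_, n, 5L)
  hf <- params$het_fraction
  for (s in 1:5) {
    le <- stats::dnorm(lrr, params$mixed_means[s], params$lrr_sd[s], log = TRUE)
    if (use_baf) {
      if (s == 1L) {
        ## CN 0: no allelic signal, BAF ~ uniform
        be <- rep(0, n)
      } else {
        centers <- params$het_centers[[as.character(s - 1L)]]
        hom_d <- 0.5 * (stats::dnorm(baf, 0, params$baf_sd) +
                          stats::dnorm(baf, 1, params$baf_sd))
        het_d <- rowMeans(matrix(vapply(centers, function(c0)
          stats::dnorm(baf, c0, params$baf_sd), numeric(n)), nrow = n))
        be <- log((1 - hf) * hom_d + hf * het_d + 0.02)
      }
      em[, s] <- le + be
    } else {
      em[, s] <- le
    }
  }
  em
}

cnv_transitions <- function(params) {
  tr <- matrix((1 - params$stay_prob) / 4, 5L, 5L)
  diag(tr) <- params$stay_prob
  log(tr)
}

## Viterbi decoding; returns integer state indices 1..5 (copy number = idx-1)
viterbi_decode <- function(log_em, log_tr, log_init) {
  n <- nrow(log_em)
  delta <- matrix(-Inf, n, 5L)
  psi <- matrix(0L, n, 5L)
  delta[1, ] <- log_init + log_em[1, ]
  for (t in 2:max(2L, n)) {
    if (t > n) break
    for (s in 1:5) {
      cand <- delta[t - 1, ] + log_tr[, s]
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]] + log_em[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Segment an LRR/BAF track into integer copy-number states
#'
#' Viterbi-decodes the 5-state HMM per chromosome and converts maximal runs of
#' equal state into segments. Runs shorter than `min_probes` are absorbed into
#' the flanking state whose model LRR mean is closer to the run's observed
#' mean. Diploid (CN 2) segments are retained in the output (they anchor
#' purity estimation) and flagged with `is_alteration = FALSE`.
#'
#' @param track probe data frame (probe_id, chrom, pos, lrr, baf; optionally
#'   sample_id and het). Probes must be position-sorted within chromosome.
#' @param params an [hmm_params()] object.
#' @return data frame of segments: sample_id, chrom, start, end (0-based
#'   half-open, ends at the last probe position + median spacing), cn_state,
#'   n_probes, mean_lrr, is_alteration.
#' @export
segment_cnv <- function(track, params = hmm_params()) {
  assert_columns(track, c("chrom", "pos", "lrr", "baf"), "track")
  sid <- if (!is.null(track$sample_id)) track$sample_id[1] else NA_character_
  use_baf <- !all(is.na(track$baf))
  if (!use_baf) warning("all BAF values missing; decoding on LRR only")
  log_tr <- cnv_transitions(params)
  log_init <- log(c(0.0025, 0.0025, 0.99, 0.0025, 0.0025))
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (is.unsorted(tr$pos, strictly = TRUE))
      stopf("probes on chromosome %s are not strictly position-sorted", ch)
    if (nrow(tr) < params$min_probes) next
    em <- cnv_log_emission(tr$lrr, if (use_baf) tr$baf else NULL, params, use_baf)
    path <- viterbi_decode(em, log_tr, log_init) - 1L  # copy numbers 0..4
    spacing <- if (nrow(tr) > 1L) stats::median(diff(tr$pos)) else 1L
    segs <- path_to_segments(path, tr$lrr, params)
    for (i in seq_len(nrow(segs))) {
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch,
        start = tr$pos[segs$first[i]],
        end = tr$pos[segs$last[i]] + spacing,
        cn_state = segs$state[i],
        n_probes = segs$last[i] - segs$first[i] + 1L,
        mean_lrr = mean(tr$lrr[segs$first[i]:segs$last[i]]),
        stringsAsFactors = FALSE)
    }
  }
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), cn_state = integer(0), n_probes = integer(0),
               mean_lrr = numeric(0))
  segs$is_alteration <- segs$cn_state != 2L
  rownames(segs) <- NULL
  segs
}

## collapse a decoded state path into runs, absorbing short runs into the
## flanking state with the closer model LRR mean
path_to_segments <- function(path, lrr, params) {
  repeat {
    r <- rle(path)
    if (length(r$lengths) == 1L || all(r$lengths >= params$min_probes)) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    i <- which(r$lengths < params$min_probes)
    i <- i[which.min(r$lengths[i])][1]
    run_mean <- mean(lrr[starts[i]:ends[i]])
    cand <- c(if (i > 1L) r$values[i - 1L] else NA_integer_,
              if (i < length(r$values)) r$values[i + 1L] else NA_integer_)
    cand <- cand[!is.na(cand)]
    dist <- abs(params$mixed_means[cand + 1L] - run_mean)
    path[starts[i]:ends[i]] <- cand[which.min(dist)]
  }
  r <- rle(path)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values, first = ends - r$lengths + 1L, last = ends)
}

#' Count altered copy-number segments per sample
#'
#' Counts segments with CN != 2 on the 22 autosomes, optionally per
#' chromosome; samples without alterations are zero-filled.
#'
#' @param segments segment data frame from [segment_cnv()] (rows from several
#'   samples can be concatenated).
#' @param per_chromosome return a sample x chromosome count matrix.
#' @param samples sample universe for zero-filling (default: samples present
#'   in `segments`, including their diploid rows).
#' @return data frame sample_id, n_segments, or a sample x chromosome matrix.
#' @export
cnv_segment_counts <- function(segments, per_chromosome = FALSE, samples = NULL) {
  assert_columns(segments, c("sample_id", "chrom", "cn_state"), "segments")
  samples <- samples %||% sort(unique(segments$sample_id))
  alt <- segments[segments$cn_state != 2L & segments$chrom %in% AUTOSOMES, , drop = FALSE]
  if (per_chromosome) {
    chroms <- AUTOSOMES
    m <- matrix(0L, length(samples), length(chroms),
                dimnames = list(samples, chroms))
    if (nrow(alt)) {
      tb <- table(alt$sample_id, alt$chrom)
      m[rownames(tb), colnames(tb)] <- tb
    }
    return(m)
  }
  counts <- stats::setNames(rep(0L, length(samples)), samples)
  if (nrow(alt)) {
    tb <- table(alt$sample_id)
    counts[names(tb)] <- as.integer(tb)
  }
  data.frame(sample_id = samples, n_segments = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}
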