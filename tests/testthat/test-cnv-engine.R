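test_that("a noiseless diploid track yields one CN 2 segment per chromosome", {
  set.seed(1)
  tr <- simulate_snp_track(data.frame(), purity = 1, noise_sd = 0.01,
                           baf_noise_sd = 0.005, chroms = c("1", "2"),
                           n_probes_per_chrom = 100L)
  segs <- segment_cnv(tr)
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$cn_state == 2L))
  expect_true(all(!segs$is_alteration))
})

test_that("a planted deletion is recovered with high overlap", {
  set.seed(2)
  truth <- data.frame(chrom = "1", start = 200000L, end = 450000L, cn_state = 1L)
  tr <- simulate_snp_track(truth, purity = 1, noise_sd = 0.2, chroms = "1",
                           n_probes_per_chrom = 300L)
  segs <- segment_cnv(tr)
  del <- segs[segs$cn_state == 1L, ]
  expect_equal(nrow(del), 1L)
  inter <- max(0, min(del$end, truth$end) - max(del$start, truth$start))
  union <- max(del$end, truth$end) - min(del$start, truth$start)
  expect_gte(inter / union, 0.9)
})

test_that("short state blips are absorbed by the minimum-probe rule", {
  set.seed(3)
  base <- simulate_snp_track(data.frame(), purity = 1, noise_sd = 0.05,
                             baf_noise_sd = 0.01, chroms = "1",
                             n_probes_per_chrom = 60L)
  ## inject a two-probe CN 3 excursion
  base$lrr[30:31] <- 0.40
  segs <- segment_cnv(base, hmm_params(min_probes = 3L))
  expect_true(all(segs$cn_state == 2L))
  expect_equal(nrow(segs), 1L)
})

test_that("unsorted probes are rejected and missing BAF falls back to LRR", {
  set.seed(4)
  tr <- simulate_snp_track(data.frame(), purity = 1, chroms = "1",
                           n_probes_per_chrom = 50L)
  bad <- tr[c(2, 1, 3:50), ]
  expect_error(segment_cnv(bad), "sorted")
  tr$baf <- NA_real_
  expect_warning(segs <- segment_cnv(tr), "BAF")
  expect_equal(segs$cn_state, 2L)
})

test_that("Viterbi decoding equals exhaustive best-path enumeration", {
  set.seed(5)
  params <- hmm_params()
  log_tr <- p53pathtype:::cnv_transitions(params)
  log_init <- log(c(0.0025, 0.0025, 0.99, 0.0025, 0.0025))
  for (L in c(1:4, 6, 8)) {
    for (rep in 1:3) {
      lrr <- rnorm(L, sample(c(-0.7, 0, 0.4), L, replace = TRUE), 0.3)
      baf <- runif(L)
      em <- p53pathtype:::cnv_log_emission(lrr, baf, params, use_baf = TRUE)
      got <- p53pathtype:::viterbi_decode(em, log_tr, log_init)
      want <- brute_best_path(em, log_tr, log_init)
      expect_identical(got, as.integer(want), info = sprintf("L=%d rep=%d", L, rep))
    }
  }
})

test_that("recurrent-region detection matches the enumeration oracle and honors exclusions", {
  probe_map <- data.frame(probe_id = sprintf("p%02d", 1:30), chrom = "1",
                          pos = (0:29) * 1000L)
  seg <- function(sid, start, end, cn)
    data.frame(sample_id = sid, chrom = "1", start = start, end = end,
               cn_state = cn, n_probes = 5L, mean_lrr = 0)
  cases <- paste0("C", 1:30)
  controls <- paste0("N", 1:30)
  ## 15/30 cases deleted over probes 10-19, no controls
  case_segs <- do.call(rbind, lapply(cases[1:15], seg, start = 10000L,
                                     end = 20000L, cn = 1L))
  ctrl_segs <- seg("N1", 25000L, 26000L, 2L)
  cnvr <- detect_recurrent_cnvr(case_segs, ctrl_segs, probe_map,
                                case_samples = cases, control_samples = controls)
  expect_equal(nrow(cnvr), 1L)
  expect_equal(cnvr$direction, "deletion")
  expect_equal(cnvr$n_case_carriers, 15L)
  expect_equal(cnvr$fisher_p, fisher_enum_two_sided(15, 15, 0, 30), tolerance = 1e-12)
  expect_lt(fisher_enum_two_sided(15, 15, 0, 30), 0.0005)
  expect_equal(cnvr$start, 10000L)
  expect_equal(cnvr$end, 20000L)

  ## 2/30 vs 0/30 never reaches the threshold by enumeration
  rare <- do.call(rbind, lapply(cases[1:2], seg, start = 10000L,
                                end = 20000L, cn = 1L))
  expect_gt(fisher_enum_two_sided(2, 28, 0, 30), 0.0005)
  expect_equal(nrow(detect_recurrent_cnvr(rare, ctrl_segs, probe_map,
                                          case_samples = cases,
                                          control_samples = controls)), 0L)

  ## a region inside the healthy-SV exclusion track is never reported
  excl <- data.frame(chrom = "1", start = 15000L, end = 16000L)
  expect_equal(nrow(detect_recurrent_cnvr(case_segs, ctrl_segs, probe_map,
                                          exclusion_bed = excl,
                                          case_samples = cases,
                                          control_samples = controls)), 0L)
  expect_error(detect_recurrent_cnvr(case_segs, ctrl_segs[0, ], probe_map),
               "control")

  ## output is invariant to the ordering of input segments
  perm <- case_segs[rev(seq_len(nrow(case_segs))), ]
  expect_identical(detect_recurrent_cnvr(case_segs, ctrl_segs, probe_map,
                                         case_samples = cases,
                                         control_samples = controls),
                   detect_recurrent_cnvr(perm, ctrl_segs, probe_map,
                                         case_samples = rev(cases),
                                         control_samples = controls))
})

test_that("altered-segment counts are zero-filled and autosome-restricted", {
  segs <- data.frame(sample_id = c("A", "A", "B"), chrom = c("1", "X", "2"),
                     start = 0L, end = 1000L, cn_state = c(1L, 1L, 3L),
                     n_probes = 10L, mean_lrr = 0)
  counts <- cnv_segment_counts(segs, samples = c("A", "B", "C"))
  expect_equal(counts$n_segments, c(1L, 1L, 0L))  # X excluded, C zero-filled
  m <- cnv_segment_counts(segs, per_chromosome = TRUE, samples = c("A", "B", "C"))
  expect_equal(dim(m), c(3L, 22L))
  expect_equal(m["A", "1"], 1L)
  expect_equal(sum(m), 2L)

  co <- make_test_cohort(seed = 23)
  truth_alt <- co$truth$segments[co$truth$segments$cn_state != 2L, ]
  got <- cnv_segment_counts(truth_alt, samples = co$truth$samples$sample_id)
  want <- vapply(co$truth$samples$sample_id, function(s)
    sum(truth_alt$sample_id == s & truth_alt$chrom %in% as.character(1:22)), 0L)
  expect_equal(got$n_segments, unname(want))
})

test_that("purity is recovered from allele-specific segment fits", {
  set.seed(6)
  segs <- data.frame(chrom = c("1", "2"), start = c(200000L, 100000L),
                     end = c(450000L, 350000L), cn_state = c(1L, 3L))
  for (rho in c(1.0, 0.75)) {
    tr <- simulate_snp_track(segs, rho, chroms = c("1", "2"),
                             n_probes_per_chrom = 500L)
    est <- estimate_purity_track(tr)$estimate
    expect_true(est$identifiable)
    expect_lte(abs(est$rho - rho), 0.05)
  }
  ## an all-diploid sample is unidentifiable and reported as purity 1
  flat <- simulate_snp_track(data.frame(), purity = 0.8, chroms = "1",
                             n_probes_per_chrom = 200L)
  dip_segs <- segment_cnv(flat)
  est <- estimate_purity(flat, dip_segs)
  expect_false(est$identifiable)
  expect_equal(est$rho, 1)
  expect_error(estimate_purity(flat, dip_segs[0, ]), "segments")
})
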