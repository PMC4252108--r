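## Canonical SNP-array per-state log R ratio means (diploid-normalized) and the
## LRR compression constant they imply (CN 1: -0.66 = gamma * log2(1/2) at
## gamma = 0.66). The simulator and the purity model share this calibration.
LRR_STATE_MEANS <- c(`0` = -3.5, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)
LRR_GAMMA <- 0.66

#' Direct p53 transcriptional target genes bundled as a default resource
#'
#' A compact list of well-established direct p53 target genes (cell-cycle
#' arrest, apoptosis, DNA repair, and interferon-response effectors) used as
#' the default target resource of the synthetic cohort generator. Any
#' user-supplied list (plain text or GMT) can be used instead; nothing in the
#' subtype rule is tied to this particular set.
#'
#' @return character vector of gene symbols.
#' @export
default_p53_targets <- function() {
  c("CDKN1A", "BAX", "PMAIP1", "BBC3", "GADD45A", "SFN", "SERPINB5",
    "TP53I3", "IRF5", "FAS", "TNFRSF10B", "SESN1", "SESN2", "RRM2B",
    "ZMAT3", "TIGAR", "DDB2", "POLH", "XPC", "CCNG1", "PERP", "AEN",
    "APAF1", "TP53AIP1", "THBS1")
}

#' Configuration of the synthetic HGSOC-like cohort generator
#'
#' Defaults emulate a reference HGSOC cohort: 34 tumors of which 6 carry an
#' intact p53 pathway, a mean of 41 nonsynonymous/splice somatic mutations per
#' sample, mean exome depth 91x (tumor) / 84x (normal), tumor purity between
#' 0.60 and 0.95 (cohort averages near 0.73-0.79), and a variant-allele-
#' fraction floor of 0.20.
#'
#' @param n_samples number of tumor samples.
#' @param fraction_st1 fraction of samples with an intact p53 pathway (ST1).
#' @param mean_mutations cohort mean of true nonsynonymous + splice-site
#'   mutations per sample.
#' @param mutation_dispersion negative-binomial size parameter of the
#'   per-sample mutation count (smaller = more inter-sample spread).
#' @param st1_mutation_ratio multiplicative reduction of the ST1 mutation
#'   burden relative to ST2; the two group means are scaled so the cohort
#'   mean stays at `mean_mutations`.
#' @param tumor_vaf_floor minimum true tumor variant allele fraction.
#' @param mean_depth_tumor,mean_depth_normal Poisson means of per-site depth.
#' @param normal_error_rate per-read error rate in the matched normal
#'   (default 0, matching the caller's 0% normal-VAF filter).
#' @param purity_range range of per-sample tumor purity, within (0, 1].
#' @param n_chrom number of simulated autosomes.
#' @param n_probes_per_chrom SNP probes per chromosome.
#' @param probe_spacing distance between adjacent probes (bp).
#' @param het_fraction fraction of probes heterozygous in the germline.
#' @param lrr_noise_sd,baf_noise_sd per-probe Gaussian noise.
#' @param cn_segments_st1_mean,cn_segments_st2_mean Poisson means of the
#'   number of somatic copy-number segments per sample by subtype.
#' @param mechanism_probs probabilities of the four p53-pathway hit mechanisms
#'   assigned to each ST2 sample (TP53 mutation, TP53 deletion, MDM2
#'   amplification, p53-target-gene mutation).
#' @param recurrent_del_prob probability that an ST2 sample carries the
#'   planted recurrent somatic deletion region.
#' @param n_genes number of background genes in the synthetic genome.
#' @param n_expr_probes expression probes on the simulated array.
#' @param n_shifted_probes,n_shifted_genes number of probes (genes) whose mean
#'   expression differs between subtypes.
#' @param expr_effect_sd subtype shift of a differential probe, in units of
#'   the per-probe noise SD. The default 3 reflects the standardized effect
#'   size a probe must carry to be detectable at FDR 0.1 with 6 vs 28 samples.
#' @param expr_noise_sd per-probe log2 expression noise SD.
#' @param n_terms,n_planted_terms annotation terms in the synthetic GMT and
#'   how many of them are planted over the truly shifted genes.
#' @param n_healthy_sv number of polymorphic structural-variant regions seen
#'   in healthy subjects (the CNVR exclusion track).
#' @param germline_cnv_prob per-sample carrier probability of each healthy-SV
#'   region (present in tumor and matched normal alike).
#' @param seed integer seed; every draw of the generator derives from it.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_samples = 34L,
                          fraction_st1 = 6 / 34,
                          mean_mutations = 41,
                          mutation_dispersion = 5,
                          st1_mutation_ratio = 0.35,
                          tumor_vaf_floor = 0.20,
                          mean_depth_tumor = 91L,
                          mean_depth_normal = 84L,
                          normal_error_rate = 0,
                          purity_range = c(0.60, 0.95),
                          n_chrom = 22L,
                          n_probes_per_chrom = 400L,
                          probe_spacing = 5000L,
                          het_fraction = 1 / 3,
                          lrr_noise_sd = 0.2,
                          baf_noise_sd = 0.03,
                          cn_segments_st1_mean = 0.7,
                          cn_segments_st2_mean = 8,
                          mechanism_probs = c(tp53_mutation = 0.90,
                                              tp53_deletion = 0.04,
                                              mdm2_amplification = 0.02,
                                              p53_target_mutation = 0.04),
                          recurrent_del_prob = 0.5,
                          n_genes = 400L,
                          n_expr_probes = 2000L,
                          n_shifted_probes = 89L,
                          n_shifted_genes = 70L,
                          expr_effect_sd = 3,
                          expr_noise_sd = 0.5,
                          n_terms = 40L,
                          n_planted_terms = 5L,
                          n_healthy_sv = 12L,
                          germline_cnv_prob = 0.12,
                          seed = 1L) {
  cfg <- list(
    n_samples = assert_count(n_samples, "n_samples"),
    fraction_st1 = assert_proportion(fraction_st1, "fraction_st1"),
    mean_mutations = mean_mutations,
    mutation_dispersion = mutation_dispersion,
    st1_mutation_ratio = st1_mutation_ratio,
    tumor_vaf_floor = assert_proportion(tumor_vaf_floor, "tumor_vaf_floor"),
    mean_depth_tumor = assert_count(mean_depth_tumor, "mean_depth_tumor"),
    mean_depth_normal = assert_count(mean_depth_normal, "mean_depth_normal"),
    normal_error_rate = assert_proportion(normal_error_rate, "normal_error_rate"),
    purity_range = purity_range,
    n_chrom = assert_count(n_chrom, "n_chrom"),
    n_probes_per_chrom = assert_count(n_probes_per_chrom, "n_probes_per_chrom"),
    probe_spacing = assert_count(probe_spacing, "probe_spacing"),
    het_fraction = assert_proportion(het_fraction, "het_fraction"),
    lrr_noise_sd = lrr_noise_sd,
    baf_noise_sd = baf_noise_sd,
    cn_segments_st1_mean = cn_segments_st1_mean,
    cn_segments_st2_mean = cn_segments_st2_mean,
    mechanism_probs = mechanism_probs,
    recurrent_del_prob = assert_proportion(recurrent_del_prob, "recurrent_del_prob"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_expr_probes = assert_count(n_expr_probes, "n_expr_probes"),
    n_shifted_probes = assert_count(n_shifted_probes, "n_shifted_probes"),
    n_shifted_genes = assert_count(n_shifted_genes, "n_shifted_genes"),
    expr_effect_sd = expr_effect_sd,
    expr_noise_sd = expr_noise_sd,
    n_terms = assert_count(n_terms, "n_terms"),
    n_planted_terms = assert_count(n_planted_terms, "n_planted_terms"),
    n_healthy_sv = assert_count(n_healthy_sv, "n_healthy_sv"),
    germline_cnv_prob = assert_proportion(germline_cnv_prob, "germline_cnv_prob"),
    seed = assert_count(seed, "seed", positive = FALSE)
  )
  if (!is.numeric(cfg$mean_mutations) || cfg$mean_mutations <= 0)
    stopf("'mean_mutations' must be a positive real")
  if (!is.numeric(cfg$mutation_dispersion) || cfg$mutation_dispersion <= 0)
    stopf("'mutation_dispersion' must be a positive real")
  if (cfg$st1_mutation_ratio <= 0 || cfg$st1_mutation_ratio > 1)
    stopf("'st1_mutation_ratio' must be in (0, 1]")
  pr <- cfg$purity_range
  if (!is.numeric(pr) || length(pr) != 2L || pr[1] > pr[2] || pr[1] <= 0 || pr[2] > 1)
    stopf("'purity_range' must be an increasing interval within (0, 1]")
  if (any(cfg$mechanism_probs < 0) || abs(sum(cfg$mechanism_probs) - 1) > 1e-8)
    stopf("'mechanism_probs' must be non-negative and sum to 1")
  if (cfg$n_shifted_genes > cfg$n_shifted_probes)
    stopf("'n_shifted_genes' cannot exceed 'n_shifted_probes'")
  if (cfg$n_shifted_probes > cfg$n_expr_probes)
    stopf("'n_shifted_probes' cannot exceed 'n_expr_probes'")
  if (cfg$expr_noise_sd <= 0 || cfg$lrr_noise_sd < 0 || cfg$baf_noise_sd < 0)
    stopf("'expr_noise_sd' must be positive and noise SDs non-negative")
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate paired tumor/normal allele read counts at one or more sites
#'
#' Tumor alternate counts are Binomial(depth, VAF); normal alternate counts are
#' Binomial(depth, error rate), so with the default error rate of 0 every true
#' somatic site has a normal VAF of exactly 0.
#'
#' @param true_vaf true tumor variant allele fraction(s), in `[0, 1]`.
#' @param depth_t,depth_n positive tumor / normal read depths (recycled).
#' @param error_rate per-read error rate in the normal sample.
#' @return data frame with columns tumor_ref_count, tumor_alt_count,
#'   normal_ref_count, normal_alt_count.
#' @export
simulate_site_counts <- function(true_vaf, depth_t, depth_n, error_rate = 0) {
  if (any(true_vaf < 0 | true_vaf > 1)) stopf("'true_vaf' must be within [0, 1]")
  if (any(depth_t <= 0) || any(depth_n <= 0)) stopf("depths must be positive")
  n <- max(length(true_vaf), length(depth_t), length(depth_n))
  true_vaf <- rep_len(true_vaf, n)
  depth_t <- rep_len(as.integer(depth_t), n)
  depth_n <- rep_len(as.integer(depth_n), n)
  t_alt <- stats::rbinom(n, depth_t, true_vaf)
  n_alt <- stats::rbinom(n, depth_n, error_rate)
  data.frame(tumor_ref_count = depth_t - t_alt, tumor_alt_count = t_alt,
             normal_ref_count = depth_n - n_alt, normal_alt_count = n_alt)
}

#' Simulate one sample's SNP-array LRR/BAF track
#'
#' Per-probe log R ratio is drawn around the purity-mixed expected intensity of
#' the probe's copy-number state: intensities `2^(M_cn/gamma)` (with `M_cn` the
#' per-state diploid-normalized LRR means and `gamma` the array's compression
#' constant) are mixed linearly with the normal-cell fraction and compressed
#' back, so a pure CN 1 segment sits at the canonical -0.66. B-allele frequency
#' is drawn from the genotype mixture implied by the state, the germline
#' genotype, and the purity. Germline copy-number variants (carried by tumor
#' and normal cells alike) are mixed with weight 1.
#'
#' @param true_segments data frame of non-diploid intervals with columns
#'   chrom, start, end (0-based half-open), cn_state, and optionally a logical
#'   `germline`; uncovered probes are diploid.
#' @param purity tumor cell fraction in (0, 1].
#' @param noise_sd per-probe LRR noise SD.
#' @param baf_noise_sd per-probe BAF noise SD.
#' @param chroms chromosome names to simulate.
#' @param n_probes_per_chrom,probe_spacing probe grid definition.
#' @param het_fraction fraction of probes heterozygous in the germline.
#' @param state_means named per-state LRR emission means.
#' @param gamma LRR compression constant.
#' @return data frame with columns probe_id, chrom, pos, lrr, baf, het.
#' @export
simulate_snp_track <- function(true_segments, purity,
                               noise_sd = 0.2, baf_noise_sd = 0.03,
                               chroms = as.character(1:22),
                               n_probes_per_chrom = 400L,
                               probe_spacing = 5000L,
                               het_fraction = 1 / 3,
                               state_means = LRR_STATE_MEANS,
                               gamma = LRR_GAMMA) {
  assert_proportion(purity, "purity")
  if (purity <= 0) stopf("'purity' must be within (0, 1]")
  segs <- true_segments
  if (is.null(segs) || !nrow(segs))
    segs <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                       cn_state = integer(0), germline = logical(0))
  if (is.null(segs$germline)) segs$germline <- FALSE
  if (nrow(segs)) {
    segs <- segs[order(segs$chrom, segs$start), , drop = FALSE]
    for (ch in unique(segs$chrom)) {
      s <- segs[segs$chrom == ch, , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
        stopf("overlapping truth segments on chromosome %s", ch)
    }
  }
  res <- lapply(chroms, function(ch) {
    pos <- (seq_len(n_probes_per_chrom) - 1L) * probe_spacing
    cn <- rep(2L, n_probes_per_chrom)
    wgt <- rep(purity, n_probes_per_chrom)
    s <- segs[segs$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      hit <- pos >= s$start[i] & pos < s$end[i]
      cn[hit] <- s$cn_state[i]
      if (isTRUE(s$germline[i])) wgt[hit] <- 1
    }
    het <- stats::runif(n_probes_per_chrom) < het_fraction
    ## tumor B-allele copy count given state and germline genotype
    g <- ifelse(het, 1L, ifelse(stats::runif(n_probes_per_chrom) < 0.5, 0L, 2L))
    nb <- integer(n_probes_per_chrom)
    for (i in seq_len(n_probes_per_chrom)) {
      nb[i] <- if (g[i] == 0L) 0L else if (g[i] == 2L) cn[i] else
        switch(as.character(cn[i]),
               `0` = 0L,
               `1` = sample(0:1, 1L),
               `2` = 1L,
               `3` = sample(1:2, 1L),
               `4` = sample(c(1L, 3L), 1L))
    }
    w <- wgt
    denom <- 2 * (1 - w) + w * cn
    num <- (1 - w) * g + w * nb
    baf_center <- ifelse(denom > 0.05, num / denom, stats::runif(n_probes_per_chrom))
    intensity <- w * 2^(state_means[as.character(cn)] / gamma) + (1 - w)
    lrr <- gamma * log2(intensity) + stats::rnorm(n_probes_per_chrom, 0, noise_sd)
    baf <- pmin(1, pmax(0, baf_center + stats::rnorm(n_probes_per_chrom, 0, baf_noise_sd)))
    data.frame(probe_id = sprintf("%s_p%04d", ch, seq_len(n_probes_per_chrom)),
               chrom = ch, pos = pos, lrr = as.numeric(lrr), baf = baf, het = het)
  })
  do.call(rbind, res)
}

## -- internal pieces of simulate_cohort ------------------------------------

sim_gene_map <- function(cfg) {
  chrom_len <- cfg$n_probes_per_chrom * cfg$probe_spacing
  chroms <- as.character(seq_len(cfg$n_chrom))
  tp53_chrom <- as.character(min(17L, cfg$n_chrom))
  mdm2_chrom <- as.character(min(12L, cfg$n_chrom))
  if (mdm2_chrom == tp53_chrom) mdm2_chrom <- as.character(max(1L, cfg$n_chrom - 1L))
  width <- min(20000L, max(2L * cfg$probe_spacing, chrom_len %/% 20L))
  specials <- data.frame(
    gene = c("TP53", "MDM2"),
    chrom = c(tp53_chrom, mdm2_chrom),
    start = as.integer(floor(0.25 * chrom_len)),
    stringsAsFactors = FALSE)
  targets <- default_p53_targets()
  bg <- sprintf("G%04d", seq_len(cfg$n_genes))
  others <- data.frame(
    gene = c(targets, bg),
    chrom = sample(chroms, length(targets) + length(bg), replace = TRUE),
    start = as.integer(floor(stats::runif(length(targets) + length(bg), 0, chrom_len - width))),
    stringsAsFactors = FALSE)
  map <- rbind(specials, others)
  map$end <- map$start + width
  map[, c("gene", "chrom", "start", "end")]
}

sim_healthy_sv <- function(cfg, gene_map, recurrent_region) {
  chrom_len <- cfg$n_probes_per_chrom * cfg$probe_spacing
  avoid <- rbind(gene_map[gene_map$gene %in% c("TP53", "MDM2"), c("chrom", "start", "end")],
                 recurrent_region[, c("chrom", "start", "end")])
  out <- data.frame()
  tries <- 0L
  width <- 15L * cfg$probe_spacing
  while (nrow(out) < cfg$n_healthy_sv && tries < 500L) {
    tries <- tries + 1L
    ch <- sample(as.character(seq_len(cfg$n_chrom)), 1L)
    st <- as.integer(floor(stats::runif(1, 0, max(1, chrom_len - width))))
    cand <- data.frame(chrom = ch, start = st, end = st + width)
    clash <- any(avoid$chrom == ch & intervals_overlap(avoid$start, avoid$end, st, st + width))
    if (nrow(out))
      clash <- clash || any(out$chrom == ch &
                              intervals_overlap(out$start, out$end, st, st + width))
    if (!clash) out <- rbind(out, cand)
  }
  out$name <- sprintf("healthy_sv_%02d", seq_len(nrow(out)))
  out
}

## Draw one sample's somatic copy-number segments (probe-aligned, no overlap).
sim_somatic_segments <- function(cfg, subtype, mechanism, gene_map, recurrent_region) {
  chrom_len <- cfg$n_probes_per_chrom * cfg$probe_spacing
  chroms <- as.character(seq_len(cfg$n_chrom))
  tp53 <- gene_map[gene_map$gene == "TP53", ]
  mdm2 <- gene_map[gene_map$gene == "MDM2", ]
  segs <- data.frame()
  add_if_free <- function(segs, ch, st, en, cn) {
    if (nrow(segs) && any(segs$chrom == ch &
                            intervals_overlap(segs$start, segs$end, st, en)))
      return(segs)
    rbind(segs, data.frame(chrom = ch, start = st, end = en,
                           cn_state = cn, germline = FALSE))
  }
  ## forced lesions implementing the sample's p53-pathway hit mechanism
  if (identical(mechanism, "tp53_deletion"))
    segs <- add_if_free(segs, tp53$chrom,
                        max(0L, tp53$start - 5L * cfg$probe_spacing),
                        min(chrom_len, tp53$end + 5L * cfg$probe_spacing), 1L)
  if (identical(mechanism, "mdm2_amplification"))
    segs <- add_if_free(segs, mdm2$chrom,
                        max(0L, mdm2$start - 5L * cfg$probe_spacing),
                        min(chrom_len, mdm2$end + 5L * cfg$probe_spacing), 4L)
  ## planted recurrent deletion carried by a fraction of ST2 tumors
  if (subtype == "ST2" && stats::runif(1) < cfg$recurrent_del_prob)
    segs <- add_if_free(segs, recurrent_region$chrom, recurrent_region$start,
                        recurrent_region$end, 1L)
  lambda <- if (subtype == "ST1") cfg$cn_segments_st1_mean else cfg$cn_segments_st2_mean
  n_extra <- stats::rpois(1, lambda)
  ## ST2 alterations are enriched on the TP53/MDM2-bearing chromosomes,
  ## emulating the chromosome-17/12 burden concentration of serous tumors
  wts <- rep(1, cfg$n_chrom)
  if (subtype == "ST2") {
    wts[as.integer(tp53$chrom)] <- 3
    wts[as.integer(mdm2$chrom)] <- 2.5
  }
  for (i in seq_len(n_extra)) {
    for (try in 1:20) {
      ch <- sample(chroms, 1L, prob = wts)
      len <- (10L + stats::rgeom(1, 1 / 50)) * cfg$probe_spacing
      st <- as.integer(floor(stats::runif(1, 0, max(1, chrom_len - len))))
      st <- (st %/% cfg$probe_spacing) * cfg$probe_spacing
      en <- min(st + len, chrom_len)
      cn <- sample(c(0L, 1L, 3L, 4L), 1L, prob = c(0.05, 0.50, 0.30, 0.15))
      if (subtype == "ST1") {
        ## an intact-pathway sample must not acquire a TP53 loss or MDM2 gain
        if (ch == tp53$chrom && intervals_overlap(tp53$start, tp53$end, st, en)) next
        if (ch == mdm2$chrom && intervals_overlap(mdm2$start, mdm2$end, st, en)) next
      }
      n0 <- nrow(segs)
      segs <- add_if_free(segs, ch, st, en, cn)
      if (nrow(segs) > n0) break
    }
  }
  segs
}

sim_sample_sites <- function(cfg, sample_id, subtype, mechanism, purity,
                             segments, gene_map, background_genes) {
  f <- cfg$fraction_st1
  r <- cfg$st1_mutation_ratio
  scale <- f * r + (1 - f)
  mu <- cfg$mean_mutations * (if (subtype == "ST1") r else 1) / scale
  n_nonsyn <- stats::rnbinom(1, size = cfg$mutation_dispersion, mu = mu)
  if (mechanism %in% c("tp53_mutation", "p53_target_mutation"))
    n_nonsyn <- max(n_nonsyn, 1L)
  n_syn <- stats::rpois(1, 0.25 * mu)

  genes <- character(0)
  consequences <- character(0)
  if (mechanism == "tp53_mutation") {
    genes <- "TP53"
    consequences <- sample(NONSYN_CLASSES, 1L, prob = c(0.60, 0.15, 0.10, 0.15))
  } else if (mechanism == "p53_target_mutation") {
    genes <- sample(default_p53_targets(), 1L)
    consequences <- sample(NONSYN_CLASSES, 1L, prob = c(0.55, 0.15, 0.20, 0.10))
  }
  n_bg <- n_nonsyn - length(genes)
  if (n_bg > 0) {
    genes <- c(genes, sample(background_genes, n_bg, replace = TRUE))
    consequences <- c(consequences,
                      sample(NONSYN_CLASSES, n_bg, replace = TRUE,
                             prob = c(0.75, 0.10, 0.07, 0.08)))
  }
  if (n_syn > 0) {
    genes <- c(genes, sample(background_genes, n_syn, replace = TRUE))
    consequences <- c(consequences, rep("synonymous", n_syn))
  }
  n <- length(genes)
  if (!n) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref_allele = character(0),
                      alt_allele = character(0), gene_symbol = character(0),
                      consequence = character(0), fis = numeric(0),
                      true_vaf = numeric(0)))
  }
  gm <- gene_map[match(genes, gene_map$gene), ]
  pos <- as.integer(floor(stats::runif(n, gm$start, gm$end)))

  ## clonal VAF from the local copy state: a mutation on m of c tumor copies in
  ## a tumor of purity rho sits at m*rho / ((1-rho)*c_normal + rho*c_tumor)
  cn_t <- rep(2L, n); cn_n <- rep(2L, n)
  for (i in seq_len(nrow(segments))) {
    hit <- gm$chrom == segments$chrom[i] & pos >= segments$start[i] & pos < segments$end[i]
    cn_t[hit] <- segments$cn_state[i]
    if (isTRUE(segments$germline[i])) cn_n[hit] <- segments$cn_state[i]
  }
  cn_t[cn_t == 0L] <- 2L  # no sites survive in homozygous deletions
  mult <- ifelse(cn_t <= 2L, 1L,
                 ifelse(stats::runif(n) < 0.5, 1L, cn_t - 1L))
  vaf <- mult * purity / ((1 - purity) * cn_n + purity * cn_t)
  vaf <- pmin(0.99, pmax(cfg$tumor_vaf_floor, vaf))

  fis <- rep(NA_real_, n)
  mis <- consequences == "missense"
  fis[mis] <- stats::rnorm(sum(mis), 0.9, 0.7)
  if (mechanism == "tp53_mutation" && consequences[1] == "missense")
    fis[1] <- stats::runif(1, 2.5, 4.5)  # driver lesions carry high impact

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(sample_id = sample_id, chrom = gm$chrom, pos = pos,
             ref_allele = ref, alt_allele = unname(alt), gene_symbol = genes,
             consequence = consequences, fis = fis, true_vaf = vaf,
             stringsAsFactors = FALSE)
}

sim_expression <- function(cfg, samples) {
  n_s <- nrow(samples)
  probe_ids <- sprintf("EP%05d", seq_len(cfg$n_expr_probes))
  all_genes <- c(sprintf("G%04d", seq_len(cfg$n_genes)), default_p53_targets())
  shifted_genes <- sample(sprintf("G%04d", seq_len(cfg$n_genes)), cfg$n_shifted_genes)
  ## probe -> gene map: the shifted probes cover the shifted genes, with the
  ## surplus probes duplicated over the first genes (many-to-one probes)
  gene_of <- rep(NA_character_, cfg$n_expr_probes)
  gene_of[seq_len(cfg$n_shifted_probes)] <-
    shifted_genes[((seq_len(cfg$n_shifted_probes) - 1L) %% cfg$n_shifted_genes) + 1L]
  rest <- (cfg$n_shifted_probes + 1L):cfg$n_expr_probes
  mapped <- stats::runif(length(rest)) < 0.85
  gene_of[rest[mapped]] <- sample(setdiff(all_genes, shifted_genes),
                                  sum(mapped), replace = TRUE)
  shift_sign <- stats::setNames(sample(c(-1, 1), cfg$n_shifted_genes, replace = TRUE),
                                shifted_genes)
  delta <- rep(0, cfg$n_expr_probes)
  sp <- seq_len(cfg$n_shifted_probes)
  delta[sp] <- cfg$expr_effect_sd * cfg$expr_noise_sd * shift_sign[gene_of[sp]]

  mu <- stats::runif(cfg$n_expr_probes, 4, 10)
  is_st1 <- samples$subtype == "ST1"
  log_expr <- matrix(stats::rnorm(cfg$n_expr_probes * n_s, 0, cfg$expr_noise_sd),
                     nrow = cfg$n_expr_probes)
  log_expr <- log_expr + mu + outer(delta, as.numeric(is_st1))
  scale <- stats::runif(n_s, 0.5, 2)
  raw <- sweep(2^log_expr, 2, scale, `*`)
  dimnames(raw) <- list(probe_ids, samples$sample_id)
  list(matrix = raw,
       probe_map = data.frame(probe_id = probe_ids, gene = gene_of,
                              stringsAsFactors = FALSE),
       shifted_probes = probe_ids[sp],
       shifted_genes = shifted_genes)
}

sim_terms <- function(cfg, gene_map, shifted_genes) {
  universe <- gene_map$gene
  terms <- list()
  ## planted terms draw from a shared core of the truly shifted genes, the way
  ## sibling annotation terms share most of their members
  core <- sample(shifted_genes, min(20L, length(shifted_genes)))
  for (i in seq_len(cfg$n_planted_terms)) {
    k <- sample(10:16, 1L)
    terms[[sprintf("PLANTED_%02d", i)]] <-
      sort(unique(c(sample(core, min(k, length(core))), sample(universe, 2L))))
  }
  for (i in seq_len(cfg$n_terms - cfg$n_planted_terms)) {
    k <- sample(10:40, 1L)
    terms[[sprintf("TERM_%03d", i)]] <- sort(sample(universe, k))
  }
  terms
}

#' Simulate a ground-truthed synthetic HGSOC-like cohort
#'
#' Generates, from a single seed, every input consumed by the downstream
#' stages: a paired tumor/normal variant count table with gene, consequence,
#' and functional-impact annotations; per-sample tumor and matched-normal
#' SNP-array LRR/BAF tracks; a probe-level expression matrix with a
#' probe-to-gene map; a p53 direct-target gene list and a term-to-gene GMT; a
#' healthy-subject structural-variant exclusion track; and the full ground
#' truth (subtype labels, true somatic sites with VAF, true copy-number
#' segments, true purity, and per-sample pathway alteration flags).
#'
#' ST2 samples draw more mutations and more copy-number segments than ST1
#' samples; every ST2 sample carries at least one of the four p53-pathway hit
#' mechanisms while ST1 samples, by construction, carry none.
#'
#' @param config a [cohort_config()] object.
#' @param out_dir optional directory; when given, all cohort files are written
#'   there via [write_cohort()].
#' @return an object of class `synthetic_cohort`: a list with elements
#'   `variants`, `tumor_tracks`, `normal_tracks`, `expression` (matrix,
#'   probe_map), `p53_targets`, `terms`, `healthy_sv`, `gene_map`, `truth`,
#'   and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  if (!inherits(config, "cohort_config"))
    stopf("'config' must be created by cohort_config()")
  cfg <- config
  set.seed(cfg$seed)

  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  n_st1 <- round(cfg$n_samples * cfg$fraction_st1)
  subtype <- sample(c(rep("ST1", n_st1), rep("ST2", cfg$n_samples - n_st1)))
  purity <- stats::runif(cfg$n_samples, cfg$purity_range[1], cfg$purity_range[2])
  mechanism <- ifelse(subtype == "ST1", "none",
                      sample(names(cfg$mechanism_probs), cfg$n_samples,
                             replace = TRUE, prob = cfg$mechanism_probs))

  gene_map <- sim_gene_map(cfg)
  chrom_len <- cfg$n_probes_per_chrom * cfg$probe_spacing
  tp53_chrom <- gene_map$chrom[gene_map$gene == "TP53"]
  recurrent_region <- data.frame(
    chrom = tp53_chrom,
    start = as.integer(floor(0.55 * chrom_len / cfg$probe_spacing)) * cfg$probe_spacing,
    end = as.integer(floor(0.67 * chrom_len / cfg$probe_spacing)) * cfg$probe_spacing)
  healthy_sv <- sim_healthy_sv(cfg, gene_map, recurrent_region)

  background_genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  variants <- list(); truth_sites <- list(); truth_segs <- list()
  tumor_tracks <- list(); normal_tracks <- list()
  chroms <- as.character(seq_len(cfg$n_chrom))

  for (i in seq_len(cfg$n_samples)) {
    sid <- sample_ids[i]
    segs <- sim_somatic_segments(cfg, subtype[i], mechanism[i], gene_map,
                                 recurrent_region)
    ## germline CNVs shared between the tumor and its matched normal
    germ <- data.frame()
    for (j in seq_len(nrow(healthy_sv))) {
      if (stats::runif(1) < cfg$germline_cnv_prob) {
        cand <- data.frame(chrom = healthy_sv$chrom[j], start = healthy_sv$start[j],
                           end = healthy_sv$end[j], cn_state = sample(c(1L, 3L), 1L),
                           germline = TRUE)
        clash <- nrow(segs) && any(segs$chrom == cand$chrom &
                                     intervals_overlap(segs$start, segs$end,
                                                       cand$start, cand$end))
        if (!clash) germ <- rbind(germ, cand)
      }
    }
    all_segs <- rbind(segs, germ)
    sites <- sim_sample_sites(cfg, sid, subtype[i], mechanism[i], purity[i],
                              all_segs, gene_map, background_genes)
    depth_t <- pmax(10L, stats::rpois(nrow(sites), cfg$mean_depth_tumor))
    depth_n <- pmax(10L, stats::rpois(nrow(sites), cfg$mean_depth_normal))
    counts <- simulate_site_counts(sites$true_vaf, depth_t, depth_n,
                                   cfg$normal_error_rate)
    variants[[sid]] <- cbind(sites[, c("sample_id", "chrom", "pos", "ref_allele",
                                       "alt_allele", "gene_symbol", "consequence")],
                             counts, fis = sites$fis)
    truth_sites[[sid]] <- sites
    if (nrow(all_segs))
      truth_segs[[sid]] <- cbind(sample_id = sid, all_segs)
    tt <- simulate_snp_track(all_segs, purity[i],
                             noise_sd = cfg$lrr_noise_sd,
                             baf_noise_sd = cfg$baf_noise_sd,
                             chroms = chroms,
                             n_probes_per_chrom = cfg$n_probes_per_chrom,
                             probe_spacing = cfg$probe_spacing,
                             het_fraction = cfg$het_fraction)
    nt <- simulate_snp_track(germ, 1,
                             noise_sd = cfg$lrr_noise_sd,
                             baf_noise_sd = cfg$baf_noise_sd,
                             chroms = chroms,
                             n_probes_per_chrom = cfg$n_probes_per_chrom,
                             probe_spacing = cfg$probe_spacing,
                             het_fraction = cfg$het_fraction)
    tumor_tracks[[sid]] <- cbind(sample_id = sid, tt)
    normal_tracks[[sid]] <- cbind(sample_id = sid, nt)
  }

  variants <- do.call(rbind, c(variants, list(make.row.names = FALSE)))
  truth_site_df <- do.call(rbind, c(truth_sites, list(make.row.names = FALSE)))
  truth_seg_df <- if (length(truth_segs))
    do.call(rbind, c(truth_segs, list(make.row.names = FALSE))) else
    data.frame(sample_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), cn_state = integer(0), germline = logical(0))

  samples <- data.frame(sample_id = sample_ids, subtype = subtype,
                        purity = purity, mechanism = mechanism,
                        stringsAsFactors = FALSE)
  ## alteration truth flags recomputed from the realized sites and segments
  tp53 <- gene_map[gene_map$gene == "TP53", ]
  mdm2 <- gene_map[gene_map$gene == "MDM2", ]
  nonsyn <- truth_site_df[truth_site_df$consequence %in% NONSYN_CLASSES, ]
  samples$tp53_mutated <- sample_ids %in% nonsyn$sample_id[nonsyn$gene_symbol == "TP53"]
  seg_cn_at <- function(sid, locus, worst = min) {
    s <- truth_seg_df[truth_seg_df$sample_id == sid &
                        truth_seg_df$chrom == locus$chrom &
                        intervals_overlap(truth_seg_df$start, truth_seg_df$end,
                                          locus$start, locus$end), ]
    if (!nrow(s)) 2L else as.integer(worst(s$cn_state))
  }
  samples$tp53_cn <- vapply(sample_ids, seg_cn_at, 0L, locus = tp53)
  samples$mdm2_cn <- vapply(sample_ids, seg_cn_at, 0L, locus = mdm2, worst = max)
  tgt <- nonsyn[nonsyn$gene_symbol %in% default_p53_targets(), ]
  samples$p53_target_hit <- vapply(sample_ids, function(sid)
    paste(sort(unique(tgt$gene_symbol[tgt$sample_id == sid])), collapse = ","), "")
  samples$n_nonsyn_true <- vapply(sample_ids, function(sid)
    sum(nonsyn$sample_id == sid), 0L)

  expr <- sim_expression(cfg, samples)
  terms <- sim_terms(cfg, gene_map, expr$shifted_genes)

  cohort <- list(
    variants = variants,
    tumor_tracks = tumor_tracks,
    normal_tracks = normal_tracks,
    expression = list(matrix = expr$matrix, probe_map = expr$probe_map),
    p53_targets = default_p53_targets(),
    terms = terms,
    healthy_sv = healthy_sv,
    gene_map = gene_map,
    truth = list(samples = samples,
                 sites = truth_site_df,
                 segments = truth_seg_df,
                 shifted_probes = expr$shifted_probes,
                 shifted_genes = expr$shifted_genes),
    config = cfg)
  class(cohort) <- "synthetic_cohort"
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples (%d ST1 / %d ST2), %d variant sites\n",
              nrow(x$truth$samples), sum(x$truth$samples$subtype == "ST1"),
              sum(x$truth$samples$subtype == "ST2"), nrow(x$variants)))
  cat(sprintf("  genome: %d chromosomes x %d probes; expression: %d probes x %d samples\n",
              x$config$n_chrom, x$config$n_probes_per_chrom,
              nrow(x$expression$matrix), ncol(x$expression$matrix)))
  invisible(x)
}

#' Write all files of a synthetic cohort to a directory
#'
#' Emits the variant count table, per-sample tumor and normal LRR/BAF tracks,
#' the raw expression matrix and probe-to-gene map, the p53 target list and
#' annotation GMTs, the healthy-SV exclusion BED, the gene BED, the ground
#' truth tables, and a flat key-value configuration file. Output is
#' byte-identical for identical configurations.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) stopf("'cohort' must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  write_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  for (sid in names(cohort$tumor_tracks)) {
    write_tsv(cohort$tumor_tracks[[sid]], file.path(dir, "tracks", paste0(sid, "_tumor.tsv")))
    write_tsv(cohort$normal_tracks[[sid]], file.path(dir, "tracks", paste0(sid, "_normal.tsv")))
  }
  em <- data.frame(probe_id = rownames(cohort$expression$matrix),
                   cohort$expression$matrix, check.names = FALSE)
  write_tsv(em, file.path(dir, "expression.tsv"))
  write_tsv(cohort$expression$probe_map, file.path(dir, "probe_gene_map.tsv"))
  write_gmt(list(p53_direct_targets = cohort$p53_targets),
            file.path(dir, "p53_targets.gmt"))
  write_gmt(cohort$terms, file.path(dir, "terms.gmt"))
  write_bed(cohort$healthy_sv, file.path(dir, "healthy_sv.bed"))
  gm <- cohort$gene_map[, c("chrom", "start", "end", "gene")]
  names(gm)[4] <- "name"
  write_bed(gm, file.path(dir, "genes.bed"))
  write_tsv(cohort$truth$samples, file.path(dir, "truth_samples.tsv"))
  write_tsv(cohort$truth$sites, file.path(dir, "truth_sites.tsv"))
  write_tsv(cohort$truth$segments, file.path(dir, "truth_segments.tsv"))
  writeLines(cohort$truth$shifted_probes, file.path(dir, "truth_shifted_probes.txt"))
  cfg <- cohort$config
  keys <- names(cfg)
  vals <- vapply(keys, function(k) paste(format(cfg[[k]], digits = 15), collapse = ","), "")
  writeLines(paste0(keys, "=", vals), file.path(dir, "config.txt"))
  invisible(dir)
}
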