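#' Configuration of an end-to-end pipeline run
#'
#' Collects every stage threshold (defaults are the analysis' canonical
#' settings: somatic Fisher p < 1e-5 with 0% normal VAF, recurrent-region
#' Fisher p < 0.0005, FIS > 2.0 deleterious, DE FDR < 0.1, enrichment score
#' > 1.3, MDM2 amplification at CN >= 4), the cohort generator configuration,
#' stage toggles, and the master seed.
#'
#' @param cohort a [cohort_config()] for the simulate stage.
#' @param stages named logical vector toggling the stages `simulate`,
#'   `somatic`, `cnv`, `cnvr`, `purity`, `subtype`, `de`, `go`.
#' @param p_somatic,max_normal_vaf,fis_deleterious somatic caller settings.
#' @param p_cnvr recurrent-region probe threshold.
#' @param fdr_de differential-expression FDR threshold.
#' @param mdm2_amp_cn MDM2 amplification state.
#' @param kappa,overlap_min,membership_min,linkage,es_significant annotation
#'   clustering settings.
#' @param n_permutations driver-scan permutations.
#' @param seed master seed; per-stage streams are derived with [stage_seed()].
#' @return a `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       stages = c(simulate = TRUE, somatic = TRUE, cnv = TRUE,
                                  cnvr = TRUE, purity = TRUE, subtype = TRUE,
                                  de = TRUE, go = TRUE),
                       p_somatic = 1e-5, max_normal_vaf = 0,
                       fis_deleterious = 2.0, p_cnvr = 0.0005, fdr_de = 0.1,
                       mdm2_amp_cn = 4L, kappa = 0.35, overlap_min = 3L,
                       membership_min = 3L, linkage = 0.5,
                       es_significant = 1.3, n_permutations = 300L,
                       seed = 1L) {
  if (p_somatic <= 0 || p_somatic >= 1) stopf("'p_somatic' must be in (0, 1)")
  if (p_cnvr <= 0 || p_cnvr >= 1) stopf("'p_cnvr' must be in (0, 1)")
  assert_proportion(fdr_de, "fdr_de")
  assert_proportion(max_normal_vaf, "max_normal_vaf")
  cfg <- list(cohort = cohort, stages = stages, p_somatic = p_somatic,
              max_normal_vaf = max_normal_vaf, fis_deleterious = fis_deleterious,
              p_cnvr = p_cnvr, fdr_de = fdr_de, mdm2_amp_cn = mdm2_amp_cn,
              kappa = kappa, overlap_min = overlap_min,
              membership_min = membership_min, linkage = linkage,
              es_significant = es_significant,
              n_permutations = n_permutations,
              seed = assert_count(seed, "seed", positive = FALSE))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

log_stage <- function(name, t0) {
  message(sprintf("[%s] done in %.1fs", name, as.numeric(Sys.time()) - t0))
}

#' Run the full characterization pipeline on a synthetic cohort
#'
#' Executes, in order: simulate, somatic calling, copy-number segmentation,
#' recurrent-region detection, purity estimation, subtype assignment with
#' burden comparisons, differential expression, and annotation clustering.
#' Each enabled stage writes its tables (with a comment header carrying the
#' package version and configuration hash) under `out_dir` and is logged to
#' stderr with timing. Reruns with the same configuration and seed are
#' byte-identical. Disabling a stage marks it skipped in the manifest; a
#' stage whose upstream is skipped refuses to run (recorded as refused).
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the run manifest (also written to `manifest.json`), invisibly the
#'   full result list with per-stage objects.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("p53run")) {
  if (!inherits(config, "run_config")) stopf("'config' must come from run_config()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- c(sprintf("p53pathtype %s", as.character(utils::packageVersion("p53pathtype"))),
           sprintf("config_hash %s", hash),
           sprintf("seed %d", config$seed))
  stages <- config$stages
  on_stage <- function(s) isTRUE(stages[[s]])
  manifest <- list(package_version = as.character(utils::packageVersion("p53pathtype")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config_hash = hash, seed = config$seed, stages = list())
  res <- list()

  mark <- function(stage, status, rows = NULL) {
    entry <- list(status = status)
    if (!is.null(rows)) entry$rows <- rows
    manifest$stages[[stage]] <<- entry
  }

  ## -- simulate ------------------------------------------------------------
  if (on_stage("simulate")) {
    t0 <- as.numeric(Sys.time())
    cc <- config$cohort
    cc$seed <- stage_seed(config$seed, "simulate")
    res$cohort <- simulate_cohort(cc)
    write_cohort(res$cohort, file.path(out_dir, "cohort"))
    mark("simulate", "done", nrow(res$cohort$variants))
    log_stage("simulate", t0)
  } else mark("simulate", "skipped")

  cohort <- res$cohort

  ## -- somatic calling -----------------------------------------------------
  if (on_stage("somatic")) {
    if (is.null(cohort)) stopf("stage 'somatic' requires the simulate stage")
    t0 <- as.numeric(Sys.time())
    res$calls <- call_somatic(cohort$variants, p_threshold = config$p_somatic,
                              max_normal_vaf = config$max_normal_vaf,
                              fis_threshold = config$fis_deleterious)
    res$drivers <- driver_scan(res$calls, n_permutations = config$n_permutations,
                               seed = stage_seed(config$seed, "driver_scan"))
    res$frequencies <- mutation_frequency_table(res$calls)
    write_tsv(res$calls, file.path(out_dir, "somatic_calls.tsv"), hdr)
    write_vcf(res$calls, file.path(out_dir, "somatic_calls.vcf"))
    write_tsv(res$drivers, file.path(out_dir, "driver_scan.tsv"), hdr)
    mark("somatic", "done", nrow(res$calls))
    log_stage("somatic", t0)
  } else mark("somatic", "skipped")

  ## -- copy-number segmentation -------------------------------------------
  if (on_stage("cnv")) {
    if (is.null(cohort)) stopf("stage 'cnv' requires the simulate stage")
    t0 <- as.numeric(Sys.time())
    params <- hmm_params(het_fraction = cohort$config$het_fraction)
    res$tumor_segments <- do.call(rbind, lapply(cohort$tumor_tracks, segment_cnv,
                                                params = params))
    res$normal_segments <- do.call(rbind, lapply(cohort$normal_tracks, segment_cnv,
                                                 params = params))
    rownames(res$tumor_segments) <- rownames(res$normal_segments) <- NULL
    write_seg(res$tumor_segments, file.path(out_dir, "tumor_segments.seg"), hdr)
    write_seg(res$normal_segments, file.path(out_dir, "normal_segments.seg"), hdr)
    mark("cnv", "done", nrow(res$tumor_segments))
    log_stage("cnv", t0)
  } else mark("cnv", "skipped")

  ## -- recurrent regions ---------------------------------------------------
  if (on_stage("cnvr")) {
    if (is.null(res$tumor_segments)) stopf("stage 'cnvr' requires the cnv stage")
    t0 <- as.numeric(Sys.time())
    probe_map <- cohort$tumor_tracks[[1]][, c("probe_id", "chrom", "pos")]
    gene_bed <- cohort$gene_map
    names(gene_bed)[names(gene_bed) == "gene"] <- "name"
    res$cnvr <- detect_recurrent_cnvr(
      res$tumor_segments, res$normal_segments, probe_map,
      exclusion_bed = cohort$healthy_sv, gene_bed = gene_bed,
      p_threshold = config$p_cnvr,
      case_samples = names(cohort$tumor_tracks),
      control_samples = names(cohort$normal_tracks))
    write_tsv(res$cnvr, file.path(out_dir, "recurrent_cnvr.tsv"), hdr)
    bed <- res$cnvr[, c("chrom", "start", "end")]
    bed$name <- if (nrow(bed)) paste0(res$cnvr$direction, "_", seq_len(nrow(bed))) else character(0)
    write_bed(bed, file.path(out_dir, "recurrent_cnvr.bed"))
    mark("cnvr", "done", nrow(res$cnvr))
    log_stage("cnvr", t0)
  } else mark("cnvr", "skipped")

  ## -- purity --------------------------------------------------------------
  if (on_stage("purity")) {
    if (is.null(cohort)) stopf("stage 'purity' requires the simulate stage")
    t0 <- as.numeric(Sys.time())
    ests <- lapply(names(cohort$tumor_tracks), function(sid) {
      germ_alt <- if (!is.null(res$normal_segments))
        res$normal_segments[res$normal_segments$sample_id == sid &
                              res$normal_segments$cn_state != 2L, , drop = FALSE]
      estimate_purity_track(cohort$tumor_tracks[[sid]], exclude = germ_alt)$estimate
    })
    res$purity <- do.call(rbind, ests)
    res$purity$sample_id <- names(cohort$tumor_tracks)
    write_tsv(res$purity, file.path(out_dir, "purity.tsv"), hdr)
    mark("purity", "done", nrow(res$purity))
    log_stage("purity", t0)
  } else mark("purity", "skipped")

  ## -- subtype assignment and burden comparisons ---------------------------
  if (on_stage("subtype")) {
    if (is.null(res$calls) || is.null(res$tumor_segments))
      stopf("stage 'subtype' requires the somatic and cnv stages")
    t0 <- as.numeric(Sys.time())
    profiles <- build_alteration_profiles(res$calls, res$tumor_segments,
                                          cohort$p53_targets, cohort$gene_map,
                                          samples = names(cohort$tumor_tracks))
    res$profiles <- profiles
    res$subtypes <- assign_cohort(profiles, mdm2_amp_cn = config$mdm2_amp_cn)
    mut_counts <- stats::setNames(rep(0, nrow(profiles)), profiles$sample_id)
    sc <- mutation_frequency_table(res$calls)$sample_counts
    mut_counts[sc$sample_id] <- sc$n_mutations
    per_chrom <- cnv_segment_counts(res$tumor_segments, per_chromosome = TRUE,
                                    samples = profiles$sample_id)
    res$burden <- list(
      mutations = compare_burden(mut_counts, res$subtypes$assignments),
      cnv = compare_burden(rowSums(per_chrom), res$subtypes$assignments,
                           per_chrom_counts = per_chrom))
    write_tsv(profiles, file.path(out_dir, "alteration_profiles.tsv"), hdr)
    write_tsv(res$subtypes$assignments, file.path(out_dir, "subtypes.tsv"), hdr)
    write_tsv(res$burden$cnv$per_chromosome,
              file.path(out_dir, "cnv_burden_per_chromosome.tsv"), hdr)
    mark("subtype", "done", nrow(res$subtypes$assignments))
    log_stage("subtype", t0)
  } else mark("subtype", "skipped")

  ## -- differential expression ---------------------------------------------
  if (on_stage("de")) {
    if (is.null(res$subtypes)) stopf("stage 'de' requires the subtype stage")
    t0 <- as.numeric(Sys.time())
    norm <- normalize_expression(cohort$expression$matrix)
    res$de <- differential_expression(norm, res$subtypes$assignments,
                                      probe_map = cohort$expression$probe_map,
                                      fdr = config$fdr_de)
    res$de_genes <- collapse_to_genes(res$de)
    write_tsv(res$de, file.path(out_dir, "differential_expression.tsv"), hdr)
    write_tsv(res$de_genes, file.path(out_dir, "de_genes.tsv"), hdr)
    mark("de", "done", nrow(res$de))
    log_stage("de", t0)
  } else mark("de", "skipped")

  ## -- annotation clustering -----------------------------------------------
  if (on_stage("go")) {
    if (is.null(res$de_genes)) {
      mark("go", "refused: upstream stage 'de' was skipped")
      message("[go] refused: differential expression output missing")
    } else {
      t0 <- as.numeric(Sys.time())
      query <- unique(res$de_genes$gene[res$de_genes$significant &
                                          !is.na(res$de_genes$gene)])
      universe <- cohort$gene_map$gene
      res$go <- cluster_terms(query, cohort$terms, universe,
                              kappa_threshold = config$kappa,
                              overlap_min = config$overlap_min,
                              membership_min = config$membership_min,
                              linkage_threshold = config$linkage,
                              es_significant = config$es_significant)
      write_tsv(res$go$clusters, file.path(out_dir, "term_clusters.tsv"), hdr)
      write_tsv(res$go$term_stats, file.path(out_dir, "term_stats.tsv"), hdr)
      mark("go", "done", nrow(res$go$clusters))
      log_stage("go", t0)
    }
  } else mark("go", "skipped")

  for (s in names(manifest$stages))
    if (!is.null(manifest$stages[[s]]$rows))
      manifest$stages[[s]]$rows <- as.integer(manifest$stages[[s]]$rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
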