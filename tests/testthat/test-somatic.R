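site_row <- function(t_ref, t_alt, n_ref, n_alt, sample = "S1", gene = "G1",
                     consequence = "missense", fis = NA_real_) {
  data.frame(sample_id = sample, chrom = "1", pos = 100L, ref_allele = "A",
             alt_allele = "T", gene_symbol = gene, consequence = consequence,
             tumor_ref_count = t_ref, tumor_alt_count = t_alt,
             normal_ref_count = n_ref, normal_alt_count = n_alt, fis = fis)
}

test_that("caller applies the exact-test and normal-VAF thresholds", {
  ## strong somatic signal: 20/50 tumor alt, 0/50 normal
  called <- call_somatic(site_row(30, 20, 50, 0))
  expect_equal(nrow(called), 1L)
  expect_lt(called$fisher_p, 1e-5)
  expect_equal(called$fisher_p, fisher_enum_two_sided(30, 20, 50, 0), tolerance = 1e-12)
  expect_equal(called$normal_vaf, 0)
  expect_equal(called$tumor_vaf, 0.4)

  ## a single alternate read cannot reach significance (p = 1 by enumeration)
  weak <- call_somatic(site_row(49, 1, 50, 0))
  expect_equal(nrow(weak), 0L)
  expect_equal(fisher_enum_two_sided(49, 1, 50, 0), 1, tolerance = 1e-12)

  ## any normal support vetoes the call regardless of p
  contaminated <- call_somatic(site_row(20, 30, 40, 5))
  expect_equal(nrow(contaminated), 0L)
  expect_equal(nrow(call_somatic(site_row(20, 30, 40, 5), max_normal_vaf = 0.2)), 1L)

  ## zero-depth sites are skipped with a reason, not called
  suppressMessages(res <- call_somatic(rbind(site_row(0, 0, 50, 0),
                                             site_row(30, 20, 50, 0))))
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "skipped")$skip_reason, "zero tumor depth")
})

test_that("caller Fisher p agrees with hypergeometric enumeration over many tables", {
  set.seed(7)
  n <- 150
  t_ref <- sample(0:200, n, replace = TRUE)
  t_alt <- sample(0:60, n, replace = TRUE)
  n_ref <- sample(1:200, n, replace = TRUE)
  n_alt <- sample(0:20, n, replace = TRUE)
  keep <- (t_ref + t_alt) > 0
  sites <- site_row(t_ref[keep], t_alt[keep], n_ref[keep], n_alt[keep])
  called <- call_somatic(sites, p_threshold = 1, max_normal_vaf = 1)
  called <- called[called$tumor_alt_count > 0, ]
  oracle <- mapply(fisher_enum_two_sided, called$tumor_ref_count,
                   called$tumor_alt_count, called$normal_ref_count,
                   called$normal_alt_count)
  expect_equal(called$fisher_p, unname(oracle), tolerance = 1e-12)
})

test_that("deleteriousness is a strict threshold on the impact score", {
  expect_true(classify_deleterious(2.1))
  expect_false(classify_deleterious(2.0))
  expect_false(classify_deleterious(-1.0))
  out <- classify_deleterious(c(3, NA, 1))
  expect_identical(as.logical(out), c(TRUE, FALSE, FALSE))
  expect_identical(attr(out, "missing"), c(FALSE, TRUE, FALSE))
})

test_that("driver scan handles ties, exclusions and matches exhaustive enumeration", {
  ## identical scores everywhere: every permutation ties, add-one p = 1
  calls <- do.call(rbind, lapply(1:6, function(i)
    site_row(50, 30, 50, 0, sample = paste0("S", i),
             gene = rep(c("GA", "GB"), 3)[i], fis = 1.5)))
  res <- driver_scan(calls, n_permutations = 200)
  expect_true(all(res$permutation_p == 1))

  ## a gene seen in one sample only is never scored
  one <- rbind(calls, site_row(50, 30, 50, 0, sample = "S9", gene = "GZ", fis = 3))
  expect_false("GZ" %in% driver_scan(one, n_permutations = 200)$gene_symbol)
  expect_error(driver_scan(calls, n_permutations = 50), "at least 100")

  ## exhaustive null: gene holding the 3 largest of 20 distinct scores
  fis <- seq(0.1, 2.0, by = 0.1)
  genes <- c(rep("TOP", 3), paste0("B", 1:17))
  samples <- paste0("S", 1:20)
  calls20 <- do.call(rbind, lapply(1:20, function(i)
    site_row(50, 30, 50, 0, sample = samples[i], gene = genes[i],
             fis = rev(fis)[i])))
  calls20$gene_symbol <- genes  # TOP gets 2.0, 1.9, 1.8
  res <- driver_scan(calls20, n_permutations = "exhaustive")
  obs <- mean(c(2.0, 1.9, 1.8))
  subsets <- utils::combn(fis, 3)
  expected_p <- (1 + sum(colMeans(subsets) >= obs)) / (1 + ncol(subsets))
  expect_equal(res$permutation_p[res$gene_symbol == "TOP"], expected_p)
})

test_that("driver-scan p-values are super-uniform under an exchangeable null", {
  set.seed(11)
  n_genes <- 40
  calls <- do.call(rbind, lapply(seq_len(n_genes * 3), function(i)
    site_row(50, 30, 50, 0, sample = paste0("S", i),
             gene = paste0("G", (i - 1) %% n_genes), fis = rnorm(1))))
  res <- driver_scan(calls, n_permutations = 500, seed = 3)
  grid <- seq(0.05, 1, by = 0.05)
  ecdf_excess <- max(vapply(grid, function(x) mean(res$permutation_p <= x) - x, 0))
  expect_lt(ecdf_excess, 0.15)
})

test_that("mutation frequency tables collapse per sample and filter consequences", {
  calls <- rbind(
    site_row(50, 30, 50, 0, sample = "S1", gene = "GA"),
    site_row(50, 30, 50, 0, sample = "S1", gene = "GA"),   # same sample, same gene
    site_row(50, 30, 50, 0, sample = "S2", gene = "GA", consequence = "splice_site"),
    site_row(50, 30, 50, 0, sample = "S2", gene = "GB", consequence = "synonymous"))
  tab <- mutation_frequency_table(calls)
  expect_equal(tab$gene_counts$n_samples[tab$gene_counts$gene_symbol == "GA"], 2L)
  expect_false("GB" %in% tab$gene_counts$gene_symbol)
  expect_equal(tab$sample_counts$n_mutations[tab$sample_counts$sample_id == "S1"], 2L)
  empty <- mutation_frequency_table(calls[0, ])
  expect_equal(nrow(empty$gene_counts), 0L)

  ## counts over a ground-truth call set reproduce the generator truth
  co <- make_test_cohort(seed = 17)
  truth_ns <- co$truth$sites[co$truth$sites$consequence %in%
                               c("missense", "nonsense", "splice_site",
                                 "frameshift_indel"), ]
  tab <- mutation_frequency_table(truth_ns)
  for (g in c("TP53", utils::head(unique(truth_ns$gene_symbol), 3))) {
    truth_k <- length(unique(truth_ns$sample_id[truth_ns$gene_symbol == g]))
    got_k <- tab$gene_counts$n_samples[tab$gene_counts$gene_symbol == g]
    expect_equal(if (length(got_k)) got_k else 0L, truth_k, info = g)
  }
})
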