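# p53pathtype

Somatic alteration profiling and p53-pathway subtyping for high-grade serous
ovarian cancer (HGSOC) cohorts.

Nearly all HGSOC tumors inactivate p53, but a minority carries no detectable
TP53 mutation. This package asks, for each tumor in a paired tumor–normal
cohort, whether the p53 pathway is demonstrably impaired and stratifies the
cohort into **ST1** (pathway intact: no TP53 nonsynonymous/splice mutation,
no TP53 copy-number loss, no MDM2 amplification, no mutation in a direct p53
target gene) versus **ST2** (any of those four hits). Around that rule it
implements the full supporting pipeline:

* **Somatic calling** from paired allele counts: a site is somatic iff the
  matched normal VAF ≤ 0 (default), the two-sided Fisher's exact test on
  `[[t_ref, t_alt], [n_ref, n_alt]]` gives p < 10⁻⁵, and the tumor carries
  alternate reads. Missense calls with functional impact score > 2.0 are
  deleterious; `driver_scan()` finds genes accumulating high-impact mutations
  by permutation.
* **Copy number**: 5-state HMM (CN 0–4) over SNP-array LRR/BAF tracks with
  Viterbi decoding (`segment_cnv()`); case–control recurrent-region detection
  at p < 5·10⁻⁴ with healthy-subject SV exclusion (`detect_recurrent_cnvr()`);
  allele-specific grid-search purity estimation (`estimate_purity()`), where
  candidate purity ρ inverts each segment's mean LRR r and mirrored het BAF b
  via b = (1−ρ+ρ·nB)/(2(1−ρ)+ρ(nA+nB)), r = γ·log2((2(1−ρ)+ρ(nA+nB))/2) and
  minimizes the distance of (nA, nB) to non-negative integers.
* **Burden comparisons**: exact Wilcoxon rank-sum tests between subtypes,
  Storey q-values across the 22 autosomes, BH elsewhere (`compare_burden()`,
  `fdr_adjust()`).
* **Expression**: 75th-percentile-shift normalization, per-probe Welch
  t-tests at BH FDR < 0.1, probe→gene collapsing
  (`normalize_expression()`, `differential_expression()`).
* **Annotation clustering**: EASE-adjusted one-tailed Fisher enrichment,
  Cohen's-kappa term similarity, fuzzy multiple-linkage grouping, cluster
  enrichment score = mean(−log₁₀ p) with > 1.3 significant
  (`cluster_terms()`).
* **A ground-truthed synthetic cohort generator** (`simulate_cohort()`)
  producing every input above with known subtype labels, somatic sites,
  copy-number segments, purities, and shifted expression probes — the
  package's own test bed.

## Worked example

Simulate a 34-sample cohort at the package's default study conditions
(6/34 pathway-intact, 41 mutations per sample on average, 91×/84× depth,
purity 0.60–0.95), call mutations, segment copy number, and classify:

```r
library(p53pathtype)

co    <- simulate_cohort(cohort_config(n_samples = 34, seed = 20260925))
calls <- call_somatic(co$variants, p_threshold = 1e-5, max_normal_vaf = 0)
segs  <- do.call(rbind, lapply(co$tumor_tracks, segment_cnv))

profiles <- build_alteration_profiles(calls, segs, co$p53_targets, co$gene_map,
                                      samples = names(co$tumor_tracks))
res <- assign_cohort(profiles)
res$counts
#> ST1 ST2
#>   6  28

mean(res$assignments$subtype == co$truth$samples$subtype)
#> [1] 1

head(mutation_frequency_table(calls)$gene_counts, 3)
#>   gene_symbol n_samples
#> 1        TP53        24
#> 2       G0324         9
#> 3       G0040         7

frequency_fisher_test(26, 34, 301, 316)$p   # cohort TP53 frequency, 26/34 vs 301/316
#> [1] 0.0005972914
```

The cohort splits 6/28 and every assignment matches the generator's ground
truth; TP53 tops the mutated-gene table (24/34 samples called here — the
remaining mutated samples carry their hit below the caller's power at the
simulated depth), and a 26/34 mutation frequency is significantly lower than
a 301/316 reference cohort (p ≈ 6·10⁻⁴).

The whole pipeline — simulation through annotation clustering, with manifest
and per-stage outputs — runs via `run_pipeline(run_config(seed = 1), "out/")`
or the wrapper `inst/scripts/run_pipeline.R`.

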