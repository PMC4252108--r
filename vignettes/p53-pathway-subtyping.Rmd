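---
title: "Methods: somatic profiling and p53-pathway subtyping of serous ovarian cancer cohorts"
author: "p53pathtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic profiling and p53-pathway subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

High-grade serous ovarian cancer (HGSOC) is dominated by TP53 inactivation,
yet a minority of tumors carries no detectable TP53 mutation. This package
implements a multi-stage characterization of paired tumor-normal cohorts that
ends in a two-class, rule-based stratification: **ST1**, tumors whose p53
pathway shows no detectable hit, versus **ST2**, tumors impaired through any
of four mechanisms — a somatic TP53 nonsynonymous/splice mutation, TP53
copy-number loss, MDM2 amplification (MDM2 degrades p53, so its amplification
phenocopies p53 loss), or a nonsynonymous mutation in a direct p53
transcriptional target gene. The stages feeding that rule, and the downstream
comparisons, are:

1. **Somatic calling** from paired allele read counts: a site is somatic iff
   the matched normal carries a variant allele fraction of at most 0% (by
   default), the two-sided Fisher's exact test on
   `[[tumor_ref, tumor_alt], [normal_ref, normal_alt]]` has `p < 1e-5`, and
   the tumor has at least one alternate read. Missense calls with a
   functional impact score strictly above 2.0 are labelled deleterious, and a
   permutation scan flags genes accumulating high-impact mutations across at
   least two patients.
2. **Copy-number segmentation** of SNP-array log R ratio (LRR) and B-allele
   frequency (BAF) tracks by a 5-state hidden Markov model (CN 0-4, with 4
   standing for >= 4), Viterbi-decoded per chromosome.
3. **Recurrent-region detection**: per probe and per direction, a carrier /
   non-carrier Fisher test of tumors against matched normals; probes with
   `p < 0.0005` merge into regions, and regions touching structural variants
   seen in healthy subjects are removed.
4. **Purity estimation** by an allele-specific grid search (below).
5. **Burden comparisons** between subtypes: Wilcoxon rank-sum tests (exact
   when group sizes permit and the data are tie-free) on mutation counts and
   on per-autosome copy-number segment counts, the latter corrected across
   the 22 autosomes by Storey's q-value.
6. **Differential expression** on percentile-shift-normalized probe signals
   by per-probe Welch t-tests with Benjamini-Hochberg control at FDR 0.1.
7. **Functional annotation clustering** of the resulting gene list: per-term
   EASE-adjusted one-tailed Fisher enrichment, Cohen's kappa term similarity,
   fuzzy multiple-linkage grouping, and cluster enrichment scores
   (mean of `-log10 p`; > 1.3 significant).

Every stage is exercised end to end against a ground-truthed synthetic cohort
generator, so each claim the package makes about recovery, error control, or
calibration is a computation the test suite or the acceptance script actually
performs.

# The synthetic cohort generator

The generator (`simulate_cohort()`) emits every input the pipeline consumes
— variant count tables, tumor and matched-normal LRR/BAF tracks, an
expression matrix, a p53 direct-target list, annotation GMTs, a healthy-SV
exclusion BED — together with the full ground truth. Its defaults describe
the reference cohort the package targets:

* **34 samples, 6 of them ST1** (`fraction_st1 = 6/34`).
* **41 nonsynonymous/splice mutations per sample** on cohort average, drawn
  from a negative binomial (`mutation_dispersion = 5`) because observed
  per-sample burdens in such cohorts are strongly overdispersed; the ST1
  group mean is reduced by `st1_mutation_ratio = 0.35` with the two group
  means rescaled so the cohort mean stays at 41.
* **Depth 91x (tumor) and 84x (normal)**, Poisson per site.
* **Tumor purity uniform on (0.60, 0.95)**, matching reported cohort-average
  purities near 0.73-0.79 for these tumors.
* **Clonal variant allele fractions.** A somatic mutation on `m` of `c`
  tumor copies in a tumor of purity `rho` sits at
  `VAF = m * rho / ((1 - rho) * c_normal + rho * c_tumor)`; the local copy
  state comes from the sample's simulated segments (diploid for most sites,
  so most VAFs sit near `rho / 2`, with LOH sites higher and gained sites
  spread). VAFs are floored at `tumor_vaf_floor = 0.20`, the minimum observed
  for clonal driver mutations in this tumor type. We model VAF mechanistically
  rather than as a uniform smear because clonal early drivers concentrate at
  `rho / 2`; a uniform distribution down to the floor would place a large
  mass of sites where an exact test at ~90x depth has materially less than
  95% power, which misrepresents what the observed VAF spectrum implies.
* **Sequencing error 0 in the normal** by default, matching the caller's
  0%-normal-VAF filter; it is configurable for robustness experiments.
* **LRR/BAF tracks.** Per-state LRR means are the canonical SNP-array values
  `{CN0: -3.5, CN1: -0.66, CN2: 0, CN3: +0.40, CN4: +0.68}`. Purity mixing
  happens on the linear intensity scale: state intensities `2^(M_cn / gamma)`
  are mixed with the normal-cell fraction and compressed back with
  `gamma = 0.66`, so a pure CN 1 segment sits exactly at -0.66 and a
  contaminated one moves toward 0. BAF comes from the genotype mixture
  implied by the state, the germline genotype (heterozygous with probability
  1/3), and the purity. Germline copy-number variants — drawn from the same
  healthy-SV region pool that the recurrence stage excludes — appear in the
  tumor and its matched normal alike and are mixed with weight 1.
* **Expression**: 2,000 probes, of which 89 probes mapping to 70 genes are
  mean-shifted between subtypes by 3 per-probe SDs (0.5 log2 units of noise,
  so a 1.5 log2-fold shift). The default is 3 SDs because that is the
  standardized effect a probe must carry to be reliably detectable at FDR 0.1
  with 6 versus 28 samples; smaller shifts (e.g. 2 SDs) are detectable for
  only roughly half to two-thirds of probes at these group sizes, which the
  test suite treats as a power statement, not a defect.
* **Annotation terms**: 40 terms, 5 of them planted over a shared 20-gene
  core of the truly shifted genes — sibling annotation terms share most of
  their members, and that overlap is what the kappa-based clustering detects.

What the generator does **not** emulate: read-level artifacts (mapping error,
strand bias, FFPE damage), subclonal heterogeneity, germline point variants,
GC waves in LRR, probe-specific response curves, and correlated expression
modules beyond the planted shift. Passing tests therefore demonstrate
algorithmic correctness and calibration under idealized noise, not robustness
to platform artifacts.

# Purity and ploidy: design choices

Each candidate purity `rho` inverts every non-diploid segment's mean LRR
`r` and mirrored mean heterozygous BAF `b` into continuous allele-specific
copy numbers through

```
b = (1 - rho + rho * nB) / (2 (1 - rho) + rho * (nA + nB))
r = gamma * log2((2 (1 - rho) + rho * (nA + nB)) / 2)
```

and scores the probe-weighted squared distance of `(nA, nB)` to the nearest
*non-negative* integers. Two details matter:

* **Negative implied copy numbers are penalized, not clamped.** An aliasing
  solution near `rho / 2` can explain a CN 3 segment perfectly but forces a
  negative minor allele count for a CN 1 segment; scoring that count against
  0 (rather than silently truncating it) removes the alias.
* **Ploidy is derived, not searched.** With LRR normalized to the diploid
  baseline — which is how the generator and the inversion formula above
  define it — total copy number is fixed by `r` and `rho`, so a second grid
  dimension over ploidy is redundant. `psi` is reported as the probe-weighted
  mean rounded total copy number, snapped to a 1.0-5.5 grid.

`gamma` defaults to 0.66 — the compression the canonical state means
themselves imply (`-0.66 = 0.66 * log2(1/2)` for CN 1) — keeping the
segmentation emission model, the simulator, and the purity inversion mutually
calibrated; 0.55 is the usual choice for Illumina arrays and remains
available as a parameter. Because contamination moves the emission centers,
`estimate_purity_track()` decodes the track under a small grid of assumed
purities (1, 0.85, 0.7, 0.55, 0.4) and keeps the identifiable candidate with
the lowest fit. Regions altered in the matched normal should be passed as
exclusions: a germline CNV is present in every cell and would otherwise
masquerade as a fully clonal somatic event and bias `rho` upward. A sample
with only balanced-diploid segments carries no information about
contamination; it is flagged unidentifiable and reported at `rho = 1`.
Heterozygous probes are taken from a germline-genotype flag on the track (in
practice available from the matched normal array); the BAF-interval fallback
cannot recognize LOH heterozygotes at high purity, which is a known
limitation.

# Numerical and procedural choices

* **Fisher sidedness**: two-sided by the minimum-likelihood rule everywhere
  (caller, recurrence, cohort-frequency comparisons), with the customary
  1e-7 relative tie tolerance; the test suite pins this against a log-choose
  hypergeometric enumeration to 1e-12.
* **HMM**: stay probability `1 - 1e-4` per probe, off-diagonal uniform;
  initial distribution 0.99 diploid. Five states without a distinct
  copy-neutral-LOH state, since the downstream rule needs only CN classes.
  Runs shorter than `min_probes = 3` are absorbed into the flanking state
  with the closer model mean. BAF emissions include the homozygous clusters
  for every state plus a small uniform floor, so stray probes cannot produce
  infinite penalties.
* **Recurrence**: a carrier is any sample with an overlapping altered
  segment; significant probes merge across at most one intervening
  non-significant probe; any 1-bp overlap with the exclusion track removes a
  region. MDM2 "amplification" is CN >= 4 by default (high-level gain,
  configurable to >= 3).
* **Wilcoxon**: exact enumeration below n = 50 per group without ties,
  otherwise the tie-corrected normal approximation with continuity
  correction; identical groups return p = 1.
* **Storey pi0**: fixed lambda = 0.5, guarded below by `1/m`; q-values are
  `pi0` times the BH step-up, hence never above BH.
* **EASE**: the term/query overlap is reduced by one (floored at 0) with all
  margins kept, then the one-tailed enrichment tail is summed; overlap 0 or
  1 gives p = 1.
* **Fuzzy clustering determinism**: terms are sorted by id before seeding;
  merge order is descending group size with lexicographic tie-break, making
  the output invariant to input order. The kappa threshold defaults to 0.35
  (the customary functional-clustering default); a threshold of exactly 1
  would demand identical gene memberships and leaves every term its own
  seed, so it is exposed as a parameter rather than hard-coded.
* **Normalization**: raw signals floored at 1.0, log2, per-sample shift so
  the 75th percentile (linear-interpolation definition) is zero. The shift is
  idempotent and invariant to per-sample rescaling; flooring is defined on
  the raw linear scale only. A division-by-percentile variant is available.
* **Degenerate DE probes**: zero variance in both groups yields p = 1 with a
  flag, never significance.
* **Seed handling**: every pipeline stage derives its own stream from the
  master seed via a stable label hash, so toggling one stage leaves the
  others' randomness untouched; reruns are byte-identical and every output
  table carries the configuration hash in its header.

# Problem sizes used by the tests

The suite runs cohorts of 8-16 samples on 4-6 chromosomes of 100-200 probes
for pipeline-level checks, the full 34-sample / 22-chromosome / 2,000-probe
configuration for the acceptance checks (caller recall, DE calibration and
recovery), 20 single-sample tracks of 1,000 probes for purity recovery across
purities 0.4-1.0, and complete path enumeration up to 12 probes for the
Viterbi cross-check. A 120-sample cohort validates the mutation-burden mean.
These sizes were chosen so that every stochastic check has enough replication
to be stable under reseeding while the whole suite stays fast.

# Known limitations

* The caller consumes counts as given; read-quality heuristics of production
  callers (strand bias, mapping quality, realignment around indels) are
  upstream of this package. Low-depth sites near the VAF floor sit close to
  the exact test's power boundary — a frameshift present at low depth can be
  missed, which is why targeted re-sequencing of TP53-wildtype samples
  remains good practice before calling a pathway intact.
* Segmentation assumes the emission calibration above; arrays with different
  compression need `gamma` and the state means adjusted together.
* The purity grid cannot separate contamination from a perfectly balanced
  tetraploid genome (no informative allelic imbalance), and samples whose
  only aberrations are germline CNVs are reported unidentifiable.
* The subtype rule checks mutations, TP53 loss and MDM2 gain; deletions of
  p53 target genes are not treated as pathway hits, mirroring the original
  rule's scope.
* DAVID-style clustering here works on any user-supplied GMT; it does not
  reproduce the hosted annotation content or category weighting of the DAVID
  service.
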