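---
title: "Tumor-naive cfDNA profiling for classic Hodgkin lymphoma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-naive cfDNA profiling for classic Hodgkin lymphoma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfhl)
library(dplyr)
```

# Scope and problem statement

Classic Hodgkin lymphoma is dominated by rare malignant Hodgkin
Reed–Sternberg cells, so tumor biopsies yield little tumor DNA and most
patients never get a matched tumor/normal sequencing pair. Molecular
profiling therefore has to work from plasma cell-free DNA (cfDNA) alone:
somatic variants must be separated from germline polymorphism and
sequencing artifact *without a matched normal*, tumor burden must be
inferred from shallow copy-number signal, and residual disease must be
tracked longitudinally from variants discovered at baseline.

`cfhl` implements that analysis chain as a set of composable, tested
functions:

1. **Consensus merge** of per-sample VCFs from up to four somatic variant
   callers (`read_caller_vcf()`, `consensus_merge()`).
2. A **tumor-naive filter cascade** (`run_cascade()`) combining hard
   evidence thresholds, a panel of normals (PoN), functional and
   population-frequency annotation filters, InDel/MNV rules, and a
   cohort-level recurrence filter.
3. **Copy-number metrics** from 1,000 kbp bin log2 ratios: segment
   calling, fraction of genome altered (FGA) and a grid-search estimated
   tumor fraction (ETF) (`cnv_profile()`).
4. **ctDNA quantification** in haploid genome equivalents per mL plasma
   (`hge_per_ml()`) and **longitudinal tracking** (`track_patient()`).
5. **Supervised cluster comparisons** by EBV status and SOCS1 mutation
   (`assign_clusters()`, `compare_groups()`, `vaf_overlap_match()`).
6. **Reporting**: cohort summary tables, oncoplot-ordered mutation
   matrices, per-bin CNV frequency tracks.

Because the underlying patient-level sequencing data for this disease
setting are generally not deposited, the package ships a first-class
synthetic cohort generator (`simulate_cohort()`) whose defaults encode
the study conditions the pipeline targets; every downstream claim in the
test suite is checked against the generator's ground truth.

# The filter cascade

All thresholds are strict inequalities, applied in a fixed order; each
variant is stamped with the *first* rule that removes it and carries the
ordered trace of rules evaluated, so filter attrition is fully auditable.

| order | rule | criterion |
|---|---|---|
| 1 | `depth` | read depth > 100 |
| 2 | `vaf` | variant allele frequency > 1% |
| 3 | `alt_depth` | mutant reads > 7 |
| 4 | `base_quality` | mean base quality > 25 |
| 5 | `pon` | exact chrom:pos:ref:alt key not in the panel of normals |
| 6 | `mnv_overlap` | SNV not inside an MNV span reported by a non-supporting caller |
| 7 | `effect` | effect class not synonymous/UTR/intronic/2 kb-flanking |
| 8 | `population_af` | gnomAD and 1000G allele frequency both ≤ 0.001 |
| 9 | `high_vaf_listed` | VAF ≤ 20% for variants listed in either population database |
| 10 | `indel_length` | InDels ≤ 20 bp |
| 11 | `indel_gc` | InDels > 10 bp retained only if inserted/deleted GC ≤ 60% |
| 12 | `cosmic_recurrence` | cohort-level; see below |

Interpretation choices the source description leaves open:

* **Consensus**: union over callers with the supporter count retained
  (`min_callers = 1` by default); consensus VAF and base quality are the
  medians over supporting callers; consensus depth is the maximum read
  depth with its *paired* mutant-read count (ties broken by higher
  mutant reads, then caller id).
* **"Listed" population variants** (rule 9): a variant is listed if it
  has *any* non-missing allele frequency, including 0; an absent
  annotation row means not listed.
* **MNV overlap** (rule 6): an SNV is removed when its position falls
  inside the reference span of an MNV reported by a caller that is not
  among the SNV's own supporters.
* **Equal-length alleles** with maximum allele length < 20 are
  reclassified as MNVs and retained (they are not InDels).
* **COSMIC recurrence** (rule 12): "non-unique" variants are those whose
  exact key passes the per-variant rules in baseline samples of at least
  two *distinct patients*; if such a variant is not in COSMIC it is
  removed cohort-wide. A `recurrence_scope = "cross_sample"` switch
  implements the alternative reading (≥ 2 baseline samples regardless of
  patient). A within-one-sample reading is impossible after consensus,
  because keys are unique per sample.
* GC content for rule 11 is computed on the inserted/deleted bases after
  stripping the common prefix of the two alleles.

The tracking variant (`tracking_filter_config()`) disregards the
functional-effect rule — a synonymous variant is a perfectly good tumor
marker — and relaxes the VAF cutoff to > 0.4% at follow-up timepoints.

```{r cascade-demo}
calls <- bind_rows(
  lapply(c("mutect2", "lofreq", "sinvict"), function(cl)
    tibble(sample_id = "S1", caller_id = cl, chrom = "chr1", pos = 1000L,
           ref = "A", alt = "T", read_depth = 1500L, alt_depth = 60L,
           vaf = 0.04, base_quality = 34)))
ann <- tibble(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
              gene = "KMT2D", effect_class = "coding_nonsynonymous",
              gnomad_af = NA_real_, kg_af = NA_real_, cosmic = TRUE)
pon <- build_pon(tibble(sample_id = "C1", caller_id = "mutect2",
                        chrom = "chr1", pos = 999L, ref = "G", alt = "C",
                        read_depth = 800L, alt_depth = 20L, vaf = 0.025,
                        base_quality = 30))
run_cascade(calls, pon, ann)$pass
```

# Copy-number model and the tumor-fraction estimator

Bin-level log2 ratios follow the diploid-admixture model: a bin at
integer tumor copy number $c$ in a sample with tumor fraction $t$ has
expected ratio

$$\log_2\!\left(\frac{t\,c + (1-t)\,2}{2}\right),$$

implemented by `expected_log2()`. Segments are maximal same-direction
runs of bins with $|\log_2| > 0.08$ (strict; bins at the cutoff are
neutral; no minimum segment length, so single-bin segments are allowed at
1,000 kbp resolution). FGA is the fraction of bins inside called
segments.

`estimate_tumor_fraction()` is a deliberately simple, fully specified
stand-in for HMM-based tools such as ichorCNA: for each candidate $t$ on
a 0.001 grid, every called segment (plus the neutral background) is
assigned the copy number in $0..4$ whose expected ratio is nearest its
observed mean, and the candidate is scored by bin-weighted squared error
plus a diploid-proximity penalty
$10^{-3} \sum_{\text{pieces}} n_{\text{bins}} (c - 2)^2$.

Two numerical points deserve emphasis:

* **Scale non-identifiability.** One gained copy at tumor fraction $t$
  fits *exactly* as well as two gained copies at $t/2$
  (`expected_log2(3, t) == expected_log2(4, t/2)`), and symmetrically
  for losses. The penalty resolves every such tie toward the copy state
  nearest diploid — hence a pure single-copy gain with mean
  $\log_2(1.5)$ yields $\hat t = 1$, and a profile that is truly a
  homozygous deletion at low $t$ will be reported as a single-copy loss
  at $2t$. No threshold-based estimator can distinguish these cases from
  one profile; the bias direction is documented rather than hidden.
* **Penalty weight.** The weight $10^{-3}$ per bin per squared copy step
  is chosen so that a single noisy bin cannot flip a long segment to a
  more extreme copy state at half the tumor fraction (observed with a
  weaker penalty: a spurious 0.08-crossing bin re-fitted a genuine
  8-bin single-copy loss at half its true fraction), while exact-fit tie
  resolution is unaffected because it depends only on the penalty's
  direction, not its magnitude. On 300-bin profiles with noise
  s.d. 0.02, median recovery error is below 0.01 for tumor fractions in
  [0.05, 0.8].

Near the calling threshold the estimator inherits a selection bias from
segmentation itself: when the expected shift is close to 0.08, only the
bins that fluctuate past the cutoff are called, so short called segments
overestimate the shift. Profiles with tumor fraction below ≈ 0.11 (for
single-copy events) produce no called segments at all and return 0 —
`reconcile_etf()` additionally zeroes pre-treatment estimates that lack
any supporting segment.

# Quantification and tracking

Per-sample ctDNA level is the median VAF of passing SNVs (MNVs and
InDels excluded); a sample with no passing SNV gets `NA`, not 0 —
absence of evidence at panel scale is not a measurement of zero. The
absolute concentration is

$$\text{hGE/mL} = \text{mean VAF} \times \frac{\text{cfDNA (pg/mL plasma)}}{3.3\ \text{pg}},$$

3.3 pg being the weight of one haploid genome
(`hge_per_ml(0.05, 6600)` = 100).

A variant is *trackable* when it passes at the first available timepoint
and at least one later timepoint (under the relaxed tracking rules). The
per-timepoint series averages the tracked set with undetected variants
contributing VAF 0, so the series measures residual-disease decline
rather than detected-only survivor bias. One honest caveat, surfaced by
the synthetic ground truth: a tumor-naive tracked set can latch onto a
*persistent artifact* that passes all filters and reappears across
timepoints; such markers do not decay with treatment. With several
tracked variants the average is robust; single-marker tracking is
fragile, exactly as in practice.

# Cluster analysis

Cluster labels are a pure function of tumor EBV status and the presence
of a passing SOCS1 variant (`EBV_pos_SOCS1m`, `EBV_neg_SOCS1m`,
`EBV_neg_SOCS1wt`; samples with no passing variant or unknown EBV status
are `unassigned`). SNV-load comparisons exclude SOCS1 itself, since the
clusters are defined on it. `vaf_overlap_match()` restricts both
EBV-negative clusters to samples whose median VAF lies in the closed
window from the lowest mutated-cluster median to the highest
wild-type-cluster median, so load contrasts cannot be explained by
different ctDNA levels; window endpoints are inclusive so the boundary
samples defining the window are retained.

Statistics are intentionally plain `stats::` machinery: two-sided
Wilcoxon rank-sum (exact for group sizes ≤ 25 without ties, otherwise
normal approximation with tie correction), Kruskal–Wallis for three or
more groups, Spearman correlation, significance at p < 0.05 with no
multiplicity adjustment.

# The synthetic cohort generator

`simulation_config()` defaults encode the target study conditions:
44 patients, 7 PoN controls, three clusters in proportions
0.20/0.35/0.45, a 72-gene panel (~244 kb total) on a miniature genome of
3 chromosomes × 100 Mb (300 bins of 1,000 kbp), four emulated callers,
and three timepoints for a tracked subset of six patients.

Mechanisms, and why they are shaped this way:

* **Somatic load** per cluster is negative binomial (mu 9/16/6,
  size 4/4/3), calibrated so the cohort median somatic count is ~7,
  matching the targeted setting; SOCS1-mutated patients receive
  1 + Binomial(4, 0.22) SOCS1 hits. Somatic true VAFs scale with tumor
  fraction (≈ tf/2 with log-normal scatter), so per-patient median VAFs
  span roughly 1–14%.
* **Tumor fraction** is log-normal per cluster (medians 0.07/0.12/0.045,
  sdlog 0.5), with 9% of patients carrying no ctDNA at all.
* **Caller emulation**: each caller detects a variant with probability
  `max_sens * plogis((VAF - midpoint)/scale)` (midpoints 0.6–1.3% VAF)
  and reports binomially resampled mutant reads at negative-binomial
  depth (mean 1,500). This reproduces the partial-overlap structure a
  consensus step must handle without reimplementing real callers.
* **Germline SNPs** come from a shared population pool with realistic
  allele frequencies (so the population-frequency filter has real work
  to do); **artifacts** are a shared recurrent pool (seen by controls,
  hence removable via the PoN) plus sporadic low-VAF noise. Pool loci
  are sampled *uniformly* over the panel — technical noise and
  polymorphism have no reason to favor lymphoma drivers, and
  driver-weighted artifact loci would fabricate false SOCS1-mutated
  cluster labels.
* **Clinical covariates** (cfDNA concentration, sTARC, MTV) are
  log-normal with location terms increasing in tumor fraction, giving
  the correlation structure the comparison module is meant to detect.
  The data source gives no distributional forms for these; log-normal
  positive quantities with multiplicative noise are the standard
  assumption.
* **Longitudinal decay**: responders multiply tumor fraction by 0.1 per
  timepoint, refractory patients by 0.75.
* Identical configuration and seed reproduce byte-identical bundles.

Limits worth stating: coordinates live on the miniature genome, not
hg38; caller behavior is a two-parameter logistic, not a realistic
error model; copy-number truth is piecewise-constant integer states
without subclonality; EBV status is error-free metadata. These are
deliberate — every simplification keeps a ground-truth quantity exactly
recoverable so the pipeline's statistical behavior can be asserted,
which is the generator's job.

```{r sim-demo, eval = FALSE}
sim <- simulate_cohort(simulation_config(seed = 1), tempfile("cohort"))
clin <- read_clinical_tsv(sim$files$clinical_file)
pon <- build_pon(read_sample_calls(sim$files$vcf_dir,
                                   sim$files$control_ids,
                                   sim$files$callers))
ann <- read_annotation_tsv(sim$files$annotation_file)
base <- dplyr::filter(clin, pretreatment)
res <- run_cascade(
  read_sample_calls(sim$files$vcf_dir, base$sample_id, sim$files$callers),
  pon, ann, baseline_samples = base$sample_id,
  patients = dplyr::select(base, sample_id, patient_id))
res$audit
```

# Problem sizes and performance

The shipped scale — 44 patients (56 samples with follow-ups), 7
controls, 4 callers, ~300 consensus loci per sample, 300 copy-number
bins — is the package's own choice of a desk-scale instance: large
enough that every rule fires and every statistic has usable power, small
enough that the full test suite (including two complete end-to-end
cohorts) runs in under two minutes on one CPU. The cascade is vectorized
over variants; the ETF grid search is O(grid × segments) and takes
milliseconds per profile.

# Reporting conventions

Percentages are rounded half-up to one decimal, computed against the
full cohort n, with missing values as explicit rows. Oncoplot ordering:
genes by total SNV count descending (ties by name); samples by cluster
(EBV+ & SOCS1m, EBV− & SOCS1m, EBV− & SOCS1wt), then SNV load
descending, ties by sample id; samples with no passing variant are
excluded. Both orderings are stable under permutation of the input.
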