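# cfhl — tumor-naive cfDNA profiling for classic Hodgkin lymphoma

`cfhl` is an R package for molecular profiling of cell-free DNA (cfDNA)
in classic Hodgkin lymphoma, a disease where the malignant Hodgkin
Reed–Sternberg cells are so rare in biopsies that matched tumor/normal
sequencing is usually impossible. Everything therefore has to be done
from plasma alone, *tumor-naive*:

* **Consensus variant calling without a matched normal** — per-sample
  VCFs from up to four somatic callers (Mutect2, LoFreq, SiNVICT,
  VarDict or emulations thereof) are union-merged into consensus records
  (median VAF and base quality across supporting callers, maximum read
  depth with its paired mutant-read count), then pushed through a strict
  filter cascade: read depth > 100, VAF > 1%, mutant reads > 7, base
  quality > 25, a panel of normals built from control plasma, removal of
  SNVs inside other callers' MNV spans, functional-effect and
  gnomAD/1000G population-frequency filters (AF > 0.001 removed;
  VAF > 20% removed for any variant listed in a population database),
  InDel length/GC rules, and a cohort-level filter that removes
  non-unique non-COSMIC baseline variants. Every variant leaves the
  cascade either `PASS` or stamped with the first rule that removed it,
  with a full audit trail.
* **Copy-number burden from shallow signal** — 1,000 kbp bin log2
  ratios are segmented at |log2| > 0.08, summarized as the fraction of
  genome altered (FGA), and converted to an estimated tumor fraction
  (ETF) by a grid search under the diploid-admixture model
  log2((tf·cn + (1−tf)·2)/2), a deliberately simple, fully specified
  stand-in for ichorCNA-style HMMs.
* **Absolute ctDNA quantification** — hGE/mL = mean VAF × cfDNA
  concentration (pg/mL plasma) / 3.3, the weight of one haploid genome
  in pg.
* **Longitudinal residual-disease tracking** — variants present at the
  first timepoint and re-occurring later are tracked with relaxed rules
  (effect filter off, follow-up VAF cutoff 0.4%), undetected tracked
  variants counting as VAF 0.
* **Supervised EBV/SOCS1 cluster comparisons** — samples are labelled by
  tumor EBV status and passing SOCS1 mutations; SNV load (excluding
  SOCS1), median VAF, ETF and FGA are compared across clusters with
  Wilcoxon/Kruskal–Wallis/Spearman tests, including a median-VAF overlap
  matching step that controls for ctDNA level as a confounder.
* **Reporting** — clinical baseline tables with half-up one-decimal
  percentages, oncoplot-ordered gene×sample mutation matrices, per-bin
  CNV gain/loss frequency tracks.

Because patient-level sequencing data in this setting are typically not
deposited, the package ships a first-class synthetic cohort generator
(`simulate_cohort()`) with complete ground truth — planted somatic,
germline and artifact variants, caller-specific logistic dropout,
copy-number segments at known tumor fraction, tumor-fraction-linked
cfDNA/sTARC/MTV covariates, and longitudinal decay. The generator's
defaults encode the target study conditions (44 patients, 7
panel-of-normals controls, three clusters, ~7 somatic variants per
patient at median VAFs of roughly 1–14%).

## Worked example

A full synthetic study, end to end:

```r
library(cfhl)
library(dplyr)

sim <- simulate_cohort(simulation_config(seed = 1), "cohort")
clin <- read_clinical_tsv(sim$files$clinical_file)
base <- filter(clin, pretreatment)

pon <- build_pon(read_sample_calls(sim$files$vcf_dir,
                                   sim$files$control_ids,
                                   sim$files$callers))
ann <- read_annotation_tsv(sim$files$annotation_file)
calls <- read_sample_calls(sim$files$vcf_dir, base$sample_id,
                           sim$files$callers)
res <- run_cascade(calls, pon, ann, baseline_samples = base$sample_id,
                   patients = select(base, sample_id, patient_id))
res$audit
#> # A tibble: 7 × 2
#>   rule              removed
#>   <chr>               <int>
#> 1 alt_depth               3
#> 2 base_quality           62
#> 3 cosmic_recurrence      31
#> 4 effect                202
#> 5 pon                   510
#> 6 population_af         111
#> 7 vaf                   171
```

The panel of normals does most of the germline/artifact removal (510
records), the effect and population filters clean up the rest, and the
cohort-level COSMIC-recurrence rule catches 31 recurrent non-COSMIC
calls. What survives:

```r
per_sample <- count(res$pass, sample_id)
nrow(per_sample)                                   # 44 of 44 samples
median(per_sample$n)                               # 6 passing variants
mv <- sapply(per_sample$sample_id,
             function(s) median_vaf(filter(res$variants, sample_id == s)))
sprintf("%.1f%%", 100 * median(mv, na.rm = TRUE))  # "2.3%"
```

ctDNA quantification and copy number for one patient:

```r
p16 <- filter(base, sample_id == "P16_T0")
hge_per_ml(mv[["P16_T0"]], p16$cfdna_conc)
#> 127.3501   # median VAF 0.078 x 5365 pg/mL / 3.3

prof <- cnv_profile(read_bin_tsv(file.path(sim$files$bin_dir,
                                           "P16_T0.bins.tsv")), "P16_T0")
c(segments = nrow(prof$segments), fga = prof$fga, etf = prof$etf)
#> segments      fga      etf
#>    5.000    0.110    0.149   # ground-truth tumor fraction: 0.152
```

Cluster assignment and the SNV-load contrast (SOCS1 excluded from the
load since it defines the clusters):

```r
clusters <- assign_clusters(base, res$variants)
count(clusters, cluster)
#> 1 EBV_neg_SOCS1m     10
#> 2 EBV_neg_SOCS1wt    24
#> 3 EBV_pos_SOCS1m      9
#> 4 unassigned          1

cmp <- clusters |>
  filter(cluster %in% c("EBV_neg_SOCS1m", "EBV_neg_SOCS1wt")) |>
  left_join(snv_load(res$variants), by = "sample_id") |>
  mutate(snv_load = coalesce(snv_load, 0L))
compare_groups(cmp$snv_load, cmp$cluster)
#>   test              statistic p_value n_groups n     significant
#> 1 wilcoxon_rank_sum       206 0.00114        2 10,24 TRUE
```

The EBV-negative SOCS1-mutated cluster carries the higher mutational
burden, as designed into the generator's defaults.

See the vignette (`vignettes/cfdna-hodgkin-pipeline.Rmd`) for the
underlying model, every threshold with its rationale, the tumor-fraction
estimator's identifiability limits, and the generator's design.

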