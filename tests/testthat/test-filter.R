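test_that("allele classification distinguishes SNV, MNV and InDel", {
  cls <- classify_alleles(
    ref = c("A", "CT", "A", "ATTTT", "GGGGGGGGGGGGGGGGGGGGG", "ACG"),
    alt = c("T", "AG", "ATT", "A", "G", "TGA")
  )
  expect_equal(cls$variant_class,
               c("SNV", "MNV", "InDel", "InDel", "InDel", "MNV"))
  expect_equal(cls$indel_length, c(0, 0, 2, 4, 20, 0))
  # inserted/deleted bases after common-prefix stripping drive GC content
  gcc <- classify_alleles("A", "AGCGC")$gc_content
  expect_equal(gcc, 1)
  expect_equal(classify_alleles("CATAT", "C")$gc_content, 0)
})

test_that("the panel of normals is the exact-allele union over controls", {
  mk <- function(sid, pos) cv(sample_id = sid, pos = pos)
  disjoint <- dplyr::bind_rows(lapply(1:7, function(i) mk(paste0("C", i),
                                                          1000 + i)))
  expect_length(build_pon(disjoint), 7)
  shared <- dplyr::bind_rows(mk("C1", 500), mk("C2", 500))
  expect_length(build_pon(shared), 1)
  expect_error(build_pon(character(0)), "at least one control")
  # same position, different alleles -> two distinct PoN keys
  two_alleles <- dplyr::bind_rows(cv(sample_id = "C1", pos = 9, alt = "T"),
                                  cv(sample_id = "C2", pos = 9, alt = "G"))
  expect_length(build_pon(two_alleles), 2)
})

test_that("PoN built from synthetic controls equals the planted control loci", {
  sim <- simulate_cohort(tiny_sim_config(seed = 21), withr::local_tempdir())
  ctrl_calls <- read_sample_calls(sim$files$vcf_dir, sim$files$control_ids,
                                  sim$files$callers)
  pon <- build_pon(ctrl_calls)
  truth <- sim$truth$variants
  planted <- truth[truth$sample_id %in% sim$files$control_ids &
                     truth$n_callers_detected > 0, ]
  expected <- sort(unique(paste(planted$chrom, planted$pos, planted$ref,
                                planted$alt, sep = ":")))
  expect_identical(unclass(pon), expected)
  expect_true(all(planted$category %in% c("germline", "artifact")))
})

test_that("consensus merge takes the median VAF and deepest evidence", {
  calls <- dplyr::bind_rows(
    cv(caller_id = "mutect2", read_depth = 1000, alt_depth = 30),
    cv(caller_id = "lofreq", read_depth = 800, alt_depth = 32),
    cv(caller_id = "sinvict", read_depth = 1200, alt_depth = 60),
    cv(caller_id = "vardict", read_depth = 900, alt_depth = 54)
  )
  m <- consensus_merge(calls)
  expect_equal(nrow(m), 1)
  expect_equal(m$n_callers, 4)
  expect_equal(m$vaf, median(c(30 / 1000, 32 / 800, 60 / 1200, 54 / 900)))
  expect_equal(m$read_depth, 1200)
  expect_equal(m$alt_depth, 60)     # paired with the deepest caller
  # the worked four-caller VAF example: {3,4,5,6}% -> 4.5%
  calls2 <- dplyr::bind_rows(lapply(seq_along(c(0.03, 0.04, 0.05, 0.06)),
    function(i) {
      v <- c(0.03, 0.04, 0.05, 0.06)[i]
      cv(caller_id = c("mutect2", "lofreq", "sinvict", "vardict")[i],
         read_depth = 1000, alt_depth = round(1000 * v))
    }))
  expect_equal(consensus_merge(calls2)$vaf, 0.045)
  # disjoint loci from two callers are both kept with one supporter each
  disj <- dplyr::bind_rows(cv(caller_id = "mutect2", pos = 10),
                           cv(caller_id = "lofreq", pos = 20))
  m2 <- consensus_merge(disj)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$n_callers, c(1, 1))
})

test_that("merged locus set equals the brute-force union over callers", {
  for (seed in 1:3) {
    inst <- random_filter_instance(n_loci = 60, n_samples = 2, seed = seed)
    m <- consensus_merge(inst$calls)
    got <- sort(paste(m$sample_id, m$chrom, m$pos, m$ref, m$alt))
    want <- sort(unique(paste(inst$calls$sample_id, inst$calls$chrom,
                              inst$calls$pos, inst$calls$ref,
                              inst$calls$alt)))
    expect_identical(got, want)
  }
})

test_that("primary thresholds are strict at the printed boundaries", {
  v <- consensus_merge(dplyr::bind_rows(
    cv(pos = 1, read_depth = 100, alt_depth = 10, base_quality = 30), # depth
    cv(pos = 2, read_depth = 1000, alt_depth = 10, base_quality = 30), # vaf
    cv(pos = 3, read_depth = 500, alt_depth = 7, base_quality = 30),  # alt
    cv(pos = 4, read_depth = 500, alt_depth = 50, base_quality = 25), # bq
    cv(pos = 5, read_depth = 101, alt_depth = 8, base_quality = 25.1)
  )) |> annotate_variants(empty_ann())
  out <- apply_primary_thresholds(v)
  status <- setNames(out$filter_status, out$pos)
  expect_equal(unname(status[as.character(1:4)]),
               c("depth", "vaf", "alt_depth", "base_quality"))
  # pos 5: depth 101 > 100, vaf 8/101 > 1%, alt 8 > 7, bq 25.1 > 25
  expect_equal(unname(status["5"]), "PASS")
  # the rule trace stops at the first failing rule
  expect_equal(out$rule_trace[out$pos == 1], "depth")
  expect_equal(out$rule_trace[out$pos == 5],
               "depth;vaf;alt_depth;base_quality")
})

test_that("SNVs inside another caller's MNV span are removed", {
  calls <- dplyr::bind_rows(
    cv(caller_id = "mutect2", pos = 105, ref = "A", alt = "T"),
    cv(caller_id = "mutect2", pos = 103, ref = "C", alt = "G"),
    cv(caller_id = "lofreq", pos = 104, ref = "ACT", alt = "TGA")
  )
  v <- consensus_merge(calls) |> annotate_variants(empty_ann()) |>
    apply_primary_thresholds()
  out <- remove_pon_and_mnv_overlaps(v, build_pon(cv(sample_id = "Cx",
                                                     pos = 999)),
                                     calls = calls)
  status <- setNames(out$filter_status, out$pos)
  expect_equal(unname(status["105"]), "mnv_overlap")  # inside 104-106
  expect_equal(unname(status["103"]), "PASS")         # adjacent, no overlap
  expect_equal(unname(status["104"]), "PASS")         # the MNV itself
})

test_that("PoN membership is exact-allele and removes the variant", {
  pon <- build_pon(cv(sample_id = "C1", pos = 50, ref = "A", alt = "T"))
  v <- consensus_merge(dplyr::bind_rows(
    cv(pos = 50, ref = "A", alt = "T"),
    cv(pos = 50, ref = "A", alt = "G")
  )) |> annotate_variants(empty_ann()) |> apply_primary_thresholds()
  out <- remove_pon_and_mnv_overlaps(v, pon)
  expect_equal(sort(out$filter_status), c("PASS", "pon"))
  expect_equal(out$filter_status[out$alt == "T"], "pon")
})

test_that("annotation filters enforce effect, population AF and high-VAF rules", {
  mk <- function(pos, vaf, effect = "coding_nonsynonymous",
                 gaf = NA, kaf = NA) {
    list(call = cv(pos = pos, read_depth = 1000, alt_depth = round(1000 * vaf)),
         ann = ann_row(pos = pos, effect_class = effect, gnomad_af = gaf,
                       kg_af = kaf))
  }
  cases <- list(
    mk(1, 0.05, effect = "synonymous"),
    mk(2, 0.05, effect = "intronic"),
    mk(3, 0.05, gaf = 0.002),              # population_af
    mk(4, 0.05, kaf = 0.0011),             # population_af via 1000G
    mk(5, 0.25, gaf = 1e-6),               # high VAF and listed
    mk(6, 0.25),                           # high VAF, unlisted -> retained
    mk(7, 0.05, gaf = 0.001),              # boundary: not > 0.001
    mk(8, 0.05, effect = "other_functional")
  )
  calls <- dplyr::bind_rows(lapply(cases, `[[`, "call"))
  ann <- dplyr::bind_rows(lapply(cases, `[[`, "ann"))
  out <- consensus_merge(calls) |> annotate_variants(ann) |>
    apply_primary_thresholds() |> apply_annotation_filters()
  status <- setNames(out$filter_status, out$pos)
  expect_equal(unname(status[as.character(1:8)]),
               c("effect", "effect", "population_af", "population_af",
                 "high_vaf_listed", "PASS", "PASS", "PASS"))
  # tracking mode disregards the functional-effect filter
  out2 <- consensus_merge(calls) |> annotate_variants(ann) |>
    apply_primary_thresholds() |>
    apply_annotation_filters(tracking_filter_config())
  expect_equal(out2$filter_status[out2$pos == 1], "PASS")
})

test_that("InDel length and GC rules follow the printed cutoffs", {
  gc_rich <- paste(rep(c("G", "C", "G", "T"), 4)[1:15], collapse = "") # 15bp GC>60
  at_rich <- paste(rep("A", 25), collapse = "")
  mid_at <- paste(rep(c("A", "T", "A", "G"), 3), collapse = "")        # 12bp GC 25%
  calls <- dplyr::bind_rows(
    cv(pos = 1, ref = "A", alt = paste0("A", gc_rich)),
    cv(pos = 2, ref = paste0("T", at_rich), alt = "T"),
    cv(pos = 3, ref = "GGA", alt = "TCG"),
    cv(pos = 4, ref = "A", alt = paste0("A", mid_at))
  )
  out <- consensus_merge(calls) |> annotate_variants(empty_ann()) |>
    apply_primary_thresholds() |> apply_indel_mnv_rules()
  status <- setNames(out$filter_status, out$pos)
  expect_equal(unname(status["1"]), "indel_gc")       # 15 bp, GC > 60%
  expect_equal(unname(status["2"]), "indel_length")   # 25 bp regardless of GC
  expect_equal(unname(status["3"]), "PASS")           # equal length -> MNV
  expect_equal(out$variant_class[out$pos == 3], "MNV")
  expect_equal(unname(status["4"]), "PASS")           # 12 bp but GC low
})

test_that("non-unique baseline variants outside COSMIC are removed cohort-wide", {
  mk <- function(sid, pos) cv(sample_id = sid, pos = pos)
  calls <- dplyr::bind_rows(
    mk("P1_T0", 100), mk("P2_T0", 100), mk("P3_T0", 100), # recurrent, no COSMIC
    mk("P1_T0", 200), mk("P2_T0", 200), mk("P3_T0", 200), # recurrent, COSMIC
    mk("P1_T0", 300)                                      # unique
  )
  ann <- dplyr::bind_rows(
    ann_row(pos = 100, cosmic = FALSE),
    ann_row(pos = 200, cosmic = TRUE),
    ann_row(pos = 300, cosmic = FALSE)
  )
  pats <- tibble::tibble(sample_id = c("P1_T0", "P2_T0", "P3_T0"),
                         patient_id = c("P1", "P2", "P3"))
  res <- run_cascade(calls, build_pon(cv(sample_id = "C", pos = 9)), ann,
                     patients = pats)
  v <- res$variants
  expect_true(all(v$filter_status[v$pos == 100] == "cosmic_recurrence"))
  expect_true(all(v$filter_status[v$pos == 200] == "PASS"))
  expect_true(all(v$filter_status[v$pos == 300] == "PASS"))
  expect_equal(res$audit$removed[res$audit$rule == "cosmic_recurrence"], 3)
  # one patient with two baseline samples is still "unique"
  pats2 <- tibble::tibble(sample_id = c("P1_T0", "P2_T0", "P3_T0"),
                          patient_id = "P1")
  res2 <- run_cascade(calls, build_pon(cv(sample_id = "C", pos = 9)), ann,
                      patients = pats2)
  expect_true(all(res2$variants$filter_status[res2$variants$pos == 100] ==
                    "PASS"))
  # ... unless the scope is per-sample
  res3 <- run_cascade(calls, build_pon(cv(sample_id = "C", pos = 9)), ann,
                      config = filter_config(recurrence_scope = "cross_sample"),
                      patients = pats2)
  expect_true(all(res3$variants$filter_status[res3$variants$pos == 100] ==
                    "cosmic_recurrence"))
})

test_that("the cascade is audit-complete, order-insensitive and idempotent", {
  inst <- random_filter_instance(n_loci = 80, n_samples = 3, seed = 42)
  res <- run_cascade(inst$calls, inst$pon, inst$annotations)
  v <- res$variants
  # audit completeness: each locus exactly once, PASS or a named rule
  expect_equal(nrow(v), nrow(dplyr::distinct(
    inst$calls, sample_id, chrom, pos, ref, alt)))
  rule_names <- c("PASS", "depth", "vaf", "alt_depth", "base_quality", "pon",
                  "mnv_overlap", "effect", "population_af", "high_vaf_listed",
                  "indel_length", "indel_gc", "cosmic_recurrence")
  expect_true(all(v$filter_status %in% rule_names))
  expect_equal(sum(res$audit$removed) + nrow(res$pass), nrow(v))
  # order-insensitivity
  shuffled <- inst$calls[sample.int(nrow(inst$calls)), ]
  res2 <- run_cascade(shuffled, inst$pon, inst$annotations)
  expect_identical(as.data.frame(res2$variants), as.data.frame(v))
  # idempotence: feeding back the surviving caller records changes nothing
  pass_keys <- paste(res$pass$sample_id, res$pass$chrom, res$pass$pos,
                     res$pass$ref, res$pass$alt)
  surviving_calls <- inst$calls |>
    dplyr::filter(paste(sample_id, chrom, pos, ref, alt) %in% pass_keys)
  res3 <- run_cascade(surviving_calls, inst$pon, inst$annotations)
  expect_setequal(paste(res3$pass$sample_id, res3$pass$chrom, res3$pass$pos,
                        res3$pass$ref, res3$pass$alt), pass_keys)
  # empty input
  res0 <- run_cascade(inst$calls[0, ], inst$pon, inst$annotations)
  expect_equal(nrow(res0$pass), 0)
  expect_equal(nrow(res0$audit), 0)
})

test_that("planted somatic variants survive and PoN artifacts never do", {
  sim <- simulate_cohort(simulation_config(seed = 4), withr::local_tempdir())
  ctrl_calls <- read_sample_calls(sim$files$vcf_dir, sim$files$control_ids,
                                  sim$files$callers)
  pon <- build_pon(ctrl_calls)
  ann <- read_annotation_tsv(sim$files$annotation_file)
  base_ids <- sim$truth$samples$sample_id[sim$truth$samples$pretreatment]
  calls <- read_sample_calls(sim$files$vcf_dir, base_ids, sim$files$callers)
  pats <- dplyr::distinct(sim$truth$samples[sim$truth$samples$pretreatment, ],
                          sample_id, patient_id)
  res <- run_cascade(calls, pon, ann, baseline_samples = base_ids,
                     patients = pats)
  truth <- sim$truth$variants
  som <- truth[truth$category == "somatic" & truth$sample_id %in% base_ids &
                 truth$true_vaf > 0.02 & truth$n_callers_detected > 0, ]
  som_keys <- paste(som$sample_id, som$chrom, som$pos, som$ref, som$alt)
  pass_keys <- paste(res$pass$sample_id, res$pass$chrom, res$pass$pos,
                     res$pass$ref, res$pass$alt)
  deep <- res$variants$read_depth > 200
  deep_keys <- paste(res$variants$sample_id, res$variants$chrom,
                     res$variants$pos, res$variants$ref,
                     res$variants$alt)[deep]
  eligible <- intersect(som_keys, deep_keys)
  expect_gt(length(eligible), 50)
  expect_gte(mean(eligible %in% pass_keys), 0.95)
  # specificity: no passing variant is a planted control-pool artifact
  pon_hits <- res$pass |>
    dplyr::mutate(key = paste(chrom, pos, ref, alt, sep = ":")) |>
    dplyr::filter(key %in% unclass(pon))
  expect_equal(nrow(pon_hits), 0)
})
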