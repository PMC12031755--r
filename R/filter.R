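#' Filter cascade configuration
#'
#' All thresholds of the tumor-naive cfDNA filter cascade. Every printed
#' cutoff is a strict inequality: read depth > 100, VAF > 1%, mutant read
#' depth > 7, base quality > 25, population allele fraction > 0.001,
#' high-VAF rule at VAF > 0.20, InDel GC screen for length > 10 bp at
#' GC > 60%, unconditional InDel removal above 20 bp, and MNV
#' reclassification for equal-length alleles below 20 bases.
#'
#' @param min_depth,min_vaf,min_alt_depth,min_base_quality primary
#'   per-variant thresholds (exclusive bounds).
#' @param min_callers minimum number of supporting callers for a
#'   consensus variant (default 1: union merge; the cascade, not caller
#'   voting, provides specificity).
#' @param max_pop_af population allele-frequency cutoff applied to gnomAD
#'   and 1000 Genomes independently.
#' @param high_vaf VAF above which any database-listed variant is treated
#'   as germline and removed.
#' @param apply_effect_filter drop variants without predicted functional
#'   effect (synonymous, UTR, intronic, 2 kb flanking). Disabled for
#'   longitudinal tracking.
#' @param indel_gc_min_len,indel_gc_max InDel length above which the GC
#'   screen applies, and its GC fraction cutoff.
#' @param indel_max_len InDel length above which removal is unconditional.
#' @param mnv_max_len equal-length variants shorter than this are
#'   reclassified as MNVs and bypass the InDel rules.
#' @param recurrence_scope how "non-unique" is interpreted for the COSMIC
#'   recurrence filter: identical variant in baseline samples of at least
#'   two distinct patients (`"cross_patient"`, default) or in at least two
#'   baseline samples (`"cross_sample"`).
#' @return a list of class `cfhl_filter_config`.
#' @export
filter_config <- function(min_depth = 100, min_vaf = 0.01, min_alt_depth = 7,
                          min_base_quality = 25, min_callers = 1,
                          max_pop_af = 0.001, high_vaf = 0.20,
                          apply_effect_filter = TRUE,
                          indel_gc_min_len = 10, indel_gc_max = 0.60,
                          indel_max_len = 20, mnv_max_len = 20,
                          recurrence_scope = c("cross_patient", "cross_sample")) {
  structure(list(
    min_depth = min_depth, min_vaf = min_vaf, min_alt_depth = min_alt_depth,
    min_base_quality = min_base_quality, min_callers = min_callers,
    max_pop_af = max_pop_af, high_vaf = high_vaf,
    apply_effect_filter = apply_effect_filter,
    indel_gc_min_len = indel_gc_min_len, indel_gc_max = indel_gc_max,
    indel_max_len = indel_max_len, mnv_max_len = mnv_max_len,
    recurrence_scope = match.arg(recurrence_scope)
  ), class = "cfhl_filter_config")
}

#' Classify variants by allele lengths
#'
#' SNV: both alleles one base. MNV: equal allele lengths with maximum
#' length below `mnv_max_len` (at least two adjacent substituted bases,
#' not a length change). InDel: everything else. Also returns the InDel
#' length (absolute base-length difference), the maximum allele length
#' and the GC fraction of the inserted/deleted bases (alleles stripped of
#' their common prefix).
#'
#' @param ref,alt reference and alternate allele strings.
#' @param mnv_max_len MNV reclassification bound (exclusive).
#' @return tibble with `variant_class`, `base_length_diff`,
#'   `max_base_length`, `indel_length`, `gc_content`.
#' @export
classify_alleles <- function(ref, alt, mnv_max_len = 20) {
  lr <- nchar(ref)
  la <- nchar(alt)
  diff <- abs(lr - la)
  mx <- pmax(lr, la)
  cls <- ifelse(lr == 1 & la == 1, "SNV",
                ifelse(diff == 0 & mx < mnv_max_len, "MNV", "InDel"))
  gc <- rep(NA_real_, length(ref))
  idx <- which(cls == "InDel" & diff > 0)
  if (length(idx) > 0) {
    gc[idx] <- vapply(idx, function(i) {
      r <- ref[i]; a <- alt[i]
      n <- min(nchar(r), nchar(a)); k <- 0
      while (k < n && substr(r, k + 1, k + 1) == substr(a, k + 1, k + 1)) {
        k <- k + 1
      }
      longer <- if (nchar(r) >= nchar(a)) r else a
      gc_fraction(substr(longer, k + 1, nchar(longer)))
    }, numeric(1))
  }
  tibble(variant_class = cls, base_length_diff = diff, max_base_length = mx,
         indel_length = diff, gc_content = gc)
}

#' Build a panel of normals from control samples
#'
#' The PoN is the union of exact variant keys (chrom, pos, ref, alt)
#' observed in any control sample by any caller; matching against it is
#' exact-allele.
#'
#' @param controls either a caller-variant tibble (as from
#'   [read_caller_vcf()]) covering the control samples, or a character
#'   vector of control VCF paths.
#' @return sorted character vector of locus keys, class `cfhl_pon`.
#' @export
build_pon <- function(controls) {
  if (is.character(controls)) {
    if (length(controls) == 0) abort("need at least one control VCF")
    controls <- bind_rows(lapply(controls, read_caller_vcf))
  }
  if (!is.data.frame(controls)) abort("`controls` must be paths or a tibble")
  keys <- sort(unique(locus_key(controls$chrom, controls$pos, controls$ref,
                                controls$alt)))
  structure(keys, class = "cfhl_pon")
}

#' Merge per-caller calls into consensus variants
#'
#' Union merge over callers per sample: one record per distinct
#' (chrom, pos, ref, alt). The consensus VAF is the median across
#' supporting callers (robust to a single outlier caller); the consensus
#' depth is the maximum read depth with its paired alt depth; base
#' quality is the median. Supporting caller identities are retained for
#' the MNV-overlap rule and the optional `min_callers` threshold.
#'
#' @param calls caller-variant tibble (one or more samples).
#' @return consensus tibble with one row per sample x locus, initialized
#'   with `filter_status = "PASS"` and an empty `rule_trace`.
#' @export
consensus_merge <- function(calls) {
  if (nrow(calls) == 0) {
    out <- tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), n_callers = integer(),
      callers = character(), vaf = numeric(), read_depth = integer(),
      alt_depth = integer(), base_quality = numeric()
    )
  } else {
    out <- calls |>
      group_by(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(
        n_callers = dplyr::n_distinct(.data$caller_id),
        callers = paste(sort(unique(.data$caller_id)), collapse = ";"),
        vaf = median(.data$vaf),
        alt_depth = .data$alt_depth[order(-.data$read_depth, -.data$alt_depth,
                                          .data$caller_id)][1],
        read_depth = max(.data$read_depth),
        base_quality = median(.data$base_quality),
        .groups = "drop"
      ) |>
      select("sample_id", "chrom", "pos", "ref", "alt", "n_callers",
             "callers", "vaf", "read_depth", "alt_depth", "base_quality")
  }
  out |>
    bind_cols(classify_alleles(out$ref, out$alt)) |>
    mutate(filter_status = "PASS", rule_trace = "") |>
    arrange(.data$sample_id, .data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Attach annotations to consensus variants
#'
#' Left-joins the annotation sidecar by exact variant key. Variants
#' absent from the sidecar get `NA` gene/effect and unlisted (NA)
#' population frequencies; `cosmic` defaults to `FALSE`.
#'
#' @param variants consensus tibble from [consensus_merge()].
#' @param annotations annotation tibble (see [read_annotation_tsv()]).
#' @return annotated consensus tibble.
#' @export
annotate_variants <- function(variants, annotations) {
  ann <- annotations |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .keep_all = TRUE) |>
    select("chrom", "pos", "ref", "alt", "gene", "effect_class",
           "gnomad_af", "kg_af", "cosmic")
  variants |>
    left_join(ann, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(cosmic = ifelse(is.na(.data$cosmic), FALSE, .data$cosmic))
}

# rule engine: evaluate named rules in order on still-PASS rows, record the
# trace and stamp the first failing rule into filter_status
apply_rules <- function(variants, rules) {
  for (rn in names(rules)) {
    active <- variants$filter_status == "PASS"
    if (!any(active)) break
    fail <- rules[[rn]](variants)
    fail[is.na(fail)] <- FALSE
    variants$rule_trace[active] <- ifelse(
      nzchar(variants$rule_trace[active]),
      paste(variants$rule_trace[active], rn, sep = ";"), rn)
    variants$filter_status[active & fail] <- rn
  }
  variants
}

#' Primary per-variant thresholds
#'
#' Fails a variant unless read depth > 100, VAF > 1%, mutant read depth
#' > 7 and base quality > 25 (all strict). When `min_callers` exceeds 1,
#' a caller-support rule is evaluated first.
#'
#' @param variants annotated consensus tibble.
#' @param config a [filter_config()].
#' @return tibble with `filter_status`/`rule_trace` updated.
#' @export
apply_primary_thresholds <- function(variants, config = filter_config()) {
  rules <- list()
  if (config$min_callers > 1) {
    rules$min_callers <- function(v) v$n_callers < config$min_callers
  }
  rules$depth <- function(v) !(v$read_depth > config$min_depth)
  rules$vaf <- function(v) !(v$vaf > config$min_vaf)
  rules$alt_depth <- function(v) !(v$alt_depth > config$min_alt_depth)
  rules$base_quality <- function(v) !(v$base_quality > config$min_base_quality)
  apply_rules(variants, rules)
}

#' Panel-of-normals and MNV-overlap removal
#'
#' Removes variants whose exact key is present in the panel of normals,
#' and SNVs whose position lies within the reference span (closed
#' interval) of a multi-nucleotide variant reported by a different caller
#' in the same sample.
#'
#' @param variants annotated consensus tibble.
#' @param pon panel of normals from [build_pon()].
#' @param calls the raw caller-variant tibble the consensus was built
#'   from (source of per-caller MNV spans); may be omitted to skip the
#'   MNV-overlap rule.
#' @param config a [filter_config()].
#' @return updated consensus tibble.
#' @export
remove_pon_and_mnv_overlaps <- function(variants, pon, calls = NULL,
                                        config = filter_config()) {
  mnv_flag <- rep(FALSE, nrow(variants))
  if (!is.null(calls) && nrow(calls) > 0) {
    cls <- classify_alleles(calls$ref, calls$alt, config$mnv_max_len)
    spans <- calls |>
      mutate(variant_class = cls$variant_class) |>
      filter(.data$variant_class == "MNV") |>
      transmute(sample_id = .data$sample_id, caller_id = .data$caller_id,
                chrom = .data$chrom, span_start = .data$pos,
                span_end = .data$pos + nchar(.data$ref) - 1L)
    if (nrow(spans) > 0) {
      snv_idx <- which(variants$variant_class == "SNV")
      for (i in snv_idx) {
        sup <- strsplit(variants$callers[i], ";")[[1]]
        hit <- spans$sample_id == variants$sample_id[i] &
          spans$chrom == variants$chrom[i] &
          spans$span_start <= variants$pos[i] &
          spans$span_end >= variants$pos[i] &
          !(spans$caller_id %in% sup)
        mnv_flag[i] <- any(hit)
      }
    }
  }
  pon_keys <- unclass(pon)
  rules <- list(
    pon = function(v) locus_key(v$chrom, v$pos, v$ref, v$alt) %in% pon_keys,
    mnv_overlap = function(v) mnv_flag
  )
  apply_rules(variants, rules)
}

#' Functional-effect and population-frequency filters
#'
#' Removes variants without predicted functional effect (synonymous,
#' 5'/3' UTR, intronic, 2 kb flanking), variants with gnomAD or 1000
#' Genomes allele fraction above 0.001, and high-VAF variants
#' (VAF > 0.20) that are listed with any allele frequency in either
#' database (a listed frequency of 0 still counts as listed; an absent
#' entry does not).
#'
#' @inheritParams apply_primary_thresholds
#' @return updated consensus tibble.
#' @export
apply_annotation_filters <- function(variants, config = filter_config()) {
  no_effect <- c("synonymous", "utr5", "utr3", "intronic", "flanking_2kb")
  rules <- list()
  if (config$apply_effect_filter) {
    rules$effect <- function(v) v$effect_class %in% no_effect
  }
  rules$population_af <- function(v) {
    (!is.na(v$gnomad_af) & v$gnomad_af > config$max_pop_af) |
      (!is.na(v$kg_af) & v$kg_af > config$max_pop_af)
  }
  rules$high_vaf_listed <- function(v) {
    v$vaf > config$high_vaf & (!is.na(v$gnomad_af) | !is.na(v$kg_af))
  }
  apply_rules(variants, rules)
}

#' InDel length and GC-content rules
#'
#' InDels longer than 20 bp are removed regardless of composition; InDels
#' longer than 10 bp with GC content above 60% are removed. Equal-length
#' variants below 20 bases were already reclassified as MNVs at
#' consensus time and bypass these rules.
#'
#' @inheritParams apply_primary_thresholds
#' @return updated consensus tibble.
#' @export
apply_indel_mnv_rules <- function(variants, config = filter_config()) {
  rules <- list(
    indel_length = function(v) {
      v$variant_class == "InDel" & v$indel_length > config$indel_max_len
    },
    indel_gc = function(v) {
      v$variant_class == "InDel" & v$indel_length > config$indel_gc_min_len &
        !is.na(v$gc_content) & v$gc_content > config$indel_gc_max
    }
  )
  apply_rules(variants, rules)
}

#' Cohort-level COSMIC recurrence filter
#'
#' Non-unique mutations in baseline (pre-treatment) samples that are not
#' present in COSMIC are treated as residual artifacts and removed from
#' every sample carrying them. "Non-unique" defaults to the identical
#' variant occurring in the baselines of at least two distinct patients.
#'
#' @param variants annotated consensus tibble covering the whole cohort.
#' @param config a [filter_config()].
#' @param baseline_samples sample ids considered baseline; defaults to
#'   all samples in `variants`.
#' @param patients optional tibble `sample_id`, `patient_id`; defaults to
#'   one patient per sample.
#' @return updated consensus tibble.
#' @export
apply_cosmic_recurrence_filter <- function(variants, config = filter_config(),
                                           baseline_samples = NULL,
                                           patients = NULL) {
  if (is.null(baseline_samples)) baseline_samples <- unique(variants$sample_id)
  if (is.null(patients)) {
    patients <- tibble(sample_id = unique(variants$sample_id),
                       patient_id = unique(variants$sample_id))
  }
  base <- variants |>
    filter(.data$filter_status == "PASS",
           .data$sample_id %in% baseline_samples) |>
    left_join(patients, by = "sample_id") |>
    mutate(key = locus_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  counts <- if (config$recurrence_scope == "cross_patient") {
    base |> group_by(.data$key) |>
      summarise(n_units = dplyr::n_distinct(.data$patient_id),
                cosmic = any(.data$cosmic), .groups = "drop")
  } else {
    base |> group_by(.data$key) |>
      summarise(n_units = dplyr::n_distinct(.data$sample_id),
                cosmic = any(.data$cosmic), .groups = "drop")
  }
  bad <- counts$key[counts$n_units >= 2 & !counts$cosmic]
  rules <- list(
    cosmic_recurrence = function(v) {
      locus_key(v$chrom, v$pos, v$ref, v$alt) %in% bad
    }
  )
  apply_rules(variants, rules)
}

#' Run the complete filter cascade
#'
#' Composes, in order: consensus merge, primary thresholds (depth, VAF,
#' mutant reads, base quality), panel-of-normals removal, MNV-overlap
#' removal, functional-effect and population-frequency filters, InDel
#' rules, and the cohort-level COSMIC recurrence filter. Every input
#' locus ends up exactly once in the output, either as `PASS` or stamped
#' with the first rule that removed it, with the full ordered trace of
#' rules evaluated.
#'
#' @param calls caller-variant tibble (one or several samples).
#' @param pon panel of normals from [build_pon()].
#' @param annotations annotation sidecar tibble.
#' @param config a [filter_config()].
#' @param baseline_samples,patients passed to
#'   [apply_cosmic_recurrence_filter()].
#' @return list of class `cfhl_filter_result` with elements `variants`
#'   (full audited table), `pass` (PASS rows only) and `audit`
#'   (per-rule removal counts).
#' @export
run_cascade <- function(calls, pon, annotations, config = filter_config(),
                        baseline_samples = NULL, patients = NULL) {
  variants <- consensus_merge(calls) |>
    annotate_variants(annotations) |>
    apply_primary_thresholds(config) |>
    remove_pon_and_mnv_overlaps(pon, calls = calls, config = config) |>
    apply_annotation_filters(config) |>
    apply_indel_mnv_rules(config) |>
    apply_cosmic_recurrence_filter(config, baseline_samples = baseline_samples,
                                   patients = patients)
  audit <- variants |>
    filter(.data$filter_status != "PASS") |>
    count(rule = .data$filter_status, name = "removed") |>
    arrange(.data$rule)
  structure(list(
    variants = variants,
    pass = variants |> filter(.data$filter_status == "PASS"),
    audit = audit
  ), class = "cfhl_filter_result")
}
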