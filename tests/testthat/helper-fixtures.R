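# Builders for caller-level variant records, annotation rows and fuzzed
# filter instances, plus an independent base-R re-implementation of the
# whole filter cascade used as an oracle. The oracle deliberately shares
# no code with the package: consensus and every rule are recomputed with
# split/tapply and one monolithic predicate.

cv <- function(sample_id = "S1", caller_id = "mutect2", chrom = "chr1",
               pos = 1000L, ref = "A", alt = "T", read_depth = 1500L,
               alt_depth = 60L, base_quality = 34) {
  tibble::tibble(
    sample_id = sample_id, caller_id = caller_id, chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt,
    read_depth = as.integer(read_depth), alt_depth = as.integer(alt_depth),
    vaf = alt_depth / read_depth, base_quality = base_quality
  )
}

ann_row <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                    gene = "KMT2D", effect_class = "coding_nonsynonymous",
                    gnomad_af = NA_real_, kg_af = NA_real_, cosmic = FALSE) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 gene = gene, effect_class = effect_class,
                 gnomad_af = gnomad_af, kg_af = kg_af, cosmic = cosmic)
}

empty_ann <- function() ann_row()[0, ]

# small cohort configuration used where full scale is not the point
tiny_sim_config <- function(seed = 7, ...) {
  simulation_config(
    n_patients = 8, n_controls = 3, seed = seed,
    germline_rate = 5, germline_pool_size = 80,
    artifact_pool_size = 12, artifact_rate = 1.5,
    n_tracking = 2, ...
  )
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# fuzzed multi-sample, multi-caller instance with annotations and a PoN;
# positions are packed densely so MNV overlaps actually occur
random_filter_instance <- function(n_loci = 120, n_samples = 3, seed = 1) {
  set.seed(seed)
  callers <- c("mutect2", "lofreq", "sinvict", "vardict")
  rows <- list()
  ann <- list()
  loci_keys <- character(0)
  for (s in seq_len(n_samples)) {
    sid <- sprintf("S%d", s)
    for (i in seq_len(n_loci)) {
      chrom <- sample(c("chr1", "chr2"), 1)
      pos <- sample.int(400, 1)
      type <- sample(c("snv", "mnv", "indel"), 1, prob = c(0.6, 0.2, 0.2))
      if (type == "snv") {
        ref <- random_seq(1); alt <- random_seq(1)
        while (alt == ref) alt <- random_seq(1)
      } else if (type == "mnv") {
        len <- sample(2:4, 1)
        ref <- random_seq(len); alt <- random_seq(len)
        while (alt == ref) alt <- random_seq(len)
      } else {
        d <- sample(1:24, 1)
        anchor <- random_seq(1)
        if (runif(1) < 0.5) {
          ref <- anchor; alt <- paste0(anchor, random_seq(d))
        } else {
          ref <- paste0(anchor, random_seq(d)); alt <- anchor
        }
      }
      sup <- sample(callers, sample.int(4, 1))
      depth <- sample(60:400, length(sup), replace = TRUE)
      altd <- pmin(depth, 1L + rpois(length(sup), depth * runif(1, 0.002, 0.3)))
      for (j in seq_along(sup)) {
        rows[[length(rows) + 1]] <- cv(
          sample_id = sid, caller_id = sup[j], chrom = chrom, pos = pos,
          ref = ref, alt = alt, read_depth = depth[j], alt_depth = altd[j],
          base_quality = round(runif(1, 20, 36), 1)
        )
      }
      key <- paste(chrom, pos, ref, alt, sep = ":")
      if (!(key %in% loci_keys) && runif(1) < 0.8) {
        loci_keys <- c(loci_keys, key)
        ann[[length(ann) + 1]] <- ann_row(
          chrom = chrom, pos = pos, ref = ref, alt = alt,
          gene = sample(c("SOCS1", "KMT2D", "B2M", "GNA13"), 1),
          effect_class = sample(
            c("coding_nonsynonymous", "synonymous", "utr5", "utr3",
              "intronic", "flanking_2kb", "other_functional"), 1),
          gnomad_af = if (runif(1) < 0.4) 10^runif(1, -5, -1) else NA_real_,
          kg_af = if (runif(1) < 0.3) 10^runif(1, -5, -1) else NA_real_,
          cosmic = runif(1) < 0.3
        )
      }
    }
  }
  calls <- dplyr::bind_rows(rows)
  keys <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"))
  pon_keys <- sample(keys, max(1, round(length(keys) * 0.1)))
  list(calls = calls, annotations = dplyr::bind_rows(ann),
       pon = structure(sort(pon_keys), class = "cfhl_pon"))
}

# ---- independent oracle ----------------------------------------------------

oracle_classify <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1 && la == 1) return("SNV")
  if (lr == la && max(lr, la) < 20) return("MNV")
  "InDel"
}

oracle_indel_gc <- function(ref, alt) {
  n <- min(nchar(ref), nchar(alt)); k <- 0
  while (k < n && substr(ref, k + 1, k + 1) == substr(alt, k + 1, k + 1)) {
    k <- k + 1
  }
  longer <- if (nchar(ref) >= nchar(alt)) ref else alt
  s <- substr(longer, k + 1, nchar(longer))
  if (!nzchar(s)) return(NA_real_)
  b <- strsplit(s, "")[[1]]
  mean(b %in% c("G", "C"))
}

# full-cascade oracle: returns data.frame with sample_id, key and the name of
# the first failing rule ("PASS" if none), computed monolithically
oracle_cascade <- function(calls, pon, annotations, baseline_samples = NULL,
                           patients = NULL) {
  pon_keys <- unclass(pon)
  key_of <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  calls$key <- key_of(calls)
  grp <- split(calls, paste(calls$sample_id, calls$key, sep = "|"))
  cons <- do.call(rbind, lapply(grp, function(g) {
    ord <- order(-g$read_depth, -g$alt_depth, g$caller_id)
    data.frame(
      sample_id = g$sample_id[1], chrom = g$chrom[1], pos = g$pos[1],
      ref = g$ref[1], alt = g$alt[1], key = g$key[1],
      vaf = median(g$vaf), read_depth = max(g$read_depth),
      alt_depth = g$alt_depth[ord[1]], base_quality = median(g$base_quality),
      callers = paste(sort(unique(g$caller_id)), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cons) <- NULL
  ann <- annotations[!duplicated(paste(annotations$chrom, annotations$pos,
                                       annotations$ref, annotations$alt)), ]
  ann$key <- key_of(ann)
  m <- match(cons$key, ann$key)
  cons$effect_class <- ann$effect_class[m]
  cons$gnomad_af <- ann$gnomad_af[m]
  cons$kg_af <- ann$kg_af[m]
  cons$cosmic <- ifelse(is.na(ann$cosmic[m]), FALSE, ann$cosmic[m])

  cls <- vapply(seq_len(nrow(cons)),
                function(i) oracle_classify(cons$ref[i], cons$alt[i]),
                character(1))
  mnv_rows <- calls[vapply(seq_len(nrow(calls)), function(i) {
    oracle_classify(calls$ref[i], calls$alt[i]) == "MNV"
  }, logical(1)), ]

  first_fail <- character(nrow(cons))
  for (i in seq_len(nrow(cons))) {
    v <- cons[i, ]
    rule <- "PASS"
    no_eff <- c("synonymous", "utr5", "utr3", "intronic", "flanking_2kb")
    ilen <- abs(nchar(v$ref) - nchar(v$alt))
    gc <- if (cls[i] == "InDel" && ilen > 0) oracle_indel_gc(v$ref, v$alt) else NA
    sup <- strsplit(v$callers, ";")[[1]]
    mnv_hit <- FALSE
    if (cls[i] == "SNV" && nrow(mnv_rows) > 0) {
      for (j in seq_len(nrow(mnv_rows))) {
        mr <- mnv_rows[j, ]
        if (mr$sample_id == v$sample_id && mr$chrom == v$chrom &&
            v$pos >= mr$pos && v$pos <= mr$pos + nchar(mr$ref) - 1 &&
            !(mr$caller_id %in% sup)) {
          mnv_hit <- TRUE
          break
        }
      }
    }
    if (!(v$read_depth > 100)) rule <- "depth"
    else if (!(v$vaf > 0.01)) rule <- "vaf"
    else if (!(v$alt_depth > 7)) rule <- "alt_depth"
    else if (!(v$base_quality > 25)) rule <- "base_quality"
    else if (v$key %in% pon_keys) rule <- "pon"
    else if (mnv_hit) rule <- "mnv_overlap"
    else if (!is.na(v$effect_class) && v$effect_class %in% no_eff) rule <- "effect"
    else if ((!is.na(v$gnomad_af) && v$gnomad_af > 0.001) ||
             (!is.na(v$kg_af) && v$kg_af > 0.001)) rule <- "population_af"
    else if (v$vaf > 0.20 && (!is.na(v$gnomad_af) || !is.na(v$kg_af))) {
      rule <- "high_vaf_listed"
    } else if (cls[i] == "InDel" && ilen > 20) rule <- "indel_length"
    else if (cls[i] == "InDel" && ilen > 10 && !is.na(gc) && gc > 0.60) {
      rule <- "indel_gc"
    }
    first_fail[i] <- rule
  }
  # cohort-level COSMIC recurrence on per-variant survivors
  if (is.null(baseline_samples)) baseline_samples <- unique(cons$sample_id)
  if (is.null(patients)) {
    patients <- data.frame(sample_id = unique(cons$sample_id),
                           patient_id = unique(cons$sample_id))
  }
  surv <- cons[first_fail == "PASS" & cons$sample_id %in% baseline_samples, ]
  surv$patient_id <- patients$patient_id[match(surv$sample_id,
                                               patients$sample_id)]
  bad <- character(0)
  for (k in unique(surv$key)) {
    rows <- surv[surv$key == k, ]
    if (length(unique(rows$patient_id)) >= 2 && !any(rows$cosmic)) {
      bad <- c(bad, k)
    }
  }
  first_fail[first_fail == "PASS" & cons$key %in% bad] <- "cosmic_recurrence"
  data.frame(sample_id = cons$sample_id, key = cons$key,
             status = first_fail, stringsAsFactors = FALSE)
}
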