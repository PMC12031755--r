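#' Expected log2 ratio of a copy-number state in an impure sample
#'
#' Forward model for bin-level copy-number signal in cfDNA: the observed
#' coverage ratio is a mixture of tumor cells at integer copy number `cn`
#' and normal diploid cells, so the expected log2 ratio is
#' `log2((tf * cn + (1 - tf) * 2) / 2)`.
#'
#' @param cn integer copy number in `0..max_cn`.
#' @param tf tumor fraction in `[0, 1]` (fraction of cfDNA that is
#'   tumor-derived).
#' @param max_cn maximum copy-number state considered (default 4, which
#'   focuses on the low-level alterations typical of Hodgkin lymphoma).
#' @return expected log2 ratio; 0 whenever `cn == 2`.
#' @examples
#' expected_log2(3, 1)    # log2(1.5)
#' expected_log2(2, 0.5)  # 0
#' @export
expected_log2 <- function(cn, tf, max_cn = 4) {
  if (any(is.na(cn)) || any(cn < 0) || any(cn > max_cn) || any(cn != floor(cn))) {
    abort(sprintf("`cn` must be an integer in 0..%d", max_cn))
  }
  if (any(is.na(tf)) || any(tf < 0) || any(tf > 1)) {
    abort("`tf` must be in [0, 1]")
  }
  log2((tf * cn + (1 - tf) * 2) / 2)
}

#' Default 72-gene lymphoma panel on a miniature genome
#'
#' Genes commonly (hyper)mutated in B-cell lymphoma, laid out on a
#' desk-scale genome of 3 chromosomes x 100 Mb so that coordinates stay
#' valid BED/VCF without hg38-scale data. Interval widths sum to roughly
#' 244 kb. `weight` is the relative somatic mutation propensity used by
#' the cohort simulator; SOCS1 is handled separately because it defines
#' the clusters.
#'
#' @return a tibble with columns `gene`, `chrom`, `start`, `end` (0-based
#'   half-open) and `weight`.
#' @export
default_gene_panel <- function() {
  genes <- c(
    "SOCS1", "KMT2D", "TNFAIP3", "IGLL5", "GNA13", "CREBBP", "ARID1A",
    "CSF2RB", "STAT6", "B2M", "BCL7A", "NOTCH2", "ITPKB", "XPO1", "STAT3",
    "PTPN1", "SPEN", "TET2", "EP300", "NFKBIA", "NFKBIE", "REL", "CARD11",
    "MYC", "PIM1", "CIITA", "CD58", "CD79B", "MYD88", "EZH2", "BTG1",
    "BTG2", "DUSP2", "SGK1", "TP53", "ATM", "BCL2", "BCL6", "IRF4", "IRF8",
    "PRDM1", "FOXO1", "GNAI2", "ACTB", "HIST1H1E", "POU2F2", "ZNF217",
    "STAT5B", "JAK1", "JAK2", "PTPN6", "TRAF3", "BIRC3", "CXCR4", "ID3",
    "TCF3", "CCND3", "FAS", "PCBP1", "SF3B1", "NOTCH1", "MEF2B", "KLHL6",
    "BRAF", "KRAS", "NRAS", "EGR1", "ETS1", "ETV6", "IKZF3", "RYBP", "HLA-B"
  )
  stopifnot(length(genes) == 72L)
  # approximate per-gene mutated-sample frequencies seen in cHL cfDNA panels
  w <- c(
    SOCS1 = 0.52, KMT2D = 0.36, TNFAIP3 = 0.31, IGLL5 = 0.26, GNA13 = 0.24,
    CREBBP = 0.21, ARID1A = 0.19, CSF2RB = 0.19, STAT6 = 0.19, B2M = 0.17,
    BCL7A = 0.17, NOTCH2 = 0.14, ITPKB = 0.12, XPO1 = 0.10, STAT3 = 0.10
  )
  weight <- ifelse(genes %in% names(w), w[genes], 0.05)
  idx <- seq_along(genes) - 1L
  tibble(
    gene = genes,
    chrom = paste0("chr", idx %% 3L + 1L),
    start = 2e6 + (idx %/% 3L) * 4e6,
    end = 2e6 + (idx %/% 3L) * 4e6 + 3400,
    weight = unname(weight)
  )
}

#' Configuration for the synthetic cfDNA cohort generator
#'
#' Encodes the cohort-level conditions the pipeline is designed for:
#' 44 patients and 7 panel-of-normals controls, three supervised clusters
#' defined by EBV status and SOCS1 mutation, per-cluster somatic SNV-load
#' and tumor-fraction distributions calibrated so that the cohort median
#' somatic count is about 7 and per-patient median VAFs span roughly
#' 1-14%, four emulated variant callers with logistic VAF sensitivity,
#' germline SNPs at population frequency, recurrent and sporadic
#' sequencing artifacts, 1,000 kbp copy-number bins, and longitudinal
#' tumor-fraction decay for responders versus refractory patients.
#'
#' @param n_patients number of patients (default 44).
#' @param n_controls number of control plasma samples used to build the
#'   panel of normals (default 7).
#' @param seed integer seed; identical configurations and seeds reproduce
#'   byte-identical output bundles.
#' @param cluster_proportions named 3-vector of probabilities over
#'   `EBV_pos_SOCS1m`, `EBV_neg_SOCS1m`, `EBV_neg_SOCS1wt`; must sum to 1.
#' @param prop_ebv_pos_socs1wt optional probability of the EBV+ & SOCS1
#'   wild-type combination, not produced by default (it was not observed);
#'   when positive it is carved out of the other proportions for
#'   robustness testing.
#' @param gene_panel tibble as returned by [default_gene_panel()].
#' @param snv_load named list per cluster of `c(mu =, size =)` negative
#'   binomial parameters for the somatic variant count.
#' @param tumor_fraction named list per cluster of `c(meanlog =, sdlog =)`
#'   log-normal parameters for the baseline tumor fraction.
#' @param no_ctdna_rate probability a patient has no detectable ctDNA
#'   (tumor fraction 0, no somatic variants, no copy-number signal).
#' @param ebv_unknown_rate probability EBV status is not determined.
#' @param artifact_rate expected sporadic (non-recurrent) artifact
#'   variants per sample.
#' @param artifact_pool_size,artifact_pool_prob size of the recurrent
#'   artifact locus pool shared by all samples (including controls) and
#'   the per-sample probability of each pool locus appearing.
#' @param germline_rate expected germline SNPs per sample, drawn from a
#'   shared population pool with realistic allele frequencies.
#' @param germline_pool_size size of the population SNP pool.
#' @param caller_sensitivity tibble with columns `caller`, `midpoint`,
#'   `scale`, `max_sens`: each caller detects a variant with probability
#'   `max_sens * plogis((vaf - midpoint) / scale)`.
#' @param depth_mean,depth_size negative binomial parameters for on-target
#'   read depth per locus.
#' @param n_chrom,chrom_len,bin_size miniature genome geometry; defaults
#'   give 3 x 100 bins of 1,000 kbp.
#' @param bin_noise_sd Gaussian noise s.d. added to bin log2 ratios.
#' @param n_tracking number of patients with longitudinal samples.
#' @param n_timepoints number of timepoints per tracked patient (>= 2).
#' @param longitudinal_decay named vector `c(responder =, refractory =)`
#'   of per-timepoint multiplicative tumor-fraction factors.
#' @param prop_refractory fraction of tracked patients that are
#'   refractory (slow decay) rather than responders.
#' @param starc_elevated sTARC elevation threshold in pg/mL (1,000).
#' @param variant_type_probs named probabilities for `snv`, `mnv`, `indel`
#'   somatic variant classes.
#' @return an object of class `cfhl_sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(
    n_patients = 44,
    n_controls = 7,
    seed = 1,
    cluster_proportions = c(
      EBV_pos_SOCS1m = 0.20, EBV_neg_SOCS1m = 0.35, EBV_neg_SOCS1wt = 0.45
    ),
    prop_ebv_pos_socs1wt = 0,
    gene_panel = default_gene_panel(),
    snv_load = list(
      EBV_pos_SOCS1m = c(mu = 9, size = 4),
      EBV_neg_SOCS1m = c(mu = 16, size = 4),
      EBV_neg_SOCS1wt = c(mu = 6, size = 3)
    ),
    tumor_fraction = list(
      EBV_pos_SOCS1m = c(meanlog = log(0.07), sdlog = 0.5),
      EBV_neg_SOCS1m = c(meanlog = log(0.12), sdlog = 0.5),
      EBV_neg_SOCS1wt = c(meanlog = log(0.045), sdlog = 0.5)
    ),
    no_ctdna_rate = 0.09,
    ebv_unknown_rate = 0.02,
    artifact_rate = 3,
    artifact_pool_size = 40,
    artifact_pool_prob = 0.25,
    germline_rate = 12,
    germline_pool_size = 300,
    caller_sensitivity = tibble(
      caller = c("mutect2", "lofreq", "sinvict", "vardict"),
      midpoint = c(0.006, 0.010, 0.013, 0.008),
      scale = c(0.002, 0.003, 0.004, 0.0025),
      max_sens = c(0.98, 0.95, 0.90, 0.96)
    ),
    depth_mean = 1500,
    depth_size = 8,
    n_chrom = 3,
    chrom_len = 1e8,
    bin_size = 1e6,
    bin_noise_sd = 0.02,
    n_tracking = 6,
    n_timepoints = 3,
    longitudinal_decay = c(responder = 0.1, refractory = 0.75),
    prop_refractory = 0.5,
    starc_elevated = 1000,
    variant_type_probs = c(snv = 0.88, mnv = 0.05, indel = 0.07)) {
  cfg <- list(
    n_patients = n_patients, n_controls = n_controls, seed = seed,
    cluster_proportions = cluster_proportions,
    prop_ebv_pos_socs1wt = prop_ebv_pos_socs1wt,
    gene_panel = gene_panel, snv_load = snv_load,
    tumor_fraction = tumor_fraction, no_ctdna_rate = no_ctdna_rate,
    ebv_unknown_rate = ebv_unknown_rate, artifact_rate = artifact_rate,
    artifact_pool_size = artifact_pool_size,
    artifact_pool_prob = artifact_pool_prob,
    germline_rate = germline_rate, germline_pool_size = germline_pool_size,
    caller_sensitivity = caller_sensitivity,
    depth_mean = depth_mean, depth_size = depth_size,
    n_chrom = n_chrom, chrom_len = chrom_len, bin_size = bin_size,
    bin_noise_sd = bin_noise_sd, n_tracking = n_tracking,
    n_timepoints = n_timepoints, longitudinal_decay = longitudinal_decay,
    prop_refractory = prop_refractory, starc_elevated = starc_elevated,
    variant_type_probs = variant_type_probs
  )
  class(cfg) <- "cfhl_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 0) {
    stop_field("n_patients", "must be a non-negative count")
  }
  if (!is.numeric(cfg$n_controls) || cfg$n_controls < 1) {
    stop_field("n_controls", "must be >= 1")
  }
  cp <- cfg$cluster_proportions
  if (length(cp) != 3 || any(cp < 0) || abs(sum(cp) - 1) > 1e-8) {
    stop_field("cluster_proportions", "must be 3 non-negative values summing to 1")
  }
  need <- c("EBV_pos_SOCS1m", "EBV_neg_SOCS1m", "EBV_neg_SOCS1wt")
  if (!all(need %in% names(cp))) {
    stop_field("cluster_proportions", paste("must be named", paste(need, collapse = ", ")))
  }
  for (f in c("no_ctdna_rate", "ebv_unknown_rate", "artifact_pool_prob",
              "prop_refractory", "prop_ebv_pos_socs1wt")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_field(f, "must be in [0, 1]")
  }
  for (f in c("artifact_rate", "germline_rate")) {
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  }
  if (cfg$n_timepoints < 2) stop_field("n_timepoints", "must be >= 2")
  if (any(cfg$longitudinal_decay <= 0)) {
    stop_field("longitudinal_decay", "factors must be > 0")
  }
  gp <- cfg$gene_panel
  if (!all(c("gene", "chrom", "start", "end", "weight") %in% names(gp))) {
    stop_field("gene_panel", "needs columns gene, chrom, start, end, weight")
  }
  invisible(cfg)
}

cluster_levels <- function() {
  c("EBV_pos_SOCS1m", "EBV_neg_SOCS1m", "EBV_neg_SOCS1wt",
    "EBV_pos_SOCS1wt", "unassigned")
}

# random DNA helpers ---------------------------------------------------------

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

# one somatic/germline/artifact locus with alleles of the requested class
random_alleles <- function(type) {
  if (type == "snv") {
    ref <- rand_bases(1)
    list(ref = ref, alt = mutate_base(ref))
  } else if (type == "mnv") {
    len <- sample(2:3, 1)
    ref <- rand_bases(len)
    alt <- paste(vapply(strsplit(ref, "")[[1]], mutate_base, character(1)),
                 collapse = "")
    list(ref = ref, alt = alt)
  } else {
    d <- 1 + rpois(1, 2) # indel length
    anchor <- rand_bases(1)
    if (runif(1) < 0.5) {
      list(ref = anchor, alt = paste0(anchor, rand_bases(d)))
    } else {
      list(ref = paste0(anchor, rand_bases(d)), alt = anchor)
    }
  }
}

# sample a locus inside a panel gene; somatic draws are weighted by
# mutation propensity, while germline/artifact draws (`uniform = TRUE`)
# ignore the driver weights — SNPs and technical noise have no reason to
# favor lymphoma drivers
sample_gene_locus <- function(panel, n, exclude_socs1 = FALSE,
                              force_gene = NULL, uniform = FALSE) {
  if (n == 0) {
    return(tibble(gene = character(), chrom = character(), pos = integer()))
  }
  if (!is.null(force_gene)) {
    rows <- panel[rep(match(force_gene, panel$gene), n), ]
  } else {
    p <- panel
    if (exclude_socs1) p <- p[p$gene != "SOCS1", ]
    w <- if (uniform) rep(1, nrow(p)) else p$weight
    rows <- p[sample.int(nrow(p), n, replace = TRUE, prob = w), ]
  }
  tibble(
    gene = rows$gene,
    chrom = rows$chrom,
    pos = as.integer(rows$start + floor(runif(n) * (rows$end - rows$start)) + 1L)
  )
}

effect_levels <- function() {
  c("coding_nonsynonymous", "synonymous", "utr5", "utr3", "intronic",
    "flanking_2kb", "other_functional")
}

# shared population pools: germline SNPs and recurrent artifacts -------------

build_population_pools <- function(cfg) {
  gl <- sample_gene_locus(cfg$gene_panel, cfg$germline_pool_size,
                          uniform = TRUE)
  gl_alleles <- lapply(seq_len(nrow(gl)), function(i) random_alleles("snv"))
  germline <- gl |>
    mutate(
      ref = vapply(gl_alleles, `[[`, character(1), "ref"),
      alt = vapply(gl_alleles, `[[`, character(1), "alt"),
      af = pmin(0.5, pmax(0.002, rlnorm(dplyr::n(), log(0.05), 1))),
      effect_class = sample(effect_levels(), dplyr::n(), replace = TRUE,
                            prob = c(0.25, 0.2, 0.1, 0.1, 0.2, 0.1, 0.05))
    ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  ar <- sample_gene_locus(cfg$gene_panel, cfg$artifact_pool_size,
                          uniform = TRUE)
  ar_alleles <- lapply(seq_len(nrow(ar)), function(i) random_alleles("snv"))
  artifact <- ar |>
    mutate(
      ref = vapply(ar_alleles, `[[`, character(1), "ref"),
      alt = vapply(ar_alleles, `[[`, character(1), "alt"),
      vaf_meanlog = log(pmin(0.08, rlnorm(dplyr::n(), log(0.015), 0.4)))
    ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
  list(germline = germline, artifact = artifact)
}

# per-sample truth-variant tables --------------------------------------------

draw_germline <- function(cfg, pools) {
  k <- min(rpois(1, cfg$germline_rate), nrow(pools$germline))
  if (k == 0) {
    g <- pools$germline[0, ]
    g$true_vaf <- numeric(0)
    return(g)
  }
  idx <- sample.int(nrow(pools$germline), k, prob = pools$germline$af)
  g <- pools$germline[idx, ]
  hom <- runif(k) < 0.1
  g$true_vaf <- ifelse(hom, pmin(1, rnorm(k, 0.97, 0.02)),
                       pmin(0.7, pmax(0.3, rnorm(k, 0.5, 0.03))))
  g
}

draw_artifacts <- function(cfg, pools) {
  keep <- runif(nrow(pools$artifact)) < cfg$artifact_pool_prob
  rec <- pools$artifact[keep, ]
  if (nrow(rec) > 0) {
    rec$true_vaf <- pmin(0.2, rlnorm(nrow(rec), rec$vaf_meanlog, 0.3))
  } else {
    rec$true_vaf <- numeric(0)
  }
  rec$recurrent <- rep(TRUE, nrow(rec))
  k <- rpois(1, cfg$artifact_rate)
  spor <- sample_gene_locus(cfg$gene_panel, k, uniform = TRUE)
  if (k > 0) {
    al <- lapply(seq_len(k), function(i) random_alleles("snv"))
    spor$ref <- vapply(al, `[[`, character(1), "ref")
    spor$alt <- vapply(al, `[[`, character(1), "alt")
    spor$true_vaf <- runif(k, 0.002, 0.012)
    spor$recurrent <- FALSE
  } else {
    spor <- spor |> mutate(ref = character(0), alt = character(0),
                           true_vaf = numeric(0), recurrent = logical(0))
  }
  bind_rows(rec |> select("gene", "chrom", "pos", "ref", "alt",
                          "true_vaf", "recurrent"),
            spor)
}

draw_somatic <- function(cfg, cluster, tf) {
  if (tf <= 0) {
    return(tibble(gene = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), true_vaf = numeric(),
                  type = character()))
  }
  socs1_mut <- grepl("SOCS1m$", cluster)
  load_key <- if (cluster %in% names(cfg$snv_load)) cluster else "EBV_neg_SOCS1wt"
  par <- cfg$snv_load[[load_key]]
  n <- rnbinom(1, size = par["size"], mu = par["mu"])
  n_socs1 <- 0L
  if (socs1_mut) {
    n_socs1 <- 1L + rbinom(1, 4, 0.22) # multiple SOCS1 hits are common
    n <- max(n, n_socs1)
  }
  loci <- bind_rows(
    sample_gene_locus(cfg$gene_panel, n_socs1, force_gene = "SOCS1"),
    sample_gene_locus(cfg$gene_panel, n - n_socs1, exclude_socs1 = TRUE)
  )
  if (nrow(loci) == 0) {
    return(tibble(gene = character(), chrom = character(), pos = integer(),
                  ref = character(), alt = character(), true_vaf = numeric(),
                  type = character()))
  }
  type <- sample(names(cfg$variant_type_probs), nrow(loci), replace = TRUE,
                 prob = cfg$variant_type_probs)
  al <- lapply(type, random_alleles)
  loci |>
    mutate(
      ref = vapply(al, `[[`, character(1), "ref"),
      alt = vapply(al, `[[`, character(1), "alt"),
      true_vaf = pmin(0.6, pmax(0.005, tf / 2 * rlnorm(dplyr::n(), 0, 0.35))),
      type = type
    ) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

# caller emulation: logistic detection in VAF + binomial read resampling -----

emit_caller_records <- function(truth_vars, cfg, sample_id) {
  if (nrow(truth_vars) == 0) {
    return(tibble(
      sample_id = character(), caller_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      read_depth = integer(), alt_depth = integer(), vaf = numeric(),
      base_quality = numeric(), truth_row = integer()
    ))
  }
  sens <- cfg$caller_sensitivity
  depth <- pmax(60L, rnbinom(nrow(truth_vars), size = cfg$depth_size,
                             mu = cfg$depth_mean))
  out <- vector("list", nrow(sens))
  for (ci in seq_len(nrow(sens))) {
    p <- sens$max_sens[ci] *
      plogis((truth_vars$true_vaf - sens$midpoint[ci]) / sens$scale[ci])
    detected <- runif(nrow(truth_vars)) < p
    alt_reads <- rbinom(nrow(truth_vars), depth, truth_vars$true_vaf)
    keep <- detected & alt_reads > 0
    out[[ci]] <- tibble(
      sample_id = sample_id,
      caller_id = sens$caller[ci],
      chrom = truth_vars$chrom[keep],
      pos = truth_vars$pos[keep],
      ref = truth_vars$ref[keep],
      alt = truth_vars$alt[keep],
      read_depth = depth[keep],
      alt_depth = alt_reads[keep],
      vaf = alt_reads[keep] / depth[keep],
      base_quality = round(truth_vars$bq[keep] + rnorm(sum(keep), 0, 0.5), 1),
      truth_row = which(keep)
    )
  }
  bind_rows(out)
}

# copy-number truth and bin tables -------------------------------------------

make_bin_grid <- function(cfg) {
  per_chrom <- as.integer(cfg$chrom_len / cfg$bin_size)
  tidyr::expand_grid(chrom = paste0("chr", seq_len(cfg$n_chrom)),
                     bin = seq_len(per_chrom)) |>
    mutate(start = (.data$bin - 1) * cfg$bin_size,
           end = .data$bin * cfg$bin_size) |>
    select("chrom", "start", "end")
}

plant_segments <- function(cfg, tf) {
  grid <- make_bin_grid(cfg)
  if (tf <= 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  cn = integer()))
  }
  per_chrom <- as.integer(cfg$chrom_len / cfg$bin_size)
  n_seg <- 1 + rpois(1, 2)
  segs <- list()
  occupied <- list()
  for (i in seq_len(n_seg)) {
    for (try in 1:20) {
      chrom <- paste0("chr", sample.int(cfg$n_chrom, 1))
      len <- sample(3:15, 1)
      first <- sample.int(per_chrom - len + 1, 1)
      bins <- first:(first + len - 1)
      occ <- occupied[[chrom]]
      if (is.null(occ) || !any(bins %in% occ)) {
        occupied[[chrom]] <- c(occ, bins)
        cn <- sample(c(1L, 3L, 0L, 4L), 1, prob = c(0.4, 0.45, 0.05, 0.1))
        segs[[length(segs) + 1]] <- tibble(
          chrom = chrom,
          start = (first - 1) * cfg$bin_size,
          end = (first + len - 1) * cfg$bin_size,
          cn = cn
        )
        break
      }
    }
  }
  bind_rows(segs)
}

segments_to_bins <- function(cfg, segments, tf) {
  grid <- make_bin_grid(cfg)
  cn <- rep(2L, nrow(grid))
  if (nrow(segments) > 0) {
    for (i in seq_len(nrow(segments))) {
      hit <- grid$chrom == segments$chrom[i] &
        grid$start >= segments$start[i] & grid$end <= segments$end[i]
      cn[hit] <- segments$cn[i]
    }
  }
  grid$log2_ratio <- expected_log2(cn, tf) + rnorm(nrow(grid), 0, cfg$bin_noise_sd)
  grid
}

# clinical covariates ---------------------------------------------------------

draw_starc <- function(tf, cfg) {
  tf_eff <- pmax(tf, 0.005)
  exp(log(26000) + 0.9 * (log(tf_eff) - log(0.08)) + rnorm(length(tf), 0, 0.8))
}

draw_cfdna_conc <- function(tf) {
  tf_eff <- pmax(tf, 0.005)
  exp(log(9000) + 0.3 * (log(tf_eff) - log(0.08)) + rnorm(length(tf), 0, 0.5))
}

draw_mtv <- function(tf) {
  tf_eff <- pmax(tf, 0.005)
  exp(log(163) + 0.8 * (log(tf_eff) - log(0.08)) + rnorm(length(tf), 0, 0.7))
}

#' Simulate a synthetic cfDNA cohort with full ground truth
#'
#' Generates a complete desk-scale study: per-sample VCFs from four
#' emulated variant callers, an annotation sidecar (functional effect,
#' gnomAD/1000G allele frequencies, COSMIC membership), bin-level
#' copy-number tables, a clinical table (cfDNA concentration, sTARC, MTV,
#' EBV status, stage, subtype, relapse), control samples for the panel of
#' normals, and longitudinal follow-up samples for a subset of patients.
#' Every emitted caller record traces back to exactly one ground-truth
#' category (somatic, germline or artifact), which makes parameter
#' recovery and filter sensitivity/specificity directly testable.
#'
#' @param config a [simulation_config()] object.
#' @param out_dir directory for the file bundle; created if needed.
#' @return invisibly, a list with elements `truth` (patients, samples,
#'   variants, segments tibbles plus the population pools) and `files`
#'   (paths: `vcf_dir`, `bin_dir`, `annotation_file`, `clinical_file`,
#'   `control_ids`, `callers`).
#' @export
simulate_cohort <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_dir <- file.path(out_dir, "vcf")
  bin_dir <- file.path(out_dir, "bins")
  dir.create(vcf_dir, showWarnings = FALSE)
  dir.create(bin_dir, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create output dir %s", out_dir))
  set.seed(config$seed)

  pools <- build_population_pools(config)
  callers <- config$caller_sensitivity$caller

  n <- config$n_patients
  clusters <- character(n)
  if (n > 0) {
    clusters <- sample(names(config$cluster_proportions), n, replace = TRUE,
                       prob = config$cluster_proportions)
    if (config$prop_ebv_pos_socs1wt > 0) {
      flip <- runif(n) < config$prop_ebv_pos_socs1wt
      clusters[flip] <- "EBV_pos_SOCS1wt"
    }
  }
  no_ctdna <- runif(n) < config$no_ctdna_rate
  ebv_unknown <- runif(n) < config$ebv_unknown_rate

  patients <- tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    cluster = clusters,
    ebv_status = ifelse(ebv_unknown, "unknown",
                        ifelse(grepl("^EBV_pos", clusters), "positive", "negative")),
    socs1_truth = ifelse(grepl("SOCS1m$", clusters), "mutated", "wildtype"),
    no_ctdna = no_ctdna,
    sex = ifelse(runif(n) < 0.43, "F", "M"),
    age = pmin(80, pmax(18, round(rlnorm(n, log(36), 0.35)))),
    stage = ifelse(runif(n) < 0.5, "I-II", "III-IV"),
    subtype = if (n > 0) sample(c("MC", "NOS", "NS"), n, replace = TRUE,
                                prob = c(0.136, 0.227, 0.637)) else character(0)
  )
  tf0 <- numeric(n)
  for (i in seq_len(n)) {
    par <- config$tumor_fraction[[
      if (clusters[i] %in% names(config$tumor_fraction)) clusters[i]
      else "EBV_pos_SOCS1m"]]
    tf0[i] <- min(0.8, rlnorm(1, par["meanlog"], par["sdlog"]))
  }
  tf0[no_ctdna] <- 0
  patients$tf_baseline <- tf0
  relapse_prob <- c(EBV_pos_SOCS1m = 0.12, EBV_neg_SOCS1m = 0.35,
                    EBV_neg_SOCS1wt = 0.07, EBV_pos_SOCS1wt = 0.1)
  patients$relapse <- runif(n) < unname(relapse_prob[clusters])

  # longitudinal subset: patients with signal, preferring relapsed cases
  trk_candidates <- patients$patient_id[patients$tf_baseline > 0.02]
  trk_candidates <- trk_candidates[order(!patients$relapse[match(
    trk_candidates, patients$patient_id)], trk_candidates)]
  tracked_ids <- head(trk_candidates, config$n_tracking)
  patients$tracked <- patients$patient_id %in% tracked_ids
  response <- rep(NA_character_, n)
  if (length(tracked_ids) > 0) {
    refr <- runif(length(tracked_ids)) < config$prop_refractory
    if (all(refr)) refr[1] <- FALSE # keep at least one responder when possible
    response[match(tracked_ids, patients$patient_id)] <-
      ifelse(refr, "refractory", "responder")
  }
  patients$response <- response

  samples <- list(); variants <- list(); segments <- list()
  timepoint_labels <- c("pre", paste0("fu", seq_len(config$n_timepoints - 1)))

  write_sample <- function(sample_id, patient_id, timepoint_idx, tf,
                           somatic, pretreatment) {
    germ <- draw_germline(config, pools)
    art <- draw_artifacts(config, pools)
    truth_vars <- bind_rows(
      somatic |> mutate(category = "somatic"),
      germ |> transmute(gene = .data$gene, chrom = .data$chrom,
                        pos = .data$pos, ref = .data$ref, alt = .data$alt,
                        true_vaf = .data$true_vaf, category = "germline"),
      art |> transmute(gene = .data$gene, chrom = .data$chrom, pos = .data$pos,
                       ref = .data$ref, alt = .data$alt,
                       true_vaf = .data$true_vaf, category = "artifact")
    ) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      mutate(bq = ifelse(.data$category == "artifact",
                         rnorm(dplyr::n(), 28, 3), rnorm(dplyr::n(), 34, 2)))
    calls <- emit_caller_records(truth_vars, config, sample_id)
    truth_vars$n_callers_detected <-
      as.integer(table(factor(calls$truth_row, levels = seq_len(nrow(truth_vars)))))
    for (cl in callers) {
      write_caller_vcf(
        calls |> filter(.data$caller_id == cl),
        file.path(vcf_dir, sprintf("%s.%s.vcf", sample_id, cl)),
        caller = cl, sample_id = sample_id, config = config
      )
    }
    segs <- plant_segments(config, tf)
    bins <- segments_to_bins(config, segs, tf)
    write_bin_tsv(bins, file.path(bin_dir, sprintf("%s.bins.tsv", sample_id)))
    list(
      variants = truth_vars |> mutate(sample_id = sample_id,
                                      patient_id = patient_id),
      segments = if (nrow(segs) > 0) segs |> mutate(sample_id = sample_id)
                 else NULL,
      tf = tf
    )
  }

  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    n_tp <- if (patients$tracked[i]) config$n_timepoints else 1L
    decay <- if (patients$tracked[i]) {
      unname(config$longitudinal_decay[[patients$response[i]]])
    } else 1
    somatic0 <- draw_somatic(config, clusters[i], tf0[i])
    for (tp in seq_len(n_tp)) {
      tf_tp <- tf0[i] * decay^(tp - 1)
      sid <- sprintf("%s_T%d", pid, tp - 1)
      somatic_tp <- somatic0
      if (nrow(somatic_tp) > 0) {
        somatic_tp$true_vaf <- pmin(
          0.6, somatic_tp$true_vaf * decay^(tp - 1) *
            rlnorm(nrow(somatic_tp), 0, 0.2))
      }
      res <- write_sample(sid, pid, tp, tf_tp, somatic_tp,
                          pretreatment = (tp == 1))
      variants[[length(variants) + 1]] <- res$variants
      if (!is.null(res$segments)) segments[[length(segments) + 1]] <- res$segments
      samples[[length(samples) + 1]] <- tibble(
        sample_id = sid, patient_id = pid,
        timepoint = timepoint_labels[tp], timepoint_index = tp - 1L,
        pretreatment = tp == 1L,
        tf = tf_tp,
        cfdna_conc = draw_cfdna_conc(tf_tp),
        starc = draw_starc(tf_tp, config),
        mtv = if (tp == 1L) draw_mtv(tf_tp) else
          draw_mtv(tf_tp) * ifelse(tf_tp < 0.01, NA, 1)
      )
    }
  }

  # controls: germline + artifacts only (no tumor), for the PoN
  control_ids <- sprintf("C%02d", seq_len(config$n_controls))
  for (cid in control_ids) {
    res <- write_sample(cid, cid, 1L, 0,
                        draw_somatic(config, "EBV_neg_SOCS1wt", 0),
                        pretreatment = TRUE)
    variants[[length(variants) + 1]] <- res$variants
  }

  variants <- bind_rows(variants)
  samples_tbl <- if (length(samples) > 0) bind_rows(samples) else tibble(
    sample_id = character(), patient_id = character(), timepoint = character(),
    timepoint_index = integer(), pretreatment = logical(), tf = numeric(),
    cfdna_conc = numeric(), starc = numeric(), mtv = numeric())
  segments_tbl <- if (length(segments) > 0) bind_rows(segments) else
    tibble(chrom = character(), start = numeric(), end = numeric(),
           cn = integer(), sample_id = character())

  clinical <- samples_tbl |>
    left_join(patients |> select("patient_id", "ebv_status", "sex", "age",
                                 "stage", "subtype", "relapse"),
              by = "patient_id") |>
    select("patient_id", "sample_id", "timepoint", "timepoint_index",
           "pretreatment", "ebv_status", "sex", "age", "stage", "subtype",
           "relapse", "cfdna_conc", "starc", "mtv")
  clinical_file <- file.path(out_dir, "clinical.tsv")
  write_clinical_tsv(clinical, clinical_file)

  annotation_file <- file.path(out_dir, "annotations.tsv")
  write_annotation_tsv(build_annotations(variants, pools), annotation_file)

  bundle <- list(
    truth = list(
      config = config, patients = patients, samples = samples_tbl,
      variants = variants, segments = segments_tbl, pools = pools
    ),
    files = list(
      out_dir = out_dir, vcf_dir = vcf_dir, bin_dir = bin_dir,
      annotation_file = annotation_file, clinical_file = clinical_file,
      control_ids = control_ids, callers = callers,
      sample_ids = unique(samples_tbl$sample_id)
    )
  )
  invisible(bundle)
}

# annotation sidecar: one row per distinct locus across the whole cohort
build_annotations <- function(variants, pools) {
  if (nrow(variants) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene = character(),
                  effect_class = character(), gnomad_af = numeric(),
                  kg_af = numeric(), cosmic = logical()))
  }
  ann <- variants |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
             .data$gene, .data$category)
  germ <- pools$germline |>
    select("chrom", "pos", af_pool = "af", effect_pool = "effect_class")
  ann |>
    left_join(germ, by = c("chrom", "pos")) |>
    mutate(
      effect_class = case_when(
        category == "germline" ~ .data$effect_pool,
        TRUE ~ "coding_nonsynonymous"
      ),
      gnomad_af = ifelse(.data$category == "germline", .data$af_pool, NA_real_),
      kg_af = ifelse(.data$category == "germline",
                     .data$af_pool * runif(dplyr::n(), 0.5, 1.5), NA_real_),
      cosmic = .data$category == "somatic" & runif(dplyr::n()) < 0.7
    ) |>
    select("chrom", "pos", "ref", "alt", "gene", "effect_class",
           "gnomad_af", "kg_af", "cosmic")
}
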