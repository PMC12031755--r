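#' Median VAF of PASS SNVs in one sample
#'
#' The per-sample ctDNA level summary used for pre-treatment samples:
#' the median variant allele frequency of passing single-nucleotide
#' variants (MNVs and InDels excluded). Undefined (NA) when the sample
#' has no passing SNV — deliberately not 0, since absence of evidence at
#' panel scale is not a measurement of zero.
#'
#' @param variants audited consensus tibble for one sample.
#' @return median VAF, or `NA_real_` if no PASS SNV exists.
#' @export
median_vaf <- function(variants) {
  snvs <- variants |>
    filter(.data$filter_status == "PASS", .data$variant_class == "SNV")
  if (nrow(snvs) == 0) return(NA_real_)
  median(snvs$vaf)
}

#' Circulating tumor DNA concentration in haploid genome equivalents
#'
#' `hGE/mL = mean VAF x cfDNA concentration (pg/mL plasma) / 3.3`, where
#' 3.3 pg is the weight of one human haploid genome.
#'
#' @param mean_vaf mean VAF of the tracked (re-occurring) variants.
#' @param cfdna_conc cfDNA concentration in pg per mL plasma.
#' @return haploid genome equivalents of ctDNA per mL plasma.
#' @export
hge_per_ml <- function(mean_vaf, cfdna_conc) {
  if (any(is.na(mean_vaf)) || any(is.na(cfdna_conc)) ||
      any(mean_vaf < 0) || any(cfdna_conc < 0)) {
    abort("`mean_vaf` and `cfdna_conc` must be non-negative")
  }
  mean_vaf * cfdna_conc / 3.3
}

#' Filter configuration for longitudinal tracking
#'
#' Tracking relaxes two cascade settings to gain sensitivity for
#' residual disease: the functional-effect filter is disregarded (a
#' synonymous variant is a perfectly good tumor marker), and follow-up
#' samples use a VAF cutoff of > 0.004 instead of > 1%.
#'
#' @param followup apply the relaxed follow-up VAF cutoff.
#' @param base a [filter_config()] to start from.
#' @return a `cfhl_filter_config`.
#' @export
tracking_filter_config <- function(followup = FALSE, base = filter_config()) {
  base$apply_effect_filter <- FALSE
  if (followup) base$min_vaf <- 0.004
  base
}

#' Select trackable variants for one patient
#'
#' A variant is trackable when it is called at the first available
#' timepoint and at least one later timepoint. Presence at any timepoint
#' is judged under the tracking cascade (effect filter off; follow-up
#' VAF > 0.004), with detection by any caller sufficing.
#'
#' @param variants audited consensus tibble covering all of one
#'   patient's timepoints, filtered under tracking rules, with a
#'   `timepoint_index` column (0 = first available timepoint).
#' @return tibble of tracked variant keys (`chrom`, `pos`, `ref`, `alt`,
#'   `gene` if present), a subset of the first-timepoint call set. Empty
#'   with a warning when nothing is trackable.
#' @export
select_trackable <- function(variants) {
  if (!"timepoint_index" %in% names(variants)) {
    abort("`variants` needs a `timepoint_index` column")
  }
  tps <- sort(unique(variants$timepoint_index))
  if (length(tps) < 2) abort("tracking requires at least two timepoints")
  pass <- variants |>
    filter(.data$filter_status == "PASS") |>
    mutate(key = locus_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  first_keys <- pass$key[pass$timepoint_index == tps[1]]
  later_keys <- pass$key[pass$timepoint_index > tps[1]]
  tracked_keys <- intersect(first_keys, later_keys)
  out <- pass |>
    filter(.data$timepoint_index == tps[1], .data$key %in% tracked_keys) |>
    select(any_of(c("chrom", "pos", "ref", "alt", "gene", "key")))
  if (nrow(out) == 0) {
    warn("no trackable variants identified for this patient")
  }
  out
}

#' Build a longitudinal tracking series for one patient
#'
#' Per timepoint: the mean VAF over the tracked variant set (a tracked
#' variant undetected at a timepoint contributes VAF 0, so the series
#' reflects residual-disease decline rather than detected-only survivor
#' bias; set `undetected_zero = FALSE` to average detected variants
#' only), the ctDNA concentration in hGE/mL, the unreconciled estimated
#' tumor fraction, and the comparator biomarkers sTARC and MTV.
#'
#' @param tracked tracked variant keys from [select_trackable()].
#' @param variants audited tracking-cascade tibble across timepoints
#'   (with `timepoint_index`).
#' @param clinical clinical rows for this patient's samples, one per
#'   timepoint, with `timepoint_index`, `cfdna_conc`, `starc`, `mtv`.
#' @param etf optional tibble `timepoint_index`, `etf` with unreconciled
#'   tumor-fraction estimates.
#' @param undetected_zero contribute 0 for undetected tracked variants.
#' @return tibble with one row per timepoint: `timepoint_index`,
#'   `n_tracked`, `n_detected`, `mean_vaf`, `hge_per_ml`, `etf`,
#'   `starc`, `mtv`. `hge_per_ml` is `NA` (flagged via `hge_missing`)
#'   where the cfDNA concentration is unavailable.
#' @export
build_tracking_series <- function(tracked, variants, clinical, etf = NULL,
                                  undetected_zero = TRUE) {
  pass <- variants |>
    filter(.data$filter_status == "PASS") |>
    mutate(key = locus_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    filter(.data$key %in% tracked$key)
  tps <- sort(unique(clinical$timepoint_index))
  rows <- lapply(tps, function(tp) {
    v <- pass |> filter(.data$timepoint_index == tp)
    n_det <- nrow(v)
    mv <- if (nrow(tracked) == 0) {
      NA_real_
    } else if (undetected_zero) {
      sum(v$vaf) / nrow(tracked)
    } else if (n_det > 0) {
      mean(v$vaf)
    } else {
      0
    }
    cl <- clinical |> filter(.data$timepoint_index == tp)
    conc <- if (nrow(cl) == 1) cl$cfdna_conc else NA_real_
    hge <- if (!is.na(mv) && !is.na(conc)) hge_per_ml(mv, conc) else NA_real_
    tibble(
      timepoint_index = tp,
      n_tracked = nrow(tracked),
      n_detected = n_det,
      mean_vaf = mv,
      hge_per_ml = hge,
      hge_missing = is.na(conc),
      etf = if (!is.null(etf)) {
        e <- etf$etf[etf$timepoint_index == tp]
        if (length(e) == 1) e else NA_real_
      } else NA_real_,
      starc = if (nrow(cl) == 1) cl$starc else NA_real_,
      mtv = if (nrow(cl) == 1) cl$mtv else NA_real_
    )
  })
  bind_rows(rows)
}

#' Run the tracking pipeline for one patient
#'
#' Convenience wrapper: runs the tracking cascade per timepoint (strict
#' VAF cutoff at the first available timepoint, relaxed > 0.004 cutoff
#' at follow-ups, effect filter off throughout), selects trackable
#' variants and assembles the series.
#'
#' @param calls caller-variant tibble for all of the patient's samples.
#' @param sample_index tibble `sample_id`, `timepoint_index` ordering the
#'   patient's samples.
#' @param pon panel of normals.
#' @param annotations annotation sidecar tibble.
#' @param clinical clinical rows with `sample_id`, `timepoint_index`,
#'   `cfdna_conc`, `starc`, `mtv`.
#' @param etf optional per-timepoint tumor-fraction tibble (see
#'   [build_tracking_series()]).
#' @param config base [filter_config()].
#' @return list with `tracked`, `series`, and the per-timepoint audited
#'   `variants`.
#' @export
track_patient <- function(calls, sample_index, pon, annotations, clinical,
                          etf = NULL, config = filter_config()) {
  if (nrow(sample_index) < 2) abort("tracking requires at least two timepoints")
  first_tp <- min(sample_index$timepoint_index)
  audited <- lapply(seq_len(nrow(sample_index)), function(i) {
    sid <- sample_index$sample_id[i]
    tp <- sample_index$timepoint_index[i]
    cfg <- tracking_filter_config(followup = tp > first_tp, base = config)
    res <- run_cascade(calls |> filter(.data$sample_id == sid),
                       pon, annotations, cfg)
    res$variants |> mutate(timepoint_index = tp)
  })
  variants <- bind_rows(audited)
  tracked <- select_trackable(variants)
  series <- build_tracking_series(tracked, variants, clinical, etf = etf)
  list(tracked = tracked, series = series, variants = variants)
}
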