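#' Assign supervised EBV/SOCS1 cluster labels
#'
#' Each sample's label is a pure function of its tumor EBV status and
#' the presence of at least one passing SOCS1 variant:
#' `EBV_pos_SOCS1m`, `EBV_neg_SOCS1m`, `EBV_neg_SOCS1wt` (plus the
#' `EBV_pos_SOCS1wt` combination, kept for robustness although not
#' observed in practice). Samples with no passing variant at all — no
#' detectable ctDNA — or with unknown EBV status are `unassigned`.
#'
#' @param clinical tibble with `sample_id` and `ebv_status`
#'   (`"positive"`, `"negative"` or `"unknown"`).
#' @param variants audited consensus tibble covering those samples.
#' @return tibble `sample_id`, `cluster`.
#' @export
assign_clusters <- function(clinical, variants) {
  pass <- variants |> filter(.data$filter_status == "PASS")
  per_sample <- pass |>
    group_by(.data$sample_id) |>
    summarise(n_pass = dplyr::n(),
              socs1 = any(!is.na(.data$gene) & .data$gene == "SOCS1"),
              .groups = "drop")
  clinical |>
    select("sample_id", "ebv_status") |>
    left_join(per_sample, by = "sample_id") |>
    mutate(
      n_pass = ifelse(is.na(.data$n_pass), 0L, .data$n_pass),
      socs1 = ifelse(is.na(.data$socs1), FALSE, .data$socs1),
      cluster = case_when(
        n_pass == 0 ~ "unassigned",
        !(ebv_status %in% c("positive", "negative")) ~ "unassigned",
        ebv_status == "positive" & socs1 ~ "EBV_pos_SOCS1m",
        ebv_status == "positive" & !socs1 ~ "EBV_pos_SOCS1wt",
        ebv_status == "negative" & socs1 ~ "EBV_neg_SOCS1m",
        TRUE ~ "EBV_neg_SOCS1wt"
      )
    ) |>
    select("sample_id", "cluster")
}

#' SNV load per sample
#'
#' Count of passing SNVs, by default excluding SOCS1 mutations: the
#' clusters are defined by SOCS1 status, so including its mutations in
#' the load comparison would bias the contrast by construction.
#'
#' @param variants audited consensus tibble.
#' @param exclude_socs1 exclude SOCS1 variants from the count.
#' @return tibble `sample_id`, `snv_load`.
#' @export
snv_load <- function(variants, exclude_socs1 = TRUE) {
  pass <- variants |>
    filter(.data$filter_status == "PASS", .data$variant_class == "SNV")
  if (exclude_socs1) {
    pass <- pass |> filter(is.na(.data$gene) | .data$gene != "SOCS1")
  }
  pass |> count(.data$sample_id, name = "snv_load")
}

#' Match clusters on overlapping median VAF
#'
#' Confound control for SNV-load comparisons: restricts both EBV-negative
#' clusters to samples whose per-sample median VAF lies in the closed
#' window from the lowest median VAF of the SOCS1-mutated cluster to the
#' highest median VAF of the wild-type cluster, so that load differences
#' cannot be explained by different ctDNA levels. An inverted window
#' (no overlap) yields empty subsets with a warning. Idempotent: matching
#' the matched subsets returns them unchanged.
#'
#' @param m_samples,wt_samples tibbles with `sample_id` and `median_vaf`
#'   for the SOCS1-mutated and wild-type clusters.
#' @return list with `m`, `wt` (matched subsets) and `window`
#'   (`c(lo, hi)`).
#' @export
vaf_overlap_match <- function(m_samples, wt_samples) {
  if (nrow(m_samples) == 0 || all(is.na(m_samples$median_vaf)) ||
      nrow(wt_samples) == 0 || all(is.na(wt_samples$median_vaf))) {
    abort("both clusters need at least one defined median VAF")
  }
  lo <- min(m_samples$median_vaf, na.rm = TRUE)
  hi <- max(wt_samples$median_vaf, na.rm = TRUE)
  if (lo > hi) {
    warn("median-VAF ranges do not overlap; matched subsets are empty")
    return(list(m = m_samples[0, ], wt = wt_samples[0, ],
                window = c(lo, hi)))
  }
  inside <- function(x) !is.na(x) & x >= lo & x <= hi
  list(
    m = m_samples |> filter(inside(.data$median_vaf)),
    wt = wt_samples |> filter(inside(.data$median_vaf)),
    window = c(lo, hi)
  )
}

#' Rank-based comparison of two or three groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test, exact when both groups
#' have at most 25 observations and no ties, otherwise the normal
#' approximation with tie correction. Three or more groups:
#' Kruskal-Wallis test. Significance is declared at p < 0.05, with no
#' multiple-testing adjustment.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`.
#' @param exact_max largest per-group n for which the exact two-group
#'   distribution is used.
#' @return one-row tibble: `test`, `statistic`, `p_value`, `n_groups`,
#'   `n` (comma-separated per-group sizes), `significant`.
#' @export
compare_groups <- function(values, groups, exact_max = 25) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- as.character(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes == 0)) {
    abort("need at least two non-empty groups")
  }
  if (length(sizes) == 2) {
    g <- names(sizes)
    x <- values[groups == g[1]]
    y <- values[groups == g[2]]
    use_exact <- max(sizes) <= exact_max && !any(duplicated(values))
    ht <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = !use_exact))
    test <- "wilcoxon_rank_sum"
  } else {
    ht <- kruskal.test(values, factor(groups))
    test <- "kruskal_wallis"
  }
  tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = min(1, ht$p.value),
    n_groups = length(sizes),
    n = paste(as.integer(sizes), collapse = ","),
    significant = ht$p.value < 0.05
  )
}

#' Spearman correlation between two variables
#'
#' Pairs with a missing value in either variable are dropped pairwise;
#' at least 3 complete pairs are required.
#'
#' @param x,y paired numeric vectors.
#' @return one-row tibble: `test`, `statistic` (rho), `p_value`, `n`,
#'   `significant`.
#' @export
correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(
    test = "spearman",
    statistic = unname(ht$estimate),
    p_value = ht$p.value,
    n = length(x),
    significant = ht$p.value < 0.05
  )
}
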