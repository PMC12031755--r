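#' Summarize a clinical cohort table
#'
#' Descriptive statistics in the layout of a clinical baseline table:
#' for categorical fields, level counts with percentages of the full
#' cohort (half-up, one decimal); for numeric fields, mean (SD),
#' median with min and max, and an explicit missing row with count and
#' percentage.
#'
#' @param clinical tibble with one row per patient.
#' @param categorical,numeric character vectors naming the columns to
#'   summarize; defaults cover the fields present.
#' @return object of class `cfhl_cohort_summary`: list with `n`,
#'   `categorical` (field, level, count, percent) and `numeric` (field,
#'   mean, sd, median, min, max, n_missing, pct_missing).
#' @export
summarize_cohort <- function(clinical,
                             categorical = intersect(
                               c("sex", "stage", "ebv_status", "subtype",
                                 "relapse", "pretreatment_available",
                                 "followup_available"),
                               names(clinical)),
                             numeric = intersect(
                               c("age", "mtv", "starc", "cfdna_conc"),
                               names(clinical))) {
  n <- nrow(clinical)
  if (n == 0) abort("empty clinical table")
  cat_rows <- lapply(categorical, function(f) {
    x <- clinical[[f]]
    x <- ifelse(is.na(x), "Missing", as.character(x))
    tab <- table(x)
    tibble(field = f, level = names(tab), count = as.integer(tab),
           percent = round_half_up(100 * as.integer(tab) / n, 1))
  })
  num_rows <- lapply(numeric, function(f) {
    x <- clinical[[f]]
    miss <- sum(is.na(x))
    ok <- x[!is.na(x)]
    tibble(
      field = f,
      mean = mean(ok), sd = sd(ok),
      median = median(ok), min = min(ok), max = max(ok),
      n_missing = miss,
      pct_missing = round_half_up(100 * miss / n, 1)
    )
  })
  structure(list(
    n = n,
    categorical = bind_rows(cat_rows),
    numeric = bind_rows(num_rows)
  ), class = "cfhl_cohort_summary")
}

#' @export
print.cfhl_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (N = %d)\n", x$n))
  for (f in unique(x$categorical$field)) {
    cat(sprintf("  %s\n", f))
    rows <- x$categorical[x$categorical$field == f, ]
    for (i in seq_len(nrow(rows))) {
      cat(sprintf("    %-12s %d (%.1f%%)\n", rows$level[i], rows$count[i],
                  rows$percent[i]))
    }
  }
  for (i in seq_len(nrow(x$numeric))) {
    r <- x$numeric[i, ]
    cat(sprintf("  %s: mean %.1f (SD %.1f), median %.1f [%.1f, %.1f]",
                r$field, r$mean, r$sd, r$median, r$min, r$max))
    if (r$n_missing > 0) {
      cat(sprintf(", missing %d (%.1f%%)", r$n_missing, r$pct_missing))
    }
    cat("\n")
  }
  invisible(x)
}

#' Serialize / reparse a cohort summary
#'
#' Writes the summary as a single TSV with a `section` column so that
#' reading it back reproduces the object exactly.
#'
#' @param summary a `cfhl_cohort_summary`.
#' @param path TSV path.
#' @return `path` / the reparsed summary.
#' @export
write_cohort_summary <- function(summary, path) {
  cat_part <- summary$categorical |>
    mutate(section = "categorical", n = summary$n)
  num_part <- summary$numeric |>
    mutate(section = "numeric", n = summary$n)
  out <- bind_rows(cat_part, num_part)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_cohort_summary
#' @export
read_cohort_summary <- function(path) {
  raw <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, na.strings = "NA"))
  n <- raw$n[1]
  cat_part <- raw |>
    filter(.data$section == "categorical") |>
    select("field", "level", "count", "percent") |>
    mutate(count = as.integer(.data$count))
  num_part <- raw |>
    filter(.data$section == "numeric") |>
    select("field", "mean", "sd", "median", "min", "max", "n_missing",
           "pct_missing") |>
    mutate(n_missing = as.integer(.data$n_missing))
  structure(list(n = n, categorical = cat_part, numeric = num_part),
            class = "cfhl_cohort_summary")
}

#' Gene-by-sample mutation incidence matrix with oncoplot ordering
#'
#' Builds the incidence matrix of passing SNVs. Genes are sorted by the
#' total number of SNVs per gene (descending, ties by gene name);
#' samples are sorted by cluster (EBV+ & SOCS1m, EBV- & SOCS1m,
#' EBV- & SOCS1wt), then by SNV load descending, ties by sample id.
#' Samples without any passing variant (no detectable ctDNA) are
#' excluded. The ordering is stable under permutation of the input.
#'
#' @param variants audited consensus tibble.
#' @param clusters tibble `sample_id`, `cluster` from [assign_clusters()].
#' @return list of class `cfhl_mutation_matrix`: `matrix` (genes x
#'   samples, 0/1 incidence), `gene_snv_counts`, `sample_snv_load`,
#'   `sample_order`, `gene_order`, `clusters`.
#' @export
build_mutation_matrix <- function(variants, clusters) {
  pass <- variants |>
    filter(.data$filter_status == "PASS", .data$variant_class == "SNV",
           !is.na(.data$gene))
  keep_samples <- clusters |> filter(.data$cluster != "unassigned")
  pass <- pass |> filter(.data$sample_id %in% keep_samples$sample_id)
  gene_counts <- pass |> count(.data$gene, name = "n_snv")
  sample_load <- pass |> count(.data$sample_id, name = "snv_load")
  gene_order <- gene_counts |>
    arrange(desc(.data$n_snv), .data$gene) |>
    pull("gene")
  cluster_rank <- c(EBV_pos_SOCS1m = 1, EBV_neg_SOCS1m = 2,
                    EBV_neg_SOCS1wt = 3, EBV_pos_SOCS1wt = 4)
  sample_order <- keep_samples |>
    inner_join(sample_load, by = "sample_id") |>
    arrange(cluster_rank[.data$cluster], desc(.data$snv_load),
            .data$sample_id) |>
    pull("sample_id")
  mat <- matrix(0L, nrow = length(gene_order), ncol = length(sample_order),
                dimnames = list(gene_order, sample_order))
  if (nrow(pass) > 0) {
    inc <- pass |> distinct(.data$gene, .data$sample_id)
    mat[cbind(match(inc$gene, gene_order),
              match(inc$sample_id, sample_order))] <- 1L
  }
  structure(list(
    matrix = mat,
    gene_snv_counts = gene_counts |> arrange(desc(.data$n_snv), .data$gene),
    sample_snv_load = sample_load,
    sample_order = sample_order,
    gene_order = gene_order,
    clusters = keep_samples
  ), class = "cfhl_mutation_matrix")
}

#' Per-bin gain/loss frequency across copy-number profiles
#'
#' For each bin of a shared grid: the fraction of samples whose called
#' segments cover the bin as a gain, and as a loss.
#'
#' @param profiles list of `cfhl_cnv_profile` objects on identical bin
#'   grids.
#' @return tibble `chrom`, `start`, `end`, `gain_freq`, `loss_freq`.
#' @export
cnv_frequency_track <- function(profiles) {
  if (length(profiles) == 0) abort("need at least one profile")
  grid <- profiles[[1]]$bins |> select("chrom", "start", "end")
  for (p in profiles) {
    g <- p$bins |> select("chrom", "start", "end")
    if (!identical(as.data.frame(g), as.data.frame(grid))) {
      abort("profiles are on inconsistent bin grids")
    }
  }
  gain <- numeric(nrow(grid))
  loss <- numeric(nrow(grid))
  for (p in profiles) {
    segs <- p$segments
    if (nrow(segs) == 0) next
    for (i in seq_len(nrow(segs))) {
      hit <- grid$chrom == segs$chrom[i] & grid$start >= segs$start[i] &
        grid$end <= segs$end[i]
      if (segs$direction[i] == "gain") gain[hit] <- gain[hit] + 1
      else loss[hit] <- loss[hit] + 1
    }
  }
  grid |>
    mutate(gain_freq = gain / length(profiles),
           loss_freq = loss / length(profiles))
}
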