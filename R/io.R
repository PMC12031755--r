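#' Write caller variant records as a VCF 4.2 file
#'
#' One file per sample per caller, with the caller name recorded in the
#' `##source` header line and per-record `DP`, `AD` (ref,alt) and `BQ`
#' FORMAT fields. Deterministic output: same records, same bytes.
#'
#' @param calls tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `read_depth`, `alt_depth`, `base_quality` (rows may be empty).
#' @param path output file path.
#' @param caller caller name for the `##source` header.
#' @param sample_id sample column name.
#' @param config optional [simulation_config()] supplying contig lengths
#'   for the header; defaults to the miniature genome.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, caller, sample_id, config = NULL) {
  n_chrom <- if (is.null(config)) 3 else config$n_chrom
  chrom_len <- if (is.null(config)) 1e8 else config$chrom_len
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s", caller),
    sprintf("##contig=<ID=chr%d,length=%d>", seq_len(n_chrom),
            as.integer(chrom_len)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality of alt reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_id), collapse = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    ord <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
    calls <- calls[ord, ]
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD:BQ\t0/1:%d:%d,%d:%.1f",
      calls$chrom, calls$pos, calls$ref, calls$alt,
      calls$read_depth, calls$read_depth - calls$alt_depth,
      calls$alt_depth, calls$base_quality
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read one caller's VCF into a caller-variant tibble
#'
#' Parses a single-sample VCF 4.2 file (via vcfR) into the tabular
#' caller-variant representation used by the consensus merge. The caller
#' identity is taken from the `##source` header unless overridden.
#'
#' @param path VCF file path.
#' @param caller_id optional caller name; default from the header.
#' @param sample_id optional sample name; default from the genotype column.
#' @return tibble with columns `sample_id`, `caller_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `read_depth`, `alt_depth`, `vaf`, `base_quality`.
#' @export
read_caller_vcf <- function(path, caller_id = NULL, sample_id = NULL) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(sprintf("malformed VCF %s: %s", path,
                                      conditionMessage(e)))
  )
  if (is.null(caller_id)) {
    src <- vcfR::queryMETA(v, element = "source")
    caller_id <- if (length(src) > 0) sub("^source=", "", src[[1]][1]) else NA_character_
  }
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@gt) == 0) {
    return(tibble(
      sample_id = character(), caller_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      read_depth = integer(), alt_depth = integer(), vaf = numeric(),
      base_quality = numeric()
    ))
  }
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  if (is.null(sample_id)) sample_id <- colnames(v@gt)[2]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1]))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  bq <- suppressWarnings(as.numeric(vcfR::extract.gt(v, "BQ")[, 1]))
  alt_depth <- suppressWarnings(
    as.integer(vapply(strsplit(ad, ","),
                      function(x) if (length(x) >= 2) x[2] else NA_character_,
                      character(1))))
  pos <- as.integer(fix[, "POS"])
  if (any(is.na(pos)) || any(is.na(dp)) || any(is.na(alt_depth))) {
    bad <- which(is.na(pos) | is.na(dp) | is.na(alt_depth))[1]
    abort(sprintf("malformed VCF record in %s (record %d)", path, bad))
  }
  tibble(
    sample_id = sample_id, caller_id = caller_id,
    chrom = fix[, "CHROM"], pos = pos,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    read_depth = dp, alt_depth = alt_depth,
    vaf = alt_depth / dp, base_quality = bq
  )
}

#' Read all caller VCFs for a set of samples
#'
#' @param vcf_dir directory containing `<sample>.<caller>.vcf` files.
#' @param sample_ids sample identifiers to read.
#' @param callers caller names.
#' @return combined caller-variant tibble.
#' @export
read_sample_calls <- function(vcf_dir, sample_ids, callers) {
  files <- tidyr::expand_grid(sample_id = sample_ids, caller = callers)
  out <- lapply(seq_len(nrow(files)), function(i) {
    path <- file.path(vcf_dir, sprintf("%s.%s.vcf", files$sample_id[i],
                                       files$caller[i]))
    read_caller_vcf(path, caller_id = files$caller[i],
                    sample_id = files$sample_id[i])
  })
  bind_rows(out)
}

write_bin_tsv <- function(bins, path) {
  out <- bins |>
    mutate(start = sprintf("%d", as.integer(.data$start)),
           end = sprintf("%d", as.integer(.data$end)),
           log2_ratio = sprintf("%.6f", .data$log2_ratio))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin-level copy-number table
#'
#' Expects BED-like 0-based half-open bins with columns `chrom`, `start`,
#' `end`, `log2_ratio`.
#'
#' @param path TSV file path.
#' @return tibble of bins.
#' @export
read_bin_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)) |>
    mutate(start = as.numeric(.data$start), end = as.numeric(.data$end),
           log2_ratio = as.numeric(.data$log2_ratio))
}

write_annotation_tsv <- function(ann, path) {
  out <- ann |>
    mutate(gnomad_af = ifelse(is.na(.data$gnomad_af), "",
                              sprintf("%.6g", .data$gnomad_af)),
           kg_af = ifelse(is.na(.data$kg_af), "",
                          sprintf("%.6g", .data$kg_af)),
           cosmic = ifelse(.data$cosmic, "TRUE", "FALSE"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant annotation sidecar
#'
#' Annotations are keyed by (chrom, pos, ref, alt) and carry the gene,
#' functional effect class, gnomAD and 1000 Genomes allele frequencies
#' (empty when the variant is not listed) and COSMIC membership.
#'
#' @param path TSV file path.
#' @return annotation tibble with `gnomad_af`/`kg_af` `NA` when unlisted.
#' @export
read_annotation_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))) |>
    mutate(pos = as.integer(.data$pos),
           gnomad_af = as.numeric(.data$gnomad_af),
           kg_af = as.numeric(.data$kg_af),
           cosmic = as.logical(.data$cosmic))
}

write_clinical_tsv <- function(clinical, path) {
  out <- clinical |>
    mutate(across(any_of(c("cfdna_conc", "starc", "mtv")),
                  ~ ifelse(is.na(.x), "", sprintf("%.4f", .x))))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the clinical sample table
#'
#' @param path TSV file path with one row per plasma sample.
#' @return tibble with typed columns (`cfdna_conc`, `starc`, `mtv`
#'   numeric; `pretreatment`, `relapse` logical).
#' @export
read_clinical_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))) |>
    mutate(across(any_of(c("cfdna_conc", "starc", "mtv", "age")), as.numeric),
           across(any_of(c("pretreatment", "relapse")), as.logical))
}
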