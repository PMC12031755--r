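#' Round half away from zero
#'
#' Standard arithmetic rounding (0.05 -> 0.1 at one decimal), as used in
#' clinical summary tables, in contrast to base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# locus key shared by PoN matching, consensus merge and tracking
locus_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# fraction of G/C bases in a DNA string; NA for empty string
gc_fraction <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    b <- strsplit(toupper(s), "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "cfhl_config_error")
}
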