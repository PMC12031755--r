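#' Call gain/loss segments from bin-level log2 ratios
#'
#' Maximal runs of consecutive bins, within a chromosome, whose log2
#' ratio strictly exceeds `+threshold` (gain) or falls strictly below
#' `-threshold` (loss). Bins exactly at the cutoff are neutral. No
#' minimum segment length is imposed: single-bin segments are legitimate
#' at 1,000 kbp resolution.
#'
#' @param bins tibble with `chrom`, `start`, `end`, `log2_ratio`; bins
#'   must be sorted and non-overlapping within each chromosome.
#' @param threshold log2-ratio cutoff (default 0.08, calibrated on
#'   control plasma samples; see [calibrate_cn_threshold()]).
#' @return tibble of segments: `chrom`, `start`, `end`, `direction`
#'   (`"gain"`/`"loss"`), `n_bins`, `mean_log2`.
#' @export
call_segments <- function(bins, threshold = 0.08) {
  validate_bins(bins)
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    state <- ifelse(b$log2_ratio > threshold, "gain",
                    ifelse(b$log2_ratio < -threshold, "loss", "neutral"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in seq_along(r$values)) {
      if (r$values[j] == "neutral") next
      idx <- starts[j]:ends[j]
      out[[length(out) + 1]] <- tibble(
        chrom = ch,
        start = b$start[starts[j]],
        end = b$end[ends[j]],
        direction = r$values[j],
        n_bins = length(idx),
        mean_log2 = mean(b$log2_ratio[idx])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), n_bins = integer(),
                  mean_log2 = numeric()))
  }
  bind_rows(out)
}

validate_bins <- function(bins) {
  if (nrow(bins) == 0) abort("no bins supplied")
  if (any(bins$end <= bins$start)) abort("bins must satisfy end > start")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start)) abort(sprintf("bins unsorted on %s", ch))
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      abort(sprintf("overlapping bins on %s", ch))
    }
  }
  invisible(bins)
}

#' Fraction of genome altered
#'
#' Number of bins inside called gain/loss segments divided by the total
#' number of bins.
#'
#' @param segments segment tibble from [call_segments()].
#' @param n_bins total number of bins in the profile.
#' @return fraction in `[0, 1]`.
#' @export
compute_fga <- function(segments, n_bins) {
  if (n_bins <= 0) abort("total bin count must be positive")
  sum(segments$n_bins) / n_bins
}

#' Estimate tumor fraction from a copy-number profile
#'
#' Grid-search mixture estimator: for each candidate tumor fraction
#' `tf` on a 0.001-step grid, every called segment (and the neutral
#' background) is assigned the integer copy number in `0..max_cn` whose
#' expected log2 ratio under the diploid-admixture model
#' ([expected_log2()]) is nearest its observed mean; the candidate's
#' score is the bin-weighted squared error plus a diploid-proximity
#' penalty that resolves the inherent scale ambiguity of the mixture
#' model (e.g. one gained copy at tumor fraction t fits exactly as well
#' as two gained copies at t/2) in favor of copy states closest to
#' diploid. The penalty weight is large enough that a single noisy bin
#' cannot flip a long segment to a more extreme copy state at half the
#' tumor fraction, but it never overrides an exact-fit preference for
#' near-diploid states. Returns 0 when no segment breaches the calling
#' threshold.
#'
#' This is a deliberately simple, fully specified estimator of the
#' ctDNA fraction from shallow whole-genome copy-number signal. It is
#' not ichorCNA: there is no HMM, no subclonal states and no ploidy
#' search.
#'
#' @param bins bin tibble (`chrom`, `start`, `end`, `log2_ratio`).
#' @param max_cn maximum copy-number state (default 4).
#' @param threshold segment-calling cutoff passed to [call_segments()].
#' @param grid_step tumor-fraction grid resolution.
#' @param cn_penalty weight of the diploid-proximity penalty per bin per
#'   squared copy-number step from 2.
#' @return estimated tumor fraction in `[0, 1]`.
#' @export
estimate_tumor_fraction <- function(bins, max_cn = 4, threshold = 0.08,
                                    grid_step = 0.001, cn_penalty = 1e-3) {
  validate_bins(bins)
  segments <- call_segments(bins, threshold)
  if (nrow(segments) == 0) return(0)
  seg_keys <- paste(segments$chrom, segments$start)
  in_seg <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(segments))) {
    in_seg <- in_seg | (bins$chrom == segments$chrom[i] &
                          bins$start >= segments$start[i] &
                          bins$end <= segments$end[i])
  }
  pieces <- tibble(mean_log2 = segments$mean_log2, n_bins = segments$n_bins)
  if (any(!in_seg)) {
    pieces <- bind_rows(pieces, tibble(
      mean_log2 = mean(bins$log2_ratio[!in_seg]), n_bins = sum(!in_seg)))
  }
  tf_grid <- seq(0, 1, by = grid_step)
  cn_states <- 0:max_cn
  best_tf <- 0
  best_score <- Inf
  for (tf in tf_grid) {
    exp_l2 <- expected_log2(cn_states, tf, max_cn = max_cn)
    err <- abs(outer(pieces$mean_log2, exp_l2, "-"))
    pick <- apply(err, 1, which.min)
    resid <- pieces$mean_log2 - exp_l2[pick]
    score <- sum(pieces$n_bins * resid^2) +
      cn_penalty * sum(pieces$n_bins * (cn_states[pick] - 2)^2)
    if (score < best_score - 1e-15) {
      best_score <- score
      best_tf <- tf
    }
  }
  best_tf
}

#' Assemble a copy-number profile for one sample
#'
#' Calls segments, computes the fraction of genome altered and the
#' estimated tumor fraction in one pass.
#'
#' @param bins bin tibble.
#' @param sample_id sample identifier.
#' @param threshold segment-calling cutoff.
#' @param max_cn maximum copy-number state.
#' @return list of class `cfhl_cnv_profile`: `sample_id`, `bins`,
#'   `segments`, `fga`, `etf`, `etf_adjusted`.
#' @export
cnv_profile <- function(bins, sample_id = NA_character_, threshold = 0.08,
                        max_cn = 4) {
  segments <- call_segments(bins, threshold)
  structure(list(
    sample_id = sample_id,
    bins = bins,
    segments = segments,
    fga = compute_fga(segments, nrow(bins)),
    etf = estimate_tumor_fraction(bins, max_cn = max_cn,
                                  threshold = threshold),
    etf_adjusted = FALSE
  ), class = "cfhl_cnv_profile")
}

#' Reconcile discordant FGA and tumor-fraction calls
#'
#' For pre-treatment samples with no called copy-number segments
#' (FGA = 0) but a positive estimated tumor fraction, the tumor fraction
#' is set to 0 and flagged as adjusted: with no supporting segment the
#' positive estimate is considered noise. Follow-up samples used for
#' disease tracking and correlation are never adjusted.
#'
#' @param profile a `cfhl_cnv_profile`.
#' @param is_pretreatment logical flag.
#' @return the profile, possibly with `etf = 0` and `etf_adjusted = TRUE`.
#' @export
reconcile_etf <- function(profile, is_pretreatment) {
  if (isTRUE(is_pretreatment) && profile$fga == 0 && profile$etf > 0) {
    profile$etf <- 0
    profile$etf_adjusted <- TRUE
  }
  profile
}

#' Calibrate the segment-calling threshold on control samples
#'
#' Returns the maximum absolute bin log2 ratio observed across control
#' profiles, i.e. the smallest cutoff at which no control bin would be
#' called. The shipped default of 0.08 remains the reference cutoff.
#'
#' @param control_bins list of control bin tibbles.
#' @return calibrated threshold (scalar).
#' @export
calibrate_cn_threshold <- function(control_bins) {
  if (length(control_bins) == 0) abort("need at least one control profile")
  max(vapply(control_bins, function(b) max(abs(b$log2_ratio)), numeric(1)))
}

#' Convert raw bin read counts to log2 ratios by median normalization
#'
#' Minimal normalization for synthetic read-count tables: divides counts
#' by their median and takes log2. Real data should arrive as
#' GC/mappability-corrected log2 ratios from an upstream binning tool.
#'
#' @param counts non-negative numeric vector of per-bin read counts.
#' @return numeric vector of log2 ratios.
#' @export
counts_to_log2 <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  m <- median(counts)
  if (m <= 0) abort("median count must be positive")
  log2(counts / m)
}
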