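#' @title Length-bias statistics
#' @description Localizes germline-segment-specific CDR3 length biases with
#'   two-tailed paired (by donor) t-tests over a sliding window of two
#'   contiguous lengths, compares compartments, and correlates per-segment
#'   mean lengths across cohorts by Spearman rank correlation.
#' @name bias_stats
NULL

# per-donor frequency matrix (donors x lengths) over a common grid
.freq_matrix <- function(dist, lengths) {
  donors <- sort(unique(dist$donor_id))
  m <- matrix(0, length(donors), length(lengths),
              dimnames = list(donors, lengths))
  keep <- dist$length %in% lengths
  m[cbind(match(dist$donor_id[keep], donors),
          match(dist$length[keep], lengths))] <- dist$pct[keep]
  m
}

#' Sliding-window paired t-test of a segment distribution against the overall
#'
#' For each window of two contiguous CDR3 lengths (l, l+1), the per-donor
#' statistic is the segment-minus-overall frequency difference summed over
#' the two lengths; a two-tailed one-sample t-test across donors tests that
#' statistic against zero. The window is significant at `p < alpha` (the
#' conventional thresholds are 1e-4 for VH comparisons over 11 donors and
#' 1e-2 for VL over 5 donors). The segment's own contribution is not removed
#' from the overall distribution. Zero-variance windows are reported with
#' p = 1 and flagged degenerate rather than NaN.
#'
#' @param segment_dist,overall_dist per-donor distributions from
#'   [length_distribution] for one segment and for the overall repertoire of
#'   the same donors/compartment.
#' @param alpha significance threshold on the two-tailed p-value.
#' @param support integer lengths to analyze; default the union of observed
#'   lengths.
#' @return data.frame: `group_key`, `window_start` (window covers
#'   `window_start` and `window_start + 1`), `mean_diff` (percentage points),
#'   `direction` (`"enriched"`/`"depleted"`), `p_value`, `significant`,
#'   `degenerate`.
#' @export
sliding_window_ttest <- function(segment_dist, overall_dist, alpha = 1e-4,
                                 support = NULL) {
  donors <- sort(unique(overall_dist$donor_id))
  if (length(donors) < 2L) stop("sliding_window_ttest requires >= 2 donors")
  if (!setequal(donors, unique(segment_dist$donor_id))) {
    stop("segment and overall distributions must cover the same donors")
  }
  if (is.null(support)) {
    support <- sort(unique(c(segment_dist$length, overall_dist$length)))
    support <- seq(min(support), max(support))
  }
  seg <- .freq_matrix(segment_dist, support)[donors, , drop = FALSE]
  ovl <- .freq_matrix(overall_dist, support)[donors, , drop = FALSE]
  diff <- seg - ovl
  gk <- segment_dist$group_key[1]
  out <- do.call(rbind, lapply(seq_len(length(support) - 1L), function(i) {
    d <- diff[, i] + diff[, i + 1L]
    degenerate <- stats::sd(d) < .Machine$double.eps^0.5
    p <- if (degenerate) 1 else stats::t.test(d, mu = 0)$p.value
    data.frame(group_key = gk, window_start = support[i],
               mean_diff = mean(d),
               direction = if (mean(d) > 0) "enriched" else "depleted",
               p_value = p, significant = !degenerate && p < alpha,
               degenerate = degenerate)
  }))
  rownames(out) <- NULL
  out
}

#' Compartment mean-length differences per segment
#'
#' AE-minus-naive mean CDR3 length per donor and segment, then averaged
#' across donors with SEM. Segments absent from either compartment in a
#' donor are excluded for that donor (and reported).
#'
#' @param records clonotype representatives covering both compartments.
#' @param group_by segment column, default `"v_call"`.
#' @param compartments the two compartments compared, difference =
#'   second minus first.
#' @param min_n minimum records per (segment, donor, compartment) cell.
#' @return data.frame: `group_key`, `mean_diff`, `sem`, `n_donors`.
#' @export
compare_compartments <- function(records, group_by = "v_call",
                                 compartments = c("naive", "AE"), min_n = 80) {
  len <- cdr3_length(records)
  gk <- do.call(paste, c(unname(records[group_by]), sep = "|"))
  key <- paste(gk, records$donor_id, records$compartment, sep = "\r")
  mu <- vapply(split(len, key), mean, 0)
  nn <- lengths(split(len, key))
  mu <- mu[nn >= min_n]
  info <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
  segs <- unique(info[, 1])
  out <- do.call(rbind, lapply(segs, function(s) {
    donors <- unique(info[info[, 1] == s, 2])
    d <- vapply(donors, function(dn) {
      a <- mu[paste(s, dn, compartments[1], sep = "\r")]
      b <- mu[paste(s, dn, compartments[2], sep = "\r")]
      if (is.na(a) || is.na(b)) NA_real_ else unname(b - a)
    }, 0)
    d <- d[!is.na(d)]
    if (!length(d)) {
      message("compare_compartments: segment ", s,
              " absent from one compartment in every donor; excluded")
      return(NULL)
    }
    data.frame(group_key = s, mean_diff = mean(d),
               sem = if (length(d) >= 2L) stats::sd(d) / sqrt(length(d)) else NA_real_,
               n_donors = length(d))
  }))
  rownames(out) <- NULL
  out
}

#' Spearman correlation of per-segment mean lengths between two cohorts
#'
#' Rank correlation over the intersection of segment keys; requires at least
#' three shared segments.
#'
#' @param means_a,means_b named numeric vectors, segment -> mean CDR3 length.
#' @return Spearman's rank correlation coefficient in `[-1, 1]`.
#' @export
spearman_segments <- function(means_a, means_b) {
  shared <- intersect(names(means_a), names(means_b))
  if (length(shared) < 3L) stop("fewer than 3 shared segments")
  stats::cor(means_a[shared], means_b[shared], method = "spearman")
}
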