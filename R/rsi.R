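#' @title Repertoire Similarity Index
#' @description The RSI of a set of same-length CDR3 amino-acid sequences is
#'   `[1 - median(pairwise Levenshtein distance) / length] x 100`. High
#'   values flag sequence convergence or residual clonal expansion; the
#'   profile across germline segments and lengths verifies that regions of
#'   length-bias enrichment are not explained by expansion.
#' @name rsi
NULL

#' Levenshtein distance between two strings
#'
#' Minimum number of unit-cost substitutions, insertions and deletions.
#'
#' @param a,b character strings (vectorized over `b`).
#' @return integer distance(s).
#' @export
levenshtein <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' RSI of one set of same-length CDR3 sequences
#'
#' Median over all unordered pairs of Levenshtein distances, divided by the
#' common length, subtracted from 1 and expressed as a percentage. An even
#' pair count uses the interpolated (mid-point) median. Requires at least
#' two sequences.
#'
#' @param sequences character vector of CDR3 amino-acid strings, all of one
#'   length.
#' @return RSI percentage in `[0, 100]`.
#' @examples
#' rsi_of_set(c("ARDY", "ARDY", "ARDY"))  # 100
#' rsi_of_set(c("AAAA", "CCCC"))          # 0
#' @export
rsi_of_set <- function(sequences) {
  if (length(sequences) < 2L) stop("RSI is undefined for fewer than 2 sequences")
  n <- unique(nchar(sequences))
  if (length(n) != 1L) stop("RSI requires sequences of identical length")
  d <- utils::adist(sequences)
  med <- stats::median(d[upper.tri(d)])
  (1 - med / n) * 100
}

#' RSI profile across germline segments and CDR3 lengths
#'
#' For each donor, RSI is computed over the sequences sharing the same
#' `v_call`, the same partner segment (`vl_call` for paired repertoires,
#' `j_call` for heavy-only), and the same CDR3 length; values are then
#' averaged per (`v_call`, length) across partner groups and donors. Groups
#' below `min_set` sequences are skipped; cells with no qualifying group are
#' absent, not zero.
#'
#' @param records clonotype representatives (productive).
#' @param grouping `"by_VL"` or `"by_JH"`: the partner segment that, with
#'   `v_call` and length, defines each RSI set.
#' @param min_set minimum set size (default 3; a 2-element median is a single
#'   pair).
#' @return data.frame: `v_call`, `length`, `mean_rsi`, `sem`, `n_sets`.
#' @export
rsi_profile <- function(records, grouping = c("by_VL", "by_JH"), min_set = 3) {
  grouping <- match.arg(grouping)
  partner <- if (grouping == "by_VL") records$vl_call else records$j_call
  len <- nchar(records$cdr3_aa)
  key <- paste(records$donor_id, records$v_call, partner, len, sep = "\r")
  sets <- split(records$cdr3_aa, key)
  sizes <- lengths(sets)
  small <- sum(sizes < min_set)
  if (small) {
    message("rsi_profile: skipped ", small, " group(s) below ", min_set,
            " sequences")
  }
  sets <- sets[sizes >= min_set]
  if (!length(sets)) {
    warning("rsi_profile: no group reaches the minimum set size")
    return(data.frame(v_call = character(0), length = integer(0),
                      mean_rsi = numeric(0), sem = numeric(0),
                      n_sets = integer(0)))
  }
  vals <- vapply(sets, rsi_of_set, 0)
  info <- do.call(rbind, strsplit(names(vals), "\r", fixed = TRUE))
  cell <- paste(info[, 2], info[, 4], sep = "\r")
  out <- do.call(rbind, lapply(unique(cell), function(cl) {
    v <- vals[cell == cl]
    p <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    data.frame(v_call = p[1], length = as.integer(p[2]),
               mean_rsi = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_sets = length(v))
  }))
  out <- out[order(out$v_call, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
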