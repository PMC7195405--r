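#' @title Germline-conditioned CDR3 length distributions
#' @description Per-donor, germline-segment-conditioned CDR3 length
#'   spectratypes in percentages, the minimum-count filter, and the
#'   per-donor-then-average normalization used throughout: every statistic is
#'   computed within a donor first and then averaged, unweighted, across
#'   donors so that donors with deeper sequencing do not dominate.
#' @name distributions
NULL

#' Per-donor CDR3 length distributions
#'
#' Tabulates, for each (group, donor, compartment) cell, the percentage of
#' records at each CDR3 length. Records should be clonotype representatives
#' (nonproductive records, which bypass clonotyping, may be passed directly;
#' with `pool_donors = TRUE` donors are combined prior to calculation, the
#' convention used for nonproductive sequences).
#'
#' @param records data.frame of rearrangement records.
#' @param group_by `"overall"` (pool all segments), a single column name
#'   (e.g. `"v_call"`, `"vl_call"`), or a vector of columns
#'   (e.g. `c("v_call", "j_call")`).
#' @param pool_donors combine donors before tabulating (donor id becomes
#'   `"pooled"`).
#' @return data.frame: `group_key`, `donor_id`, `compartment`, `length`,
#'   `pct`, `n` (cell total). Percentages sum to 100 within each cell.
#' @export
length_distribution <- function(records, group_by = "overall",
                                pool_donors = FALSE) {
  if (nrow(records) == 0L) stop("no records: empty group for length_distribution")
  len <- cdr3_length(records)
  gk <- if (identical(group_by, "overall")) {
    rep("overall", nrow(records))
  } else {
    do.call(paste, c(unname(records[group_by]), sep = "|"))
  }
  donor <- if (pool_donors) "pooled" else records$donor_id
  cell <- paste(gk, donor, records$compartment, sep = "\r")
  out <- do.call(rbind, lapply(unique(cell), function(cl) {
    ix <- which(cell == cl)
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    tab <- table(len[ix])
    data.frame(group_key = parts[1], donor_id = parts[2],
               compartment = parts[3],
               length = as.integer(names(tab)),
               pct = 100 * as.numeric(tab) / length(ix),
               n = length(ix))
  }))
  rownames(out) <- NULL
  out
}

#' Minimum-count filter for germline-segment cells
#'
#' Drops (group, donor, compartment) cells whose total count is below
#' `min_n` (default 80: germline segments within a donor with fewer than 80
#' counts are excluded from analyses). Exclusions are reported in a message.
#'
#' @param distributions output of [length_distribution].
#' @param min_n minimum cell count; a cell with `n >= min_n` is retained.
#' @return filtered distributions data.frame.
#' @export
filter_min_count <- function(distributions, min_n = 80) {
  drop <- distributions$n < min_n
  if (any(drop)) {
    cells <- unique(paste(distributions$group_key[drop],
                          distributions$donor_id[drop], sep = "/"))
    message("filter_min_count: excluded ", length(cells),
            " cell(s) under ", min_n, " counts: ",
            paste(utils::head(cells, 8L), collapse = ", "),
            if (length(cells) > 8L) ", ..." else "")
  }
  distributions[!drop, , drop = FALSE]
}

#' Average length distributions across donors
#'
#' Unweighted mean (and SEM, `sd / sqrt(n_donors)`) of per-donor percentages
#' at each length, per (group, compartment). Donors missing a length
#' contribute 0% at that length. SEM is reported only with >= 2 donors; with
#' exactly 2 donors the SEM equals half the range, and `n_donors` lets
#' presentation code show the range instead.
#'
#' @param distributions output of [length_distribution] (optionally filtered).
#' @return data.frame: `group_key`, `compartment`, `length`, `mean_pct`,
#'   `sem_pct`, `n_donors`.
#' @export
average_across_donors <- function(distributions) {
  if (nrow(distributions) == 0L) stop("no donors to average")
  cell <- paste(distributions$group_key, distributions$compartment, sep = "\r")
  out <- do.call(rbind, lapply(unique(cell), function(cl) {
    d <- distributions[cell == cl, , drop = FALSE]
    donors <- unique(d$donor_id)
    lengths <- sort(unique(d$length))
    m <- matrix(0, length(donors), length(lengths),
                dimnames = list(donors, lengths))
    m[cbind(match(d$donor_id, donors), match(d$length, lengths))] <- d$pct
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    data.frame(group_key = parts[1], compartment = parts[2],
               length = lengths,
               mean_pct = colMeans(m),
               sem_pct = if (length(donors) >= 2L) {
                 apply(m, 2, stats::sd) / sqrt(length(donors))
               } else NA_real_,
               n_donors = length(donors))
  }))
  rownames(out) <- NULL
  out
}

#' Mean CDR3 length
#'
#' Arithmetic mean CDR3 length of records, or of a distribution data.frame
#' (percentage-weighted). Segment-level statistics should average per-donor
#' means (see [segment_mean_lengths]).
#'
#' @param x data.frame of records (with `cdr3_aa`/`cdr3_nt`) or a
#'   distribution data.frame with `length` and `pct` columns.
#' @return mean length, residues.
#' @export
mean_cdr3_length <- function(x) {
  if (!nrow(x)) stop("empty input to mean_cdr3_length")
  if (all(c("length", "pct") %in% names(x))) {
    sum(x$length * x$pct) / sum(x$pct)
  } else {
    mean(cdr3_length(x))
  }
}

#' Per-segment mean CDR3 lengths, per donor then averaged
#'
#' Computes each donor's mean CDR3 length per segment (cells under `min_n`
#' records excluded) and averages across donors, with SEM.
#'
#' @param records clonotype representatives.
#' @param group_by segment column, default `"v_call"`.
#' @param min_n minimum records per (segment, donor) cell.
#' @return data.frame: `group_key`, `compartment`, `mean_length`, `sem`,
#'   `n_donors`.
#' @export
segment_mean_lengths <- function(records, group_by = "v_call", min_n = 80) {
  len <- cdr3_length(records)
  gk <- do.call(paste, c(unname(records[group_by]), sep = "|"))
  cell <- paste(gk, records$compartment, records$donor_id, sep = "\r")
  per_donor <- vapply(split(len, cell), mean, 0)
  counts <- lengths(split(len, cell))
  per_donor <- per_donor[counts >= min_n]
  if (!length(per_donor)) stop("no (segment, donor) cell reaches min_n")
  parts <- do.call(rbind, strsplit(names(per_donor), "\r", fixed = TRUE))
  seg <- paste(parts[, 1], parts[, 2], sep = "\r")
  out <- do.call(rbind, lapply(unique(seg), function(s) {
    v <- per_donor[seg == s]
    p <- strsplit(s, "\r", fixed = TRUE)[[1]]
    data.frame(group_key = p[1], compartment = p[2],
               mean_length = mean(v),
               sem = if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n_donors = length(v))
  }))
  rownames(out) <- NULL
  out
}
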