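#' @title AIRR rearrangement table input/output
#' @description Readers and writers for the rearrangement-table dialect used
#'   throughout the package, plus the record-level validity rules shared by
#'   all analysis stages.
#' @name airr_io
NULL

# Fixed column order of the on-disk dialect. sim_* columns carry simulator
# ground truth and are optional.
.airr_columns <- c(
  "sequence_id", "donor_id", "compartment", "isotype",
  "v_call", "d_call", "j_call", "vl_call",
  "junction", "junction_aa", "productive",
  "cdr3_nt", "cdr3_aa",
  "sim_v_aa", "sim_n1_nt", "sim_d_nt", "sim_n2_nt",
  "sim_j_trim_nt", "sim_j_len_aa", "sim_j_positions", "sim_lineage_id"
)

.compartments <- c("naive", "AE", "AE_IgM", "nonproductive")
.isotypes <- c("IgM", "IgG", "IgA", "unknown")

#' CDR3 amino-acid length of a nonproductive (frameshifted) rearrangement
#'
#' Nonproductive junctions are not translated; their CDR3 length in residues
#' is defined as the nearest integer of the CDR3 nucleotide length divided by
#' three. Halves cannot arise (nt/3 never ends in .5); round-half-away-from-
#' zero is used and documented for completeness.
#'
#' @param cdr3_nt_length integer vector of CDR3 nucleotide lengths (>= 0).
#' @return integer vector of CDR3 lengths in amino-acid residues.
#' @examples
#' nonproductive_cdr3_aa_length(c(33, 34, 35))  # 11 11 12
#' @export
nonproductive_cdr3_aa_length <- function(cdr3_nt_length) {
  if (any(is.na(cdr3_nt_length)) || any(cdr3_nt_length < 0)) {
    stop("cdr3_nt_length must be non-negative and non-missing")
  }
  as.integer(floor(cdr3_nt_length / 3 + 0.5))
}

#' Validate rearrangement records
#'
#' Checks the record invariants: `v_call`, `donor_id` and `compartment`
#' present; productive records have a stop-free `cdr3_aa` and, when the
#' nucleotide CDR3 is present, `nchar(cdr3_nt) == 3 * nchar(cdr3_aa)`;
#' nonproductive records carry `cdr3_nt` (their length is defined from it)
#' and no `cdr3_aa`.
#'
#' @param records data.frame of rearrangement records.
#' @return logical vector, TRUE for valid rows.
#' @export
validate_rearrangements <- function(records) {
  ok <- !is.na(records$v_call) & nzchar(records$v_call) &
    !is.na(records$donor_id) & nzchar(records$donor_id) &
    !is.na(records$compartment) & records$compartment %in% .compartments
  prod <- !is.na(records$productive) & records$productive
  has_aa <- !is.na(records$cdr3_aa) & nzchar(records$cdr3_aa)
  ok_prod <- prod & has_aa &
    (is.na(records$cdr3_nt) |
       nchar(records$cdr3_nt) == 3L * nchar(records$cdr3_aa)) &
    !grepl("[*X]", records$cdr3_aa)
  ok_nonprod <- !prod & !has_aa & !is.na(records$cdr3_nt)
  ok & (ok_prod | ok_nonprod)
}

.strip_anchors <- function(x) {
  # IMGT junction = Cys-104 ... Trp/Phe-118; CDR3 drops the two anchors
  out <- ifelse(!is.na(x) & nchar(x) >= 2L, substr(x, 2L, nchar(x) - 1L), NA_character_)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

.strip_anchors_nt <- function(x) {
  out <- ifelse(!is.na(x) & nchar(x) >= 6L, substr(x, 4L, nchar(x) - 3L), NA_character_)
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Read a rearrangement table
#'
#' Reads a tab-separated rearrangement table (AIRR-style columns; see
#' [write_rearrangements] for the dialect) into a data.frame of records.
#' CDR3 strings are taken from `cdr3_aa`/`cdr3_nt` when present, otherwise
#' derived from `junction_aa`/`junction` by stripping the two IMGT anchor
#' residues (Cys-104, Trp/Phe-118). Rows failing the record invariants are
#' reported by `sequence_id` in a warning and skipped.
#'
#' @param path file path of a tab-separated rearrangement table.
#' @param dialect only `"airr_tsv"` is supported.
#' @return data.frame of validated rearrangement records.
#' @export
read_rearrangements <- function(path, dialect = "airr_tsv") {
  dialect <- match.arg(dialect, "airr_tsv")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = c("", "NA"), check.names = FALSE)
  required <- c("sequence_id", "v_call", "productive")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("rearrangement table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!any(c("junction_aa", "junction", "cdr3_aa", "cdr3_nt") %in% names(df))) {
    stop("rearrangement table is missing mandatory column: junction or junction_aa")
  }
  if (nrow(df) == 0L) {
    warning("empty rearrangement table: ", path)
    return(empty_rearrangements())
  }
  for (col in .airr_columns) if (is.null(df[[col]])) df[[col]] <- NA_character_
  df$productive <- toupper(df$productive) %in% c("T", "TRUE")
  if (all(is.na(df$cdr3_aa))) df$cdr3_aa <- .strip_anchors(df$junction_aa)
  if (all(is.na(df$cdr3_nt))) df$cdr3_nt <- .strip_anchors_nt(df$junction)
  df$cdr3_aa[!df$productive] <- NA_character_
  df$isotype[is.na(df$isotype)] <- "unknown"
  for (col in grep("^sim_.*(_nt|_aa$|_len_aa)", .airr_columns, value = TRUE)) {
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  }
  ok <- validate_rearrangements(df)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) failed validation and were skipped: ",
            paste(utils::head(df$sequence_id[!ok], 10L), collapse = ", "),
            if (sum(!ok) > 10L) ", ..." else "")
  }
  df <- df[ok, .airr_columns, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a rearrangement table
#'
#' Writes records as a tab-separated table with a fixed, documented column
#' order (`sequence_id`, `donor_id`, `compartment`, `isotype`, `v_call`,
#' `d_call`, `j_call`, `vl_call`, `junction`, `junction_aa`, `productive`,
#' `cdr3_nt`, `cdr3_aa`, then the `sim_*` ground-truth columns). Missing
#' optional fields are written as empty cells.
#'
#' @param records data.frame of rearrangement records.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_rearrangements <- function(records, path) {
  for (col in .airr_columns) if (is.null(records[[col]])) records[[col]] <- NA
  out <- records[, .airr_columns, drop = FALSE]
  out$productive <- ifelse(out$productive, "T", "F")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Empty record collection with the canonical columns
#' @return zero-row data.frame of rearrangement records.
#' @export
empty_rearrangements <- function() {
  df <- as.data.frame(stats::setNames(
    rep(list(character(0)), length(.airr_columns)), .airr_columns))
  df$productive <- logical(0)
  for (col in c("sim_v_aa", "sim_n1_nt", "sim_d_nt", "sim_n2_nt",
                "sim_j_trim_nt", "sim_j_len_aa")) df[[col]] <- integer(0)
  df
}

#' CDR3 amino-acid length of each record
#'
#' Productive records use `nchar(cdr3_aa)`; nonproductive records use the
#' nearest-integer nt/3 rule (see [nonproductive_cdr3_aa_length]).
#'
#' @param records data.frame of rearrangement records.
#' @return integer vector of CDR3 lengths in residues.
#' @export
cdr3_length <- function(records) {
  len <- integer(nrow(records))
  prod <- records$productive
  len[prod] <- nchar(records$cdr3_aa[prod])
  if (any(!prod)) {
    len[!prod] <- nonproductive_cdr3_aa_length(nchar(records$cdr3_nt[!prod]))
  }
  len
}
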