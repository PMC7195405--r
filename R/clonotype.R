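#' @title Clonotype collapsing
#' @description Collapses rearrangement records into clonotypes (inferred
#'   lineages) and retains one randomly chosen representative per clonotype.
#'   Three grouping rules are supported: `paired` (donor + VH + VL + CDR3
#'   length, then single-linkage clustering at >= 57% CDR3 amino-acid
#'   identity), `heavy` (donor + VH + JH + CDR3 length, same identity
#'   clustering), and `exact` (donor + VH + JH + CDR3 length + CDR3
#'   sequence). Isotype can be segregated prior to clustering.
#' @name clonotyping
NULL

#' Positional CDR3 amino-acid identity
#'
#' Fraction of positions with equal residues between two same-length
#' amino-acid strings. Clonotype candidates always share length; unequal
#' lengths are a contract violation.
#'
#' @param a,b amino-acid strings of equal length.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' cdr3_identity("AAAAAAA", "AAAAGGG")  # 4/7
#' @export
cdr3_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("cdr3_identity requires equal-length strings")
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  mean(x == y)
}

# single-linkage partition of same-length strings at identity >= threshold;
# returns integer cluster labels (union-find)
.single_linkage <- function(seqs, threshold) {
  m <- length(seqs)
  if (m == 1L) return(1L)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <- parent[parent[i]]; i }
  chars <- do.call(rbind, strsplit(seqs, ""))
  L <- ncol(chars)
  for (i in seq_len(m - 1L)) {
    ident <- rowMeans(chars[(i + 1L):m, , drop = FALSE] ==
                        matrix(chars[i, ], m - i, L, byrow = TRUE))
    for (j in which(ident >= threshold)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  labels <- vapply(seq_len(m), find, 1L)
  match(labels, unique(labels))
}

.v_subfamily <- function(v_call) sub("[-.].*$", "", v_call)

#' Cluster rearrangement records into clonotypes
#'
#' Partitions productive records by the grouping key of `mode` and, for the
#' `paired` and `heavy` modes, single-linkage clusters each partition at CDR3
#' amino-acid identity `>= identity` (single linkage because lineage
#' membership is transitive by descent). Nonproductive records are rejected:
#' they are never clonotype-clustered. With `wa_fallback = TRUE` (exact
#' mode), records whose `v_call` carries only subfamily information merge
#' with gene-level calls of the same subfamily and a missing `j_call` is
#' ignored; the representative draw then prefers fully annotated members.
#'
#' @param records data.frame of productive rearrangement records.
#' @param mode `"paired"`, `"heavy"` or `"exact"`.
#' @param identity identity threshold in `[0, 1]`; membership at
#'   `identity >= threshold` (default the nominal 0.57).
#' @param seed integer seed for the representative draw.
#' @param isotype_partition segregate isotypes prior to clustering (records
#'   with `isotype == "unknown"` are then excluded).
#' @param wa_fallback enable the ambiguous-call handling described above.
#' @return object of class `clonotype_set`: `records` (input plus
#'   `clone_id`), `clones` (one row per clonotype: `clone_id`, `n_members`,
#'   `representative_id`), `mode`, `identity`.
#' @export
cluster_clonotypes <- function(records, mode = c("paired", "heavy", "exact"),
                               identity = 0.57, seed = 1L,
                               isotype_partition = FALSE, wa_fallback = FALSE) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) {
    return(structure(list(records = records,
                          clones = data.frame(clone_id = character(0),
                                              n_members = integer(0),
                                              representative_id = character(0)),
                          mode = mode, identity = identity),
                     class = "clonotype_set"))
  }
  if (any(!records$productive)) {
    stop("nonproductive records must not be clonotype-clustered")
  }
  if (isotype_partition) {
    records <- records[records$isotype != "unknown", , drop = FALSE]
  }
  len <- nchar(records$cdr3_aa)
  v_key <- if (wa_fallback) .v_subfamily(records$v_call) else records$v_call
  partner <- switch(mode,
    paired = records$vl_call,
    heavy = records$j_call,
    exact = records$j_call)
  iso <- if (isotype_partition) records$isotype else ""
  if (wa_fallback) {
    # J dropped from the partition key; compatibility handled per sequence
    key <- paste(records$donor_id, v_key, len, iso, sep = "\r")
  } else {
    key <- paste(records$donor_id, v_key,
                 ifelse(is.na(partner), "<NA>", partner), len, iso, sep = "\r")
  }
  clone_of <- integer(nrow(records))
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    if (mode == "exact") {
      if (wa_fallback) {
        labs <- integer(length(idx))
        seqs <- records$cdr3_aa[idx]
        jc <- records$j_call[idx]
        jc[is.na(jc) | !nzchar(jc)] <- NA_character_
        used <- 0L
        for (s in unique(seqs)) {
          rows <- which(seqs == s)
          js <- unique(jc[rows][!is.na(jc[rows])])
          if (length(js) == 0L) js <- "*"
          grp <- match(jc[rows], js)
          grp[is.na(grp)] <- 1L   # missing J joins the first J group
          labs[rows] <- used + grp
          used <- used + length(js)
        }
        labs <- match(labs, unique(labs))
      } else {
        labs <- match(records$cdr3_aa[idx], unique(records$cdr3_aa[idx]))
      }
    } else {
      labs <- .single_linkage(records$cdr3_aa[idx], identity)
    }
    clone_of[idx] <- next_id + labs
    next_id <- next_id + max(labs)
  }
  records$clone_id <- sprintf("C%06d", clone_of)
  set.seed(as.integer(seed))
  groups <- split(seq_len(nrow(records)), records$clone_id)
  reps <- vapply(groups, function(ix) {
    if (wa_fallback) {
      full <- ix[grepl("-", records$v_call[ix]) &
                   !is.na(records$j_call[ix]) & nzchar(records$j_call[ix])]
      if (length(full)) ix <- full
    }
    records$sequence_id[ix[sample.int(length(ix), 1L)]]
  }, "")
  clones <- data.frame(clone_id = names(reps),
                       n_members = unname(lengths(groups)),
                       representative_id = unname(reps))
  rownames(clones) <- NULL
  structure(list(records = records, clones = clones, mode = mode,
                 identity = identity),
            class = "clonotype_set")
}

#' Representative records, one per clonotype
#'
#' @param clonotypes a `clonotype_set` from [cluster_clonotypes].
#' @return data.frame of rearrangement records (plus `clone_id`), one row per
#'   clonotype, in clone-id order.
#' @export
representatives <- function(clonotypes) {
  stopifnot(inherits(clonotypes, "clonotype_set"))
  rec <- clonotypes$records
  out <- rec[match(clonotypes$clones$representative_id, rec$sequence_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat("Clonotype set: ", nrow(x$clones), " clonotypes from ",
      nrow(x$records), " records (mode = ", x$mode,
      ", identity >= ", x$identity, ")\n", sep = "")
  invisible(x)
}
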