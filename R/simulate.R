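#' @title Synthetic VDJ-recombination repertoire generator
#' @description Generates multi-donor cohorts of heavy-chain rearrangement
#'   records with known germline-segment-dependent CDR3 length biases,
#'   trimming biases, nonproductive fractions and clonal expansion. Every
#'   record carries ground-truth junction annotation (`sim_*` columns), so
#'   downstream stages can be validated against the generative truth.
#' @name synthetic_repertoire
NULL

# one fixed codon per amino acid, used to reverse-translate germline motifs
.codon_of <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "AGT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

.aa_to_nt <- function(aa) {
  vapply(strsplit(aa, ""), function(ch) paste(.codon_of[ch], collapse = ""), "")
}

.rand_nt <- function(k) {
  total <- sum(k)
  if (total == 0L) return(rep("", length(k)))
  nts <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  grp <- factor(rep.int(seq_along(k), k), levels = seq_along(k))
  out <- vapply(split(nts, grp), paste, "", collapse = "")
  unname(out)
}

#' Default germline segment panels
#'
#' Panels of synthetic germline segments: each has a name, the amino-acid
#' motif it can contribute to the CDR3 (for J segments, the residues that can
#' occupy IMGT positions 114-117 and upstream; for V segments, residues at
#' 105-107), and the matching nucleotides. J motifs span 4 ("JH4", tail
#' `YFDY`) to 9 ("JH6") residues, the human range. D segments contribute
#' nucleotides only.
#'
#' @param n number of V-heavy (or light) segments.
#' @return data.frame with columns `name`, `cdr3_motif`, `nt_motif`.
#' @export
default_vh_segments <- function(n = 12) {
  # all motifs 3 residues so the pre-selection (and nonproductive) length
  # law is V-independent by construction
  motifs <- c("ARD", "AKD", "ARE", "ART", "ARG", "AGD", "ARS", "ASD",
              "ARV", "AKG", "ARL", "ATD", "ARW", "AVD", "ARQ", "AND")
  stopifnot(n <= length(motifs))
  data.frame(name = sprintf("VH%02d", seq_len(n)),
             cdr3_motif = motifs[seq_len(n)],
             nt_motif = .aa_to_nt(motifs[seq_len(n)]))
}

#' @rdname default_vh_segments
#' @export
default_jh_segments <- function() {
  motifs <- c(JH1 = "AEYFQH", JH2 = "YWYFDL", JH3 = "AFDI",
              JH4 = "YFDY", JH5 = "NWFDP", JH6 = "YYYYYGMDV")
  data.frame(name = names(motifs), cdr3_motif = unname(motifs),
             nt_motif = .aa_to_nt(unname(motifs)))
}

#' @rdname default_vh_segments
#' @export
default_dh_segments <- function() {
  data.frame(
    name = sprintf("DH%d", 1:5),
    cdr3_motif = NA_character_,
    nt_motif = c("GGTATAACTGGAACGAC", "GTATTACGATTTTTGGAGT", "GATATTGTAGTAGTACC",
                 "AGCATATTGTGGTGGTGA", "GGGTATAGCAGCAGCTGG"))
}

#' @rdname default_vh_segments
#' @export
default_vl_segments <- function(n = 10) {
  data.frame(name = sprintf("VL%02d", seq_len(n)),
             cdr3_motif = NA_character_, nt_motif = NA_character_)
}

#' Length-dependent selection bias
#'
#' Describes how repertoire selection reshapes the CDR3 length law for
#' rearrangements using a given germline segment (or VH/JH pair). The
#' accepted-set length law is a discretized skew-normal with optional
#' heavy-tail (kurtosis) mixing and an additive window spike; `kind =
#' "neutral"` accepts with constant probability.
#'
#' @param segment a `v_call` name, or `c(v_call, j_call)` pair, that the bias
#'   applies to; `NULL` applies to every record.
#' @param kind `"neutral"`, `"short"` or `"long"` (label only; the shape comes
#'   from the numeric parameters).
#' @param mean_shift target mean CDR3 length shift, residues.
#' @param skew skew-normal shape parameter (dimensionless; >0 skews long).
#' @param kurtosis_factor weight in `[0, 1)` of a 2.5x-wider component mixed
#'   in to raise tail weight (excess kurtosis) without moving the mean.
#' @param window_spike optional `list(lengths =, mass =)`: probability mass
#'   (fraction, e.g. 0.08) moved onto a uniform spike over `lengths`.
#' @param stage `"naive"` or `"AE"`: the maturation stage at which the bias
#'   acts. AE records pass the naive-stage then the AE-stage acceptance.
#' @return object of class `selection_bias`.
#' @export
selection_bias <- function(segment = NULL, kind = c("neutral", "short", "long"),
                           mean_shift = 0, skew = 0, kurtosis_factor = 0,
                           window_spike = NULL, stage = c("naive", "AE")) {
  kind <- match.arg(kind)
  stage <- match.arg(stage)
  stopifnot(kurtosis_factor >= 0, kurtosis_factor < 1)
  if (!is.null(window_spike)) {
    stopifnot(is.list(window_spike), window_spike$mass >= 0, window_spike$mass < 1)
  }
  structure(list(segment = segment, kind = kind, mean_shift = mean_shift,
                 skew = skew, kurtosis_factor = kurtosis_factor,
                 window_spike = window_spike, stage = stage),
            class = "selection_bias")
}

#' Target CDR3 length law of a selection bias
#'
#' Builds the discrete probability law over `support` that selection drives
#' the accepted set towards: a skew-normal density (location calibrated so the
#' discrete mean equals `base_mean + mean_shift`), mixed with a 2.5x-wider
#' component with weight `kurtosis_factor`, then mixed with a uniform window
#' spike of mass `window_spike$mass`.
#'
#' @param bias a [selection_bias].
#' @param support integer vector of CDR3 lengths (residues).
#' @param base_mean,base_sd location and scale of the unshifted law.
#' @return named numeric probability vector over `support` (sums to 1).
#' @export
build_length_law <- function(bias, support = 3:35, base_mean = 14.5, base_sd = 2) {
  pmf_at <- function(xi) {
    core <- function(sd) {
      z <- (support - xi) / sd
      stats::dnorm(z) * stats::pnorm(bias$skew * z)
    }
    p <- (1 - bias$kurtosis_factor) * core(base_sd) +
      bias$kurtosis_factor * core(2.5 * base_sd)
    p / sum(p)
  }
  target_mean <- base_mean + bias$mean_shift
  f <- function(xi) sum(support * pmf_at(xi)) - target_mean
  xi <- stats::uniroot(f, lower = min(support) - 5, upper = max(support) + 5)$root
  p <- pmf_at(xi)
  if (!is.null(bias$window_spike)) {
    w <- support %in% bias$window_spike$lengths
    stopifnot(any(w))
    spike <- ifelse(w, 1 / sum(w), 0)
    p <- (1 - bias$window_spike$mass) * p + bias$window_spike$mass * spike
  }
  stats::setNames(p, support)
}

#' Simulation configuration
#'
#' Bundles the germline panels, usage frequencies, trimming and N-addition
#' laws, selection biases, cohort layout and clonal-expansion law that define
#' a synthetic repertoire. Trimming is geometric per segment end (`p_trim_*`);
#' N-region lengths are Poisson (`lambda_n`). Defaults give 3 donors x
#' (5000 naive + 5000 antigen-experienced + 1000 nonproductive) with 12 VH,
#' 6 JH and 10 VL segments.
#'
#' @param donors character vector of donor ids.
#' @param n_naive,n_ae,n_nonproductive records per donor per compartment.
#' @param nonproductive_fraction optional probability in `[0,1]`; when set,
#'   each donor's nonproductive count is drawn Binomial(n_naive + n_ae, p)
#'   instead of being fixed at `n_nonproductive`.
#' @param vh,dh,jh,vl germline panels (see [default_vh_segments]).
#' @param vh_usage,dh_usage,jh_usage,vl_usage usage weights (recycled to the
#'   panel size; default mildly uneven).
#' @param p_trim_j,p_trim_d geometric trimming parameter per end.
#' @param lambda_n Poisson mean of each N-region length, nucleotides.
#' @param selection list of [selection_bias] objects.
#' @param extra_j_trim named integer vector: extra J trimming (nt) applied to
#'   productive rearrangements of the named `v_call`s, emulating selection of
#'   differentially trimmed J segments during naive maturation.
#' @param vj_coupling optional `list(vl =, jh =, weight =)`: records drawn
#'   with that `vl_call` re-draw their J with `weight` extra odds on `jh`.
#' @param expansion lineage-size law: `list(type = "fixed", size = k)` or
#'   `list(type = "geometric", prob = p)` (size = 1 + rgeom(p)).
#' @param mutation_rate per-residue substitution rate of expanded copies.
#' @param length_support,base_mean,base_sd CDR3 length grid and base law.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(donors = paste0("D", 1:3),
                       n_naive = 5000, n_ae = 5000, n_nonproductive = 1000,
                       nonproductive_fraction = NULL,
                       vh = default_vh_segments(), dh = default_dh_segments(),
                       jh = default_jh_segments(), vl = default_vl_segments(),
                       vh_usage = NULL, dh_usage = NULL, jh_usage = NULL,
                       vl_usage = NULL,
                       p_trim_j = 0.25, p_trim_d = 0.35, lambda_n = 4,
                       selection = list(),
                       extra_j_trim = NULL, vj_coupling = NULL,
                       expansion = list(type = "geometric", prob = 0.7),
                       mutation_rate = 0.02,
                       length_support = 3:35, base_mean = 14.5, base_sd = 2) {
  stopifnot(length(donors) >= 1, nrow(vh) >= 1, nrow(dh) >= 1,
            nrow(jh) >= 1, nrow(vl) >= 1)
  if (!is.null(nonproductive_fraction)) {
    stopifnot(nonproductive_fraction >= 0, nonproductive_fraction <= 1)
  }
  usage <- function(w, n) {
    if (is.null(w)) w <- seq(1.5, 1, length.out = n)
    w <- rep_len(w, n)
    stopifnot(all(w >= 0), sum(w) > 0)
    w / sum(w)
  }
  for (b in selection) stopifnot(inherits(b, "selection_bias"))
  structure(list(
    donors = donors, n_naive = n_naive, n_ae = n_ae,
    n_nonproductive = n_nonproductive,
    nonproductive_fraction = nonproductive_fraction,
    vh = vh, dh = dh, jh = jh, vl = vl,
    vh_usage = usage(vh_usage, nrow(vh)), dh_usage = usage(dh_usage, nrow(dh)),
    jh_usage = usage(jh_usage, nrow(jh)), vl_usage = usage(vl_usage, nrow(vl)),
    p_trim_j = p_trim_j, p_trim_d = p_trim_d, lambda_n = lambda_n,
    selection = selection, extra_j_trim = extra_j_trim,
    vj_coupling = vj_coupling, expansion = expansion,
    mutation_rate = mutation_rate,
    length_support = length_support, base_mean = base_mean, base_sd = base_sd),
    class = "sim_config")
}

# bias applying to (v_call, j_call) at a given stage, most specific wins
.find_bias <- function(config, v_call, j_call, stage) {
  best <- NULL
  best_spec <- -1L
  for (b in config$selection) {
    if (b$stage != stage) next
    seg <- b$segment
    spec <- if (is.null(seg)) 0L
      else if (length(seg) == 1L && seg == v_call) 1L
      else if (length(seg) == 2L && seg[1] == v_call && seg[2] == j_call) 2L
      else next
    if (spec > best_spec) { best <- b; best_spec <- spec }
  }
  best
}

.translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt),
                                     if.fuzzy.codon = "X"))
}

# Raw junction draws before selection: returns a data.frame of candidate
# junctions (productive frame not yet enforced).
.draw_junctions <- function(config, m, productive) {
  vi <- sample.int(nrow(config$vh), m, replace = TRUE, prob = config$vh_usage)
  di <- sample.int(nrow(config$dh), m, replace = TRUE, prob = config$dh_usage)
  ji <- sample.int(nrow(config$jh), m, replace = TRUE, prob = config$jh_usage)
  li <- sample.int(nrow(config$vl), m, replace = TRUE, prob = config$vl_usage)
  cp <- config$vj_coupling
  if (!is.null(cp)) {
    hit <- config$vl$name[li] == cp$vl
    if (any(hit)) {
      w <- config$jh_usage
      w[config$jh$name == cp$jh] <- w[config$jh$name == cp$jh] * (1 + cp$weight)
      ji[hit] <- sample.int(nrow(config$jh), sum(hit), replace = TRUE,
                            prob = w / sum(w))
    }
  }
  v_nt <- config$vh$nt_motif[vi]
  d_nt_full <- config$dh$nt_motif[di]
  j_nt_full <- config$jh$nt_motif[ji]
  d_len <- nchar(d_nt_full)
  tl <- pmin(stats::rgeom(m, config$p_trim_d), d_len)
  tr <- pmin(stats::rgeom(m, config$p_trim_d), d_len - tl)
  d_trimmed <- substr(d_nt_full, tl + 1L, d_len - tr)
  j_trim <- stats::rgeom(m, config$p_trim_j)
  if (productive && !is.null(config$extra_j_trim)) {
    extra <- config$extra_j_trim[config$vh$name[vi]]
    extra[is.na(extra)] <- 0L
    j_trim <- j_trim + as.integer(extra)
  }
  j_trim <- pmin(j_trim, nchar(j_nt_full))
  j_rem <- substr(j_nt_full, j_trim + 1L, nchar(j_nt_full))
  n1 <- stats::rpois(m, config$lambda_n)
  n2 <- stats::rpois(m, config$lambda_n)
  cdr3_nt <- paste0(v_nt, .rand_nt(n1), d_trimmed, .rand_nt(n2), j_rem)
  data.frame(
    v_call = config$vh$name[vi], d_call = config$dh$name[di],
    j_call = config$jh$name[ji], vl_call = config$vl$name[li],
    cdr3_nt = cdr3_nt,
    sim_v_aa = nchar(v_nt) %/% 3L, sim_n1_nt = n1,
    sim_d_nt = nchar(d_trimmed), sim_n2_nt = n2,
    sim_j_trim_nt = j_trim, sim_j_len_aa = nchar(j_nt_full) %/% 3L)
}

#' Ground-truth occupied IMGT positions of the J contribution
#'
#' For a J segment of `j_len_aa` residues trimmed by `j_trim_nt` nucleotides
#' at its 5' end, the intact germline codons are the last
#' `j_len_aa - ceiling(j_trim_nt / 3)` residues; in a productive junction the
#' germline J 3' end is codon-aligned, so these residues occupy the last CDR3
#' positions, right-aligned at IMGT 117. Returned as a `;`-separated string
#' of positions within 114-117 (suffix-closed by construction).
#'
#' @param j_len_aa J motif length, residues.
#' @param j_trim_nt nucleotides trimmed from the J 5' end.
#' @param cdr3_len_aa CDR3 length (positions below 118 - cdr3_len_aa do not
#'   exist and are excluded).
#' @return character vector, e.g. `"115;116;117"`.
#' @export
j_ground_truth_positions <- function(j_len_aa, j_trim_nt, cdr3_len_aa) {
  k <- pmax(0L, j_len_aa - as.integer(ceiling(j_trim_nt / 3)))
  mapply(function(ki, li) {
    pos <- 117L - seq_len(min(ki, 4L)) + 1L
    pos <- pos[pos >= 114L & pos > 117L - li]
    paste(sort(pos), collapse = ";")
  }, k, cdr3_len_aa)
}

#' Estimate the pre-selection CDR3 length law
#'
#' Monte-Carlo estimate of the productive CDR3 length distribution before any
#' selection, conditional on the segment(s) a bias applies to. Used to build
#' the acceptance function so that the accepted-set law equals the bias's
#' target law.
#'
#' @param config a [sim_config].
#' @param segment `NULL`, a `v_call`, or a `c(v_call, j_call)` pair.
#' @param n Monte-Carlo draws.
#' @return named probability vector over `config$length_support` (floored at
#'   1e-6 before normalization to keep the acceptance ratio finite).
#' @export
estimate_preselection_law <- function(config, segment = NULL, n = 6000) {
  # condition by forcing the segment's usage rather than filtering draws
  if (!is.null(segment)) {
    keep <- config$vh$name == segment[1]
    stopifnot(any(keep))
    config$vh <- config$vh[keep, , drop = FALSE]
    config$vh_usage <- 1
    if (length(segment) == 2L) {
      keep_j <- config$jh$name == segment[2]
      stopifnot(any(keep_j))
      config$jh <- config$jh[keep_j, , drop = FALSE]
      config$jh_usage <- 1
      config$vj_coupling <- NULL
    }
  }
  lens <- integer(0)
  while (length(lens) < n) {
    d <- .draw_junctions(config, 2L * n, productive = TRUE)
    len_nt <- nchar(d$cdr3_nt)
    d <- d[len_nt %% 3L == 0L & len_nt >= 9L, , drop = FALSE]
    if (nrow(d) == 0L) next
    aa <- .translate_nt(d$cdr3_nt)
    keep <- !grepl("[*X]", aa)
    lens <- c(lens, nchar(aa[keep]))
  }
  tab <- table(factor(lens[seq_len(n)], levels = config$length_support))
  p <- pmax(as.numeric(tab) / n, 1e-6)
  stats::setNames(p / sum(p), config$length_support)
}

#' Length-dependent selection of a productive rearrangement
#'
#' Acceptance-rejection against the bias's target length law. The acceptance
#' probability at CDR3 length `l` is
#' `a(l) = (target(l) / presel(l)) / max(target / presel)`, so the accepted
#' set follows the target law exactly; a neutral bias accepts with constant
#' probability 1.
#'
#' @param lengths integer vector of CDR3 lengths (residues) of productive
#'   records.
#' @param bias a [selection_bias] (or `NULL` for no selection).
#' @param preselection_law law from [estimate_preselection_law] (required for
#'   non-neutral biases).
#' @param config the [sim_config] (length grid and base law).
#' @return logical vector: accept each record.
#' @export
apply_selection <- function(lengths, bias, preselection_law = NULL,
                            config = sim_config()) {
  if (is.null(bias) || bias$kind == "neutral") {
    return(rep(TRUE, length(lengths)))
  }
  stopifnot(!is.null(preselection_law))
  target <- build_length_law(bias, config$length_support,
                             config$base_mean, config$base_sd)
  ratio <- target / preselection_law
  # normalize over lengths where both laws are estimated/meaningful: the
  # Monte-Carlo floor of the pre-selection law would otherwise let far-tail
  # ratios dominate and starve the segment of accepted records. Lengths the
  # generative process almost never reaches are capped at acceptance 1;
  # their target mass is < 1% in total, so the accepted law still matches
  # the target within the documented tolerance.
  reliable <- target >= 1e-3 & preselection_law >= 5e-3
  if (!any(reliable)) reliable <- target >= 1e-3
  M <- max(ratio[reliable])
  a <- pmin(1, ratio / M)
  idx <- match(lengths, config$length_support)
  p <- ifelse(is.na(idx), 0, a[idx])
  stats::runif(length(lengths)) < p
}

# accepted productive records for one donor/compartment; presel_laws is a
# cache of preselection laws keyed by bias segment.
.sample_productive <- function(config, n, donor_id, compartment, presel_laws) {
  out <- NULL
  stages <- if (compartment == "naive") "naive" else c("naive", "AE")
  while (is.null(out) || nrow(out) < n) {
    d <- .draw_junctions(config, max(4L * n, 2000L), productive = TRUE)
    len_nt <- nchar(d$cdr3_nt)
    d <- d[len_nt %% 3L == 0L & len_nt >= 9L, , drop = FALSE]
    aa <- .translate_nt(d$cdr3_nt)
    ok <- !grepl("[*X]", aa)
    d <- d[ok, , drop = FALSE]
    d$cdr3_aa <- aa[ok]
    len <- nchar(d$cdr3_aa)
    keep <- len %in% config$length_support
    d <- d[keep, , drop = FALSE]
    len <- len[keep]
    acc <- rep(TRUE, nrow(d))
    for (stage in stages) {
      for (key in unique(d$v_call)) {
        rows <- which(d$v_call == key & acc)
        if (!length(rows)) next
        # per-row bias lookup (may be keyed on v or v+j)
        for (j in unique(d$j_call[rows])) {
          rr <- rows[d$j_call[rows] == j]
          b <- .find_bias(config, key, j, stage)
          if (is.null(b) || b$kind == "neutral") next
          law_key <- paste(c(stage, b$segment), collapse = "|")
          if (is.null(presel_laws[[law_key]])) {
            assign(law_key, estimate_preselection_law(config, b$segment),
                   envir = presel_laws)
          }
          acc[rr] <- apply_selection(len[rr], b, presel_laws[[law_key]], config)
        }
      }
    }
    d <- d[acc, , drop = FALSE]
    out <- if (is.null(out)) d else rbind(out, d)
  }
  out <- out[seq_len(n), , drop = FALSE]
  out$donor_id <- donor_id
  out$compartment <- compartment
  out$productive <- TRUE
  out
}

.sample_nonproductive <- function(config, n, donor_id) {
  out <- NULL
  while (is.null(out) || nrow(out) < n) {
    d <- .draw_junctions(config, max(3L * n, 1000L), productive = FALSE)
    len_nt <- nchar(d$cdr3_nt)
    d <- d[len_nt %% 3L != 0L & len_nt >= 8L, , drop = FALSE]
    out <- if (is.null(out)) d else rbind(out, d)
  }
  out <- out[seq_len(n), , drop = FALSE]
  out$cdr3_aa <- NA_character_
  out$donor_id <- donor_id
  out$compartment <- "nonproductive"
  out$productive <- FALSE
  out
}

.mutate_cdr3 <- function(aa, nt, rate) {
  ch <- strsplit(aa, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(names(.codon_of), ch[i]), 1L)
    substr(nt, 3L * i - 2L, 3L * i) <- .codon_of[ch[i]]
  }
  list(aa = paste(ch, collapse = ""), nt = nt)
}

.expand_lineages <- function(records, config) {
  law <- config$expansion
  n <- nrow(records)
  sizes <- switch(law$type,
    fixed = rep(as.integer(law$size), n),
    geometric = 1L + stats::rgeom(n, law$prob),
    stop("unknown expansion law: ", law$type))
  records$sim_lineage_id <- paste0(records$donor_id, "_", records$compartment,
                                   "_L", seq_len(n))
  extra <- sizes - 1L
  if (!any(extra > 0L)) return(records)
  idx <- rep(which(extra > 0L), extra[extra > 0L])
  copies <- records[idx, , drop = FALSE]
  for (i in seq_len(nrow(copies))) {
    m <- .mutate_cdr3(copies$cdr3_aa[i], copies$cdr3_nt[i], config$mutation_rate)
    copies$cdr3_aa[i] <- m$aa
    copies$cdr3_nt[i] <- m$nt
  }
  rbind(records, copies)
}

#' Generate a synthetic multi-donor cohort
#'
#' Emits every donor and compartment of the configuration: productive naive
#' and antigen-experienced (AE) records (AE records pass the naive-stage and
#' then the AE-stage selection, so stage-specific biases are separately
#' injectable), nonproductive frameshifted records (junction length not a
#' multiple of 3, no selection), and clonal expansion (lineage copies with
#' point-mutated CDR3s). Deterministic given `seed`.
#'
#' @param config a [sim_config].
#' @param seed integer seed (mandatory).
#' @return list of class `sim_cohort`: `records` (data.frame, one row per
#'   sequence, with `sim_*` ground-truth columns), `truth` (per-bias target
#'   length laws and estimated pre-selection laws), `config`, `seed`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  presel_laws <- new.env(parent = emptyenv())
  parts <- list()
  for (donor in config$donors) {
    n_np <- config$n_nonproductive
    if (!is.null(config$nonproductive_fraction)) {
      n_np <- stats::rbinom(1L, config$n_naive + config$n_ae,
                            config$nonproductive_fraction)
    }
    if (config$n_naive > 0) {
      parts[[length(parts) + 1L]] <- .expand_lineages(
        .sample_productive(config, config$n_naive, donor, "naive", presel_laws),
        config)
    }
    if (config$n_ae > 0) {
      parts[[length(parts) + 1L]] <- .expand_lineages(
        .sample_productive(config, config$n_ae, donor, "AE", presel_laws),
        config)
    }
    if (n_np > 0) {
      np <- .sample_nonproductive(config, n_np, donor)
      np$sim_lineage_id <- NA_character_
      parts[[length(parts) + 1L]] <- np
    }
  }
  rec <- do.call(rbind, parts)
  rec$sequence_id <- sprintf("seq%06d", seq_len(nrow(rec)))
  rec$isotype <- ifelse(rec$compartment == "AE",
                        sample(c("IgG", "IgA"), nrow(rec), replace = TRUE,
                               prob = c(0.7, 0.3)), "IgM")
  rec$junction <- NA_character_
  rec$junction_aa <- NA_character_
  rec$sim_j_positions <- NA_character_
  prod <- rec$productive
  gt <- j_ground_truth_positions(
    rec$sim_j_len_aa[prod], rec$sim_j_trim_nt[prod], nchar(rec$cdr3_aa[prod]))
  gt[!nzchar(gt)] <- NA_character_   # fully trimmed J: no occupied position
  rec$sim_j_positions[prod] <- gt
  rec <- rec[, .airr_columns, drop = FALSE]
  rownames(rec) <- NULL
  truth <- list(
    target_laws = lapply(config$selection, function(b) {
      list(bias = b, law = build_length_law(b, config$length_support,
                                            config$base_mean, config$base_sd))
    }),
    preselection_laws = as.list(presel_laws))
  structure(list(records = rec, truth = truth, config = config, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic repertoire cohort (seed ", x$seed, ")\n", sep = "")
  cat("  donors:      ", paste(x$config$donors, collapse = ", "), "\n")
  tab <- table(x$records$compartment)
  cat("  records:     ", nrow(x$records), " (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
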