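---
title: "Methods: germline-conditioned CDR-H3 length analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germline-conditioned CDR-H3 length analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repspectra)
```

## Scope and model

`repspectra` analyzes the length repertoire of the antibody heavy-chain CDR3
(CDR-H3, IMGT positions 105–117) conditional on germline gene segments. The
observable for every analysis is the per-donor *spectratype*: the percentage
of clonotypes at each CDR-H3 length, within a (germline segment, donor,
compartment) cell. All cross-donor statistics follow one normalization rule:
**compute within a donor first, then average unweighted across donors**, so
sequencing depth never weights a donor. Cells with fewer than 80 clonotypes
in a donor are excluded (`filter_min_count`, `min_n = 80`).

Productive CDR3 lengths are residue counts of the translated CDR3 (the IMGT
junction minus the Cys-104 and Trp-118 anchors). Nonproductive (frameshifted)
rearrangements are not translatable; their length is defined as the nearest
integer of the nucleotide length over three
(`nonproductive_cdr3_aa_length`). Nonproductive records are a readout of the
recombination machinery *before* selection, so they are pooled across donors
and never clonotype-collapsed.

## Clonotype collapsing

A clonotype is the set of records sharing donor, germline calls and CDR-H3
length whose CDR3s are linked, single-linkage, at position-wise amino-acid
identity of at least 0.57 (`cluster_clonotypes`). Three key modes exist:
`"paired"` (donor, VH, VL, length), `"heavy"` (donor, VH, JH, length) and
`"exact"` (adds the CDR3 sequence itself, collapsing only true duplicates).
Single linkage is transitive: two sequences below the threshold belong to
one clonotype if a chain of above-threshold pairs connects them. Identity
0.57 sits between 4/7 (merged) and 3/7 (split) for length-7 CDR3s, the
shortest length where the distinction is common.

## Bias statistics

`sliding_window_ttest` localizes a segment's length bias: for each window of
two contiguous lengths, the per-donor statistic is the segment-minus-overall
frequency difference summed over the window, tested against zero with a
two-tailed one-sample (donor-paired) t-test. `compare_compartments` reports
the AE-minus-naive mean-length difference per segment, per donor then
averaged. `spearman_segments` rank-correlates per-segment mean lengths
between cohorts.

`pc_scores` eigendecomposes the covariance, across segments, of the
`n_segments x 22` matrix of mean percentages at lengths 5–26
(`build_matrix`; lengths outside the grid are dropped without
renormalizing). The sign convention fixes PC1 to correlate positively with
each row's third standardized moment and PC2 with the fourth, so PC1 orders
segments by apparent skewness and PC2 by tail weight.

The Repertoire Similarity Index of a set of same-length CDR3s is

\[ \mathrm{RSI} = \left(1 - \frac{\mathrm{median}\ d_{\mathrm{Lev}}(i,j)}{n}\right) \times 100, \]

the median running over all unordered pairs (`rsi_of_set`). High RSI flags
convergence or residual clonal structure; `rsi_profile` maps it over
(V segment, partner segment, length, donor) sets.

## The simulator

`generate_cohort` draws junctions segment by segment: a V motif contributes
the CDR3's first residues, a D nucleotide stretch and two N-regions (uniform
random nucleotides, Poisson(`lambda_n`) lengths) fill the middle, and a J
motif contributes the suffix after geometric 5'-trimming (`p_trim_j`).
Productive junctions are rejection-sampled to be in-frame and stop-free;
nonproductive junctions to be frameshifted. Because the germline J end is
codon-aligned, every *intact* J codon appears verbatim in the productive
CDR3 suffix — this is what makes suffix-based occupancy inference
(`infer_j_occupancy`) well-posed.

### Length-dependent selection

A `selection_bias` declares how selection reshapes a segment's length law:
the target is a discretized skew-normal over `length_support`, with the
location solved by `uniroot` so the *discrete* mean equals
`base_mean + mean_shift`, plus optional heavy-tail mixing and window spikes
(`build_length_law`). Sampling is acceptance–rejection: the acceptance
probability is proportional to `target / preselection`, where the
pre-selection law is estimated by seeded Monte Carlo with the segment's
usage forced (`estimate_preselection_law`). The proportionality constant is
the maximum ratio over the reliably estimated support, so the accepted law
equals the target exactly in expectation. Biases carry a `stage`:
naive-stage biases shape both compartments (antigen-experienced cells pass
naive selection first), AE-stage biases shape only the AE compartment —
reproducing naive/AE dissociation of a length bias.

One consequence matters for experiment design: a *neutral* segment follows
the pre-selection law, whose mean is set by trimming and N-addition, not by
`base_mean`. Recovering an injected `mean_shift` therefore requires a
*shaped control* — a second segment with the same law family and
`mean_shift = 0` — rather than a neutral one.

### Ground truth and the occupancy convention

Each record carries `sim_*` columns: junction component lengths, the
lineage id, and `sim_j_positions`, the IMGT 114–117 positions occupied by
untrimmed germline J residues. The convention is codon-based: a J codon
that lost one or two nucleotides to trimming counts as trimmed, and its
junction-completed residue is *not* germline-occupied
(`j_ground_truth_positions`); `junction_components` accordingly folds the
1–2 remaining nucleotides of a partial codon into the N2 count, so the
component lengths always sum to the CDR3 nucleotide length.

Suffix inference cannot reach this ground truth perfectly: when a partially
trimmed codon is completed by uniform random nucleotides, the germline
residue is recreated with probability roughly 1/4 (one missing nucleotide)
to 1/16 or more (two missing), and the matcher then claims one extra
position. With geometric trimming about half of trimmed junctions end in a
partial codon, so per-record agreement with ground truth plateaus around
95% at the default configuration (about 99% among full-codon trims, the
remainder being ordinary N-region mimicry at roughly one residue in
twenty). Aggregate occupancy profiles are therefore computed from either
source, selected by `use_ground_truth`.

## Worked example

A small cohort, end to end:

```{r example}
cfg <- sim_config(donors = c("D1", "D2", "D3"), n_naive = 300, n_ae = 600,
                  n_nonproductive = 100,
                  expansion = list(type = "fixed", size = 1))
pl <- suppressMessages(run_pipeline(cfg, seed = 1, min_count = 20))
pl
head(pl$averaged)
head(pl$bias_tests[order(pl$bias_tests$p_value), ])
```

The stages can equally be driven by hand — `read_rearrangements` on an
AIRR-style TSV, then `cluster_clonotypes`, `length_distribution`,
`filter_min_count`, `average_across_donors`, `sliding_window_ttest`,
`pc_scores`, `rsi_profile` and `occupancy_profile`.

## Problem sizes and limitations

The default configuration (3 donors, 5,000 clonotypes per compartment,
12 VH / 5 DH / 6 JH segments) runs in seconds and gives per-segment donor
cells of a few hundred records. At this scaled-down germline diversity,
(donor, V, J, length) keys are dense, and 57% single-linkage merges some
*independent* short CDR3s whose shared V motif and J suffix alone approach
the threshold; analyses that need a faithful record-to-clonotype map on
such cohorts should use `mode = "exact"` when no clonal expansion was
simulated. The simulator's germline motifs are synthetic stand-ins with
realistic lengths, not database alleles; all VH motifs deliberately share
one length so that the pre-selection (and nonproductive) length law is
V-independent by construction.
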