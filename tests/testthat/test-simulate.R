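no_noise_config <- function(...) {
  # degenerate trimming and N-addition; D nt chosen in-frame and stop-free
  sim_config(donors = "D1",
             dh = data.frame(name = "DH1", cdr3_motif = "GYS",
                             nt_motif = "GGTTATAGT"),
             p_trim_j = 1, p_trim_d = 1, lambda_n = 0, ...)
}

test_that("the no-noise limit concatenates the germline motifs exactly", {
  cfg <- no_noise_config(n_naive = 40, n_ae = 0, n_nonproductive = 0,
                         expansion = list(type = "fixed", size = 1))
  co <- generate_cohort(cfg, 5)
  rec <- co$records
  vh <- setNames(cfg$vh$cdr3_motif, cfg$vh$name)
  jh <- setNames(cfg$jh$cdr3_motif, cfg$jh$name)
  expect_identical(rec$cdr3_aa,
                   unname(paste0(vh[rec$v_call], "GYS", jh[rec$j_call])))
  expect_true(all(rec$sim_n1_nt == 0 & rec$sim_n2_nt == 0 &
                    rec$sim_j_trim_nt == 0))
  # untrimmed J: all of IMGT 114-117 occupied
  expect_true(all(rec$sim_j_positions == "114;115;116;117"))
})

test_that("J trimming removes 5'-most residues first (codon arithmetic)", {
  # trimming 3k nt removes exactly the first k residues of a 4-residue J
  expect_equal(j_ground_truth_positions(4L, 0L, 13L), "114;115;116;117")
  expect_equal(j_ground_truth_positions(4L, 3L, 13L), "115;116;117")
  expect_equal(j_ground_truth_positions(4L, c(1L, 2L, 3L), 13L),
               rep("115;116;117", 3))  # partial codon counts as trimmed
  expect_equal(j_ground_truth_positions(4L, 12L, 13L), "")
  # suffix-closedness: every emitted set is a contiguous run ending at 117
  for (tr in 0:15) {
    s <- j_ground_truth_positions(6L, tr, 14L)
    pos <- as.integer(strsplit(s, ";")[[1]])
    if (length(pos)) expect_equal(pos, seq(min(pos), 117L))
  }
})

test_that("geometric trimming and Poisson N-addition match their laws", {
  cfg <- sim_config(p_trim_j = 0.5, lambda_n = 4)
  set.seed(99)
  d <- repspectra:::.draw_junctions(cfg, 10000, productive = TRUE)
  # capped only at the full J length; cap mass is negligible at p = 0.5
  se_trim <- sqrt((1 - 0.5) / 0.5^2 / 10000)
  expect_lt(abs(mean(d$sim_j_trim_nt) - (1 - 0.5) / 0.5), 3 * se_trim + 0.01)
  se_n <- sqrt(4 / 10000)
  expect_lt(abs(mean(d$sim_n1_nt) - 4), 3 * se_n)
  expect_lt(abs(mean(d$sim_n2_nt) - 4), 3 * se_n)
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- sim_config(donors = "D1", n_naive = 60, n_ae = 40,
                    n_nonproductive = 30)
  a <- generate_cohort(cfg, 123)$records
  b <- generate_cohort(cfg, 123)$records
  expect_identical(a, b)
  c <- generate_cohort(cfg, 124)$records
  expect_false(identical(a, c))
})

test_that("nonproductive draws are frameshifted and carry no protein CDR3", {
  rec <- tiny_cohort()$records
  np <- rec[!rec$productive, ]
  expect_true(all(nchar(np$cdr3_nt) %% 3 != 0))
  expect_true(all(is.na(np$cdr3_aa)))
  prod <- rec[rec$productive, ]
  expect_true(all(nchar(prod$cdr3_nt) == 3 * nchar(prod$cdr3_aa)))
  expect_false(any(grepl("[*X]", prod$cdr3_aa)))
})

test_that("nonproductive_fraction draws a binomial nonproductive count", {
  cfg <- sim_config(donors = "D1", n_naive = 1000, n_ae = 0,
                    nonproductive_fraction = 0.1,
                    expansion = list(type = "fixed", size = 1))
  co <- generate_cohort(cfg, 7)
  k <- sum(!co$records$productive)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("neutral selection accepts with constant probability", {
  b <- selection_bias(kind = "neutral")
  expect_true(all(apply_selection(5:30, b)))
})

test_that("selection drives the accepted set to the configured target law", {
  bias <- selection_bias("VH01", "short", mean_shift = -1.5)
  cfg <- sim_config(donors = "D1", n_naive = 6000, n_ae = 0,
                    n_nonproductive = 0, vh_usage = c(6, rep(1, 11)),
                    selection = list(bias),
                    expansion = list(type = "fixed", size = 1))
  co <- generate_cohort(cfg, 31)
  lens <- nchar(co$records$cdr3_aa[co$records$v_call == "VH01"])
  law <- build_length_law(bias, cfg$length_support, cfg$base_mean, cfg$base_sd)
  emp <- as.numeric(table(factor(lens, levels = cfg$length_support))) /
    length(lens)
  expect_gt(length(lens), 400)
  expect_lt(0.5 * sum(abs(emp - law)), 0.1)   # Monte-Carlo scale tolerance
  expect_lt(abs(mean(lens) - sum(cfg$length_support * law)), 0.3)
})

test_that("lineage expansion replicates clonotypes within the identity radius", {
  cfg <- sim_config(donors = "D1", n_naive = 150, n_ae = 0,
                    n_nonproductive = 0,
                    expansion = list(type = "fixed", size = 4))
  co <- generate_cohort(cfg, 17)
  rec <- co$records
  expect_equal(nrow(rec), 600)
  expect_equal(length(unique(rec$sim_lineage_id)), 150)
  # copies keep the founder's length and stay close in sequence
  for (lid in sample(unique(rec$sim_lineage_id), 20)) {
    members <- rec$cdr3_aa[rec$sim_lineage_id == lid]
    expect_length(unique(nchar(members)), 1L)
    expect_gte(cdr3_identity(members[1], members[length(members)]), 0.57)
  }
})
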