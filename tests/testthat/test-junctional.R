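test_that("suffix matching against the J motif follows the worked examples", {
  # JH4 motif YFDY: full match occupies 114-117
  r <- infer_j_occupancy("ARDGYFDY", "YFDY")
  expect_equal(r$positions, 114:117)
  expect_equal(r$k, 4L)
  expect_false(r$truncated)
  # first motif residue replaced: only the 3-residue suffix matches
  expect_equal(infer_j_occupancy("ARDGWFDY", "YFDY")$positions, 115:117)
  expect_equal(infer_j_occupancy("ARDGYFDW", "YFDY")$positions, integer(0))
  # a long J motif can match deeper than 114 but positions clip to 114-117
  long <- infer_j_occupancy("ARYYYYYGMDV", "YYYYYGMDV")
  expect_equal(long$k, 9L)
  expect_equal(long$positions, 114:117)
  # short CDR3s clip positions that do not exist (position > 117 - length)
  short <- infer_j_occupancy("FDY", "YFDY")
  expect_equal(short$k, 3L)
  expect_equal(short$positions, 115:117)
  expect_true(short$truncated)
})

test_that("the vectorized suffix matcher agrees with the scalar one", {
  set.seed(5)
  motifs <- default_jh_segments()$cdr3_motif
  seqs <- c(rand_aa(150, 12), paste0(rand_aa(50, 6), "YFDY"), "YFDY", "Y")
  for (m in motifs) {
    kv <- repspectra:::.suffix_match_len(seqs, m)
    ks <- vapply(seqs, function(s) infer_j_occupancy(s, m)$k, 0L)
    expect_equal(kv, unname(ks))
  }
})

test_that("occupancy decreases monotonically from 117 toward 114 in aggregate", {
  rec <- tiny_cohort()$records
  prod <- rec[rec$productive, ]
  jt <- sort(table(prod$j_call), decreasing = TRUE)
  j <- names(jt)[1]
  vt <- sort(table(prod$v_call[prod$j_call == j]), decreasing = TRUE)
  prof <- occupancy_profile(prod, v_call = names(vt)[1], j_call = j,
                            min_n = 5, use_ground_truth = TRUE)
  expect_s3_class(prof, "occupancy_profile")
  # trimming removes 5'-most J residues first, so occupancy at position p
  # cannot exceed occupancy at p+1 within a length cell
  for (l in unique(prof$reference$length)) {
    cell <- prof$reference[prof$reference$length == l, ]
    cell <- cell[order(cell$position), ]
    expect_true(all(diff(cell$occupancy) >= 0))
  }
  expect_output(print(prof), "occupancy")
})

test_that("cells under min_n sequences are excluded from the profile", {
  rec <- make_records(c(rep("ARDGYFDY", 90), rep("ARDAGYFDY", 10)),
                      v_call = "VH01", j_call = "JH4")
  prof <- occupancy_profile(rec, "VH01", "JH4", min_n = 80)
  expect_setequal(prof$profile$length, 8L)  # length-9 cell has n = 10 < 80
  expect_true(all(prof$profile$occupancy == 1))
  expect_error(occupancy_profile(rec, "VH01", "ZZ9"), "no motif")
  expect_warning(occupancy_profile(rec, "VH99", "JH4", min_n = 80), "under 80")
})

test_that("ground-truth and inferred occupancy coincide in the no-noise limit", {
  cfg <- sim_config(donors = "D1", n_naive = 120, n_ae = 0, n_nonproductive = 0,
                    dh = data.frame(name = "DH1", cdr3_motif = "GYS",
                                    nt_motif = "GGTTATAGT"),
                    p_trim_j = 1, p_trim_d = 1, lambda_n = 0,
                    expansion = list(type = "fixed", size = 1))
  rec <- generate_cohort(cfg, 9)$records
  jt <- sort(table(rec$j_call), decreasing = TRUE)
  j <- names(jt)[1]
  v <- names(sort(table(rec$v_call[rec$j_call == j]), decreasing = TRUE))[1]
  gt <- occupancy_profile(rec, v, j, min_n = 1, use_ground_truth = TRUE)
  inf <- occupancy_profile(rec, v, j, min_n = 1, use_ground_truth = FALSE)
  expect_equal(inf$profile, gt$profile)
  expect_true(all(gt$profile$occupancy == 1))  # untrimmed J occupies fully
})

test_that("J usage conditional on V averages per donor and sums to one", {
  rec <- rbind(
    make_records(rand_aa(40, 10), v_call = "VH01",
                 j_call = rep(c("JH4", "JH6"), c(30, 10)),
                 donor_id = "D1"),
    make_records(rand_aa(40, 10), v_call = "VH01",
                 j_call = rep(c("JH4", "JH6"), c(10, 30)),
                 donor_id = "D2"),
    make_records(rand_aa(20, 10), v_call = "VH02", j_call = "JH4",
                 donor_id = rep(c("D1", "D2"), each = 10)))
  u <- jh_usage_by_segment(rec)
  v1 <- u[u$segment == "VH01", ]
  # unweighted donor average: (0.75 + 0.25) / 2 for each J
  expect_equal(v1$mean_prop[v1$j_call == "JH4"], 0.5)
  expect_equal(v1$mean_prop[v1$j_call == "JH6"], 0.5)
  expect_equal(u$mean_prop[u$segment == "VH02" & u$j_call == "JH4"], 1)
  sums <- tapply(u$mean_prop, u$segment, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # overall usage is identical in every segment block
  expect_equal(unique(split(u$overall_prop, u$j_call)$JH4),
               unname(tapply(u$overall_prop[u$j_call == "JH4"],
                             u$segment[u$j_call == "JH4"], unique))[[1]])
})

test_that("junction components account for every CDR3 nucleotide", {
  rec <- tiny_cohort()$records
  prod <- rec[rec$productive, ]
  jc <- junction_components(prod)
  expect_equal(3L * (jc$v_aa + jc$j_aa) + jc$n1_nt + jc$d_nt + jc$n2_nt,
               nchar(prod$cdr3_nt))
  # partial J codons are folded into N2, never into j_aa
  expect_true(all(jc$j_aa == (3L * prod$sim_j_len_aa - prod$sim_j_trim_nt) %/% 3L))
  expect_error(junction_components(make_records("ARDY")), "ground-truth")
})
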