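# helper: per-donor distributions for hand-built percentage matrices
dist_from_matrix <- function(m, group_key = "VH01") {
  lengths <- as.integer(colnames(m))
  do.call(rbind, lapply(rownames(m), function(dn) {
    data.frame(group_key = group_key, donor_id = dn, compartment = "AE",
               length = lengths, pct = m[dn, ], n = 1000L)
  }))
}

test_that("the window statistic equals the hand-computed paired difference", {
  lens <- as.character(9:12)
  seg <- matrix(c(30, 30, 20, 20,
                  32, 28, 22, 18,
                  28, 32, 18, 22), 3, 4, byrow = TRUE,
                dimnames = list(c("D1", "D2", "D3"), lens))
  ovl <- matrix(25, 3, 4, dimnames = dimnames(seg))
  res <- sliding_window_ttest(dist_from_matrix(seg), dist_from_matrix(ovl, "overall"),
                              alpha = 0.05)
  expect_equal(res$window_start, 9:11)
  # window (9,10): per-donor diff sums are (10, 10, 10)
  expect_equal(res$mean_diff[res$window_start == 9], 10)
  expect_true(res$degenerate[res$window_start == 9])  # zero variance
  expect_equal(res$p_value[res$window_start == 9], 1)
  # window (10,11): per-donor sums are (0, 0, 0) -> degenerate too
  d <- (seg - ovl)[, 2] + (seg - ovl)[, 3]
  expect_equal(res$mean_diff[res$window_start == 10], mean(d))
  # directions follow the sign of the mean difference
  expect_equal(res$direction, ifelse(res$mean_diff > 0, "enriched", "depleted"))
})

test_that("p-values agree with stats::t.test and respect alpha", {
  set.seed(42)
  lens <- as.character(8:13)
  seg <- matrix(25 + rnorm(30), 5, 6,
                dimnames = list(paste0("D", 1:5), lens))
  ovl <- matrix(25, 5, 6, dimnames = dimnames(seg))
  res <- sliding_window_ttest(dist_from_matrix(seg),
                              dist_from_matrix(ovl, "overall"), alpha = 0.05)
  for (i in seq_len(nrow(res))) {
    w <- res$window_start[i]
    d <- seg[, as.character(w)] + seg[, as.character(w + 1)] - 50
    expect_equal(res$p_value[i], stats::t.test(d, mu = 0)$p.value)
  }
  expect_equal(res$significant, !res$degenerate & res$p_value < 0.05)
})

test_that("donor coverage is validated", {
  seg <- matrix(c(50, 50, 50, 50), 2, 2,
                dimnames = list(c("D1", "D2"), c("10", "11")))
  ovl <- matrix(50, 2, 2, dimnames = list(c("D1", "D3"), c("10", "11")))
  expect_error(sliding_window_ttest(dist_from_matrix(seg),
                                    dist_from_matrix(ovl, "overall")),
               "same donors")
  one <- dist_from_matrix(seg["D1", , drop = FALSE])
  expect_error(sliding_window_ttest(one, one), ">= 2 donors")
})

test_that("an injected window enrichment is localized at the right lengths", {
  # 6 donors from a common multinomial law, VH01 given +12pp at lengths 9-10
  set.seed(7)
  support <- 5:26
  base <- stats::dnorm(support, 14.5, 2); base <- base / sum(base)
  spike <- base
  spike[support %in% 9:10] <- spike[support %in% 9:10] + 0.06
  spike <- spike / sum(spike)
  mk <- function(law, gk) {
    do.call(rbind, lapply(paste0("D", 1:6), function(dn) {
      x <- as.numeric(stats::rmultinom(1, 4000, law))
      data.frame(group_key = gk, donor_id = dn, compartment = "AE",
                 length = support, pct = 100 * x / sum(x), n = 4000L)
    }))
  }
  res <- sliding_window_ttest(mk(spike, "VH01"), mk(base, "overall"),
                              alpha = 1e-4)
  hits <- res$window_start[res$significant & res$direction == "enriched"]
  expect_true(all(c(8, 9, 10) %in% hits))
})

test_that("compare_compartments recovers a known AE shift per segment", {
  rec <- rbind(
    make_records(rand_aa(200, 14), donor_id = rep(c("D1", "D2"), each = 100),
                 compartment = "naive", v_call = "VH01"),
    make_records(rand_aa(200, 12), donor_id = rep(c("D1", "D2"), each = 100),
                 compartment = "AE", v_call = "VH01"),
    make_records(rand_aa(200, 13), donor_id = rep(c("D1", "D2"), each = 100),
                 compartment = "naive", v_call = "VH02"),
    make_records(rand_aa(200, 13), donor_id = rep(c("D1", "D2"), each = 100),
                 compartment = "AE", v_call = "VH02"))
  cc <- compare_compartments(rec)
  expect_equal(cc$mean_diff[cc$group_key == "VH01"], -2)
  expect_equal(cc$mean_diff[cc$group_key == "VH02"], 0)
  expect_equal(cc$n_donors, c(2L, 2L))
  # a segment present in only one compartment is excluded with a message
  rec2 <- rbind(rec, make_records(rand_aa(100, 10), compartment = "naive",
                                  v_call = "VH03"))
  expect_message(cc2 <- compare_compartments(rec2), "VH03")
  expect_false("VH03" %in% cc2$group_key)
})

test_that("spearman_segments is rank-based over the shared segments", {
  a <- c(VH01 = 12, VH02 = 14, VH03 = 16, VH04 = 13)
  b <- c(VH02 = 140, VH03 = 160, VH04 = 130, VH01 = 120, VH99 = 1)
  expect_equal(spearman_segments(a, b), 1)
  # a monotone-decreasing relabeling gives -1 (rank, not linear, correlation)
  expect_equal(spearman_segments(a, -b[names(a)]^3), -1)
  expect_error(spearman_segments(a[1:2], b), "3 shared")
})
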