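# Independent oracles and fixture builders shared across tests.

# textbook dynamic-programming Levenshtein distance, independent of adist
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# brute-force RSI: enumerate all unordered pairs, interpolated median
rsi_brute <- function(sequences) {
  n <- nchar(sequences[1])
  ds <- c()
  for (i in seq_len(length(sequences) - 1)) {
    for (j in (i + 1):length(sequences)) {
      ds <- c(ds, lev_dp(sequences[i], sequences[j]))
    }
  }
  ds <- sort(ds)
  k <- length(ds)
  med <- if (k %% 2 == 1) ds[(k + 1) / 2] else (ds[k / 2] + ds[k / 2 + 1]) / 2
  (1 - med / n) * 100
}

rand_aa <- function(n, len, alphabet = LETTERS[1:20]) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

# minimal valid productive record table from parallel vectors
make_records <- function(cdr3_aa, donor_id = "D1", compartment = "naive",
                         v_call = "VH01", j_call = "JH4", vl_call = "VL01",
                         isotype = "IgM") {
  n <- length(cdr3_aa)
  df <- empty_rearrangements()[0, ]
  out <- data.frame(
    sequence_id = sprintf("s%05d", seq_len(n)),
    donor_id = rep_len(donor_id, n), compartment = rep_len(compartment, n),
    isotype = rep_len(isotype, n),
    v_call = rep_len(v_call, n), d_call = "DH1",
    j_call = rep_len(j_call, n), vl_call = rep_len(vl_call, n),
    junction = NA_character_, junction_aa = NA_character_,
    productive = TRUE,
    cdr3_nt = repspectra:::.aa_to_nt(cdr3_aa), cdr3_aa = cdr3_aa,
    sim_v_aa = NA_integer_, sim_n1_nt = NA_integer_, sim_d_nt = NA_integer_,
    sim_n2_nt = NA_integer_, sim_j_trim_nt = NA_integer_,
    sim_j_len_aa = NA_integer_, sim_j_positions = NA_character_,
    sim_lineage_id = NA_character_)
  out[names(df)]
}

# brute-force single-linkage clonotype oracle, independent of the package's
# union-find: same (donor, V, J, CDR3 length) key, then transitive closure
# of pairs with position-wise identity >= threshold
cluster_oracle_count <- function(records, threshold = 0.57) {
  key <- paste(records$donor_id, records$v_call, records$j_call,
               nchar(records$cdr3_aa))
  total <- 0L
  for (k in unique(key)) {
    seqs <- records$cdr3_aa[key == k]
    n <- length(seqs)
    grp <- seq_len(n)
    if (n > 1L) {
      for (i in 1:(n - 1)) {
        xi <- strsplit(seqs[i], "")[[1]]
        for (j in (i + 1):n) {
          id <- mean(xi == strsplit(seqs[j], "")[[1]])
          if (id >= threshold) grp[grp == grp[j]] <- grp[i]
        }
      }
    }
    total <- total + length(unique(grp))
  }
  total
}

# small simulated cohort shared by several tests (lazy, built once)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(donors = c("D1", "D2"), n_naive = 250, n_ae = 250,
                        n_nonproductive = 120,
                        expansion = list(type = "fixed", size = 1))
      cache <<- generate_cohort(cfg, seed = 20240801)
    }
    cache
  }
})
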