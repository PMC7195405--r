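#' @title End-to-end pipeline
#' @description Runs simulate -> clonotype -> distributions -> bias tests ->
#'   PCA -> RSI -> junctional analyses with one configuration and one seed,
#'   writing tidy TSV outputs and a run manifest. A single global seed fans
#'   out to fixed per-stage child seeds (`seed + stage offset`, offsets 0,
#'   1000, 2000, ...) so each stage is independently reproducible.
#' @name pipeline
NULL

#' Run the full repertoire analysis pipeline
#'
#' @param config a [sim_config] (the simulated cohort stands in for a real
#'   rearrangement table; pass `records` to analyze an existing table
#'   instead).
#' @param seed global integer seed.
#' @param outdir output directory (created if needed); TSVs for each stage
#'   and `manifest.json` are written there.
#' @param records optional data.frame of rearrangement records; when given,
#'   the simulation stage is skipped.
#' @param clonotype_mode grouping rule passed to [cluster_clonotypes].
#' @param min_count minimum per-donor segment count (default 80).
#' @param alpha sliding-window significance threshold (default 1e-4).
#' @return list of class `rep_pipeline`: stage results plus `manifest`
#'   (config hash, seed, per-stage record counts, output files).
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, outdir = NULL,
                         records = NULL, clonotype_mode = "heavy",
                         min_count = 80, alpha = 1e-4) {
  seeds <- as.integer(seed) + c(simulate = 0L, clonotype = 1000L, rsi = 2000L)
  counts <- list()
  files <- character(0)
  emit <- function(df, name) {
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      f <- file.path(outdir, paste0(name, ".tsv"))
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, f)
    }
  }
  if (is.null(records)) {
    cohort <- generate_cohort(config, seeds["simulate"])
    records <- cohort$records
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      f <- file.path(outdir, "cohort.tsv")
      write_rearrangements(records, f)
      files <- c(files, f)
    }
  }
  counts$records <- nrow(records)

  prod <- records[records$productive, , drop = FALSE]
  nonprod <- records[!records$productive, , drop = FALSE]
  clono <- cluster_clonotypes(prod, mode = clonotype_mode,
                              seed = seeds["clonotype"])
  reps <- representatives(clono)
  counts$clonotypes <- nrow(reps)
  counts$nonproductive <- nrow(nonprod)
  emit(clono$clones, "clonotypes")

  dist_seg <- length_distribution(reps, group_by = "v_call")
  dist_all <- length_distribution(reps, group_by = "overall")
  dist_seg_f <- suppressMessages(filter_min_count(dist_seg, min_count))
  avg_seg <- average_across_donors(dist_seg_f)
  emit(dist_seg_f, "distributions_segment")
  emit(avg_seg, "distributions_averaged")
  counts$segment_cells <- length(unique(paste(dist_seg_f$group_key,
                                              dist_seg_f$donor_id,
                                              dist_seg_f$compartment)))

  ae_seg <- dist_seg_f[dist_seg_f$compartment == "AE", , drop = FALSE]
  ae_all <- dist_all[dist_all$compartment == "AE", , drop = FALSE]
  bias <- NULL
  if (nrow(ae_seg) && length(unique(ae_all$donor_id)) >= 2L) {
    bias <- do.call(rbind, lapply(unique(ae_seg$group_key), function(s) {
      seg_d <- ae_seg[ae_seg$group_key == s, , drop = FALSE]
      donors <- unique(seg_d$donor_id)
      if (length(donors) < 2L) return(NULL)  # paired test needs >= 2 donors
      sliding_window_ttest(seg_d,
                           ae_all[ae_all$donor_id %in% donors, , drop = FALSE],
                           alpha = alpha)
    }))
    if (!is.null(bias)) emit(bias, "bias_tests")
  }

  ae_avg <- avg_seg[avg_seg$compartment == "AE", , drop = FALSE]
  pca <- NULL
  if (length(unique(ae_avg$group_key)) >= 3L) {
    pca <- pc_scores(build_matrix(ae_avg))
    emit(data.frame(segment = rownames(pca$scores),
                    pca$scores[, 1:min(4, ncol(pca$scores)), drop = FALSE]),
         "pca_scores")
  }

  set.seed(seeds["rsi"])
  rsi <- suppressMessages(
    rsi_profile(reps[reps$compartment == "AE", , drop = FALSE],
                grouping = "by_JH"))
  emit(rsi, "rsi_profile")

  jh_usage <- jh_usage_by_segment(reps)
  emit(jh_usage, "jh_usage")

  np_dist <- NULL
  if (nrow(nonprod)) {
    np_dist <- length_distribution(nonprod, group_by = "overall",
                                   pool_donors = TRUE)
    emit(np_dist, "nonproductive_distribution")
  }

  manifest <- list(seed = as.integer(seed), stage_seeds = as.list(seeds),
                   counts = counts, files = files,
                   config_hash = .config_hash(config))
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(records = records, clonotypes = clono,
                 representatives = reps,
                 distributions = dist_seg_f, averaged = avg_seg,
                 overall = dist_all, bias_tests = bias, pca = pca,
                 rsi = rsi, jh_usage = jh_usage,
                 nonproductive_distribution = np_dist,
                 manifest = manifest),
            class = "rep_pipeline")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

#' @export
print.rep_pipeline <- function(x, ...) {
  m <- x$manifest$counts
  cat("Repertoire analysis pipeline run (seed ", x$manifest$seed, ")\n",
      "  records: ", m$records, "; clonotypes: ", m$clonotypes,
      "; nonproductive: ", m$nonproductive, "\n", sep = "")
  if (!is.null(x$bias_tests)) {
    cat("  significant bias windows: ", sum(x$bias_tests$significant), "\n",
        sep = "")
  }
  invisible(x)
}
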