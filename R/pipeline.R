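# Orchestration: each run_* function is one pipeline stage reading and
# writing the package's plain-text formats, deterministic for a given seed.
# The inst/scripts/coexsum wrapper exposes them as shell subcommands.

#' Generate a full set of synthetic fixtures on disk
#'
#' Writes an expression panel (with tissue annotation), a count matrix, a
#' promoter FASTA and a membrane-profile trace table, each with its truth
#' record as JSON, into `out_dir`. Deterministic per `seed`.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving all four generators.
#' @param panel_args,counts_args,promoter_args,profile_args Named lists of
#'   overrides for [simulate_expression_panel()], [simulate_count_matrix()],
#'   [simulate_promoter()] and [simulate_membrane_profiles()].
#' @return Invisibly, a named list of the written paths.
#' @export
run_simulate <- function(out_dir, seed = 1L,
                         panel_args = list(), counts_args = list(),
                         promoter_args = list(), profile_args = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) abort("Output directory is not writable.")

  sim_panel <- do.call(simulate_expression_panel,
                       modifyList(list(seed = seed), panel_args))
  panel_dir <- file.path(out_dir, "panel")
  write_expression_panel(sim_panel$panel, panel_dir)
  write_sim_truth(sim_panel$truth, file.path(out_dir, "panel_truth.json"))

  sim_counts <- do.call(simulate_count_matrix, modifyList(
    list(n_genes = 2000, library_scales = c(1, 1.5, 0.75, 2), seed = seed),
    counts_args
  ))
  write_counts(sim_counts$counts, file.path(out_dir, "counts.tsv"))
  write_sim_truth(sim_counts$truth, file.path(out_dir, "counts_truth.json"))

  sim_prom <- do.call(simulate_promoter, modifyList(
    list(
      length = 1000, tss_index = 801,
      planted = tibble(
        name = c("CArG", "CArG", "MCAT"),
        sequence = c("ACTTTTATGG", "CCAGATATGG", "CATTCCT"),
        tss_position = c(57L, -710L, -232L),
        strand = "+"
      ),
      avoid_motifs = builtin_motifs()[c("CArG", "MCAT")],
      seed = seed
    ),
    promoter_args
  ))
  write_promoters(
    tibble(id = "promoter_1", sequence = sim_prom$sequence,
           tss_index = sim_prom$tss_index),
    file.path(out_dir, "promoters.fa")
  )
  write_sim_truth(sim_prom$truth, file.path(out_dir, "promoter_truth.json"))

  sim_prof <- do.call(simulate_membrane_profiles,
                      modifyList(list(seed = seed), profile_args))
  write_profiles(sim_prof$profiles, file.path(out_dir, "profiles.tsv"))
  write_sim_truth(sim_prof$truth, file.path(out_dir, "profiles_truth.json"))

  invisible(list(
    panel = panel_dir,
    panel_truth = file.path(out_dir, "panel_truth.json"),
    counts = file.path(out_dir, "counts.tsv"),
    counts_truth = file.path(out_dir, "counts_truth.json"),
    promoters = file.path(out_dir, "promoters.fa"),
    promoter_truth = file.path(out_dir, "promoter_truth.json"),
    profiles = file.path(out_dir, "profiles.tsv"),
    profiles_truth = file.path(out_dir, "profiles_truth.json")
  ))
}

#' Compute TMM factors and log2-CPM values for a count table on disk
#'
#' @param counts_file Tab-separated count table (see [write_counts()]).
#' @param out_dir Output directory.
#' @param trim_m,trim_a,pseudocount Passed to [tmm_factors()] /
#'   [normalize_log_cpm()].
#' @return Invisibly, the paths of the factor table and normalized matrix.
#' @export
run_normalize <- function(counts_file, out_dir,
                          trim_m = 0.30, trim_a = 0.05, pseudocount = 1) {
  counts <- read_counts(counts_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  factors <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  write_result_table(
    factors, file.path(out_dir, "tmm_factors.tsv"),
    params = list(trim_m = trim_m, trim_a = trim_a,
                  reference_library = attr(factors, "reference_library"))
  )
  norm <- normalize_log_cpm(counts, factors, pseudocount = pseudocount)
  readr::write_tsv(norm, file.path(out_dir, "log_cpm.tsv"))
  invisible(list(factors = file.path(out_dir, "tmm_factors.tsv"),
                 log_cpm = file.path(out_dir, "log_cpm.tsv")))
}

#' Run the cross-tissue co-expression stage on a panel on disk
#'
#' Ranks tissues by the query's median expression, correlates the query
#' against every gene in the top tissues, sums the coefficients into R_sum
#' and extracts the positive extreme. Both output tables carry a parameter
#' header for provenance.
#'
#' @param panel_dir Panel directory (see [write_expression_panel()]).
#' @param out_dir Output directory.
#' @param query_gene Query gene identifier.
#' @param n_top Number of top tissues (default 10).
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param quantile Extreme tail fraction (default 0.005).
#' @param missing_policy,min_tissues Passed to [rsum()].
#' @return Invisibly, the paths of the correlation table and extreme set.
#' @export
run_coexpress <- function(panel_dir, out_dir, query_gene,
                          n_top = 10, method = "pearson",
                          quantile = 0.005,
                          missing_policy = "zero", min_tissues = 5) {
  panel <- read_expression_panel(panel_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_top <- min(n_top, dplyr::n_distinct(panel$tissue))
  tissues <- rank_tissues_by_query(panel, query_gene, n_top = n_top)$tissue
  tab <- correlate_query(panel, query_gene, tissues = tissues,
                         method = method) %>%
    rsum(missing_policy = missing_policy, min_tissues = min_tissues)
  ext <- extreme(tab, quantile = quantile)

  params <- list(query_gene = query_gene, n_top = n_top, method = method,
                 quantile = quantile, missing_policy = missing_policy,
                 tissues = tissues)
  write_result_table(tab, file.path(out_dir, "correlation_table.tsv"), params)
  write_result_table(ext, file.path(out_dir, "extreme_set.tsv"),
                     c(params, list(
                       threshold_value = attr(ext, "threshold_value"),
                       nominal_size = attr(ext, "nominal_size")
                     )))
  invisible(list(correlation_table = file.path(out_dir, "correlation_table.tsv"),
                 extreme_set = file.path(out_dir, "extreme_set.tsv")))
}

#' Scan promoters on disk for the motif registry
#'
#' @param fasta Promoter FASTA with `tss=` tokens (see [write_promoters()]).
#' @param out_dir Output directory.
#' @param motifs Motif registry (default [builtin_motifs()]), or a path to a
#'   JSON registry from [write_motif_registry()].
#' @param strands,max_mismatch Passed to [scan_motifs()].
#' @return Invisibly, the path of the hit table.
#' @export
run_scan <- function(fasta, out_dir, motifs = builtin_motifs(),
                     strands = "both", max_mismatch = NULL) {
  if (is.character(motifs)) motifs <- read_motif_registry(motifs)
  promoters <- read_promoters(fasta)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hits <- scan_motifs(promoters, motifs, strands = strands,
                      max_mismatch = max_mismatch)
  write_result_table(
    hits, file.path(out_dir, "motif_hits.tsv"),
    params = list(
      strands = strands,
      motifs = paste(vapply(motifs, function(m) {
        sprintf("%s:%s:mm%d", m$name, m$pattern, m$max_mismatch)
      }, character(1)), collapse = ";")
    )
  )
  invisible(list(hits = file.path(out_dir, "motif_hits.tsv")))
}

#' Run the line-profile colocalization stage on traces on disk
#'
#' Writes the per-profile correlation table and a structured text report
#' with n, mean, SEM, t, df and p of the one-sample test versus 0, plus the
#' per-profile ratio fluctuation.
#'
#' @param profiles_file Trace table (see [write_profiles()]).
#' @param out_dir Output directory.
#' @param method Correlation method along profiles.
#' @param epsilon Denominator floor for [intensity_ratio()] (default 1% of
#'   the channel-2 mean).
#' @return Invisibly, the paths of the per-profile table and the report.
#' @export
run_coloc <- function(profiles_file, out_dir, method = "pearson",
                      epsilon = NULL) {
  profiles <- read_profiles(profiles_file)
  if (nrow(profiles) == 0) abort("Empty profile file.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per <- profile_correlations(profiles, method = method)
  res <- aggregate_profiles(per)
  ratio <- intensity_ratio(profiles, epsilon = epsilon)
  fluct <- ratio_fluctuation(ratio)

  write_result_table(left_join(per, fluct, by = "profile_id"),
                     file.path(out_dir, "per_profile.tsv"),
                     params = list(method = method,
                                   epsilon = attr(ratio, "epsilon_used")))
  report <- c(
    "Colocalization report",
    sprintf("n = %d", res$n_profiles),
    sprintf("mean_r = %.6f", res$mean_r),
    sprintf("sem_r = %.6f", res$sem_r),
    sprintf("t = %.6f", res$t_statistic),
    sprintf("df = %d", res$degrees_of_freedom),
    sprintf("p = %.6g", res$p_value),
    sprintf("epsilon = %.6g", attr(ratio, "epsilon_used")),
    sprintf("mean_fluctuation_cv = %.6f", mean(fluct$fluctuation_cv))
  )
  writeLines(report, file.path(out_dir, "coloc_report.txt"))
  invisible(list(per_profile = file.path(out_dir, "per_profile.tsv"),
                 report = file.path(out_dir, "coloc_report.txt")))
}
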