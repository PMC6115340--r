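#' Simulate a negative-binomial count matrix with depth and composition bias
#'
#' Test bed for between-library scaling-factor normalization. Baseline
#' per-gene means are drawn once from a log-normal distribution; library
#' `j` scales every mean by `library_scales[j]` (sequencing-depth bias).
#' Optionally a fraction `de_fraction` of genes is additionally up-shifted
#' `de_fold`-fold, but only in the libraries named by `de_libraries`
#' (asymmetric composition bias, the situation TMM exists to correct).
#'
#' @param n_genes Number of genes.
#' @param library_scales Positive depth multipliers, one per library.
#' @param de_fraction Fraction of genes (in `[0, 1)`) made differentially
#'   abundant in `de_libraries`.
#' @param de_fold Fold change (> 0) applied to those genes.
#' @param de_libraries Indices of the libraries carrying the shift; defaults
#'   to the last library.
#' @param base_log_mean,base_log_sd Log-normal parameters (natural log) of the
#'   baseline means.
#' @param dispersion Negative-binomial dispersion (size = 1/dispersion).
#' @param seed Integer seed.
#'
#' @return A list with `counts` (tibble: `gene_id` column plus one integer
#'   column per library, named `lib1`, `lib2`, ...) and `truth` (a
#'   [new_sim_truth()] record with the DE gene ids, scales, fold and seed).
#' @examples
#' sim <- simulate_count_matrix(500, library_scales = c(1, 2), seed = 1)
#' colSums(sim$counts[-1])
#' @export
simulate_count_matrix <- function(n_genes,
                                  library_scales,
                                  de_fraction = 0,
                                  de_fold = 1,
                                  de_libraries = NULL,
                                  base_log_mean = 3,
                                  base_log_sd = 1.2,
                                  dispersion = 0.1,
                                  seed = 1L) {
  stopifnot(n_genes >= 1, length(library_scales) >= 1)
  if (any(library_scales <= 0)) abort("`library_scales` must be positive.")
  if (de_fraction < 0 || de_fraction >= 1) {
    abort("`de_fraction` must lie in [0, 1).")
  }
  if (de_fold <= 0) abort("`de_fold` must be positive.")
  n_libs <- length(library_scales)
  if (is.null(de_libraries)) de_libraries <- n_libs
  stopifnot(all(de_libraries %in% seq_len(n_libs)))

  set.seed(seed)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  lib_ids <- sprintf("lib%d", seq_len(n_libs))
  mu0 <- exp(rnorm(n_genes, base_log_mean, base_log_sd))

  n_de <- floor(de_fraction * n_genes)
  de_genes <- if (n_de > 0) sample(gene_ids, n_de) else character()

  counts <- matrix(0L, nrow = n_genes, ncol = n_libs,
                   dimnames = list(gene_ids, lib_ids))
  for (j in seq_len(n_libs)) {
    mu <- mu0 * library_scales[j]
    if (j %in% de_libraries && n_de > 0) {
      mu[gene_ids %in% de_genes] <- mu[gene_ids %in% de_genes] * de_fold
    }
    counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }

  truth <- new_sim_truth(
    kind = "count_matrix",
    de_gene_ids = de_genes,
    de_libraries = lib_ids[de_libraries],
    de_fold = de_fold,
    library_scales = setNames(library_scales, lib_ids),
    dispersion = dispersion,
    seed = seed
  )

  counts_tbl <- as_tibble(counts, rownames = "gene_id")
  list(counts = counts_tbl, truth = truth)
}
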