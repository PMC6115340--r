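#' Simulate a multi-tissue expression panel with a planted co-expression module
#'
#' Generates log-scale expression for `n_genes` genes across `n_tissues`
#' tissues under a one-factor latent model: within each tissue, every sample
#' carries a standard-normal latent factor that drives the query gene (loading
#' `loading_query`) and each module gene (loading `loading_module`); all other
#' genes have zero loading. Independent Gaussian noise with standard deviation
#' `noise_sd` is added to every gene, and each gene gets its own baseline drawn
#' once from N(`baseline_log_mean`, `baseline_log_sd`).
#'
#' Under this model the population Pearson correlation between the query and
#' any module gene is the closed form
#' \deqn{r = \lambda_q \lambda_m / \sqrt{(\lambda_q^2+\sigma^2)(\lambda_m^2+\sigma^2)}}
#' which is recorded in the returned truth object, one value per tissue.
#'
#' @param n_tissues Number of tissues.
#' @param n_genes Size of the gene universe (including query and module genes).
#' @param samples_per_tissue Either a single integer (recycled) or a vector of
#'   length `n_tissues`; every entry must be at least 3.
#' @param n_module Number of planted module genes (ignored when
#'   `module_gene_ids` is given).
#' @param query_gene_id,module_gene_ids Identifiers of the query gene and the
#'   planted module; defaults pick the first genes of the universe. The module
#'   never contains the query.
#' @param loading_query,loading_module Latent-factor loadings
#'   (\eqn{\lambda_q}, \eqn{\lambda_m}).
#' @param noise_sd Residual standard deviation \eqn{\sigma} (> 0).
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline distribution on
#'   the log2 scale.
#' @param seed Integer seed; the same seed reproduces the panel bit for bit.
#'
#' @return A list with two elements:
#'   \describe{
#'     \item{panel}{a tibble with columns `tissue`, `sample_id`, `gene_id`,
#'       `value` (log2-scale expression), one row per measurement;}
#'     \item{truth}{a `sim_truth` list recording `query_gene_id`,
#'       `planted_gene_ids`, `expected_pairwise_r` (named per tissue), the
#'       loadings, `noise_sd` and `seed`.}
#'   }
#' @examples
#' sim <- simulate_expression_panel(
#'   n_tissues = 2, n_genes = 50, samples_per_tissue = 10, seed = 1
#' )
#' sim$truth$expected_pairwise_r
#' @export
simulate_expression_panel <- function(n_tissues = 10,
                                      n_genes = 2000,
                                      samples_per_tissue = 60,
                                      n_module = 20,
                                      query_gene_id = NULL,
                                      module_gene_ids = NULL,
                                      loading_query = 1,
                                      loading_module = 1,
                                      noise_sd = sqrt(2 / 3),
                                      baseline_log_mean = 4,
                                      baseline_log_sd = 1.5,
                                      seed = 1L) {
  stopifnot(n_tissues >= 1, n_genes >= 2)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort("`noise_sd` must be a positive number.")
  }
  if (length(samples_per_tissue) == 1) {
    samples_per_tissue <- rep(samples_per_tissue, n_tissues)
  }
  if (length(samples_per_tissue) != n_tissues) {
    abort("`samples_per_tissue` must have length 1 or `n_tissues`.")
  }
  if (any(samples_per_tissue < 3)) {
    abort("Every tissue needs at least 3 samples.")
  }

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  if (is.null(query_gene_id)) query_gene_id <- gene_ids[1]
  if (is.null(module_gene_ids)) {
    if (n_module > n_genes - 1) {
      abort("Module larger than the gene universe (excluding the query).")
    }
    module_gene_ids <- setdiff(gene_ids, query_gene_id)[seq_len(n_module)]
  }
  module_gene_ids <- setdiff(module_gene_ids, query_gene_id)
  if (!all(c(query_gene_id, module_gene_ids) %in% gene_ids)) {
    abort("Query and module genes must belong to the gene universe.")
  }

  tissues <- sprintf("tissue_%02d", seq_len(n_tissues))

  set.seed(seed)
  baseline <- rnorm(n_genes, baseline_log_mean, baseline_log_sd)
  names(baseline) <- gene_ids
  loading <- setNames(numeric(n_genes), gene_ids)
  loading[query_gene_id] <- loading_query
  loading[module_gene_ids] <- loading_module

  panel <- purrr::map2(tissues, samples_per_tissue, function(ts, n_s) {
    f <- rnorm(n_s)                            # latent factor per sample
    eps <- matrix(rnorm(n_genes * n_s, sd = noise_sd), nrow = n_genes)
    vals <- baseline + tcrossprod(loading, f) + eps
    tibble(
      tissue = ts,
      sample_id = rep(sprintf("%s_s%03d", ts, seq_len(n_s)), each = n_genes),
      gene_id = rep(gene_ids, n_s),
      value = as.vector(vals)
    )
  }) %>% bind_rows()

  r_expected <- loading_query * loading_module /
    sqrt((loading_query^2 + noise_sd^2) * (loading_module^2 + noise_sd^2))

  truth <- new_sim_truth(
    kind = "expression_panel",
    query_gene_id = query_gene_id,
    planted_gene_ids = module_gene_ids,
    expected_pairwise_r = setNames(rep(r_expected, n_tissues), tissues),
    loading_query = loading_query,
    loading_module = loading_module,
    noise_sd = noise_sd,
    seed = seed
  )

  list(panel = panel, truth = truth)
}

#' Construct a planted-structure truth record
#'
#' Lightweight container emitted by every simulator so downstream tests can
#' compare recovered structure against what was planted.
#'
#' @param kind Which generator produced the record.
#' @param ... Named truth fields (planted ids, expected correlations, planted
#'   motifs, overlap parameter, seed, ...).
#' @return A list of class `sim_truth`.
#' @export
new_sim_truth <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth:", x$kind, ">\n")
  utils::str(unclass(x), max.level = 1, give.attr = FALSE)
  invisible(x)
}

#' Closed-form planted pairwise correlation of the latent-factor model
#'
#' @param loading_query,loading_module Factor loadings.
#' @param noise_sd Residual standard deviation.
#' @return The population Pearson correlation between query and module gene.
#' @export
expected_pairwise_r <- function(loading_query, loading_module, noise_sd) {
  loading_query * loading_module /
    sqrt((loading_query^2 + noise_sd^2) * (loading_module^2 + noise_sd^2))
}
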