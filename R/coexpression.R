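# Cross-tissue co-expression ranking around a query gene: per-tissue
# correlation of the query against every other gene, summed into R_sum,
# and extraction of the positive extreme of the R_sum distribution.

# panel long tibble -> genes x samples matrix for one tissue
.tissue_matrix <- function(panel, ts, gene_ids) {
  df <- panel[panel$tissue == ts, ]
  samples <- unique(df$sample_id)
  m <- matrix(NA_real_, length(gene_ids), length(samples),
              dimnames = list(gene_ids, samples))
  m[cbind(match(df$gene_id, gene_ids), match(df$sample_id, samples))] <- df$value
  if (anyNA(m)) {
    abort(paste0("Tissue ", ts, " is missing values for part of the gene universe."))
  }
  m
}

.check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("tissue", "sample_id", "gene_id", "value") %in% names(panel)))
  unique(panel$gene_id)
}

#' Rank tissues by the query gene's expression level
#'
#' Tissues are ordered by descending median expression of the query gene;
#' ties are broken by tissue identifier order. The top `n_top` tissues are
#' the panel subsequently used for correlation analysis.
#'
#' @param panel A long expression panel (`tissue`, `sample_id`, `gene_id`,
#'   `value`), as produced by [simulate_expression_panel()] or
#'   [read_expression_panel()].
#' @param query_gene Query gene identifier.
#' @param n_top Number of tissues to keep (default 10).
#' @return A tibble with columns `tissue` and `median_expression`, highest
#'   first, `n_top` rows.
#' @export
rank_tissues_by_query <- function(panel, query_gene, n_top = 10) {
  .check_panel(panel)
  if (!query_gene %in% panel$gene_id) {
    abort(paste0("Unknown query gene: ", query_gene))
  }
  ranked <- panel %>%
    filter(.data$gene_id == query_gene) %>%
    group_by(.data$tissue) %>%
    summarise(median_expression = median(.data$value), .groups = "drop") %>%
    arrange(desc(.data$median_expression), .data$tissue)
  if (n_top > nrow(ranked)) {
    abort("`n_top` exceeds the number of tissues in the panel.")
  }
  head(ranked, n_top)
}

#' Correlate the query gene against every other gene, per tissue
#'
#' For each selected tissue, the query's sample vector is correlated with
#' every other gene's sample vector. Genes with zero variance in a tissue
#' (correlation undefined) are recorded as missing for that tissue; the query
#' row itself is excluded from the output.
#'
#' @inheritParams rank_tissues_by_query
#' @param tissues Tissues to include; defaults to the top tissues from
#'   [rank_tissues_by_query()] (all tissues when the panel has 10 or fewer).
#' @param method `"pearson"` (default) or `"spearman"` (Pearson on average
#'   ranks).
#' @return A correlation table: tibble with `gene_id` plus one numeric column
#'   of correlation coefficients per tissue (`NA` where undefined).
#' @export
correlate_query <- function(panel, query_gene, tissues = NULL,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  gene_ids <- .check_panel(panel)
  if (!query_gene %in% gene_ids) {
    abort(paste0("Unknown query gene: ", query_gene))
  }
  if (is.null(tissues)) {
    tissues <- rank_tissues_by_query(
      panel, query_gene,
      n_top = min(10, dplyr::n_distinct(panel$tissue))
    )$tissue
  }
  other <- setdiff(gene_ids, query_gene)

  cols <- purrr::map(tissues, function(ts) {
    m <- .tissue_matrix(panel, ts, gene_ids)
    if (ncol(m) < 3) abort(paste0("Tissue ", ts, " has fewer than 3 samples."))
    if (method == "spearman") {
      m <- t(apply(m, 1, rank))
    }
    q <- m[query_gene, ]
    x <- t(m[other, , drop = FALSE])
    sds <- apply(x, 2, sd)
    r <- rep(NA_real_, length(other))
    if (sd(q) > 0) {
      ok <- sds > 0
      if (any(ok)) {
        r[ok] <- as.vector(cor(q, x[, ok, drop = FALSE]))
      }
    }
    r
  })
  out <- tibble(gene_id = other)
  for (i in seq_along(tissues)) out[[tissues[i]]] <- cols[[i]]
  out
}

#' Sum per-tissue correlation coefficients into R_sum
#'
#' \eqn{R_{sum} = \sum_t r_t} over the included tissues. Missing per-tissue
#' coefficients (zero-variance genes) are zero-imputed under the default
#' policy; under `"min_observed"` genes observed in fewer than `min_tissues`
#' tissues are dropped and the sum runs over observed tissues only.
#'
#' @param cor_table A correlation table from [correlate_query()].
#' @param missing_policy `"zero"` (default) or `"min_observed"`.
#' @param min_tissues Minimum tissues observed under `"min_observed"`.
#' @return The table with `r_sum` and `n_tissues_observed` columns appended,
#'   sorted by descending `r_sum`.
#' @export
rsum <- function(cor_table, missing_policy = c("zero", "min_observed"),
                 min_tissues = 5) {
  missing_policy <- match.arg(missing_policy)
  tissue_cols <- setdiff(names(cor_table),
                         c("gene_id", "r_sum", "n_tissues_observed"))
  m <- as.matrix(cor_table[tissue_cols])
  out <- cor_table %>%
    mutate(
      r_sum = rowSums(m, na.rm = TRUE),
      n_tissues_observed = rowSums(!is.na(m))
    )
  if (missing_policy == "min_observed") {
    out <- filter(out, .data$n_tissues_observed >= min_tissues)
  }
  arrange(out, desc(.data$r_sum), .data$gene_id)
}

#' Extract the extreme of the R_sum distribution
#'
#' Returns the `ceiling(quantile * n)` genes with the highest (side
#' `"positive"`) or lowest (`"negative"`) `r_sum`; ties at the boundary value
#' are all included, so the set can exceed its nominal size.
#'
#' @param cor_table A table carrying an `r_sum` column (see [rsum()]).
#' @param quantile Tail fraction in `(0, 0.5]` (default 0.005, i.e. top 0.5%).
#' @param side `"positive"` (default) or `"negative"`.
#' @return An `extreme_set`: the member rows sorted from most extreme, with
#'   attributes `quantile`, `side`, `threshold_value` and `nominal_size`.
#' @export
extreme <- function(cor_table, quantile = 0.005,
                    side = c("positive", "negative")) {
  side <- match.arg(side)
  if (!"r_sum" %in% names(cor_table)) {
    abort("`cor_table` has no `r_sum` column; call rsum() first.")
  }
  n <- nrow(cor_table)
  if (n == 0) abort("Empty correlation table.")
  if (quantile <= 0 || quantile > 0.5) abort("`quantile` must lie in (0, 0.5].")
  k <- ceiling(quantile * n)
  rs <- cor_table$r_sum
  if (side == "positive") {
    threshold <- sort(rs, decreasing = TRUE)[k]
    members <- cor_table %>%
      filter(.data$r_sum >= threshold) %>%
      arrange(desc(.data$r_sum), .data$gene_id)
  } else {
    threshold <- sort(rs)[k]
    members <- cor_table %>%
      filter(.data$r_sum <= threshold) %>%
      arrange(.data$r_sum, .data$gene_id)
  }
  structure(members,
            quantile = quantile, side = side,
            threshold_value = threshold, nominal_size = k,
            class = c("extreme_set", class(members)))
}

#' @method glance extreme_set
#' @export
glance.extreme_set <- function(x, ...) {
  tibble(
    n_members = nrow(x),
    nominal_size = attr(x, "nominal_size"),
    quantile = attr(x, "quantile"),
    side = attr(x, "side"),
    threshold_value = attr(x, "threshold_value")
  )
}
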