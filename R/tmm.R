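#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes one scaling factor per library relative to a reference library.
#' For library j versus the reference r, using depth-adjusted abundances
#' \eqn{p = y/N}, each gene contributes an M-value \eqn{M_g = \log_2(p_j/p_r)}
#' and an average log-abundance \eqn{A_g = \tfrac12 \log_2(p_j p_r)}. Genes
#' with a zero count in either library are excluded; the top and bottom
#' `trim_m` of M-values and `trim_a` of A-values are trimmed; the factor is
#' two to the power of the weighted mean of the remaining M-values, with
#' inverse approximate (delta-method binomial) variance weights
#' \eqn{w_g^{-1} = (N_j-y_j)/(N_j y_j) + (N_r-y_r)/(N_r y_r)}. Factors are
#' rescaled to geometric mean 1. The reference library is the one whose
#' upper-quartile depth-adjusted abundance is closest to the mean across
#' libraries.
#'
#' A factor captures composition bias only: a pure depth change (all counts
#' in a library multiplied by a constant) leaves its factor unchanged because
#' depth is carried by the library size, not the factor.
#'
#' @param counts A data frame with a `gene_id` column and one nonnegative
#'   integer column per library, or a numeric matrix with gene rownames.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return A tibble with columns `library_id` and `norm_factor`, carrying the
#'   reference library id in attribute `reference_library`.
#' @examples
#' sim <- simulate_count_matrix(500, library_scales = c(1, 1), seed = 1)
#' tmm_factors(sim$counts)
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  y <- .counts_matrix(counts)
  if (ncol(y) < 2) abort("TMM needs at least 2 libraries.")
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5) {
    abort("Trim fractions must lie in [0, 0.5).")
  }
  lib_size <- colSums(y)
  if (any(lib_size == 0)) abort("A library has all-zero counts.")

  # reference: upper-quartile of depth-adjusted counts closest to the mean
  uq <- apply(y, 2, function(col) quantile(col / sum(col), 0.75))
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(y)), function(j) {
    .tmm_pair_factor(y[, j], y[, ref], lib_size[j], lib_size[ref],
                     trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))

  structure(
    tibble(library_id = colnames(y), norm_factor = unname(f)),
    reference_library = colnames(y)[ref]
  )
}

# One library's TMM factor versus the reference.
.tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  if (length(obs) == 0) return(1)

  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)

  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra_ <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

.counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(colnames(counts))) {
      colnames(counts) <- sprintf("lib%d", seq_len(ncol(counts)))
    }
    return(counts)
  }
  stopifnot(is.data.frame(counts), "gene_id" %in% names(counts))
  if (anyDuplicated(counts$gene_id)) abort("Duplicate gene ids.")
  m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(m) <- counts$gene_id
  if (any(m < 0)) abort("Counts must be nonnegative.")
  m
}

#' Normalize counts to log2 counts-per-million using TMM factors
#'
#' \deqn{\log_2\!\big( y_{gj} / (N_j f_j) \times 10^6 + c \big)}
#' where \eqn{N_j} is the library size, \eqn{f_j} the TMM factor and
#' \eqn{c} the pseudocount. Monotone in counts within a library; invariant
#' to a pure depth change (doubling all counts of a library leaves its
#' normalized values unchanged because \eqn{N_j} doubles and \eqn{f_j} does
#' not move).
#'
#' @param counts As for [tmm_factors()].
#' @param factors A tibble from [tmm_factors()] (computed if `NULL`).
#' @param pseudocount Added inside the log (default 1).
#' @return A tibble with `gene_id` plus one numeric column per library on the
#'   log2-CPM scale.
#' @export
normalize_log_cpm <- function(counts, factors = NULL, pseudocount = 1) {
  y <- .counts_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  if (!setequal(factors$library_id, colnames(y))) {
    abort("`factors` do not match the count matrix libraries.")
  }
  f <- setNames(factors$norm_factor, factors$library_id)[colnames(y)]
  eff <- colSums(y) * f
  out <- log2(sweep(y, 2, eff, "/") * 1e6 + pseudocount)
  as_tibble(out, rownames = "gene_id")
}
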