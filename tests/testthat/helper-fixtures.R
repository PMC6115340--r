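# Shared fixtures and independent oracles used across test files.

# Brute-force Pearson correlation straight from the definition.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Brute-force TMM: an independent implementation of the trimmed
# weighted-mean-of-M-values formula, written against the published
# definition rather than the package's code path (quantile-free rank trim,
# explicit loops).
tmm_oracle <- function(counts_mat, trim_m = 0.30, trim_a = 0.05) {
  n_lib <- ncol(counts_mat)
  lib_size <- colSums(counts_mat)
  # reference: upper-quartile of depth-adjusted counts closest to the mean
  uq <- numeric(n_lib)
  for (j in seq_len(n_lib)) {
    uq[j] <- unname(quantile(counts_mat[, j] / lib_size[j], 0.75))
  }
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(n_lib)
  for (j in seq_len(n_lib)) {
    yo <- counts_mat[, j]; yr <- counts_mat[, ref]
    keep <- yo > 0 & yr > 0
    yo <- yo[keep]; yr <- yr[keep]
    no <- lib_size[j]; nr <- lib_size[ref]
    m <- log2((yo / no) / (yr / nr))
    a <- 0.5 * log2((yo / no) * (yr / nr))
    w <- (no - yo) / (no * yo) + (nr - yr) / (nr * yr)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra_ <- rank(a)
    sel <- which(rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a)
    num <- 0; den <- 0
    for (g in sel) {
      num <- num + m[g] / w[g]
      den <- den + 1 / w[g]
    }
    f[j] <- 2^(num / den)
  }
  f / exp(mean(log(f)))
}

# 5-gene x 2-tissue worked panel with hand-sized numbers, used wherever a
# tiny fully-inspectable panel is needed.
worked_panel <- function() {
  genes <- paste0("g", 1:5)
  vals <- list(
    tA = matrix(c(
      1, 2, 3, 4, 5,      # g1 (query)
      2, 4, 6, 8, 10,     # g2: perfect linear copy
      5, 4, 3, 2, 1,      # g3: reversed
      1, 3, 2, 5, 4,      # g4: partial
      7, 7, 7, 7, 7       # g5: constant (zero variance)
    ), nrow = 5, byrow = TRUE),
    tB = matrix(c(
      2, 1, 4, 3, 6,
      1, 2, 2, 3, 5,
      9, 7, 5, 3, 1,
      2, 2, 5, 1, 4,
      1, 1, 2, 2, 3
    ), nrow = 5, byrow = TRUE)
  )
  purrr::imap(vals, function(m, ts) {
    rownames(m) <- genes
    colnames(m) <- paste0(ts, "_s", 1:5)
    tibble::as_tibble(m, rownames = "gene_id") |>
      tidyr::pivot_longer(-gene_id, names_to = "sample_id",
                          values_to = "value") |>
      dplyr::mutate(tissue = ts)
  }) |>
    dplyr::bind_rows() |>
    dplyr::select(tissue, sample_id, gene_id, value)
}

# Promoter carrying the three printed regulatory elements at their signed
# TSS positions, on a background free of off-target CArG/MCAT matches.
planted_promoter <- function(seed = 42) {
  simulate_promoter(
    length = 1000, tss_index = 801,
    planted = tibble::tibble(
      name = c("CArG", "CArG", "MCAT"),
      sequence = c("ACTTTTATGG", "CCAGATATGG", "CATTCCT"),
      tss_position = c(57L, -710L, -232L),
      strand = "+"
    ),
    avoid_motifs = builtin_motifs()[c("CArG", "MCAT")],
    seed = seed
  )
}
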