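# Tissue ranking, per-tissue correlation, R_sum and the extreme set.

test_that("tissues are ranked by median query expression with id tie-break", {
  panel <- tidyr::expand_grid(
    tissue = c("t1", "t2", "t3"),
    sample_id = paste0("s", 1:3),
    gene_id = c("q", "g2")
  ) |>
    dplyr::mutate(
      sample_id = paste(tissue, sample_id, sep = "_"),
      value = dplyr::case_when(
        gene_id == "q" & tissue == "t1" ~ 10,
        gene_id == "q" & tissue == "t2" ~ 5,
        gene_id == "q" & tissue == "t3" ~ 1,
        TRUE ~ 2
      )
    )
  expect_identical(rank_tissues_by_query(panel, "q", n_top = 2)$tissue,
                   c("t1", "t2"))

  # all medians equal -> identifier order
  flat <- dplyr::mutate(panel, value = 3)
  expect_identical(rank_tissues_by_query(flat, "q", n_top = 3)$tissue,
                   c("t1", "t2", "t3"))

  # brute-force sort oracle on a simulated panel
  sim <- simulate_expression_panel(n_tissues = 6, n_genes = 20,
                                   samples_per_tissue = 5, n_module = 3,
                                   seed = 31)
  q <- sim$truth$query_gene_id
  meds <- sim$panel |>
    dplyr::filter(gene_id == q) |>
    dplyr::group_by(tissue) |>
    dplyr::summarise(m = median(value), .groups = "drop")
  oracle <- meds$tissue[order(-meds$m, meds$tissue)]
  expect_identical(rank_tissues_by_query(sim$panel, q, n_top = 6)$tissue,
                   oracle)

  expect_error(rank_tissues_by_query(panel, "nope"), "Unknown query")
  expect_error(rank_tissues_by_query(panel, "q", n_top = 9), "exceeds")
})

test_that("correlations on the worked panel match the Pearson formula oracle", {
  panel <- worked_panel()
  tab <- correlate_query(panel, "g1", tissues = c("tA", "tB"))
  expect_identical(tab$gene_id, c("g2", "g3", "g4", "g5"))

  wide <- panel |>
    tidyr::pivot_wider(names_from = sample_id, values_from = value)
  for (ts in c("tA", "tB")) {
    sub <- wide[!is.na(wide[[paste0(ts, "_s1")]]), ]
    vecs <- lapply(seq_len(nrow(sub)), function(i) {
      unlist(sub[i, paste0(ts, "_s", 1:5)])
    })
    names(vecs) <- sub$gene_id
    for (g in c("g2", "g3", "g4", "g5")) {
      got <- tab[[ts]][tab$gene_id == g]
      sg <- sd(vecs[[g]])
      if (sg == 0) {
        expect_true(is.na(got))
      } else {
        expect_equal(got, pearson_oracle(vecs[["g1"]], vecs[[g]]),
                     tolerance = 1e-12)
      }
    }
  }

  # perfect copy and zero-variance rules
  expect_equal(tab$tA[tab$gene_id == "g2"], 1, tolerance = 1e-12)
  expect_true(is.na(tab$tA[tab$gene_id == "g5"]))
  expect_false(is.na(tab$tB[tab$gene_id == "g5"]))
})

test_that("rsum applies the missing-value policy and matches brute force", {
  tab <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    t1 = c(1, 0.5, NA), t2 = c(1, 0.5, NA), t3 = c(1, -0.5, NA),
    t4 = c(1, -0.5, 0.2)
  )
  out <- rsum(tab)
  expect_equal(out$r_sum[out$gene_id == "a"], 4)
  expect_equal(out$r_sum[out$gene_id == "b"], 0)
  expect_equal(out$r_sum[out$gene_id == "c"], 0.2)
  expect_equal(out$n_tissues_observed[out$gene_id == "c"], 1)

  kept <- rsum(tab, missing_policy = "min_observed", min_tissues = 2)
  expect_false("c" %in% kept$gene_id)

  # random table equals brute-force summation
  set.seed(14)
  rnd <- tibble::tibble(gene_id = paste0("g", 1:50))
  for (t in paste0("t", 1:6)) {
    v <- runif(50, -1, 1)
    v[sample(50, 5)] <- NA
    rnd[[t]] <- v
  }
  out2 <- rsum(rnd)
  m <- as.matrix(rnd[-1])
  brute <- sapply(seq_len(50), function(i) sum(m[i, ], na.rm = TRUE))
  expect_equal(out2$r_sum[match(rnd$gene_id, out2$gene_id)], brute,
               tolerance = 1e-12)
})

test_that("extreme keeps ceil(q*n) genes, includes boundary ties, sorts descending", {
  tab <- tibble::tibble(gene_id = sprintf("g%04d", 1:2000),
                        r_sum = seq(2000, 1) / 100)
  ext <- extreme(tab, quantile = 0.005)
  expect_equal(nrow(ext), 10)
  expect_identical(ext$gene_id, sprintf("g%04d", 1:10))
  expect_true(all(diff(ext$r_sum) <= 0))
  expect_equal(attr(ext, "threshold_value"), ext$r_sum[10])

  # degenerate all-equal table: every gene is a boundary tie
  flat <- tibble::tibble(gene_id = paste0("g", 1:40), r_sum = 1)
  expect_equal(nrow(extreme(flat, quantile = 0.1)), 40)

  # glance reports the set's shape
  g <- glance(ext)
  expect_equal(g$n_members, 10)
  expect_equal(g$nominal_size, 10)

  expect_error(extreme(tab[0, ], 0.005), "Empty")
  expect_error(extreme(tibble::tibble(gene_id = "a", x = 1)), "r_sum")
})

test_that("joint sample permutation leaves correlations unchanged", {
  sim <- simulate_expression_panel(n_tissues = 2, n_genes = 40,
                                   samples_per_tissue = 12, n_module = 5,
                                   seed = 17)
  q <- sim$truth$query_gene_id
  tab0 <- correlate_query(sim$panel, q)

  set.seed(2)
  shuffled <- sim$panel |>
    dplyr::group_by(tissue) |>
    dplyr::group_modify(function(df, key) {
      samples <- unique(df$sample_id)
      df[order(match(df$sample_id, sample(samples))), ]
    }) |>
    dplyr::ungroup() |>
    dplyr::select(tissue, sample_id, gene_id, value)
  tab1 <- correlate_query(shuffled, q)
  expect_equal(tab1[order(tab1$gene_id), ], tab0[order(tab0$gene_id), ],
               tolerance = 1e-12)
})

test_that("independently shuffling a gene destroys its R_sum", {
  sim <- simulate_expression_panel(n_tissues = 10, n_genes = 30,
                                   samples_per_tissue = 60, n_module = 5,
                                   seed = 23)
  q <- sim$truth$query_gene_id
  victim <- sim$truth$planted_gene_ids[1]
  set.seed(5)
  shuffles <- replicate(100, {
    p <- sim$panel |>
      dplyr::group_by(tissue) |>
      dplyr::group_modify(function(df, key) {
        idx <- df$gene_id == victim
        df$value[idx] <- sample(df$value[idx])
        df
      }) |>
      dplyr::ungroup()
    tab <- rsum(correlate_query(p, q, tissues = unique(p$tissue)))
    tab$r_sum[tab$gene_id == victim]
  })
  expect_lt(abs(mean(shuffles)), 0.5)
})

test_that("spearman method equals the Pearson path on rank-transformed data", {
  sim <- simulate_expression_panel(n_tissues = 2, n_genes = 15,
                                   samples_per_tissue = 10, n_module = 4,
                                   seed = 41)
  q <- sim$truth$query_gene_id
  sp <- correlate_query(sim$panel, q, method = "spearman")
  ranked <- sim$panel |>
    dplyr::group_by(tissue, gene_id) |>
    dplyr::mutate(value = rank(value)) |>
    dplyr::ungroup()
  pe <- correlate_query(ranked, q, method = "pearson")
  expect_equal(sp, pe, tolerance = 1e-12)
})
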