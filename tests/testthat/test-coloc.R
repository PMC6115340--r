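# Line-profile colocalization statistics.

test_that("per-profile correlation hits its closed forms", {
  base <- tibble::tibble(profile_id = "p1", position = 1:6,
                         channel1 = c(1, 5, 2, 8, 3, 9))
  ident <- dplyr::mutate(base, channel2 = channel1)
  expect_equal(profile_correlations(ident)$r, 1, tolerance = 1e-12)

  affine <- dplyr::mutate(base, channel2 = 3 * channel1 + 7)
  expect_equal(profile_correlations(affine)$r, 1, tolerance = 1e-12)

  # noise-free anti-phase square waves -> exactly -1
  lo <- simulate_membrane_profiles(n_profiles = 3, overlap = 0, noise_sd = 0,
                                   seed = 2)
  expect_equal(profile_correlations(lo$profiles)$r, rep(-1, 3),
               tolerance = 1e-12)

  # zero-variance profile excluded with a warning, others kept
  flat <- tibble::tibble(profile_id = "p2", position = 1:6,
                         channel1 = 1, channel2 = c(1, 2, 3, 4, 5, 6))
  both <- dplyr::bind_rows(ident, flat)
  expect_warning(out <- profile_correlations(both), "Excluded")
  expect_true(is.na(out$r[out$profile_id == "p2"]))
  expect_equal(out$r[out$profile_id == "p1"], 1)
})

test_that("pearson is affine-invariant and spearman monotone-invariant", {
  sim <- simulate_membrane_profiles(n_profiles = 4, overlap = 0.6, seed = 9)
  r0 <- profile_correlations(sim$profiles)$r
  rescaled <- dplyr::mutate(sim$profiles, channel2 = 2.5 * channel2 + 11)
  expect_equal(profile_correlations(rescaled)$r, r0, tolerance = 1e-12)

  s0 <- profile_correlations(sim$profiles, method = "spearman")$r
  mono <- dplyr::mutate(sim$profiles, channel2 = exp(channel2 / 50))
  expect_equal(profile_correlations(mono, method = "spearman")$r, s0,
               tolerance = 1e-12)
})

test_that("aggregation reproduces the one-sample t closed form", {
  res <- aggregate_profiles(c(0.1, 0.2, 0.3))
  expect_equal(res$mean_r, 0.2, tolerance = 1e-12)
  expect_equal(res$sem_r, sd(c(0.1, 0.2, 0.3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(res$sem_r, 0.05774, tolerance = 1e-4)
  expect_equal(res$t_statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$degrees_of_freedom, 2)
  # independent t-CDF evaluation
  expect_equal(res$p_value, 2 * (1 - pt(0.2 / (sd(c(0.1, 0.2, 0.3)) / sqrt(3)), 2)),
               tolerance = 1e-12)

  zero <- aggregate_profiles(c(0, 0, 0, 0))
  expect_equal(zero$mean_r, 0)
  expect_equal(zero$t_statistic, 0)
  expect_equal(zero$p_value, 1)
  expect_true(zero$degenerate)

  const <- aggregate_profiles(rep(0.5, 5))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 0)
  expect_equal(const$t_statistic, Inf)

  expect_error(aggregate_profiles(0.3), "at least 2")

  # brute-force equality on random inputs
  set.seed(3)
  for (i in 1:20) {
    rs <- runif(sample(3:15, 1), -1, 1)
    res <- aggregate_profiles(rs)
    expect_equal(res$mean_r, mean(rs), tolerance = 1e-12)
    expect_equal(res$sem_r, sd(rs) / sqrt(length(rs)), tolerance = 1e-12)
    expect_equal(res$t_statistic, mean(rs) / (sd(rs) / sqrt(length(rs))),
                 tolerance = 1e-12)
    expect_equal(res$p_value,
                 2 * pt(-abs(res$t_statistic), length(rs) - 1),
                 tolerance = 1e-12)
  }
})

test_that("tidy and glance expose the aggregate in broom shape", {
  res <- aggregate_profiles(c(0.1, 0.2, 0.3))
  td <- tidy(res)
  expect_equal(nrow(td), 3)
  expect_named(td, c("profile", "r"))
  gl <- glance(res)
  expect_equal(gl$n_profiles, 3)
  expect_equal(gl$mean_r, 0.2)
})

test_that("intensity ratio is floored, finite and separates the overlap regimes", {
  prof <- tibble::tibble(profile_id = "p", position = 1:5,
                         channel1 = c(10, 20, 30, 40, 50),
                         channel2 = c(10, 20, 30, 40, 50))
  rt <- intensity_ratio(prof)
  expect_equal(rt$ratio, rep(1, 5))
  expect_equal(ratio_fluctuation(rt)$fluctuation_cv, 0)

  zeros <- dplyr::mutate(prof, channel2 = c(10, 0, 30, 0, 50))
  rt0 <- intensity_ratio(zeros)
  expect_true(all(is.finite(rt0$ratio)))
  expect_equal(attr(rt0, "epsilon_used"), 0.01 * mean(zeros$channel2))

  expect_error(intensity_ratio(prof, epsilon = 0), "positive")

  # anti-phase domains fluctuate far more than coincident ones
  lo <- simulate_membrane_profiles(n_profiles = 5, overlap = 0, noise_sd = 0,
                                   seed = 6)
  hi <- simulate_membrane_profiles(n_profiles = 5, overlap = 1, noise_sd = 0,
                                   seed = 6)
  cv_lo <- mean(ratio_fluctuation(intensity_ratio(lo$profiles))$fluctuation_cv)
  cv_hi <- mean(ratio_fluctuation(intensity_ratio(hi$profiles))$fluctuation_cv)
  expect_gt(cv_lo, 0.5)
  expect_equal(cv_hi, 0, tolerance = 1e-12)
  expect_gt(cv_lo, cv_hi + 0.5)
})

test_that("two-group comparison matches the pooled-variance formula", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3)
  b <- c(1, 2, 3, 4)
  got <- compare_groups(a, b)
  # hand-evaluated pooled-variance formula
  sp2 <- ((3 - 1) * var(a) + (4 - 1) * var(b)) / (3 + 4 - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(got$t_statistic, t_oracle, tolerance = 1e-12)
  expect_equal(got$degrees_of_freedom, 5)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), 5), tolerance = 1e-12)

  welch <- compare_groups(a, b, var_equal = FALSE)
  expect_lt(welch$degrees_of_freedom, 5 + 1e-9)

  degen <- compare_groups(c(1, 1), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 0)
  expect_equal(compare_groups(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("permuting one channel within profiles drives the mean toward 0", {
  sim <- simulate_membrane_profiles(n_profiles = 8, overlap = 1, seed = 12)
  observed <- aggregate_profiles(profile_correlations(sim$profiles))$mean_r
  set.seed(4)
  null_means <- replicate(100, {
    shuffled <- sim$profiles |>
      dplyr::group_by(profile_id) |>
      dplyr::mutate(channel2 = sample(channel2)) |>
      dplyr::ungroup()
    mean(profile_correlations(shuffled)$r)
  })
  expect_gt(observed, 0.8)
  expect_lt(abs(mean(null_means)), 0.05)
  expect_lt(max(abs(null_means)), 0.4)
})

test_that("mean per-profile r is monotone across the overlap grid", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- sapply(grid, function(ov) {
    mean(sapply(1:20, function(s) {
      sim <- simulate_membrane_profiles(n_profiles = 4,
                                        points_per_profile = 120,
                                        overlap = ov, seed = 300 + s)
      mean(profile_correlations(sim$profiles)$r)
    }))
  })
  expect_true(all(diff(means) > 0))
})
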