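# Membrane line-profile colocalization: per-profile two-channel correlation,
# aggregation with a one-sample t-test versus 0, intensity-ratio fluctuation,
# and a two-group comparison of colocalization.

#' Per-profile correlation of the two channels
#'
#' Computes the correlation of `channel1` versus `channel2` within each
#' profile. Profiles in which either channel has zero variance (correlation
#' undefined) are excluded with a warning and reported with `r = NA`.
#'
#' @param profiles A tibble with columns `profile_id`, `position`,
#'   `channel1`, `channel2` (the trace format of
#'   [simulate_membrane_profiles()] / [read_profiles()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble: `profile_id`, `n_points`, `r`.
#' @export
profile_correlations <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("profile_id", "channel1", "channel2") %in% names(profiles)))
  out <- profiles %>%
    group_by(.data$profile_id) %>%
    summarise(
      n_points = dplyr::n(),
      r = {
        c1 <- .data$channel1
        c2 <- .data$channel2
        if (dplyr::n() < 3 || sd(c1) == 0 || sd(c2) == 0) NA_real_
        else cor(c1, c2, method = method)
      },
      .groups = "drop"
    )
  if (anyNA(out$r)) {
    warn(paste0("Excluded ", sum(is.na(out$r)),
                " profile(s) with undefined correlation (zero variance or < 3 points)."))
  }
  out
}

#' Aggregate per-profile correlations with a one-sample t-test versus 0
#'
#' Treats each profile's coefficient as one observation: reports the mean,
#' the standard error of the mean, and the two-tailed one-sample Student t
#' versus 0 with n − 1 degrees of freedom. When every coefficient is equal
#' (zero variance) the t statistic is degenerate; the result is flagged and
#' the p-value reported as 0 (mean nonzero) or 1 (mean zero).
#'
#' @param rs Either a numeric vector of per-profile correlations or a data
#'   frame with an `r` column (as from [profile_correlations()]; `NA`s are
#'   dropped).
#' @return A `coloc_result` list: `per_profile_r`, `n_profiles`, `mean_r`,
#'   `sem_r`, `t_statistic`, `degrees_of_freedom`, `p_value`, `degenerate`.
#' @examples
#' aggregate_profiles(c(0.1, 0.2, 0.3))
#' @export
aggregate_profiles <- function(rs) {
  if (is.data.frame(rs)) rs <- rs$r
  rs <- rs[!is.na(rs)]
  n <- length(rs)
  if (n < 2) abort("Need at least 2 profiles to aggregate.")
  m <- mean(rs)
  s <- sd(rs)
  sem <- s / sqrt(n)
  if (s == 0) {
    degenerate <- TRUE
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    degenerate <- FALSE
    tstat <- m / sem
    p <- 2 * pt(-abs(tstat), df = n - 1)
  }
  structure(
    list(per_profile_r = rs, n_profiles = n, mean_r = m, sem_r = sem,
         t_statistic = tstat, degrees_of_freedom = n - 1, p_value = p,
         degenerate = degenerate),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization: R = %.3f +/- %.3f (mean +/- SEM), N = %d\n",
              x$mean_r, x$sem_r, x$n_profiles))
  cat(sprintf("One-sample t vs 0: t = %.4f, df = %d, two-tailed p = %.4g%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' @method tidy coloc_result
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(profile = seq_along(x$per_profile_r), r = x$per_profile_r)
}

#' @method glance coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(
    n_profiles = x$n_profiles, mean_r = x$mean_r, sem_r = x$sem_r,
    t_statistic = x$t_statistic, degrees_of_freedom = x$degrees_of_freedom,
    p_value = x$p_value, degenerate = x$degenerate
  )
}

#' Channel intensity ratio along each profile
#'
#' The per-position ratio `channel1 / max(channel2, epsilon)`; the epsilon
#' floor keeps the ratio finite where channel 2 drops to 0. The default
#' epsilon is 1% of the mean of channel 2 across the input.
#'
#' @inheritParams profile_correlations
#' @param epsilon Positive floor for the denominator (default 1% of the
#'   channel-2 mean).
#' @return A `ratio_trace` tibble: `profile_id`, `position`, `ratio`, with
#'   the floor recorded in attribute `epsilon_used`.
#' @export
intensity_ratio <- function(profiles, epsilon = NULL) {
  stopifnot(all(c("profile_id", "position", "channel1", "channel2") %in%
                  names(profiles)))
  if (is.null(epsilon)) epsilon <- 0.01 * mean(profiles$channel2)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    abort("`epsilon` must be a positive number.")
  }
  out <- profiles %>%
    mutate(ratio = .data$channel1 / pmax(.data$channel2, epsilon)) %>%
    select("profile_id", "position", "ratio")
  structure(out, epsilon_used = epsilon,
            class = c("ratio_trace", class(out)))
}

#' Fluctuation of the intensity ratio, per profile
#'
#' Operationalizes "the ratio fluctuates along the membrane" as the
#' coefficient of variation sd(ratio)/mean(ratio) within each profile:
#' interdigitating (non-overlapping) domains give a large CV, coincident
#' channels a CV near 0.
#'
#' @param ratio_trace Output of [intensity_ratio()].
#' @return A tibble: `profile_id`, `fluctuation_cv`.
#' @export
ratio_fluctuation <- function(ratio_trace) {
  ratio_trace %>%
    as_tibble() %>%
    group_by(.data$profile_id) %>%
    summarise(fluctuation_cv = sd(.data$ratio) / mean(.data$ratio),
              .groups = "drop")
}

#' Compare colocalization between two groups of profiles
#'
#' Two-sample Student t-test on the per-profile coefficients, two-tailed;
#' pooled variance by default (`var_equal = FALSE` gives Welch). The
#' degenerate zero-pooled-variance case returns t = 0, p = 1 when the group
#' means coincide and p = 0 otherwise, flagged.
#'
#' @param rs_a,rs_b Numeric vectors (or data frames with an `r` column) of
#'   per-profile correlations, each of length at least 2.
#' @param var_equal Pooled-variance Student test if `TRUE` (default).
#' @return A one-row tibble: `t_statistic`, `degrees_of_freedom`, `p_value`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`, `degenerate`.
#' @export
compare_groups <- function(rs_a, rs_b, var_equal = TRUE) {
  if (is.data.frame(rs_a)) rs_a <- rs_a$r
  if (is.data.frame(rs_b)) rs_b <- rs_b$r
  rs_a <- rs_a[!is.na(rs_a)]
  rs_b <- rs_b[!is.na(rs_b)]
  if (length(rs_a) < 2 || length(rs_b) < 2) {
    abort("Each group needs at least 2 profiles.")
  }
  if (sd(rs_a) == 0 && sd(rs_b) == 0) {
    same <- isTRUE(all.equal(mean(rs_a), mean(rs_b)))
    return(tibble(
      t_statistic = if (same) 0 else sign(mean(rs_a) - mean(rs_b)) * Inf,
      degrees_of_freedom = length(rs_a) + length(rs_b) - 2,
      p_value = if (same) 1 else 0,
      mean_a = mean(rs_a), mean_b = mean(rs_b),
      n_a = length(rs_a), n_b = length(rs_b),
      degenerate = TRUE
    ))
  }
  tt <- stats::t.test(rs_a, rs_b, var.equal = var_equal)
  tibble(
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    mean_a = mean(rs_a), mean_b = mean(rs_b),
    n_a = length(rs_a), n_b = length(rs_b),
    degenerate = FALSE
  )
}
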