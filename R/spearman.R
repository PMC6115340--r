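#' Spearman rank correlation with an exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of the two rank vectors
#' (average ranks for ties). For n of at most 10 the two-sided p-value is
#' exact: every permutation of one rank vector is enumerated and the tail is
#' the fraction of permutations with \eqn{|\rho_{perm}| \ge |\rho_{obs}|}.
#' For larger n the usual t-approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with n − 2 degrees of freedom is
#' used.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `p_method`
#'   (`"exact"` or `"t-approximation"`).
#' @examples
#' spearman_pair(1:8, c(2, 1, 4, 3, 6, 5, 8, 7))
#' @export
spearman_pair <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 paired observations.")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Zero rank variance: Spearman correlation undefined.")
  }
  rho <- cor(rx, ry)

  if (n <= 10) {
    p <- .spearman_exact_p(rx, ry, rho)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  tibble(rho = rho, p_value = min(p, 1), n = n, p_method = method)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 9 here).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact two-sided tail over all n! permutations of ry, chunked on the first
# element so the permutation matrix never exceeds 9 columns.
.spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  mx <- mean(rx); my <- mean(ry)
  sx <- sd(rx); sy <- sd(ry)
  # rho is linear in S = sum(rx * ry_perm)
  rho_from_s <- function(s) (s - n * mx * my) / ((n - 1) * sx * sy)
  tol <- 1e-12
  if (n <= 9) {
    P <- .permutations(n)
    s <- as.vector(matrix(ry[P], nrow(P)) %*% rx)
    count <- sum(abs(rho_from_s(s)) >= abs(rho_obs) - tol)
    total <- nrow(P)
  } else {
    sub <- .permutations(n - 1L)
    count <- 0
    total <- 0
    for (i in seq_len(n)) {
      rest <- seq_len(n)[-i]
      s <- ry[i] * rx[1] +
        as.vector(matrix(ry[rest][sub], nrow(sub)) %*% rx[-1])
      count <- count + sum(abs(rho_from_s(s)) >= abs(rho_obs) - tol)
      total <- total + nrow(sub)
    }
  }
  count / total
}
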