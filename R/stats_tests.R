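# Nonparametric group comparison and rank correlation with exact small-sample
# inference: Mann-Whitney U via midranks (exact two-sided p by full
# enumeration when feasible, normal approximation with tie and continuity
# correction otherwise) and Spearman's rho (exact for n <= 8).

#' Mann-Whitney U test
#'
#' U is computed from midranks (so ties are handled); the two-sided p-value
#' is exact by full enumeration of all `choose(n+m, n)` group assignments
#' when that is feasible, otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b numeric samples.
#' @param mode `"auto"` (exact when `choose(n+m, n) <= enum_limit`),
#'   `"exact"` or `"normal"`.
#' @param enum_limit maximum number of arrangements to enumerate.
#' @return A [stat_result()] with `statistic = U` of the first sample;
#'   details carry `U_a`, `U_b` and the mode used.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "normal"),
                           enum_limit = 2e5) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop_config("mann_whitney_u: empty sample")
  n <- length(a); m <- length(b); N <- n + m
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks
  U_a <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  U_b <- n * m - U_a
  use_exact <- mode == "exact" || (mode == "auto" && choose(N, n) <= enum_limit)
  if (use_exact) {
    idx <- utils::combn(N, n)
    Us <- colSums(matrix(rk[idx], nrow = n)) - n * (n + 1) / 2
    dev <- abs(Us - n * m / 2)
    p <- mean(dev >= abs(U_a - n * m / 2) - 1e-9)
    method <- "mann_whitney_exact"
  } else {
    mu <- n * m / 2
    ties <- table(pooled)
    sig2 <- (n * m / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    zc <- (abs(U_a - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(zc, 0)))
    method <- "mann_whitney_normal"
  }
  stat_result(U_a, p_value = p, method = method,
              details = list(U_a = U_a, U_b = U_b, n = n, m = m))
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks. The two-sided p-value is
#' exact (full enumeration of rank permutations) for `n <= 8`, otherwise the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A [stat_result()].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_config("spearman_rho: length mismatch")
  n <- length(x)
  if (n < 3L) stop_config("spearman_rho: need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop_config("spearman_rho: zero rank variance")
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "spearman_exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "spearman_t"
  }
  stat_result(rho, p_value = p, method = method, details = list(n = n))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    block <- cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub)))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}
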