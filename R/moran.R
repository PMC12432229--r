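# Spatial autocorrelation with permutation inference: global Moran's I and
# the Anselin local Moran's I (LISA) with quadrant labelling and
# contiguous-cluster extraction.

row_standardize <- function(nb, n) {
  lapply(seq_len(n), function(i) {
    k <- length(nb[[i]])
    if (k == 0) numeric(0) else rep(1 / k, k)
  })
}

#' A statistic with inferential companions
#'
#' Light container used by all group comparisons, correlations and spatial
#' statistics: the statistic, a p-value (frequentist or pseudo-p), a Bayes
#' factor and a 95% highest-density interval where the method provides them.
#'
#' @param statistic numeric statistic value.
#' @param p_value p-value or permutation pseudo-p (`NA` if not applicable).
#' @param bayes_factor_10 Bayes factor for the effect (`NA` if not computed).
#' @param hdi numeric `c(low, high)` 95% HDI (`NA`s if not computed).
#' @param method character tag.
#' @param details list of method-specific extras.
#' @export
stat_result <- function(statistic, p_value = NA_real_,
                        bayes_factor_10 = NA_real_, hdi = c(NA_real_, NA_real_),
                        method = "", details = list()) {
  structure(list(statistic = statistic, p_value = p_value,
                 bayes_factor_10 = bayes_factor_10,
                 hdi_low = hdi[1], hdi_high = hdi[2],
                 method = method, details = details),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result:%s> statistic %.6g", x$method, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf(", p %.4g", x$p_value))
  if (!is.na(x$bayes_factor_10)) cat(sprintf(", BF10 %.4g", x$bayes_factor_10))
  if (!is.na(x$hdi_low)) cat(sprintf(", 95%% HDI [%.4g, %.4g]", x$hdi_low, x$hdi_high))
  cat("\n")
  invisible(x)
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with a permutation pseudo-p `(1 + exceedances) / (1 + n_permutations)`.
#'
#' @param values numeric vector (one value per spatial unit).
#' @param nb neighbour list (integer indices per unit), e.g. from
#'   [make_hex_grid()].
#' @param n_permutations permutations for the pseudo-p (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default), `"less"` or `"two_sided"`.
#' @param row_standardized use row-standardised weights (default TRUE).
#' @return A [stat_result()]; details carry the permutation null mean/sd.
#' @export
global_morans_i <- function(values, nb, n_permutations = 999, seed = 1L,
                            alternative = c("greater", "less", "two_sided"),
                            row_standardized = TRUE) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 3L) stop_config("global_morans_i: need >= 3 units")
  if (stats::var(values) == 0) stop_config("global_morans_i: constant field")
  w <- if (row_standardized) row_standardize(nb, n) else
    lapply(nb, function(x) rep(1, length(x)))
  S0 <- sum(unlist(w))
  moran_of <- function(x) {
    z <- x - mean(x)
    num <- sum(vapply(seq_len(n), function(i)
      if (length(nb[[i]])) z[i] * sum(w[[i]] * z[nb[[i]]]) else 0, 0))
    (n / S0) * num / sum(z^2)
  }
  I_obs <- moran_of(values)
  perms <- with_seed(derive_seed(seed, "global_moran"), {
    vapply(seq_len(n_permutations), function(k) moran_of(sample(values)), 0)
  })
  exceed <- switch(alternative,
                   greater = sum(perms >= I_obs),
                   less = sum(perms <= I_obs),
                   two_sided = sum(abs(perms - mean(perms)) >= abs(I_obs - mean(perms))))
  stat_result(I_obs, p_value = (1 + exceed) / (1 + n_permutations),
              method = "global_morans_i",
              details = list(n = n, n_permutations = n_permutations,
                             null_mean = mean(perms), null_sd = stats::sd(perms),
                             expectation = -1 / (n - 1)))
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' Per-unit `I_i = z_i * sum_j w_ij z_j` on standardised values, quadrant
#' labels from the signs of `z_i` and its spatial lag, pseudo-p from
#' conditional permutation (unit i held fixed, neighbours drawn from the
#' remaining values), and clusters as contiguous groups of significant
#' high-high cells.
#'
#' @param values numeric vector.
#' @param nb neighbour list.
#' @param n_permutations default 999.
#' @param alpha significance for cluster membership (default 0.002).
#' @param seed integer seed.
#' @return list: data.frame `local` (`I_i`, `pseudo_p`, `quadrant`),
#'   `clusters` (list of cell-index vectors), `alpha`.
#' @export
local_morans_i <- function(values, nb, n_permutations = 999, alpha = 0.002,
                           seed = 1L) {
  n <- length(values)
  if (stats::var(values) == 0) stop_config("local_morans_i: constant field")
  z <- (values - mean(values)) / stats::sd(values)
  w <- row_standardize(nb, n)
  lag <- vapply(seq_len(n), function(i)
    if (length(nb[[i]])) sum(w[[i]] * z[nb[[i]]]) else NA_real_, 0)
  I <- z * lag
  pseudo_p <- rep(NA_real_, n)
  with_seed(derive_seed(seed, "local_moran"), {
    for (i in seq_len(n)) {
      k <- length(nb[[i]])
      if (k == 0) next
      others <- z[-i]
      draws <- vapply(seq_len(n_permutations), function(j)
        mean(others[sample.int(n - 1L, k)]), 0)
      I_perm <- z[i] * draws
      exceed <- if (I[i] >= 0) sum(I_perm >= I[i]) else sum(I_perm <= I[i])
      pseudo_p[i] <- (1 + exceed) / (1 + n_permutations)
    }
  })
  quadrant <- rep("not_significant", n)
  sig <- !is.na(pseudo_p) & pseudo_p < alpha
  quadrant[sig & z > 0 & lag > 0] <- "high_high"
  quadrant[sig & z < 0 & lag < 0] <- "low_low"
  quadrant[sig & z > 0 & lag < 0] <- "high_low"
  quadrant[sig & z < 0 & lag > 0] <- "low_high"
  hh <- which(quadrant == "high_high")
  clusters <- list()
  visited <- rep(FALSE, n)
  for (s in hh) {
    if (visited[s]) next
    comp <- integer(0); queue <- s; visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      nxt <- intersect(nb[[cur]], hh)
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
    clusters[[length(clusters) + 1L]] <- sort(comp)
  }
  list(local = data.frame(I_i = I, pseudo_p = pseudo_p, quadrant = quadrant),
       clusters = clusters, alpha = alpha)
}
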