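# Classical equality-of-variance tests, vectorised over features. Both are
# known to be highly sensitive to outliers; they serve as the comparison
# baselines for the moderated deviation test.

#' Rowwise F test for equality of two group variances
#'
#' F = s1^2 / s2^2 (unbiased variances, group order as in the labels) with a
#' two-sided p-value 2 * min(P(F <= f), P(F >= f)) on (n1 - 1, n2 - 1)
#' degrees of freedom, capped at 1. Swapping the groups maps F to 1/F and
#' leaves p unchanged.
#'
#' @param x M-value matrix or [methyl_matrix] (beta input is
#'   logit-transformed).
#' @param groups labels defining exactly two groups, each of size >= 2.
#' @return Data frame: `probe_id`, `statistic`, `p_value`, `adj_p_value`
#'   (BH), `var_group1`, `var_group2`.
#' @export
var_f_test <- function(x, groups) {
  x <- ensure_m_scale(x)
  groups <- as_groups(groups)
  if (nlevels(groups) != 2L) stop("the F test needs exactly two groups")
  nk <- table(groups)
  if (any(nk < 2L)) stop("each group needs at least 2 samples")
  gv <- group_variances(as_plain_matrix_any(x), groups)
  s1 <- gv[, 1L]; s2 <- gv[, 2L]
  f <- s1 / s2
  df1 <- nk[1L] - 1L; df2 <- nk[2L] - 1L
  p <- 2 * pmin(stats::pf(f, df1, df2),
                stats::pf(f, df1, df2, lower.tail = FALSE))
  p <- pmin(p, 1)
  zero_den <- s2 == 0 & s1 > 0
  if (any(zero_den)) {
    message(sum(zero_den), " feature(s) with zero denominator variance: p set to 0")
    p[zero_den] <- 0
  }
  p[s1 == 0 & s2 == 0] <- 1
  data.frame(probe_id = feature_ids(x), statistic = f, p_value = p,
             adj_p_value = bh_adjust(p), var_group1 = s1, var_group2 = s2,
             stringsAsFactors = FALSE)
}

#' Rowwise Bartlett test for homogeneity of K group variances
#'
#' The classical chi-square statistic
#' T = \[(N-K) ln s_p^2 - sum_k (n_k - 1) ln s_k^2\] / C with the usual
#' Bartlett correction C, referred to the upper tail of chi-square with K - 1
#' degrees of freedom (the statistic is non-negative and one-sided by
#' construction). Any group with zero variance sends T to infinity (p = 0).
#'
#' @param x M-value matrix or [methyl_matrix].
#' @param groups labels defining K >= 2 groups, each of size >= 2.
#' @return Data frame: `probe_id`, `statistic`, `p_value`, `adj_p_value`,
#'   and per-group variances `var_group1..K`.
#' @export
bartlett_rowwise <- function(x, groups) {
  x <- ensure_m_scale(x)
  groups <- as_groups(groups)
  K <- nlevels(groups)
  if (K < 2L) stop("Bartlett's test needs at least two groups")
  nk <- as.vector(table(groups))
  if (any(nk < 2L)) stop("each group needs at least 2 samples")
  N <- sum(nk)
  gv <- group_variances(as_plain_matrix_any(x), groups)
  sp2 <- drop(gv %*% (nk - 1L)) / (N - K)
  corr <- 1 + (sum(1 / (nk - 1L)) - 1 / (N - K)) / (3 * (K - 1L))
  lg <- log(gv)  # -Inf where a group variance is 0
  stat <- ((N - K) * log(sp2) - drop(lg %*% (nk - 1L))) / corr
  zero <- rowSums(gv == 0) > 0
  if (any(zero)) {
    message(sum(zero), " feature(s) with a zero group variance: statistic infinite, p = 0")
    stat[zero] <- Inf
  }
  p <- stats::pchisq(stat, df = K - 1L, lower.tail = FALSE)
  out <- data.frame(probe_id = feature_ids(x), statistic = stat, p_value = p,
                    adj_p_value = bh_adjust(p), stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[paste0("var_group", k)]] <- gv[, k]
  out
}
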