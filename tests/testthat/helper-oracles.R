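# Shared fixtures and independent oracles used across the test files.

# write a features x samples matrix to a temp TSV shaped like a 450k export
write_matrix_file <- function(values, ids = NULL, samples = NULL, sep = "\t",
                              path = tempfile(fileext = ".tsv")) {
  if (is.null(ids)) ids <- paste0("cg", sprintf("%05d", seq_len(nrow(values))))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  df <- data.frame(probe_id = ids, values, check.names = FALSE)
  colnames(df) <- c("probe_id", samples)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

write_sheet_file <- function(samples, groups, sep = "\t",
                             path = tempfile(fileext = ".tsv")) {
  utils::write.table(data.frame(sample_id = samples, group = groups),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# classical pooled-variance two-sample t (textbook formula), two-sided p
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# quadratic-time BH: q_i = suffix minimum of p_(j) * G / j over ranks j >= i
bh_bruteforce <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "first")
  cand <- p * n / r
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(1, cand[r >= r[i]])
  q
}

# bisection inverse of the (strictly decreasing) trigamma function
trigamma_inverse_bisect <- function(y, lo = 1e-6, hi = 1e6, tol = 1e-10) {
  for (i in 1:300) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < tol * mid) break
  }
  (lo + hi) / 2
}

# small deterministic simulated dataset reused by several files
tiny_sim <- function(seed = 7L, G = 300L, n = 8L, n_dv = 30L, n_out = 5L) {
  simulate_methylation(n_features = G, n1 = n, n2 = n, n_dv = n_dv,
                       n_outliers = n_out, seed = seed)
}
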