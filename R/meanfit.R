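# Companion differential-methylation (mean shift) test: moderated t on the
# M values themselves, with the mean-beta difference as the effect summary.

#' Test each feature for differential methylation (mean shift)
#'
#' The standard moderated-t analysis of M values: rowwise least squares on
#' the design, empirical Bayes squeezing of the residual variances, t-test of
#' the chosen contrast, BH adjustment. The effect is also summarised as the
#' difference in group mean beta values (`delta_beta`), the interpretable
#' proportion-scale shift used for significance filtering.
#'
#' @inheritParams varfit
#' @return An object of class `meanfit` with a per-feature `table`
#'   (`probe_id`, `effect` on the M scale, `t`, `df_total`, `p_value`,
#'   `adj_p_value`, `delta_beta`), the `prior`, and the resolved `spec`.
#'   Has `print`, `coef` and `as.data.frame` methods.
#' @seealso [significant_dm], [varfit]
#' @export
meanfit <- function(x, design = NULL, groups = NULL, contrast = NULL) {
  xm <- ensure_m_scale(x)
  spec <- resolve_design(xm, design, groups)
  if (!is.null(contrast)) spec$contrast <- contrast
  if (is.null(spec$contrast))
    stop("no contrast: supply 'contrast' for designs with more than two groups")
  fit <- row_lm(as_plain_matrix_any(xm), spec$design)
  prior <- fit_var_prior(fit$sigma2, fit$df_residual)
  mt <- moderated_t(fit, prior$d0, prior$s0_sq, spec$contrast)
  tab <- data.frame(
    probe_id = feature_ids(xm),
    effect = mt$effect,
    t = mt$t,
    df_total = mt$df_total,
    p_value = mt$p,
    adj_p_value = bh_adjust(mt$p),
    stringsAsFactors = FALSE
  )
  gl <- spec$groups
  if (!is.null(gl) && nlevels(gl) == 2L) {
    beta <- as_plain_matrix_any(m_to_beta(xm))
    b1 <- rowMeans(beta[, gl == levels(gl)[1L], drop = FALSE])
    b2 <- rowMeans(beta[, gl == levels(gl)[2L], drop = FALSE])
    tab$delta_beta <- b2 - b1
  }
  rownames(tab) <- NULL
  structure(list(table = tab, prior = prior, spec = spec,
                 df_residual = fit$df_residual,
                 n = c(features = nrow(tab), samples = ncol(xm))),
            class = "meanfit")
}

#' Select significantly differentially methylated features
#'
#' BH-adjusted p below `fdr` AND an absolute difference in group mean beta of
#' at least `min_delta_beta` (default 0.1, i.e. a 10-percentage-point shift in
#' methylation proportion).
#'
#' @param fit a [meanfit] object fitted with two groups.
#' @param fdr FDR cutoff.
#' @param min_delta_beta minimum absolute mean-beta difference.
#' @return The selected rows of the result table.
#' @export
significant_dm <- function(fit, fdr = 0.05, min_delta_beta = 0.1) {
  stopifnot(inherits(fit, "meanfit"))
  tab <- fit$table
  if (is.null(tab$delta_beta))
    stop("fit carries no delta_beta; refit with two groups")
  out <- tab[tab$adj_p_value < fdr & abs(tab$delta_beta) >= min_delta_beta, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.meanfit <- function(x, ...) {
  cat("Differential methylation fit (moderated t on M values)\n")
  cat(sprintf("  %d features, %d samples; residual df = %d\n",
              x$n["features"], x$n["samples"], x$df_residual))
  cat(sprintf("  variance prior: d0 = %s, s0^2 = %.4g\n",
              if (is.infinite(x$prior$d0)) "Inf" else
                sprintf("%.3g", x$prior$d0), x$prior$s0_sq))
  cat(sprintf("  features at BH FDR < 0.05: %d\n",
              sum(x$table$adj_p_value < 0.05)))
  invisible(x)
}

#' @export
coef.meanfit <- function(object, ...) {
  stats::setNames(object$table$effect, object$table$probe_id)
}

#' @export
as.data.frame.meanfit <- function(x, ...) x$table

#' Overlap between two feature rankings
#'
#' Cumulative size of the intersection of the top-r features of two rankings
#' (e.g. differential methylation vs differential variability), for
#' r = 1..top_n, together with the median overlap profile of randomly drawn
#' feature sets of the same sizes — the chance baseline, whose expected value
#' at rank r is approximately r^2 / universe size.
#'
#' @param ranked1,ranked2 character vectors of feature IDs, best first, drawn
#'   from the same universe.
#' @param top_n maximum rank considered.
#' @param universe the common feature universe (default: union of both lists).
#' @param n_random number of random pairs for the baseline.
#' @return Data frame with `rank`, `overlap`, `random_median`.
#' @export
ranking_overlap <- function(ranked1, ranked2, top_n,
                            universe = union(ranked1, ranked2),
                            n_random = 100L) {
  if (top_n > length(universe))
    stop("top_n exceeds the size of the feature universe")
  if (top_n > length(ranked1) || top_n > length(ranked2))
    stop("top_n exceeds the length of a ranking")
  cum_overlap <- function(a, b, n) {
    # overlap at rank r = |top_r(a) ∩ top_r(b)|
    pos_b <- match(a[seq_len(n)], b[seq_len(n)])
    counts <- integer(n)
    hit_rank <- pmax(seq_len(n), pos_b)       # rank at which the pair is joint
    hit_rank <- hit_rank[!is.na(hit_rank)]
    if (length(hit_rank))
      counts <- cumsum(tabulate(hit_rank, nbins = n))
    counts
  }
  obs <- cum_overlap(ranked1, ranked2, top_n)
  rnd <- replicate(n_random, {
    a <- sample(universe, top_n)
    b <- sample(universe, top_n)
    cum_overlap(a, b, top_n)
  })
  data.frame(rank = seq_len(top_n), overlap = obs,
             random_median = apply(rnd, 1L, stats::median))
}
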