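# Evaluation metrics for simulation batteries: type I error at nominal
# cutoffs, FDR/power at a BH cutoff, ROC points and outlier ranking curves.

#' Median type I error across replicate simulations
#'
#' For each replicate, the proportion of truly null features with raw p at or
#' below each nominal level; the median (and, for diagnostics, the mean and
#' standard deviation) across replicates is reported. Differentially variable
#' features are excluded from the tally; outlier-bearing null features are
#' counted — a robust test must hold its size in their presence.
#'
#' @param p_list list of raw p-value vectors, one per replicate (or a single
#'   vector / a G x R matrix).
#' @param is_null logical vector (or list, one per replicate) flagging the
#'   truly null features.
#' @param nominal nominal significance levels.
#' @return Data frame with `nominal`, `median_rate`, `mean_rate`, `sd_rate`,
#'   `n_reps`.
#' @export
type1_error <- function(p_list, is_null,
                        nominal = c(0.001, 0.01, 0.05, 0.1)) {
  if (is.matrix(p_list)) p_list <- asplit(p_list, 2L)
  if (is.numeric(p_list)) p_list <- list(p_list)
  if (length(p_list) == 0L) stop("empty simulation battery")
  if (!is.list(is_null)) is_null <- rep(list(is_null), length(p_list))
  rates <- vapply(seq_along(p_list), function(i) {
    p0 <- p_list[[i]][is_null[[i]]]
    vapply(nominal, function(a) mean(p0 <= a), numeric(1))
  }, numeric(length(nominal)))
  rates <- matrix(rates, nrow = length(nominal))
  data.frame(nominal = nominal,
             median_rate = apply(rates, 1L, stats::median),
             mean_rate = rowMeans(rates),
             sd_rate = apply(rates, 1L, stats::sd),
             n_reps = length(p_list))
}

#' Observed FDR and power at a BH cutoff
#'
#' Discoveries are features with BH-adjusted p at or below `fdr`. The
#' observed FDR is false discoveries over total discoveries (0 when there are
#' none); power is true discoveries over the number of truly differentially
#' variable features (`NA` when there are none).
#'
#' @param p raw p-values.
#' @param is_dv logical vector flagging the truly differentially variable
#'   features.
#' @param fdr nominal BH cutoff.
#' @param adj_p optional pre-computed adjusted p-values (BH is applied to `p`
#'   otherwise).
#' @return List with `observed_fdr`, `power`, `n_discoveries`.
#' @export
fdr_power <- function(p, is_dv, fdr = 0.05, adj_p = NULL) {
  if (is.null(adj_p)) adj_p <- bh_adjust(p)
  disc <- adj_p <= fdr
  nd <- sum(disc)
  fd <- sum(disc & !is_dv)
  td <- sum(disc & is_dv)
  list(observed_fdr = if (nd == 0L) 0 else fd / nd,
       power = if (sum(is_dv) == 0L) NA_real_ else td / sum(is_dv),
       n_discoveries = nd)
}

#' ROC points for a p-value ranking
#'
#' Features are ranked by ascending p (ties kept in stable input order);
#' cumulative true- and false-positive rates are reported at every rank.
#' Outlier-bearing null features count as negatives — a method fooled by
#' outliers pays for it in false positives.
#'
#' @param p raw p-values.
#' @param is_dv logical truth labels (positives).
#' @return Data frame with `fpr` and `tpr`, starting at (0, 0) and ending at
#'   (1, 1).
#' @export
roc_points <- function(p, is_dv) {
  if (!any(is_dv) || all(is_dv))
    stop("ROC needs at least one positive and one negative feature")
  o <- order(p)
  lab <- is_dv[o]
  data.frame(fpr = c(0, cumsum(!lab) / sum(!is_dv)),
             tpr = c(0, cumsum(lab) / sum(is_dv)))
}

#' Area under an ROC curve (trapezoid rule)
#'
#' @param roc a data frame from [roc_points].
#' @return Scalar area in \[0, 1\].
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Cumulative count of flagged features along a ranking
#'
#' How many outlier-bearing (or otherwise flagged) features appear among the
#' top r features ranked by ascending p, for r = 1..top_k. An outlier-robust
#' test keeps this curve near its chance diagonal; variance-based tests pile
#' the flagged features at the top.
#'
#' @param p raw p-values.
#' @param flagged logical vector of flagged features.
#' @param top_k maximum rank (<= number of features).
#' @return Integer vector of length `top_k`.
#' @export
outlier_rank_curve <- function(p, flagged, top_k) {
  if (top_k > length(p)) stop("top_k exceeds the number of features")
  cumsum(flagged[order(p)])[seq_len(top_k)]
}

#' Replicate type-I-error battery under the hierarchical null
#'
#' Simulates `n_reps` null data sets (optionally with injected outliers),
#' runs the requested variability tests on each, and tallies per-replicate
#' type I error rates over all null features at the nominal levels.
#' Per-replicate seeds are derived deterministically from `seed`.
#'
#' @param n_reps number of replicate simulations.
#' @param nominal nominal significance levels.
#' @param methods subset of `c("abs", "sq", "f", "bartlett")`.
#' @param n_features,n1,n2,d0,s0_sq,n_outliers passed to
#'   [simulate_methylation].
#' @param seed base seed.
#' @return Data frame with one row per (method, nominal level): median, mean
#'   and sd of the per-replicate error rate.
#' @export
type1_battery <- function(n_reps = 200L, nominal = c(0.001, 0.01, 0.05, 0.1),
                          methods = c("abs", "sq", "f", "bartlett"),
                          n_features = 10000, n1 = 50, n2 = 50,
                          d0 = 20, s0_sq = 0.64, n_outliers = 0, seed = 1L) {
  rates <- array(NA_real_,
                 dim = c(length(nominal), length(methods), n_reps),
                 dimnames = list(NULL, methods, NULL))
  for (r in seq_len(n_reps)) {
    sim <- simulate_methylation(
      n_features = n_features, n1 = n1, n2 = n2, d0 = d0, s0_sq = s0_sq,
      n_outliers = n_outliers, seed = derive_seed(seed, 0L, r))
    tests <- run_dv_tests(sim$M, sim$groups, methods)
    for (m in methods)
      rates[, m, r] <- vapply(nominal,
                              function(a) mean(tests[[m]]$p <= a), numeric(1))
  }
  out <- expand.grid(nominal = nominal, method = methods,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$median_rate <- mapply(function(a, m)
    stats::median(rates[match(a, nominal), m, ]), out$nominal, out$method)
  out$mean_rate <- mapply(function(a, m)
    mean(rates[match(a, nominal), m, ]), out$nominal, out$method)
  out$sd_rate <- mapply(function(a, m)
    stats::sd(rates[match(a, nominal), m, ]), out$nominal, out$method)
  out$n_reps <- n_reps
  out
}
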