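# Hierarchical simulation engine for methylation M values: scaled
# inverse chi-square feature variances, bimodal means at +/-2 mimicking
# methylated/unmethylated CpGs, optional single-sample outliers and
# inflated-variance (differentially variable) features.

#' Draw feature variances from a scaled inverse chi-square prior
#'
#' sigma^2 = d0 * s0_sq / X with X ~ chi-square(d0): the conjugate variance
#' prior of the hierarchical model, with mean d0 * s0_sq / (d0 - 2) for
#' d0 > 2 and concentrating at s0_sq as d0 grows.
#'
#' @param n number of draws.
#' @param d0 prior degrees of freedom (> 0).
#' @param s0_sq prior scale (> 0).
#' @return Vector of n positive variances.
#' @export
draw_variances <- function(n, d0 = 20, s0_sq = 0.64) {
  if (d0 <= 0 || s0_sq <= 0) stop("d0 and s0_sq must be positive")
  d0 * s0_sq / stats::rchisq(n, df = d0)
}

#' Simulate a two-group methylation M-value matrix with known truth
#'
#' Generates the hierarchical model used throughout the package's benchmarks:
#' each feature receives a true variance drawn from a scaled inverse
#' chi-square prior (`d0`, `s0_sq`), exactly half the features (at random)
#' are "methylated" with mean M = +2 and the rest "unmethylated" with mean
#' M = -2, and values are sampled normally around the feature mean. Three
#' optional perturbations, applied in this order:
#'
#' * differential variability: `n_dv` features get an independent group-2
#'   variance drawn with scale `dv_s0_sq` (so the population variance ratio
#'   is `dv_s0_sq / s0_sq`, e.g. 1.5 / 0.64 = 2.34);
#' * outliers: `n_outliers` features (disjoint from the DV set by default)
#'   have one random sample's value replaced by the maximum M value of the
#'   whole pre-injection matrix.
#'
#' @param n_features number of features G.
#' @param n1,n2 samples per group.
#' @param d0 prior degrees of freedom for the variance draw.
#' @param s0_sq prior scale for group 1 / null features.
#' @param n_dv number of differentially variable features (more variable in
#'   group 2).
#' @param dv_s0_sq prior scale of the group-2 variance of DV features.
#' @param n_outliers number of features receiving one outlier value.
#' @param prop_methylated proportion of features with mean +2 (the rest get
#'   -2); the count is exact, the assignment random.
#' @param mean_low,mean_high the two mean M values.
#' @param dv_outlier_overlap if `FALSE` (default) outlier features are drawn
#'   from the non-DV features.
#' @param seed optional integer seed (`set.seed` is called if given).
#' @return A list of class `methyl_sim`: `M` (a [methyl_matrix]), `groups`
#'   (factor `group1`/`group2`), and `truth` (data frame with `probe_id`,
#'   `is_dv`, `has_outlier`, `var_group1`, `var_group2`).
#' @examples
#' sim <- simulate_methylation(n_features = 500, n1 = 10, n2 = 10,
#'                             n_dv = 50, n_outliers = 10, seed = 42)
#' table(sim$truth$is_dv, sim$truth$has_outlier)
#' @export
simulate_methylation <- function(n_features = 10000, n1 = 50, n2 = 50,
                                 d0 = 20, s0_sq = 0.64,
                                 n_dv = 0, dv_s0_sq = 1.5,
                                 n_outliers = 0, prop_methylated = 0.5,
                                 mean_low = -2, mean_high = 2,
                                 dv_outlier_overlap = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- n_features
  if (n_dv + n_outliers > G && !dv_outlier_overlap)
    stop("n_dv + n_outliers exceeds n_features")
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")

  mu <- rep(mean_low, G)
  mu[sample.int(G, round(G * prop_methylated))] <- mean_high

  var1 <- draw_variances(G, d0, s0_sq)
  var2 <- var1
  dv_idx <- integer(0)
  if (n_dv > 0L) {
    dv_idx <- sample.int(G, n_dv)
    var2[dv_idx] <- draw_variances(n_dv, d0, dv_s0_sq)
  }
  vals <- cbind(
    matrix(stats::rnorm(G * n1), G, n1) * sqrt(var1),
    matrix(stats::rnorm(G * n2), G, n2) * sqrt(var2)
  ) + mu
  out_idx <- integer(0)
  if (n_outliers > 0L) {
    pool <- if (dv_outlier_overlap) seq_len(G) else setdiff(seq_len(G), dv_idx)
    if (length(pool) < n_outliers) stop("not enough features for outliers")
    out_idx <- pool[sample.int(length(pool), n_outliers)]
    mx <- max(vals)
    cols <- sample.int(n1 + n2, n_outliers, replace = TRUE)
    vals[cbind(out_idx, cols)] <- mx
  }
  groups <- factor(rep(c("group1", "group2"), c(n1, n2)),
                   levels = c("group1", "group2"))
  ids <- paste0("probe", seq_len(G))
  M <- methyl_matrix(vals, scale = "M", probe_ids = ids,
                     sample_ids = paste0("sample", seq_len(n1 + n2)))
  truth <- data.frame(probe_id = ids,
                      is_dv = seq_len(G) %in% dv_idx,
                      has_outlier = seq_len(G) %in% out_idx,
                      var_group1 = var1, var_group2 = var2,
                      stringsAsFactors = FALSE)
  structure(list(M = M, groups = groups, truth = truth,
                 config = list(n_features = G, n1 = n1, n2 = n2, d0 = d0,
                               s0_sq = s0_sq, n_dv = n_dv,
                               dv_s0_sq = dv_s0_sq, n_outliers = n_outliers,
                               prop_methylated = prop_methylated,
                               mean_low = mean_low, mean_high = mean_high,
                               seed = seed)),
            class = "methyl_sim")
}

#' @export
print.methyl_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "simulated methylation data: %d features x (%d + %d) samples\n",
    cfg$n_features, cfg$n1, cfg$n2))
  cat(sprintf("  variance prior d0 = %g, s0^2 = %g; DV features: %d (scale %g); outliers: %d\n",
              cfg$d0, cfg$s0_sq, cfg$n_dv, cfg$dv_s0_sq, cfg$n_outliers))
  invisible(x)
}

#' Inject single-sample outliers into a matrix
#'
#' For each selected feature, one uniformly chosen sample's value is replaced
#' by the maximum value of the entire input matrix (computed before any
#' substitution). Exactly one cell changes per flagged feature.
#'
#' @param x numeric matrix or [methyl_matrix].
#' @param n_outliers number of features to perturb (chosen uniformly without
#'   replacement when `features` is `NULL`).
#' @param features optional explicit feature indices.
#' @return List with `values` (perturbed matrix, same class as input) and
#'   `features` (indices flagged).
#' @export
inject_outliers <- function(x, n_outliers, features = NULL) {
  vals <- as_plain_matrix_any(x)
  G <- nrow(vals)
  if (is.null(features)) {
    if (n_outliers > G) stop("n_outliers exceeds the number of features")
    features <- sample.int(G, n_outliers)
  }
  mx <- max(vals)
  cols <- sample.int(ncol(vals), length(features), replace = TRUE)
  vals[cbind(features, cols)] <- mx
  if (inherits(x, "methyl_matrix"))
    vals <- methyl_matrix(vals, scale = methyl_scale(x),
                          probe_ids = rownames(x), sample_ids = colnames(x))
  list(values = vals, features = sort(features))
}

#' Resample a null data set from a single-condition matrix
#'
#' Draws `n_features` features and `n1 + n2` samples without replacement and
#' splits the samples at random into two pseudo-groups. Features keep their
#' joint sample columns, so any correlation structure between features is
#' preserved; since all samples come from one condition, the split is null by
#' construction.
#'
#' @param x matrix or [methyl_matrix] of a single biological condition.
#' @param n_features number of features to draw.
#' @param n1,n2 pseudo-group sizes.
#' @return List with `M` (the resampled [methyl_matrix] or matrix) and
#'   `groups` (factor of pseudo-group labels in column order).
#' @export
resample_split <- function(x, n_features, n1, n2) {
  vals <- as_plain_matrix_any(x)
  if (n_features > nrow(vals)) stop("not enough features to resample")
  if (n1 + n2 > ncol(vals)) stop("not enough samples to resample")
  fi <- sample.int(nrow(vals), n_features)
  si <- sample.int(ncol(vals), n1 + n2)
  out <- vals[fi, si, drop = FALSE]
  grp <- factor(sample(rep(c("group1", "group2"), c(n1, n2))),
                levels = c("group1", "group2"))
  if (inherits(x, "methyl_matrix"))
    out <- methyl_matrix(out, scale = methyl_scale(x))
  list(M = out, groups = grp)
}

# deterministic per-dataset seed derived from (base seed, scenario, rep);
# kept strictly below 2^31
derive_seed <- function(base, i = 0L, j = 0L) {
  as.integer((as.double(base) * 48271 + i * 1000003 + j * 7919) %% 2147483629)
}

# p-values (raw and BH-adjusted) of the requested tests on one dataset
run_dv_tests <- function(M, groups,
                         methods = c("abs", "sq", "f", "bartlett")) {
  out <- list()
  vals <- as_plain_matrix_any(M)
  for (mth in methods) {
    res <- switch(mth,
      abs = varfit(vals, groups = groups, type = "abs")$table,
      sq = varfit(vals, groups = groups, type = "sq")$table,
      f = var_f_test(vals, groups),
      bartlett = bartlett_rowwise(vals, groups))
    out[[mth]] <- list(p = res$p_value, adj_p = res$adj_p_value)
  }
  out
}

#' Power and FDR of the variability tests across sample sizes
#'
#' For each per-group sample size, simulates `n_reps` data sets under the
#' hierarchical model with `n_dv` differentially variable features and
#' `n_outliers` outliers, runs the requested tests, and records the observed
#' false discovery rate and power at the BH `fdr` cutoff, averaged over
#' replicates. Per-dataset seeds are derived deterministically from `seed`,
#' the size and the replicate index.
#'
#' @param sizes integer vector of per-group sample sizes.
#' @param n_reps replicates per size.
#' @param methods subset of `c("abs", "sq", "f", "bartlett")`.
#' @param fdr nominal BH FDR cutoff.
#' @param n_features,n_dv,n_outliers,d0,s0_sq,dv_s0_sq passed to
#'   [simulate_methylation].
#' @param seed base seed for the deterministic per-dataset streams.
#' @return Data frame with one row per (size, method): mean `power`, mean
#'   observed `fdr`, their across-replicate standard deviations, the mean
#'   discovery count and the replicate count.
#' @export
sample_size_sweep <- function(sizes, n_reps = 50L,
                              methods = c("abs", "sq", "f", "bartlett"),
                              fdr = 0.05, n_features = 10000,
                              n_dv = 1000, n_outliers = 200,
                              d0 = 20, s0_sq = 0.64, dv_s0_sq = 1.5,
                              seed = 1L) {
  rows <- list()
  for (n in sizes) {
    acc <- lapply(methods, function(m)
      list(power = numeric(0), fdr = numeric(0), ndisc = numeric(0)))
    names(acc) <- methods
    for (r in seq_len(n_reps)) {
      sim <- simulate_methylation(
        n_features = n_features, n1 = n, n2 = n, d0 = d0, s0_sq = s0_sq,
        n_dv = n_dv, dv_s0_sq = dv_s0_sq, n_outliers = n_outliers,
        seed = derive_seed(seed, n, r))
      tests <- run_dv_tests(sim$M, sim$groups, methods)
      for (m in methods) {
        fp <- fdr_power(tests[[m]]$p, sim$truth$is_dv, fdr = fdr)
        acc[[m]]$power <- c(acc[[m]]$power, fp$power)
        acc[[m]]$fdr <- c(acc[[m]]$fdr, fp$observed_fdr)
        acc[[m]]$ndisc <- c(acc[[m]]$ndisc, fp$n_discoveries)
      }
    }
    for (m in methods)
      rows[[length(rows) + 1L]] <- data.frame(
        n_per_group = n, method = m,
        power = mean(acc[[m]]$power), fdr = mean(acc[[m]]$fdr),
        sd_power = stats::sd(acc[[m]]$power), sd_fdr = stats::sd(acc[[m]]$fdr),
        mean_discoveries = mean(acc[[m]]$ndisc), n_reps = n_reps,
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
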