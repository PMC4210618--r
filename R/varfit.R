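# The differential-variability test: a moderated Levene-type regression of
# leverage-corrected deviations from the fitted group means.

#' Leverage-corrected deviations from the fitted means
#'
#' Residuals of the mean model are converted to non-negative deviation scores
#' z_gj = L_j * |r_gj| (absolute) or L_j * r_gj^2 (squared), where
#' L_j = 1 / (1 + h_j) and h_j is the j-th hat-matrix diagonal of the mean
#' model. For a group-means design h_j = 1/n_k, so L_j = n_k / (n_k + 1):
#' deviations in small groups are damped to offset the extra shrinkage of
#' residuals towards an estimated mean. Samples with h_j = 1 (a group of one)
#' are an error — a single observation carries no variability information.
#'
#' @param x numeric matrix of M values (features x samples), or a
#'   [methyl_matrix].
#' @param design a [design_spec], design matrix, or `groups` labels.
#' @param type `"abs"` for absolute deviations (recommended) or `"sq"` for
#'   squared deviations.
#' @param groups group labels, if `design` is not given.
#' @return A list with `z` (the deviation matrix), `type`, `leverage` and the
#'   resolved `spec`.
#' @export
compute_deviations <- function(x, design = NULL, groups = NULL,
                               type = c("abs", "sq")) {
  type <- match.arg(type)
  x <- ensure_m_scale(x)
  spec <- resolve_design(x, design, groups)
  fit <- row_lm(as_plain_matrix_any(x), spec$design)
  h <- fit$hat
  if (any(h >= 1 - 1e-8))
    stop("a sample with leverage 1 (e.g. a group of size 1) admits no ",
         "variability estimate")
  lev <- 1 / (1 + h)
  r <- fit$residuals
  z <- if (type == "abs") abs(r) else r^2
  z <- sweep(z, 2L, lev, `*`)
  list(z = z, type = type, leverage = lev, spec = spec)
}

as_plain_matrix_any <- function(x) {
  if (inherits(x, "methyl_matrix")) as_plain_matrix(x) else as.matrix(x)
}

#' Test each feature for differential variability
#'
#' The core fitting function. For every feature it computes leverage-corrected
#' absolute (or squared) deviations of the M values from the fitted group
#' means, regresses those deviations on the same design, and tests the chosen
#' contrast with empirical Bayes moderated t-statistics: features with
#' deviations consistently larger in one group are reported as differentially
#' variable. Working on mean deviations rather than variances directly makes
#' the test robust to single-sample outliers, which inflate a variance
#' quadratically but an average absolute deviation only by 1/n of the
#' outlier's magnitude.
#'
#' Beta-scale input is logit-transformed to M values first. Any full-rank
#' design is accepted; with two groups the default contrast is group 2 minus
#' group 1, so positive effects mean "more variable in group 2".
#'
#' @param x a [methyl_matrix] (beta or M scale) or plain numeric matrix of M
#'   values, features x samples.
#' @param design a [design_spec], a design matrix, or `NULL` if `groups` is
#'   given.
#' @param groups group labels (one per sample), used when `design` is `NULL`
#'   and for the per-group variance summaries.
#' @param type `"abs"` (absolute deviations, recommended) or `"sq"` (squared).
#' @param contrast optional contrast vector overriding the design default.
#' @return An object of class `varfit`: a list with `table` (per-feature data
#'   frame: `probe_id`, `effect`, `t`, `df_total`, `p_value`, `adj_p_value`,
#'   per-group variances and `var_ratio`), `prior` (`d0`, `s0_sq`), `type`,
#'   `deviations`, `spec` and `n`. Has `print`, `summary`, `coef`, `plot` and
#'   `residuals` methods; `as.data.frame` extracts the table.
#' @seealso [significant_dv] for the FDR + variability-ratio filter,
#'   [meanfit] for the companion differential-methylation test.
#' @examples
#' sim <- simulate_methylation(n_features = 200, n1 = 10, n2 = 10,
#'                             n_dv = 20, seed = 1)
#' fit <- varfit(sim$M, groups = sim$groups)
#' head(as.data.frame(fit))
#' @export
varfit <- function(x, design = NULL, groups = NULL, type = c("abs", "sq"),
                   contrast = NULL) {
  type <- match.arg(type)
  xm <- ensure_m_scale(x)
  dev <- compute_deviations(xm, design, groups, type = type)
  spec <- dev$spec
  if (!is.null(contrast)) spec$contrast <- contrast
  if (is.null(spec$contrast))
    stop("no contrast: supply 'contrast' (or 'coef' in design_spec) for ",
         "designs with more than two groups")
  fit <- row_lm(dev$z, spec$design)
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
  if (!is.null(gl)) {
    gv <- group_variances(as_plain_matrix_any(xm), gl)
    for (k in seq_len(ncol(gv)))
      tab[[paste0("var_group", k)]] <- gv[, k]
    if (ncol(gv) == 2L) {
      vr <- pmax(gv[, 1L], gv[, 2L]) / pmin(gv[, 1L], gv[, 2L])
      vr[gv[, 1L] == 0 & gv[, 2L] == 0] <- 1
      tab$var_ratio <- vr
    }
  }
  rownames(tab) <- NULL
  structure(list(table = tab, prior = prior, type = type,
                 deviations = dev$z, leverage = dev$leverage, spec = spec,
                 df_residual = fit$df_residual,
                 n = c(features = nrow(tab), samples = ncol(xm))),
            class = "varfit")
}

feature_ids <- function(x) {
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("probe", seq_len(nrow(x)))
  ids
}

# coerce labels to a factor, preserving an existing level order
as_groups <- function(groups) {
  if (is.factor(groups)) droplevels(groups)
  else factor(groups, levels = unique(as.character(groups)))
}

# unbiased per-group sample variances, rowwise
group_variances <- function(x, groups) {
  groups <- as_groups(groups)
  K <- nlevels(groups)
  out <- matrix(NA_real_, nrow(x), K,
                dimnames = list(NULL, levels(groups)))
  for (k in seq_len(K)) {
    cols <- which(groups == levels(groups)[k])
    n <- length(cols)
    mu <- rowMeans(x[, cols, drop = FALSE])
    out[, k] <- (rowSums(x[, cols, drop = FALSE]^2) - n * mu^2) / (n - 1)
  }
  pmax(out, 0)  # guard tiny negative values from cancellation
}

#' Per-feature variability ratio between two groups
#'
#' Ratio of the larger to the smaller unbiased group variance of the M values,
#' with the more variable group recorded as the direction. Used as the
#' effect-size filter for calling significant differential variability
#' (conventionally >= 5). Features with both variances zero get ratio 1.
#'
#' @param x M-value matrix or [methyl_matrix].
#' @param groups labels defining exactly two groups, each of size >= 2.
#' @return Data frame with `var_group1`, `var_group2`, `var_ratio` and
#'   `direction` (which group is more variable; `"tie"` on exact equality).
#' @export
variability_ratio <- function(x, groups) {
  x <- ensure_m_scale(x)
  groups <- as_groups(groups)
  if (nlevels(groups) != 2L)
    stop("variability_ratio needs exactly two groups")
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 samples")
  gv <- group_variances(as_plain_matrix_any(x), groups)
  vr <- pmax(gv[, 1L], gv[, 2L]) / pmin(gv[, 1L], gv[, 2L])
  both0 <- gv[, 1L] == 0 & gv[, 2L] == 0
  vr[both0] <- 1
  if (any(both0))
    message(sum(both0), " feature(s) with zero variance in both groups: ratio set to 1")
  dir <- ifelse(gv[, 2L] > gv[, 1L], levels(groups)[2L],
                ifelse(gv[, 1L] > gv[, 2L], levels(groups)[1L], "tie"))
  data.frame(probe_id = feature_ids(x), var_group1 = gv[, 1L],
             var_group2 = gv[, 2L], var_ratio = vr, direction = dir,
             stringsAsFactors = FALSE)
}

#' Select significantly differentially variable features
#'
#' Applies the two-part rule used for calling differential variability in
#' practice: BH-adjusted p below `fdr` AND a variability ratio of at least
#' `ratio` between the group variances. Reports how many selected features are
#' more variable in each group.
#'
#' @param fit a [varfit] object (fitted with `groups` so per-group variances
#'   are available).
#' @param fdr FDR cutoff (default 0.05).
#' @param ratio minimum variability ratio (default 5).
#' @return The selected rows of the result table, with a `direction` column;
#'   direction counts are attached as attribute `"counts"` and printed.
#' @export
significant_dv <- function(fit, fdr = 0.05, ratio = 5) {
  stopifnot(inherits(fit, "varfit"))
  tab <- fit$table
  if (is.null(tab$var_ratio))
    stop("fit carries no per-group variances; refit with 'groups'")
  sel <- tab$adj_p_value < fdr & tab$var_ratio >= ratio
  out <- tab[sel, , drop = FALSE]
  lv <- levels(fit$spec$groups)
  out$direction <- ifelse(out$var_group2 > out$var_group1, lv[2L], lv[1L])
  counts <- c(table(factor(out$direction, levels = lv)))
  attr(out, "counts") <- counts
  rownames(out) <- NULL
  out
}

#' @export
print.varfit <- function(x, ...) {
  cat(sprintf("Differential variability fit (%s deviations)\n",
              if (x$type == "abs") "absolute" else "squared"))
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
summary.varfit <- function(object, n = 10L, sort_by = "p_value", ...) {
  tab <- object$table
  tab <- tab[order(tab[[sort_by]]), , drop = FALSE]
  out <- list(fit = object, top = utils::head(tab, n))
  class(out) <- "summary.varfit"
  out
}

#' @export
print.summary.varfit <- function(x, ...) {
  print(x$fit)
  cat("\nTop features by p-value:\n")
  print(x$top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.varfit <- function(object, ...) {
  stats::setNames(object$table$effect, object$table$probe_id)
}

#' @export
residuals.varfit <- function(object, ...) object$deviations

#' @export
as.data.frame.varfit <- function(x, ...) x$table

#' Volcano-style plot of a variability fit
#'
#' Plots the deviation-difference effect against -log10 adjusted p, with the
#' FDR cutoff marked; the standard first look at a differential-variability
#' analysis.
#'
#' @param x a [varfit].
#' @param fdr cutoff drawn as a horizontal line and used for highlighting.
#' @param ... passed to [graphics::plot].
#' @export
plot.varfit <- function(x, fdr = 0.05, ...) {
  tab <- x$table
  sig <- tab$adj_p_value < fdr
  graphics::plot(tab$effect, -log10(pmax(tab$adj_p_value, 1e-300)),
                 pch = 16, cex = 0.4,
                 col = ifelse(sig, "firebrick", "grey40"),
                 xlab = "difference in mean deviation (M scale)",
                 ylab = expression(-log[10] ~ "BH adjusted p"), ...)
  graphics::abline(h = -log10(fdr), lty = 2)
  invisible(x)
}
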